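id,name
1,whole milk
2,"low-fat, skimmed and fortified milks"
3,cheeses
4,yogurts
5,butter
6,spreading fats and oils
7,fresh meat
8,processed meats
9,poultry
10,"fish, fish products and fish dishes"
11,eggs and egg dishes
12,bread and rolls
13,ready-to-eat breakfast cereals
14,"rice, pasta and grains"
15,"potatoes (boiled, baked and mashed)"
16,"potatoes (chipped, fried and roasted)"
17,vegetables
18,fruit
19,biscuits
20,"cakes, pastries and buns"
21,chocolate confectionery
22,sugar confectionery
23,savoury snacks
24,desserts and ice-cream
25,non-alcoholic beverages
26,other foods
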