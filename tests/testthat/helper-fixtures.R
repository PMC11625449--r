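# Shared fixtures, built in code. The small cohort is cached per test run.

fx_test_cache <- new.env(parent = emptyenv())

small_cohort <- function(n = 120, seed = 7) {
  key <- sprintf("cohort_%d_%d", n, seed)
  if (is.null(fx_test_cache[[key]])) {
    comp <- generate_composition(seed = seed)
    co <- generate_cohort(cohort_spec(n_children = n, seed = seed), comp)
    fx_test_cache[[key]] <- list(
      composition = comp, roster = co$roster, diaries = co$diaries,
      intakes = compute_intakes(co$diaries, comp, co$roster)
    )
  }
  fx_test_cache[[key]]
}

# A minimal hand-built composition table (categories from the default
# taxonomy) for arithmetic-level tests.
tiny_composition <- function() {
  zero <- function(code, desc, cat, fat, sfa, mufa, pufa, prot, carb) {
    tibble::tibble(
      food_code = code, description = desc, category = cat,
      energy_kcal = 9 * fat + 4 * prot + 3.75 * carb,
      total_fat_g = fat, sfa_g = sfa, mufa_g = mufa, pufa_g = pufa,
      trans_g = 0, n6_g = pufa, n3_g = 0, ala_g = 0, epa_g = 0, dha_g = 0,
      protein_g = prot, carbohydrate_g = carb, total_sugar_g = 0,
      vitamin_e_mg = 0
    )
  }
  dplyr::bind_rows(
    zero("MILK", "whole milk", "whole milk", 3.5, 2.2, 1.0, 0.3, 3.3, 4.7),
    zero("MILK_LF", "low-fat milk", "low-fat, skimmed and fortified milks",
      1.5, 0.9, 0.4, 0.2, 3.5, 4.8),
    zero("BREAD", "white bread", "bread and rolls", 1.4, 0.4, 0.4, 0.6, 8.5, 46),
    zero("BUTTER", "butter", "butter", 82, 52, 21, 9, 0.6, 0.6),
    zero("APPLE", "apple, raw", "fruit", 0.1, 0.02, 0.03, 0.05, 0.4, 11.8)
  )
}

tiny_diary <- function(participant = "C01") {
  tibble::tibble(
    participant_id = participant,
    day = 1:4,
    is_weekend = c(FALSE, FALSE, FALSE, TRUE),
    food_code = "MILK",
    amount_g = 200
  )
}
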