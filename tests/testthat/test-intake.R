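test_that("mean daily intake matches hand arithmetic for a one-food diary", {
  # 4 days, one 200 g serving of milk at 3.5 g fat/100 g: 4*200*3.5/100/4 = 7 g/d
  ix <- mean_daily_intake(tiny_diary(), tiny_composition())
  expect_equal(ix$daily[["total_fat_g"]], 7.0)
  expect_equal(ix$daily[["sfa_g"]], 4.4)
  expect_equal(ix$n_days, 4L)
})

test_that("an empty diary yields an all-zero intake with a warning", {
  empty <- tiny_diary()[0, ]
  expect_warning(ix <- mean_daily_intake(empty, tiny_composition()), "empty")
  expect_true(all(ix$daily == 0))
})

test_that("category subtotals partition the daily totals exactly", {
  sc <- small_cohort()
  nf <- nutrient_fields()
  sums <- sc$intakes$by_category |>
    dplyr::summarise(dplyr::across(dplyr::all_of(nf), sum), .by = "participant_id") |>
    dplyr::arrange(participant_id)
  daily <- dplyr::arrange(sc$intakes$daily, participant_id)
  for (col in nf) {
    expect_equal(sums[[col]], daily[[col]], tolerance = 1e-9)
  }
})

test_that("percent_energy follows the factor arithmetic and rejects zero energy", {
  expect_equal(percent_energy(50, 1800, 9), 25)
  expect_equal(percent_energy(0, 1800, 9), 0)
  expect_equal(percent_energy(200, 1800, 9), 100)
  expect_error(percent_energy(10, 0, 9), class = "fx_undefined_pct_te")
})

test_that("category contributions behave over hand-computable cohorts", {
  comp <- tiny_composition()
  # two participants, category SFA {2,4} g/d of totals {10,10} -> 30 %
  diaries <- dplyr::bind_rows(
    tibble::tibble(participant_id = "A", day = 1L, is_weekend = TRUE,
      food_code = c("MILK", "BREAD"), amount_g = c(2 / 2.2 * 100, 8 / 0.4 * 100)),
    tibble::tibble(participant_id = "B", day = 1L, is_weekend = TRUE,
      food_code = c("MILK", "BREAD"), amount_g = c(4 / 2.2 * 100, 6 / 0.4 * 100))
  )
  ix <- compute_intakes(diaries, comp)
  cc <- category_contribution(ix, "sfa")
  expect_equal(cc$contribution_pct[cc$category == "whole milk"], 30)
  expect_equal(sum(cc$contribution_pct), 100)

  # a single consumed category takes 100 %
  solo <- compute_intakes(tiny_diary(), comp)
  cs <- category_contribution(solo, "sfa")
  expect_equal(cs$contribution_pct[cs$category == "whole milk"], 100)
  expect_true(all(cs$contribution_pct[cs$category != "whole milk"] == 0))
})

test_that("both contribution methods agree when all participants share one diet", {
  comp <- tiny_composition()
  diaries <- dplyr::bind_rows(lapply(c("A", "B", "C"), function(id) {
    d <- tiny_diary(id)
    d$food_code <- c("MILK", "BREAD", "BUTTER", "MILK")
    d
  }))
  ix <- compute_intakes(diaries, comp)
  pp <- category_contribution(ix, "total_fat", method = "population_proportion")
  mr <- category_contribution(ix, "total_fat", method = "mean_of_ratios")
  expect_equal(pp$contribution_pct, mr$contribution_pct, tolerance = 1e-12)
})

test_that("doubling amounts doubles g/d but leaves %TE and contributions unchanged", {
  sc <- small_cohort()
  doubled <- sc$diaries
  doubled$amount_g <- doubled$amount_g * 2
  ix2 <- compute_intakes(doubled, sc$composition, sc$roster)
  expect_equal(ix2$daily$sfa_g, sc$intakes$daily$sfa_g * 2, tolerance = 1e-12)
  expect_equal(ix2$daily$sfa_pct_te, sc$intakes$daily$sfa_pct_te, tolerance = 1e-12)
  expect_equal(
    category_contribution(ix2, "sfa")$contribution_pct,
    category_contribution(sc$intakes, "sfa")$contribution_pct,
    tolerance = 1e-12
  )
})

test_that("contribution of an unconsumed nutrient errors as undefined", {
  ix <- compute_intakes(tiny_diary(), tiny_composition())
  expect_error(category_contribution(ix, "epa"), class = "fx_undefined_contribution")
})
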