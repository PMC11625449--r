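test_that("default recommendation set carries the published thresholds", {
  recs <- default_recommendation_set()
  sfa <- recs[recs$nutrient == "sfa", ]
  expect_equal(sfa$bound, "upper"); expect_equal(sfa$value, 10)
  pufa <- recs[recs$nutrient == "pufa", ]
  expect_equal(pufa$bound, "lower"); expect_equal(pufa$value, 6)
  omega <- recs[recs$nutrient == "epa_dha", ]
  expect_equal(omega$unit, "mg_d"); expect_equal(omega$value, 250)
  # the unsourced cut-offs are flagged as implementer defaults
  expect_true(all(recs$implementer_default[recs$nutrient %in%
    c("total_fat", "mufa", "trans")]))
})

make_intakes_with_sfa <- function(sfa_pct) {
  n <- length(sfa_pct)
  ids <- sprintf("P%02d", seq_len(n))
  energy <- rep(1800, n)
  daily <- tibble::tibble(participant_id = ids, energy_kcal = energy)
  for (col in setdiff(nutrient_fields(), "energy_kcal")) daily[[col]] <- 0
  daily$sfa_g <- sfa_pct / 100 * energy / 9
  daily$epa_dha_mg <- 0
  for (nm in names(energy_factors())) {
    daily[[paste0(nm, "_pct_te")]] <- percent_energy(
      daily[[paste0(nm, "_g")]], energy, energy_factors()[[nm]]
    )
  }
  structure(list(
    daily = daily, by_category = tibble::tibble(),
    categories = character(), weights = setNames(rep(1, n), ids),
    factors = energy_factors()
  ), class = "fx_intakes")
}

test_that("compliance is the (weighted) share meeting each inclusive bound", {
  ix <- make_intakes_with_sfa(c(8, 9, 11, 12))
  res <- assess_compliance(ix)
  expect_equal(res$percent_compliant[res$nutrient == "sfa"], 50)

  # boundary inclusivity: exactly 10 %TE complies with "at most 10 %TE"
  ix10 <- make_intakes_with_sfa(c(10, 10, 10))
  res10 <- assess_compliance(ix10)
  expect_equal(res10$percent_compliant[res10$nutrient == "sfa"], 100)

  # weighting: upweighting the compliant children raises the rate
  w <- setNames(c(3, 3, 1, 1), ix$daily$participant_id)
  resw <- assess_compliance(ix, weights = w)
  expect_equal(resw$percent_compliant[resw$nutrient == "sfa"], 75)
  # equal weights reduce to the unweighted proportion exactly
  we <- setNames(rep(2.5, 4), ix$daily$participant_id)
  rese <- assess_compliance(ix, weights = we)
  expect_equal(rese$percent_compliant, res$percent_compliant)
})

test_that("lowering SFA can only improve SFA compliance (monotonicity)", {
  set.seed(3)
  for (i in 1:10) {
    base <- runif(30, 6, 18)
    lower <- base - runif(30, 0, 4)
    c_base <- assess_compliance(make_intakes_with_sfa(base))
    c_low <- assess_compliance(make_intakes_with_sfa(pmax(lower, 0)))
    expect_gte(
      c_low$percent_compliant[c_low$nutrient == "sfa"],
      c_base$percent_compliant[c_base$nutrient == "sfa"]
    )
  }
})

test_that("a recommendation for an unknown nutrient is a configuration error", {
  ix <- make_intakes_with_sfa(c(8, 9, 10))
  recs <- tibble::tibble(nutrient = "selenium", unit = "mg_d", bound = "lower",
    value = 1, source = "x", implementer_default = TRUE)
  expect_error(assess_compliance(ix, recs), class = "fx_config_error")
})

test_that("recommendation sets round-trip through YAML", {
  recs <- default_recommendation_set()
  path <- withr::local_tempfile(fileext = ".yaml")
  write_recommendations(recs, path)
  back <- read_recommendations(path)
  expect_equal(as.data.frame(back), as.data.frame(recs))
})
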