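test_that("paired t matches hand computation and the textbook closed form", {
  # baseline (1,2,4) vs model (2,3,3): d = (1,1,-1), t = 0.5 on 2 df
  tt <- paired_t(c(1, 2, 4), c(2, 3, 3))
  expect_equal(tt$t, 0.5)
  expect_equal(tt$df, 2)

  set.seed(11)
  for (i in 1:25) {
    n <- sample(3:50, 1)
    b <- rnorm(n); m <- rnorm(n, 0.3)
    d <- m - b
    t_closed <- mean(d) / (sd(d) / sqrt(n))
    p_closed <- 2 * stats::pt(abs(t_closed), n - 1, lower.tail = FALSE)
    tt <- paired_t(b, m)
    expect_equal(tt$t, t_closed, tolerance = 1e-12)
    expect_equal(tt$p, p_closed, tolerance = 1e-12)
    # antisymmetry
    rev <- paired_t(m, b)
    expect_equal(rev$t, -tt$t, tolerance = 1e-12)
    expect_equal(rev$mean_delta, -tt$mean_delta, tolerance = 1e-12)
  }
})

test_that("degenerate paired comparisons are flagged rather than NaN", {
  same <- paired_t(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$note, "no-change")
  expect_equal(same$p, 1)
  shifted <- paired_t(c(1, 2, 3), c(2, 3, 4))
  expect_equal(shifted$note, "zero-variance")
  expect_equal(shifted$p, 0)
})

test_that("Bonferroni adjustment is min(1, p*m) and agrees with p.adjust", {
  expect_equal(bonferroni_adjust(0.01, m = 5), 0.05)
  expect_equal(bonferroni_adjust(0.5, m = 10), 1)
  expect_equal(bonferroni_adjust(c(0.2, 0.9)), p.adjust(c(0.2, 0.9), "bonferroni"))
  expect_equal(bonferroni_adjust(0.3, m = 1), 0.3)
  expect_error(bonferroni_adjust(1.2), class = "fx_validation_error")
  expect_error(bonferroni_adjust(c(0.1, 0.2), m = 1), class = "fx_config_error")
})

test_that("relative contribution change handles removal, growth and edge cases", {
  expect_equal(contribution_pct_change(7, 0)$pct_change, -100)
  expect_equal(contribution_pct_change(2, 5)$pct_change, 150)
  expect_equal(contribution_pct_change(3, 3)$pct_change, 0)
  new_cat <- contribution_pct_change(0, 4)
  expect_true(is.na(new_cat$pct_change))
  expect_equal(new_cat$status, "new")
  expect_equal(contribution_pct_change(0, 0)$status, "absent")
})

test_that("relative change must be computed on unrounded proportions", {
  # rounding first gives a visibly different answer; the package divides
  # unrounded values
  b <- 0.181; m <- 0.655
  exact <- contribution_pct_change(b * 100, m * 100)$pct_change
  rounded <- (round(m, 1) - round(b, 1)) / round(b, 1) * 100
  expect_equal(exact, (m - b) / b * 100)
  expect_false(isTRUE(all.equal(exact, rounded)))
})

test_that("comparison table is all-zero when the model equals baseline", {
  sc <- small_cohort()
  tab <- build_comparison_table(sc$intakes, sc$intakes)
  expect_true(all(tab$delta == 0))
  expect_true(all(tab$note == "no-change"))
  expect_true(all(tab$p_adj == 1))
})

test_that("dairy and spread exchanges move SFA down and PUFA up", {
  sc <- small_cohort()
  rules <- default_rule_set(sc$composition)
  ex <- apply_exchanges(sc$diaries, rules, sc$composition)
  mx <- compute_intakes(ex$diaries, sc$composition, sc$roster)
  tab <- build_comparison_table(sc$intakes, mx)
  pick <- function(nu, un) tab$delta[tab$nutrient == nu & tab$unit == un]
  expect_lt(pick("sfa", "%TE"), 0)
  expect_lt(pick("total_fat", "%TE"), 0)
  expect_gt(pick("pufa", "%TE"), 0)   # the replacement spread is PUFA-rich
  expect_gt(pick("vitamin_e", "mg/d"), 0)
  expect_gt(pick("protein", "g/d"), 0)  # leaner cuts carry more protein
  expect_lt(pick("energy", "kcal/d"), 0)
})

test_that("misaligned arms raise an alignment error", {
  sc <- small_cohort()
  other <- sc$intakes
  other$daily <- other$daily[-1, ]
  expect_error(build_comparison_table(sc$intakes, other),
    class = "fx_alignment_error")
})

test_that("sex-stratified comparison emits one block per stratum", {
  sc <- small_cohort()
  groups <- setNames(sc$roster$sex, sc$roster$participant_id)
  tab <- build_comparison_table(sc$intakes, sc$intakes, groups = groups)
  expect_setequal(unique(tab$stratum), c("all", "female", "male"))
})
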