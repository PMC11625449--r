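# Independent oracles: stats::aov for the ANOVA F, and a Scheffe decision
# computed through the p-value route (F-scaled contrast) rather than the
# critical-value route the implementation uses.

aov_f <- function(value, group) {
  fit <- summary(stats::aov(value ~ factor(group)))[[1]]
  c(f = fit$`F value`[1], p = fit$`Pr(>F)`[1], msw = fit$`Mean Sq`[2])
}

scheffe_sig_oracle <- function(value, group, a, b, alpha = 0.05) {
  group <- factor(group)
  k <- nlevels(group)
  n <- length(value)
  o <- aov_f(value, group)
  na <- sum(group == a); nb <- sum(group == b)
  d <- mean(value[group == a]) - mean(value[group == b])
  fstat <- d^2 / (o[["msw"]] * (1 / na + 1 / nb)) / (k - 1)
  stats::pf(fstat, k - 1, n - k, lower.tail = FALSE) < alpha
}

test_that("tertile assignment is rank-based, balanced and order-invariant", {
  x <- setNames(c(3, 1, 6, 2, 5, 4), paste0("P", 1:6))
  tt <- assign_tertiles(x)
  asg <- setNames(as.character(tt$assignment$tertile), tt$assignment$participant_id)
  expect_equal(asg[c("P2", "P4")], c(P2 = "low", P4 = "low"))
  expect_equal(asg[c("P1", "P6")], c(P1 = "medium", P6 = "medium"))
  expect_equal(asg[c("P5", "P3")], c(P5 = "high", P3 = "high"))

  # invariant to input ordering
  tt2 <- assign_tertiles(x[sample(names(x))])
  expect_equal(
    tt$assignment[order(tt$assignment$participant_id), ],
    tt2$assignment[order(tt2$assignment$participant_id), ]
  )

  # group sizes differ by at most n mod 3
  for (n in c(7, 8, 60, 600)) {
    sizes <- table(assign_tertiles(setNames(rnorm(n), sprintf("Q%04d", 1:n)))$assignment$tertile)
    expect_lte(max(sizes) - min(sizes), max(1, n %% 3))
    if (n %% 3 == 0) expect_true(all(sizes == n / 3))
  }
})

test_that("degenerate all-equal values split stably with a tie warning", {
  x <- setNames(rep(5, 6), paste0("P", 1:6))
  expect_warning(tt <- assign_tertiles(x), "tied")
  asg <- tt$assignment[order(tt$assignment$participant_id), ]
  expect_equal(as.character(asg$tertile),
    c("low", "low", "medium", "medium", "high", "high"))
  expect_error(assign_tertiles(x[1:2]), class = "fx_insufficient_sample")
})

test_that("one-way ANOVA F matches hand computation and stats::aov", {
  # groups {1,2,3},{2,3,4},{3,4,5}: SSB = 6, SSW = 6, F = 3 on (2,6) df
  v <- c(1, 2, 3, 2, 3, 4, 3, 4, 5)
  g <- rep(c("low", "medium", "high"), each = 3)
  fit <- fatexchange:::anova_oneway(v, g)
  expect_equal(fit$f, 3)
  expect_equal(c(fit$df1, fit$df2), c(2, 6))

  # random instances against stats::aov
  set.seed(42)
  for (i in 1:20) {
    n <- sample(9:40, 1)
    v <- rnorm(n)
    g <- sample(c("a", "b", "c"), n, replace = TRUE, prob = c(0.4, 0.3, 0.3))
    if (min(table(g)) < 2) next
    fit <- fatexchange:::anova_oneway(v, g)
    o <- aov_f(v, g)
    expect_equal(fit$f, o[["f"]], tolerance = 1e-10)
    expect_equal(fit$p, o[["p"]], tolerance = 1e-10)
  }

  # three identical groups: no differences
  fit0 <- fatexchange:::anova_oneway(rep(c(1, 2), 3), rep(c("a", "b", "c"), each = 2))
  expect_equal(fit0$f, 0)
})

test_that("Scheffe letter groupings match exhaustive pairwise criterion evaluation", {
  set.seed(99)
  for (i in 1:20) {
    v <- c(rnorm(8, 0), rnorm(8, sample(c(0, 2, 5), 1)), rnorm(8, sample(c(0, 3), 1)))
    g <- factor(rep(c("low", "medium", "high"), each = 8),
      levels = c("low", "medium", "high"))
    fit <- fatexchange:::anova_oneway(v, g)
    sig <- fatexchange:::scheffe_pairs(fit, alpha = 0.05)
    for (pair in list(c("low", "medium"), c("low", "high"), c("medium", "high"))) {
      expect_equal(
        unname(sig[pair[1], pair[2]]),
        unname(scheffe_sig_oracle(v, g, pair[1], pair[2]))
      )
    }
    grp <- fatexchange:::letter_groups(fit$means, sig)
    # letters must be consistent with the pairwise outcomes: shared letter
    # iff not significantly different
    for (a in rownames(sig)) {
      for (b in colnames(sig)) {
        if (a == b) next
        shares <- length(intersect(
          strsplit(grp[[a]], "")[[1]], strsplit(grp[[b]], "")[[1]]
        )) > 0
        expect_equal(shares, !sig[a, b])
      }
    }
  }
})

test_that("tertile report flags the separated categories and adjusts p-values", {
  sc <- small_cohort()
  tert <- assign_tertiles(setNames(
    sc$intakes$daily$sfa_pct_te, sc$intakes$daily$participant_id
  ))
  shares <- participant_category_share(sc$intakes, "sfa")
  rep <- compare_tertiles(shares, tert)
  expect_true(all(rep$p_adj >= rep$p - 1e-15))
  expect_true(all(rep$p_adj <= 1))
  # whole-milk contribution must rise across tertiles in the generated cohort
  wm <- rep[rep$category == "whole milk", ]
  expect_lt(wm$mean_low, wm$mean_medium)
  expect_lt(wm$mean_medium, wm$mean_high)
  # identical groups carry the same letter
  flat <- shares
  flat$value <- 1
  rep0 <- compare_tertiles(flat, tert)
  expect_true(all(rep0$grp_low == rep0$grp_high))
})
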