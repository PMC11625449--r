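#' Split participants into tertiles of SFA intake (%TE)
#'
#' Participants are ranked on their percentage of total energy from SFA and
#' split into low / medium / high consumer thirds. Ranking is a stable sort
#' by (value, participant_id), so the split is deterministic and invariant
#' to input order; tied values falling across a tertile boundary are split
#' by participant id with a warning. When `n` is not divisible by 3, the
#' lower tertiles take the extra members, so group sizes differ by at most
#' `n %% 3`.
#'
#' @param x Either a named numeric vector of SFA %TE keyed by participant
#'   id, or a tibble with columns `participant_id` and `value`.
#' @return An object of class `fx_tertiles`: list with `assignment`
#'   (tibble `participant_id`, `value`, `tertile` factor low/medium/high)
#'   and `cut_points` (upper %TE bound of the low and medium groups).
#' @export
assign_tertiles <- function(x) {
  if (is.numeric(x)) {
    if (is.null(names(x))) abort("a numeric `x` must be named by participant id.")
    x <- tibble(participant_id = names(x), value = unname(x))
  }
  n <- nrow(x)
  if (n < 3) {
    abort("assign_tertiles(): need at least 3 participants.",
      class = "fx_insufficient_sample"
    )
  }
  ord <- order(x$value, x$participant_id)
  base <- n %/% 3L
  rem <- n %% 3L
  sizes <- base + c(rem >= 1L, rem >= 2L, 0L)
  tertile <- rep(factor(c("low", "medium", "high"), levels = c("low", "medium", "high")),
    times = sizes
  )
  out <- x[ord, c("participant_id", "value")]
  out$tertile <- tertile
  # tied values spanning a boundary are split deterministically by id
  boundary_ties <- out |>
    summarise(k = n_distinct(.data$tertile), .by = "value") |>
    filter(.data$k > 1)
  if (nrow(boundary_ties)) {
    warn(sprintf(
      "tied SFA %%TE value(s) split across tertile boundaries by participant id: %s.",
      paste(head(signif(boundary_ties$value, 6), 3L), collapse = ", ")
    ))
  }
  cut_points <- c(
    low_max = max(out$value[out$tertile == "low"]),
    medium_max = max(out$value[out$tertile == "medium"])
  )
  structure(
    list(assignment = arrange(out, .data$participant_id), cut_points = cut_points),
    class = "fx_tertiles"
  )
}

#' @export
print.fx_tertiles <- function(x, ...) {
  tab <- table(x$assignment$tertile)
  cat(sprintf(
    "<fx_tertiles> n = %d (low %d / medium %d / high %d); cut points %.2f, %.2f %%TE\n",
    nrow(x$assignment), tab[["low"]], tab[["medium"]], tab[["high"]],
    x$cut_points[[1]], x$cut_points[[2]]
  ))
  invisible(x)
}

# One-way ANOVA from sums of squares (closed form, so the Scheffe criterion
# can reuse MSW directly). Returns NA F when the within variance is zero.
anova_oneway <- function(value, group) {
  group <- droplevels(as.factor(group))
  k <- nlevels(group)
  n <- length(value)
  means <- tapply(value, group, mean)
  ns <- tapply(value, group, length)
  grand <- mean(value)
  ssb <- sum(ns * (means - grand)^2)
  ssw <- sum((value - means[group])^2)
  df1 <- k - 1L
  df2 <- n - k
  if (ssw <= .Machine$double.eps * max(1, sum(value^2)) || df2 == 0L) {
    # degenerate: no within-group variance
    if (ssb <= .Machine$double.eps * max(1, sum(value^2))) {
      return(list(f = NA_real_, df1 = df1, df2 = df2, p = 1, msw = 0,
        means = means, ns = ns, note = "no-variance"))
    }
    return(list(f = Inf, df1 = df1, df2 = df2, p = 0, msw = 0,
      means = means, ns = ns, note = "zero-within-variance"))
  }
  msb <- ssb / df1
  msw <- ssw / df2
  f <- msb / msw
  list(f = f, df1 = df1, df2 = df2, p = pf(f, df1, df2, lower.tail = FALSE),
    msw = msw, means = means, ns = ns, note = NA_character_)
}

# Scheffe post hoc from its closed-form criterion: the pairwise contrast
# (mean_a - mean_b) is significant at level alpha when
#   (mean_a - mean_b)^2 / (MSW * (1/n_a + 1/n_b)) > (k - 1) * F_crit
# with F_crit = qf(1 - alpha, k - 1, N - k).
scheffe_pairs <- function(fit, alpha = 0.05) {
  k <- length(fit$means)
  crit <- (k - 1) * qf(1 - alpha, fit$df1, fit$df2)
  lv <- names(fit$means)
  sig <- matrix(FALSE, k, k, dimnames = list(lv, lv))
  for (a in seq_len(k - 1)) {
    for (b in seq(a + 1, k)) {
      d2 <- (fit$means[a] - fit$means[b])^2
      den <- fit$msw * (1 / fit$ns[a] + 1 / fit$ns[b])
      s <- if (den == 0) d2 > 0 else d2 / den > crit
      sig[a, b] <- sig[b, a] <- s
    }
  }
  sig
}

# Compact letter display: groups sharing a letter are not significantly
# different. Means are ordered ascending and letters assigned to maximal
# runs of mutually non-significant groups.
letter_groups <- function(means, sig) {
  k <- length(means)
  ord <- order(means)
  runs <- list()
  for (i in seq_len(k)) {
    j <- i
    while (j < k && !any(sig[ord[i:(j + 1)], ord[i:(j + 1)]])) j <- j + 1
    runs[[length(runs) + 1L]] <- i:j
  }
  # keep maximal runs only
  keep <- !vapply(seq_along(runs), function(i) {
    any(vapply(seq_along(runs), function(j) {
      i != j && all(runs[[i]] %in% runs[[j]])
    }, logical(1)))
  }, logical(1))
  runs <- runs[keep]
  letters_out <- rep("", k)
  for (r in seq_along(runs)) {
    idx <- ord[runs[[r]]]
    letters_out[idx] <- paste0(letters_out[idx], letters[r])
  }
  setNames(letters_out, names(means))
}

#' Compare food-category contributions across SFA tertiles
#'
#' For each food category, the per-participant contribution values are
#' compared across the low / medium / high SFA consumer groups with a
#' one-way ANOVA; the ANOVA p-values are Bonferroni-adjusted across the
#' family of categories tested, and pairwise differences are flagged with a
#' Scheffe post hoc test rendered as superscript-style letter groupings
#' (groups sharing a letter do not differ at `alpha`).
#'
#' @param shares Tibble `participant_id`, `category`, `value` as produced
#'   by [participant_category_share()]; `NA` values are dropped per
#'   category.
#' @param tertiles An `fx_tertiles` assignment.
#' @param alpha Significance level (default 0.05).
#' @param family Bonferroni family size; defaults to the number of
#'   categories tested.
#' @return Tibble with per-category tertile means and SDs, `f`, `p`,
#'   `p_adj` and letter groupings `grp_low`, `grp_medium`, `grp_high`.
#' @export
compare_tertiles <- function(shares, tertiles, alpha = 0.05, family = NULL) {
  asg <- tertiles$assignment[, c("participant_id", "tertile")]
  dat <- shares |>
    inner_join(asg, by = "participant_id") |>
    filter(!is.na(.data$value))
  counts <- dat |>
    summarise(n = n(), .by = c("category", "tertile"))
  ok <- counts |>
    summarise(ok = n() == 3L && all(.data$n >= 2L), .by = "category") |>
    filter(.data$ok)
  dat <- dat |> filter(.data$category %in% ok$category)
  cats <- sort(unique(dat$category))
  if (!length(cats)) abort("compare_tertiles(): no category has >= 2 participants per tertile.")
  m <- if (is.null(family)) length(cats) else family

  rows <- lapply(cats, function(cc) {
    d <- dat[dat$category == cc, ]
    fit <- anova_oneway(d$value, d$tertile)
    grp <- if (is.na(fit$f)) {
      setNames(rep("a", 3), c("low", "medium", "high"))
    } else {
      letter_groups(fit$means, scheffe_pairs(fit, alpha))
    }
    st <- d |>
      summarise(mean = mean(.data$value), sd = sd(.data$value), .by = "tertile")
    g <- function(t, col) st[[col]][st$tertile == t]
    tibble(
      category = cc,
      mean_low = g("low", "mean"), sd_low = g("low", "sd"),
      mean_medium = g("medium", "mean"), sd_medium = g("medium", "sd"),
      mean_high = g("high", "mean"), sd_high = g("high", "sd"),
      f = fit$f, p = fit$p, p_adj = min(1, fit$p * m),
      grp_low = grp[["low"]], grp_medium = grp[["medium"]], grp_high = grp[["high"]]
    )
  })
  list_rbind(rows)
}
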