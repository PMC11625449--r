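#' Paired t test between baseline and modelled intakes
#'
#' Two-sided paired t test on participant-aligned vectors: with differences
#' `d = model - baseline`, `t = mean(d) / (sd(d) / sqrt(n))` on `n - 1`
#' degrees of freedom. Degenerate cases are handled explicitly: identical
#' vectors give a no-change result (`t = 0`, `p = 1`), and constant nonzero
#' differences give `p = 0` with a flag.
#'
#' @param baseline,model Numeric vectors of equal length (n >= 2), aligned
#'   by participant.
#' @return A list with `t`, `df`, `p`, `mean_delta`, `n` and `note`
#'   (`NA`, `"no-change"` or `"zero-variance"`).
#' @export
#' @examples
#' paired_t(c(1, 2, 4), c(2, 3, 3)) # t = 0.5 on 2 df
paired_t <- function(baseline, model) {
  n <- length(baseline)
  if (length(model) != n) abort("paired_t(): vectors must have equal length.")
  if (n < 2) abort("paired_t(): need at least 2 pairs.")
  d <- model - baseline
  if (sd(d) == 0) {
    if (mean(d) == 0) {
      return(list(t = 0, df = n - 1L, p = 1, mean_delta = 0, n = n, note = "no-change"))
    }
    return(list(
      t = sign(mean(d)) * Inf, df = n - 1L, p = 0, mean_delta = mean(d),
      n = n, note = "zero-variance"
    ))
  }
  fit <- t.test(model, baseline, paired = TRUE)
  list(
    t = unname(fit$statistic), df = unname(fit$parameter),
    p = fit$p.value, mean_delta = mean(d), n = n, note = NA_character_
  )
}

#' Bonferroni adjustment with an explicit family size
#'
#' `p_adj = min(1, p * m)`. Unlike [stats::p.adjust()], the family size `m`
#' may exceed the number of p-values supplied (the reported subset of a
#' larger tested family).
#'
#' @param p Numeric vector of p-values in \[0, 1\].
#' @param m Family size; defaults to `length(p)`.
#' @return Adjusted p-values.
#' @export
bonferroni_adjust <- function(p, m = length(p)) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) {
    abort("bonferroni_adjust(): p-values must lie in [0, 1].",
      class = "fx_validation_error"
    )
  }
  if (m < length(p)) {
    abort("bonferroni_adjust(): family size m must be >= length(p).",
      class = "fx_config_error"
    )
  }
  pmin(1, p * m)
}

#' Relative change in a category's percentage contribution
#'
#' `(model - baseline) / baseline * 100`, computed on unrounded inputs
#' (rounding before division visibly distorts relative changes). A category
#' absent at baseline but present in the model has an undefined relative
#' change and is flagged `"new"` rather than given a number; a category
#' absent in both arms is reported as 0 with flag `"absent"`.
#'
#' @param baseline_contrib,model_contrib Percentage contributions (>= 0).
#' @return Tibble with `baseline`, `model`, `pct_change` and `status`
#'   (`"ok"`, `"new"` or `"absent"`).
#' @export
#' @examples
#' contribution_pct_change(7, 0) # -100 %
contribution_pct_change <- function(baseline_contrib, model_contrib) {
  if (any(baseline_contrib < 0) || any(model_contrib < 0)) {
    abort("contribution_pct_change(): contributions must be non-negative.")
  }
  status <- dplyr::case_when(
    baseline_contrib == 0 & model_contrib == 0 ~ "absent",
    baseline_contrib == 0 ~ "new",
    TRUE ~ "ok"
  )
  tibble(
    baseline = baseline_contrib, model = model_contrib,
    pct_change = ifelse(status == "ok",
      (model_contrib - baseline_contrib) / baseline_contrib * 100,
      ifelse(status == "absent", 0, NA_real_)
    ),
    status = status
  )
}

# Endpoints of the baseline-vs-model comparison tables: energy, every fat
# class in g/d and %TE, the macronutrient panel, vitamin E and EPA+DHA.
comparison_endpoints <- function() {
  fat <- c("total_fat", "sfa", "mufa", "pufa", "trans", "n6", "n3", "ala", "epa", "dha")
  macro <- c("protein", "carbohydrate", "total_sugar")
  bind_rows(
    tibble(nutrient = "energy", unit = "kcal/d", column = "energy_kcal"),
    tibble(nutrient = c(fat, macro), unit = "g/d", column = paste0(c(fat, macro), "_g")),
    tibble(nutrient = c(fat, macro), unit = "%TE", column = paste0(c(fat, macro), "_pct_te")),
    tibble(nutrient = "vitamin_e", unit = "mg/d", column = "vitamin_e_mg"),
    tibble(nutrient = "epa_dha", unit = "mg/d", column = "epa_dha_mg")
  )
}

#' Baseline-vs-modelled comparison table
#'
#' Paired comparison of mean daily intakes between the baseline and
#' food-exchange modelled arms for every nutrient endpoint, in both unit
#' systems (g/d and %TE) plus energy (kcal/d), vitamin E (mg/d) and
#' EPA+DHA (mg/d). Signed deltas are `model - baseline`; p-values come from
#' [paired_t()] and are Bonferroni-adjusted across the family of endpoints.
#'
#' @param baseline,model `fx_intakes` objects over the same participants.
#' @param family Bonferroni family size; defaults to the number of endpoint
#'   rows in the table.
#' @param groups Optional named character vector (participant id ->
#'   stratum, e.g. sex) to emit the comparison per stratum as well.
#' @return Tibble with one row per endpoint (and per stratum if `groups`
#'   is given): means, `delta`, `t`, `df`, `p`, `p_adj`, `n`, `note`.
#' @export
build_comparison_table <- function(baseline, model, family = NULL, groups = NULL) {
  b <- baseline$daily
  m <- model$daily
  if (!identical(b$participant_id, m$participant_id)) {
    only_b <- setdiff(b$participant_id, m$participant_id)
    only_m <- setdiff(m$participant_id, b$participant_id)
    if (length(only_b) || length(only_m)) {
      abort(sprintf(
        "arms are not participant-aligned (e.g. %s).",
        paste(head(c(only_b, only_m), 3L), collapse = ", ")
      ), class = "fx_alignment_error")
    }
    m <- m[match(b$participant_id, m$participant_id), ]
  }
  ep <- comparison_endpoints()
  mfam <- if (is.null(family)) nrow(ep) else family

  one_stratum <- function(idx, label) {
    rows <- lapply(seq_len(nrow(ep)), function(i) {
      col <- ep$column[i]
      tt <- paired_t(b[[col]][idx], m[[col]][idx])
      tibble(
        stratum = label, nutrient = ep$nutrient[i], unit = ep$unit[i],
        baseline_mean = mean(b[[col]][idx]), model_mean = mean(m[[col]][idx]),
        delta = tt$mean_delta, t = tt$t, df = tt$df, p = tt$p,
        n = tt$n, note = tt$note
      )
    })
    out <- list_rbind(rows)
    out$p_adj <- bonferroni_adjust(out$p, m = mfam)
    out
  }

  res <- one_stratum(seq_len(nrow(b)), "all")
  if (!is.null(groups)) {
    g <- groups[b$participant_id]
    for (lv in sort(unique(g))) {
      res <- bind_rows(res, one_stratum(which(g == lv), lv))
    }
  }
  res
}

#' Change in food-category contributions between arms
#'
#' Baseline and modelled category contributions (via
#' [category_contribution()]) for each requested nutrient, with the
#' relative percentage change of each category's contribution.
#'
#' @param baseline,model `fx_intakes` objects over the same participants.
#' @param nutrients Nutrients to tabulate (default total fat and SFA).
#' @param weights,method Passed to [category_contribution()].
#' @return Tibble `nutrient`, `category`, `baseline`, `model`,
#'   `pct_change`, `status`.
#' @export
contribution_change_table <- function(baseline, model,
                                      nutrients = c("total_fat", "sfa"),
                                      weights = NULL,
                                      method = "population_proportion") {
  rows <- lapply(nutrients, function(nu) {
    cb <- category_contribution(baseline, nu, weights = weights, method = method)
    cm <- category_contribution(model, nu, weights = weights, method = method)
    stopifnot(identical(cb$category, cm$category))
    chg <- contribution_pct_change(cb$contribution_pct, cm$contribution_pct)
    tibble(nutrient = nu, category = cb$category) |> bind_cols(chg)
  })
  list_rbind(rows)
}
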