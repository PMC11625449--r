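#' Compute per-participant mean daily intakes
#'
#' Converts validated diary entries into mean daily nutrient intakes per
#' participant: each entry contributes `amount_g / 100` times the food's
#' per-100 g nutrient vector, summed over the diary and divided by the
#' number of distinct recorded days (normally 4; partial diaries degrade
#' gracefully). Intakes are also partitioned by food category, expressed as
#' percentage of total energy (%TE) using [energy_factors()], and EPA + DHA
#' is additionally reported in mg/d.
#'
#' %TE is computed from each participant's own energy intake; population
#' means of %TE are therefore means of individual percentages.
#'
#' @param diaries Validated diary tibble (see [read_diaries()]).
#' @param composition Validated composition table.
#' @param roster Optional roster tibble; participants present in the roster
#'   but absent from the diaries get all-zero intakes with a warning, and
#'   the roster's survey weights are carried along for weighted summaries.
#' @param factors Energy-conversion factors, see [energy_factors()].
#' @return An object of class `fx_intakes`: a list with elements `daily`
#'   (tibble: one row per participant with g/d, mg/d and `_pct_te` columns),
#'   `by_category` (per-participant per-category mean daily nutrient
#'   vectors), `categories` (all categories of the composition table) and
#'   `weights` (named numeric).
#' @export
compute_intakes <- function(diaries, composition, roster = NULL,
                            factors = energy_factors()) {
  nf <- nutrient_fields()
  scaled <- diaries |>
    inner_join(composition[, c("food_code", "category", nf)], by = "food_code") |>
    mutate(across(all_of(nf), ~ .x * .data$amount_g / 100))
  ndays <- diaries |>
    summarise(n_days = n_distinct(.data$day), .by = "participant_id")
  by_category <- scaled |>
    summarise(across(all_of(nf), sum), .by = c("participant_id", "category")) |>
    left_join(ndays, by = "participant_id") |>
    mutate(across(all_of(nf), ~ .x / .data$n_days)) |>
    select(-"n_days") |>
    arrange(.data$participant_id, .data$category)
  daily <- by_category |>
    summarise(across(all_of(nf), sum), .by = "participant_id") |>
    left_join(ndays, by = "participant_id")

  if (!is.null(roster)) {
    absent <- setdiff(roster$participant_id, daily$participant_id)
    if (length(absent)) {
      warn(sprintf(
        "participants with no diary entries get all-zero intakes: %s.",
        paste(head(absent, 5L), collapse = ", ")
      ))
      zero <- tibble(participant_id = absent, n_days = 0L)
      for (col in nf) zero[[col]] <- 0
      daily <- bind_rows(daily, zero)
    }
  }
  daily <- arrange(daily, .data$participant_id)
  daily$epa_dha_mg <- (daily$epa_g + daily$dha_g) * 1000

  pos <- daily$energy_kcal > 0
  if (any(!pos)) {
    warn("participants with zero energy intake have undefined %TE (set to NA).")
  }
  for (nm in names(factors)) {
    col <- paste0(nm, "_g")
    out <- rep(NA_real_, nrow(daily))
    out[pos] <- percent_energy(daily[[col]][pos], daily$energy_kcal[pos], factors[[nm]])
    daily[[paste0(nm, "_pct_te")]] <- out
  }

  weights <- if (!is.null(roster)) {
    setNames(roster$weight, roster$participant_id)[daily$participant_id]
  } else {
    setNames(rep(1, nrow(daily)), daily$participant_id)
  }

  structure(
    list(
      daily = daily, by_category = by_category,
      categories = sort(unique(composition$category)),
      weights = weights, factors = factors
    ),
    class = "fx_intakes"
  )
}

#' @export
print.fx_intakes <- function(x, ...) {
  cat(sprintf(
    "<fx_intakes> %d participants, %d food categories consumed\n",
    nrow(x$daily), length(unique(x$by_category$category))
  ))
  cat(sprintf(
    "  mean energy %.0f kcal/d; mean SFA %.1f %%TE; mean total fat %.1f %%TE\n",
    mean(x$daily$energy_kcal), mean(x$daily$sfa_pct_te, na.rm = TRUE),
    mean(x$daily$total_fat_pct_te, na.rm = TRUE)
  ))
  invisible(x)
}

#' Mean daily intake for a single participant
#'
#' Convenience wrapper around [compute_intakes()] for one participant's
#' diary entries. An empty diary returns an all-zero intake with a warning.
#'
#' @param entries Diary entries for one participant.
#' @param composition Validated composition table.
#' @inheritParams compute_intakes
#' @return A list with `daily` (named numeric of mean daily quantities),
#'   `pct_te` (named numeric), `epa_dha_mg`, `by_category` (tibble) and
#'   `n_days`.
#' @export
mean_daily_intake <- function(entries, composition, factors = energy_factors()) {
  nf <- nutrient_fields()
  if (nrow(entries) == 0) {
    warn("empty diary: returning all-zero intake.")
    return(list(
      daily = setNames(rep(0, length(nf)), nf),
      pct_te = setNames(rep(NA_real_, length(factors)), names(factors)),
      epa_dha_mg = 0,
      by_category = tibble(category = character()),
      n_days = 0L
    ))
  }
  if (n_distinct(entries$participant_id) != 1L) {
    abort("mean_daily_intake(): entries must belong to a single participant.")
  }
  ix <- compute_intakes(entries, composition, factors = factors)
  daily <- ix$daily
  list(
    daily = setNames(as.numeric(daily[1, nf]), nf),
    pct_te = setNames(
      as.numeric(daily[1, paste0(names(factors), "_pct_te")]),
      names(factors)
    ),
    epa_dha_mg = daily$epa_dha_mg[1],
    by_category = ix$by_category |> select(-"participant_id"),
    n_days = daily$n_days[1]
  )
}

# Resolve a nutrient short name ("sfa") or column name ("sfa_g") to the
# daily-intake column it refers to.
resolve_nutrient_col <- function(nutrient) {
  nf <- nutrient_fields()
  if (nutrient %in% nf) return(nutrient)
  cand <- paste0(nutrient, "_g")
  if (cand %in% nf) return(cand)
  abort(sprintf("unknown nutrient `%s`.", nutrient), class = "fx_config_error")
}

#' Food-category contribution to a nutrient across a cohort
#'
#' The share of cohort intake of a nutrient supplied by each food category.
#' Two estimators are available: `"population_proportion"` (the default,
#' the convention of the Irish national food-consumption surveys) computes
#' the ratio of weighted summed category intake to weighted summed total
#' intake; `"mean_of_ratios"` averages each participant's own category
#' share. Rows over all categories sum to 100.
#'
#' @param intakes An `fx_intakes` object.
#' @param nutrient Nutrient short name (`"sfa"`) or field name (`"sfa_g"`).
#' @param weights Optional named numeric of participant weights; defaults to
#'   the weights carried by `intakes`.
#' @param method `"population_proportion"` or `"mean_of_ratios"`.
#' @return Tibble with `category` and `contribution_pct`, one row for every
#'   category of the composition table (0 where unconsumed).
#' @export
category_contribution <- function(intakes, nutrient, weights = NULL,
                                  method = c("population_proportion", "mean_of_ratios")) {
  method <- match.arg(method)
  col <- resolve_nutrient_col(nutrient)
  w <- resolve_weights(intakes, weights)

  cat_tot <- intakes$by_category |>
    mutate(w = w[.data$participant_id]) |>
    summarise(value = sum(.data$w * .data[[col]]), .by = "category")

  if (method == "population_proportion") {
    den <- sum(w * intakes$daily[[col]])
    if (den <= 0) {
      abort("category_contribution(): total cohort intake of the nutrient is zero.",
        class = "fx_undefined_contribution"
      )
    }
    res <- cat_tot |> mutate(contribution_pct = .data$value / den * 100)
  } else {
    tot <- setNames(intakes$daily[[col]], intakes$daily$participant_id)
    if (all(tot <= 0)) {
      abort("category_contribution(): no participant has nonzero intake of the nutrient.",
        class = "fx_undefined_contribution"
      )
    }
    shares <- intakes$by_category |>
      mutate(
        total = tot[.data$participant_id],
        w = w[.data$participant_id]
      ) |>
      filter(.data$total > 0) |>
      mutate(share = .data[[col]] / .data$total * 100)
    # normalise by total weight of participants with nonzero intake
    wpos <- sum(w[tot > 0])
    res <- shares |>
      summarise(contribution_pct = sum(.data$w * .data$share) / wpos, .by = "category")
  }
  tibble(category = intakes$categories) |>
    left_join(res[, c("category", "contribution_pct")], by = "category") |>
    mutate(contribution_pct = ifelse(is.na(.data$contribution_pct), 0, .data$contribution_pct))
}

resolve_weights <- function(intakes, weights) {
  ids <- intakes$daily$participant_id
  if (is.null(weights)) {
    w <- intakes$weights
    if (is.null(w)) w <- setNames(rep(1, length(ids)), ids)
  } else {
    if (is.null(names(weights))) {
      abort("weights must be a named numeric vector keyed by participant_id.")
    }
    w <- weights
  }
  missing <- setdiff(ids, names(w))
  if (length(missing)) {
    abort(sprintf(
      "weights missing for participant(s): %s.",
      paste(head(missing, 5L), collapse = ", ")
    ), class = "fx_config_error")
  }
  w[ids]
}

#' Per-participant category contribution values
#'
#' For tertile comparisons: each participant's own value per food category,
#' either as the percentage of their intake of a nutrient supplied by the
#' category (`measure = "share"`) or as the category's direct percentage of
#' the participant's total energy (`measure = "pct_te"`). Both readings of
#' "category contribution" are offered because survey reports use either.
#'
#' @inheritParams category_contribution
#' @param measure `"share"` (percent of the participant's nutrient intake)
#'   or `"pct_te"` (category %TE).
#' @return Tibble `participant_id`, `category`, `value` over the full
#'   participant-by-category grid (0 where unconsumed; `NA` share when a
#'   participant's total nutrient intake is zero).
#' @export
participant_category_share <- function(intakes, nutrient,
                                       measure = c("share", "pct_te")) {
  measure <- match.arg(measure)
  col <- resolve_nutrient_col(nutrient)
  grid <- tidyr::expand_grid(
    participant_id = intakes$daily$participant_id,
    category = intakes$categories
  )
  bc <- intakes$by_category[, c("participant_id", "category", col)]
  out <- grid |>
    left_join(bc, by = c("participant_id", "category")) |>
    mutate(cat_value = ifelse(is.na(.data[[col]]), 0, .data[[col]]))
  if (measure == "share") {
    tot <- setNames(intakes$daily[[col]], intakes$daily$participant_id)
    out$value <- ifelse(tot[out$participant_id] > 0,
      out$cat_value / tot[out$participant_id] * 100, NA_real_
    )
  } else {
    nm <- sub("_g$", "", col)
    fac <- intakes$factors[[nm]]
    if (is.null(fac)) {
      abort(sprintf("no energy factor for `%s`.", nm), class = "fx_config_error")
    }
    en <- setNames(intakes$daily$energy_kcal, intakes$daily$participant_id)
    out$value <- ifelse(en[out$participant_id] > 0,
      out$cat_value * fac / en[out$participant_id] * 100, NA_real_
    )
  }
  out[, c("participant_id", "category", "value")]
}
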