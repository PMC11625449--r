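#' Default dietary fat recommendation set
#'
#' The recommendations assessed at baseline and after the exchange model:
#' SFA at most 10 %TE and PUFA at least 6 %TE (UK/Irish recommendations),
#' and EPA + DHA at least 250 mg/d (EFSA). Compliance is also reported for
#' total fat, MUFA and trans fat; their numeric cut-offs are not fixed by
#' any single authority for children, so the shipped values (total fat <=
#' 35 %TE, MUFA >= 10 %TE, trans <= 2 %TE) are clearly flagged implementer
#' defaults (`implementer_default = TRUE`) and should be replaced with the
#' user's reference values where it matters.
#'
#' @return Tibble with columns `nutrient`, `unit` (`pct_te` or `mg_d`),
#'   `bound` (`upper`/`lower`), `value`, `source`, `implementer_default`.
#' @export
default_recommendation_set <- function() {
  tribble(
    ~nutrient, ~unit, ~bound, ~value, ~source, ~implementer_default,
    "sfa", "pct_te", "upper", 10, "UK", FALSE,
    "pufa", "pct_te", "lower", 6, "UK", FALSE,
    "epa_dha", "mg_d", "lower", 250, "EFSA", FALSE,
    "total_fat", "pct_te", "upper", 35, "EFSA", TRUE,
    "mufa", "pct_te", "lower", 10, "EFSA", TRUE,
    "trans", "pct_te", "upper", 2, "UK", TRUE
  )
}

#' Assess compliance with dietary fat recommendations
#'
#' The percentage of (survey-weighted) participants whose mean daily intake
#' satisfies each recommendation. Bounds are inclusive: a participant
#' exactly at an upper bound of 10 %TE complies with "at most 10 %TE",
#' matching the operators the recommendations print.
#'
#' @param intakes An `fx_intakes` object.
#' @param recommendations Recommendation tibble, see
#'   [default_recommendation_set()].
#' @param weights Optional named participant weights (default: the weights
#'   carried by `intakes`).
#' @param arm Optional label (`"baseline"` / `"model"`) copied into the
#'   output.
#' @return Tibble `nutrient`, `unit`, `bound`, `value`, `arm`,
#'   `percent_compliant`, `n`.
#' @export
assess_compliance <- function(intakes, recommendations = default_recommendation_set(),
                              weights = NULL, arm = NA_character_) {
  w <- resolve_weights(intakes, weights)
  daily <- intakes$daily
  rows <- lapply(seq_len(nrow(recommendations)), function(i) {
    r <- recommendations[i, ]
    col <- switch(r$unit,
      pct_te = paste0(r$nutrient, "_pct_te"),
      mg_d = paste0(r$nutrient, "_mg"),
      abort(sprintf("unknown recommendation unit `%s`.", r$unit),
        class = "fx_config_error"
      )
    )
    if (!col %in% names(daily)) {
      abort(sprintf(
        "recommendation references nutrient `%s` (%s) not present in intakes.",
        r$nutrient, r$unit
      ), class = "fx_config_error")
    }
    v <- daily[[col]]
    ok <- switch(r$bound,
      upper = v <= r$value,
      lower = v >= r$value,
      abort(sprintf("unknown bound `%s`.", r$bound), class = "fx_config_error")
    )
    ok[is.na(ok)] <- FALSE
    tibble(
      nutrient = r$nutrient, unit = r$unit, bound = r$bound, value = r$value,
      arm = arm, percent_compliant = sum(w[ok]) / sum(w) * 100,
      n = length(v)
    )
  })
  list_rbind(rows)
}

#' Serialise or load a recommendation set as YAML
#'
#' @param recommendations Recommendation tibble.
#' @param path File path.
#' @return `read_recommendations()` returns the tibble; `write_*` returns
#'   `path` invisibly.
#' @export
write_recommendations <- function(recommendations, path) {
  yaml::write_yaml(
    lapply(seq_len(nrow(recommendations)), function(i) as.list(recommendations[i, ])),
    path
  )
  invisible(path)
}

#' @rdname write_recommendations
#' @export
read_recommendations <- function(path) {
  raw <- yaml::read_yaml(path)
  out <- list_rbind(lapply(raw, as_tibble))
  required <- c("nutrient", "unit", "bound", "value")
  missing <- setdiff(required, names(out))
  if (length(missing)) {
    abort(sprintf(
      "recommendation set: missing field(s): %s.", paste(missing, collapse = ", ")
    ), class = "fx_schema_error")
  }
  if (any(out$value <= 0)) {
    abort("recommendation thresholds must be positive.", class = "fx_validation_error")
  }
  out
}
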