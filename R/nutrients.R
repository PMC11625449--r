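#' Nutrient fields tracked per food and per day
#'
#' Column names of the nutrient panel carried by composition tables (per
#' 100 g) and intake tables (per day). Energy is always kilocalories; all
#' fatty-acid and macronutrient masses are grams; vitamin E is milligrams.
#' A note on vitamin E units: intakes of vitamin E in school-aged children
#' are of the order of several milligrams per day, so this package stores
#' and reports vitamin E in mg throughout and never rescales user data.
#'
#' @return Character vector of the fifteen nutrient column names.
#' @export
#' @examples
#' nutrient_fields()
nutrient_fields <- function() {
  c(
    "energy_kcal", "total_fat_g", "sfa_g", "mufa_g", "pufa_g", "trans_g",
    "n6_g", "n3_g", "ala_g", "epa_g", "dha_g",
    "protein_g", "carbohydrate_g", "total_sugar_g", "vitamin_e_mg"
  )
}

#' Energy-conversion factors (kcal per gram)
#'
#' Metabolisable-energy factors used when expressing a nutrient as a
#' percentage of total energy: all fat classes 9 kcal/g, protein 4 kcal/g,
#' carbohydrate (and sugars, as available carbohydrate) 3.75 kcal/g — the
#' UK convention matching the lineage of British/Irish food composition
#' tables. Override by passing a modified vector wherever a `factors`
#' argument is accepted.
#'
#' @return Named numeric vector of kcal-per-gram factors keyed by nutrient
#'   short name (`total_fat`, `sfa`, ..., `protein`, `carbohydrate`,
#'   `total_sugar`).
#' @export
energy_factors <- function() {
  c(
    total_fat = 9, sfa = 9, mufa = 9, pufa = 9, trans = 9,
    n6 = 9, n3 = 9, ala = 9, epa = 9, dha = 9,
    protein = 4, carbohydrate = 3.75, total_sugar = 3.75
  )
}

#' Percentage of total energy supplied by a nutrient
#'
#' @param nutrient_g Nutrient intake in grams per day.
#' @param energy_kcal Total energy intake in kcal per day; must be positive.
#' @param kcal_per_g Energy-conversion factor for the nutrient (kcal/g);
#'   see [energy_factors()].
#' @return Numeric vector of percentages of total energy (%TE).
#' @export
#' @examples
#' percent_energy(50, 1800, 9) # 25 %TE
percent_energy <- function(nutrient_g, energy_kcal, kcal_per_g) {
  if (any(!is.finite(energy_kcal)) || any(energy_kcal <= 0)) {
    abort("percent_energy(): `energy_kcal` must be positive and finite.",
      class = "fx_undefined_pct_te"
    )
  }
  if (any(nutrient_g < 0, na.rm = TRUE)) {
    abort("percent_energy(): `nutrient_g` must be non-negative.")
  }
  nutrient_g * kcal_per_g / energy_kcal * 100
}

# Fat-fraction consistency tolerance: fatty-acid classes are analysed
# separately from total fat, so their sum may exceed it slightly by
# rounding, but not by more than 5 %.
FX_FAT_TOL <- 0.05

# Validate the nutrient panel of a composition or intake table.
# Reports 1-based row numbers of the offending rows.
validate_nutrients <- function(x, tol = FX_FAT_TOL, what = "composition") {
  for (col in nutrient_fields()) {
    bad <- which(is.na(x[[col]]) | x[[col]] < 0)
    if (length(bad)) {
      abort(sprintf(
        "%s: negative or missing `%s` in row(s) %s.",
        what, col, paste(head(bad, 5L), collapse = ", ")
      ), class = "fx_validation_error")
    }
  }
  frac <- x$sfa_g + x$mufa_g + x$pufa_g + x$trans_g
  bad <- which(frac > x$total_fat_g * (1 + tol))
  if (length(bad)) {
    abort(sprintf(
      "%s: fatty-acid fractions exceed total fat beyond tolerance in row(s) %s.",
      what, paste(head(bad, 5L), collapse = ", ")
    ), class = "fx_validation_error")
  }
  bad <- which(x$ala_g > x$n3_g * (1 + tol))
  if (length(bad)) {
    abort(sprintf(
      "%s: ALA exceeds total n-3 beyond tolerance in row(s) %s.",
      what, paste(head(bad, 5L), collapse = ", ")
    ), class = "fx_validation_error")
  }
  bad <- which(x$epa_g + x$dha_g > x$n3_g * (1 + tol))
  if (length(bad)) {
    abort(sprintf(
      "%s: EPA + DHA exceeds total n-3 beyond tolerance in row(s) %s.",
      what, paste(head(bad, 5L), collapse = ", ")
    ), class = "fx_validation_error")
  }
  invisible(TRUE)
}
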