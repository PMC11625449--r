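#' Default food-category taxonomy
#'
#' The twenty-six food categories into which all consumed foods and
#' beverages are aggregated, grouped by predominant fat profile or
#' associated food-based dietary guideline (dairy split into whole milk,
#' low-fat milks, cheeses, yogurts and butter; meats split into fresh,
#' processed and poultry; snack and confectionery categories kept separate).
#' Shipped as a plain-text data file so users can supply their own grouping
#' via the `taxonomy` argument of [read_composition()].
#'
#' @return A tibble with columns `id` (integer 1-26) and `name`.
#' @export
#' @examples
#' default_food_categories()
default_food_categories <- function() {
  path <- system.file("extdata", "food_categories.csv",
    package = "fatexchange", mustWork = TRUE
  )
  tax <- read_csv(path, col_types = cols(id = col_integer(), name = col_character()))
  validate_taxonomy(tax)
  tax
}

# A taxonomy must have unique ids and names; the default one has 26 rows.
validate_taxonomy <- function(taxonomy) {
  if (!all(c("id", "name") %in% names(taxonomy))) {
    abort("taxonomy must have columns `id` and `name`.", class = "fx_schema_error")
  }
  if (anyDuplicated(taxonomy$name) || anyDuplicated(taxonomy$id)) {
    abort("taxonomy ids and names must be unique.", class = "fx_validation_error")
  }
  invisible(TRUE)
}
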