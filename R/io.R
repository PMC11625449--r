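#' Read and validate a food composition table
#'
#' The composition CSV has one row per food item with columns `food_code`,
#' `description`, `category` (a name from the taxonomy) and one column per
#' nutrient field of [nutrient_fields()], all per 100 g of food as consumed.
#' Values use a `.` decimal separator; energy is kcal. A `kj` or
#' `energy_kj` column, if present, is ignored.
#'
#' @param path Path to the CSV file.
#' @param taxonomy Category taxonomy tibble (`id`, `name`); defaults to the
#'   packaged 26-category grouping.
#' @return A validated tibble of food items.
#' @export
read_composition <- function(path, taxonomy = default_food_categories()) {
  x <- read_csv(path, col_types = cols(.default = col_double(),
    food_code = col_character(), description = col_character(),
    category = col_character()
  ))
  validate_composition(x, taxonomy)
}

#' Validate an in-memory composition table
#'
#' @param x Tibble with the composition schema of [read_composition()].
#' @inheritParams read_composition
#' @return The validated tibble, invisibly unchanged.
#' @export
validate_composition <- function(x, taxonomy = default_food_categories()) {
  required <- c("food_code", "description", "category", nutrient_fields())
  missing <- setdiff(required, names(x))
  if (length(missing)) {
    abort(sprintf(
      "composition: missing column(s): %s.", paste(missing, collapse = ", ")
    ), class = "fx_schema_error")
  }
  dup <- unique(x$food_code[duplicated(x$food_code)])
  if (length(dup)) {
    abort(sprintf(
      "composition: duplicate food_code(s): %s.",
      paste(head(dup, 5L), collapse = ", ")
    ), class = "fx_validation_error")
  }
  unknown <- setdiff(unique(x$category), taxonomy$name)
  if (length(unknown)) {
    abort(sprintf(
      "composition: category not in taxonomy: %s.",
      paste(head(unknown, 5L), collapse = "; ")
    ), class = "fx_validation_error")
  }
  validate_nutrients(x, what = "composition")
  as_tibble(x)[, required]
}

#' @rdname read_composition
#' @param x Composition tibble to write.
#' @export
write_composition <- function(x, path) {
  write_csv(x, path)
  invisible(path)
}

#' Read and validate food diaries
#'
#' The diary CSV has one row per consumption event with columns
#' `participant_id`, `day` (1-4), `is_weekend` (logical), `food_code`, and
#' `amount_g` (grams consumed, positive). Every food code must resolve in
#' the composition table. Each participant's record should span 4 recording
#' days and include at least one weekend day; a missing weekend day is an
#' error in strict mode and a warning otherwise.
#'
#' @param path Path to the CSV file.
#' @param composition Composition table the codes must resolve against.
#' @param strict If `TRUE` (default), a diary without a weekend day is an
#'   error rather than a warning.
#' @return A validated tibble of diary entries (all participants).
#' @export
read_diaries <- function(path, composition, strict = TRUE) {
  x <- read_csv(path, col_types = cols(
    participant_id = col_character(), day = col_integer(),
    is_weekend = col_logical(), food_code = col_character(),
    amount_g = col_double()
  ))
  validate_diaries(x, composition, strict = strict)
}

#' @rdname read_diaries
#' @param x Diary tibble to validate or write.
#' @export
validate_diaries <- function(x, composition, strict = TRUE) {
  required <- c("participant_id", "day", "is_weekend", "food_code", "amount_g")
  missing <- setdiff(required, names(x))
  if (length(missing)) {
    abort(sprintf("diaries: missing column(s): %s.", paste(missing, collapse = ", ")),
      class = "fx_schema_error"
    )
  }
  bad <- which(is.na(x$amount_g) | x$amount_g <= 0)
  if (length(bad)) {
    abort(sprintf(
      "diaries: non-positive amount_g in row(s) %s.",
      paste(head(bad, 5L), collapse = ", ")
    ), class = "fx_validation_error")
  }
  bad <- which(!x$day %in% 1:4)
  if (length(bad)) {
    abort(sprintf(
      "diaries: day outside 1-4 in row(s) %s (at most 4 recording days).",
      paste(head(bad, 5L), collapse = ", ")
    ), class = "fx_validation_error")
  }
  unresolved <- setdiff(unique(x$food_code), composition$food_code)
  if (length(unresolved)) {
    abort(sprintf(
      "diaries: food_code(s) not in composition table: %s.",
      paste(head(unresolved, 5L), collapse = ", ")
    ), class = "fx_resolution_error")
  }
  wk <- x |>
    summarise(has_weekend = any(.data$is_weekend), .by = "participant_id") |>
    filter(!.data$has_weekend)
  if (nrow(wk)) {
    msg <- sprintf(
      "diaries: participant(s) without a weekend day: %s.",
      paste(head(wk$participant_id, 5L), collapse = ", ")
    )
    if (strict) abort(msg, class = "fx_validation_error") else warn(msg)
  }
  as_tibble(x)[, required]
}

#' @rdname read_diaries
#' @export
write_diaries <- function(x, path) {
  write_csv(x, path)
  invisible(path)
}

#' Read and validate a participant roster
#'
#' Columns: `participant_id`, `age_y` (5-12 years), `sex` (`male`/`female`)
#' and `weight` (positive survey weight, default 1 if absent).
#'
#' @param path Path to the CSV file.
#' @return A validated roster tibble.
#' @export
read_roster <- function(path) {
  x <- read_csv(path, col_types = cols(
    participant_id = col_character(), age_y = col_double(),
    sex = col_character(), weight = col_double()
  ))
  validate_roster(x)
}

#' @rdname read_roster
#' @param x Roster tibble to validate or write.
#' @export
validate_roster <- function(x) {
  required <- c("participant_id", "age_y", "sex")
  missing <- setdiff(required, names(x))
  if (length(missing)) {
    abort(sprintf("roster: missing column(s): %s.", paste(missing, collapse = ", ")),
      class = "fx_schema_error"
    )
  }
  if (!"weight" %in% names(x)) x$weight <- 1
  if (anyDuplicated(x$participant_id)) {
    abort("roster: duplicate participant_id.", class = "fx_validation_error")
  }
  bad <- which(x$age_y < 5 | x$age_y > 12)
  if (length(bad)) {
    abort(sprintf(
      "roster: age_y outside 5-12 in row(s) %s.",
      paste(head(bad, 5L), collapse = ", ")
    ), class = "fx_validation_error")
  }
  bad <- which(!x$sex %in% c("male", "female"))
  if (length(bad)) {
    abort(sprintf(
      "roster: sex must be 'male' or 'female' (row(s) %s).",
      paste(head(bad, 5L), collapse = ", ")
    ), class = "fx_validation_error")
  }
  bad <- which(is.na(x$weight) | x$weight <= 0)
  if (length(bad)) {
    abort(sprintf(
      "roster: non-positive weight in row(s) %s.",
      paste(head(bad, 5L), collapse = ", ")
    ), class = "fx_validation_error")
  }
  as_tibble(x)[, c(required, "weight")]
}

#' @rdname read_roster
#' @export
write_roster <- function(x, path) {
  write_csv(x, path)
  invisible(path)
}
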