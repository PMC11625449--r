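#' Construct a food-exchange rule
#'
#' A rule selects consumption events by the food's category and (optionally)
#' a case-insensitive regular expression over the food description, and
#' swaps the food code for a replacement while preserving the grams
#' consumed. Two replacement forms exist: a single `replacement_code`
#' (every selected food maps to one substitute, e.g. all butter to one
#' high-PUFA spread), or a `replacement_map` (a named character vector
#' mapping each source food code to its own counterpart, e.g. each fatty
#' meat to the lean/grilled variant of the same product). A rule never
#' selects its own replacement food, so rule sets are idempotent.
#'
#' @param rule_id Short label for reporting.
#' @param category Food category the rule applies to (`NULL` = any, for
#'   map-based rules).
#' @param pattern Optional case-insensitive regex on the food description.
#' @param replacement_code Food code of the single substitute.
#' @param replacement_map Named character vector `source code -> substitute
#'   code`; exactly one of `replacement_code` / `replacement_map` must be
#'   given.
#' @return An object of class `fx_rule`.
#' @export
exchange_rule <- function(rule_id, category = NULL, pattern = NULL,
                          replacement_code = NULL, replacement_map = NULL) {
  if (is.null(replacement_code) == is.null(replacement_map)) {
    abort("exchange_rule(): give exactly one of `replacement_code` or `replacement_map`.",
      class = "fx_config_error"
    )
  }
  if (!is.null(replacement_map)) {
    if (is.null(names(replacement_map)) || any(names(replacement_map) == "")) {
      abort("`replacement_map` must be a fully named character vector.",
        class = "fx_config_error"
      )
    }
    self <- names(replacement_map) == replacement_map
    if (any(self)) {
      abort("`replacement_map` maps food(s) to themselves.", class = "fx_config_error")
    }
  }
  structure(
    list(
      rule_id = rule_id, category = category, pattern = pattern,
      replacement_code = replacement_code, replacement_map = replacement_map
    ),
    class = "fx_rule"
  )
}

#' Bundle exchange rules into an ordered rule set
#'
#' Rule order matters: when several rules select the same food, the first
#' matching rule wins.
#'
#' @param ... `fx_rule` objects, or a single list of them.
#' @return An object of class `fx_rules`.
#' @export
rule_set <- function(...) {
  rules <- list(...)
  if (length(rules) == 1L && !inherits(rules[[1]], "fx_rule")) rules <- rules[[1]]
  if (!all(vapply(rules, inherits, logical(1), "fx_rule"))) {
    abort("rule_set(): all elements must be fx_rule objects.", class = "fx_config_error")
  }
  structure(rules, class = "fx_rules")
}

#' @export
print.fx_rules <- function(x, ...) {
  cat(sprintf("<fx_rules> %d ordered exchange rule(s)\n", length(x)))
  for (r in x) {
    tgt <- if (!is.null(r$replacement_code)) {
      paste("->", r$replacement_code)
    } else {
      sprintf("-> per-source map (%d pairs)", length(r$replacement_map))
    }
    cat(sprintf(
      "  %-16s [%s%s] %s\n", r$rule_id,
      if (is.null(r$category)) "any category" else r$category,
      if (is.null(r$pattern)) "" else paste0(" ~ /", r$pattern, "/"), tgt
    ))
  }
  invisible(x)
}

# Validate a rule set against a composition table before any mutation.
validate_rules <- function(rules, composition) {
  targets <- unlist(lapply(rules, function(r) {
    c(r$replacement_code, unname(r$replacement_map))
  }))
  absent <- setdiff(unique(targets), composition$food_code)
  if (length(absent)) {
    abort(sprintf(
      "exchange rules reference replacement food(s) absent from the composition table: %s.",
      paste(absent, collapse = ", ")
    ), class = "fx_config_error")
  }
  invisible(TRUE)
}

# First matching rule per food code; a rule never captures its own
# replacement food. Returns a named vector old code -> new code for the
# codes that change, plus the matching rule id.
build_code_map <- function(rules, composition) {
  out <- tibble(
    food_code = character(), new_code = character(), rule_id = character()
  )
  taken <- character()
  for (r in rules) {
    if (!is.null(r$replacement_map)) {
      cand <- names(r$replacement_map)
      cand <- cand[cand %in% composition$food_code]
      if (!is.null(r$category)) {
        cat_of <- setNames(composition$category, composition$food_code)
        cand <- cand[cat_of[cand] == r$category]
      }
      new <- unname(r$replacement_map[cand])
    } else {
      sel <- rep(TRUE, nrow(composition))
      if (!is.null(r$category)) sel <- sel & composition$category == r$category
      if (!is.null(r$pattern)) {
        sel <- sel & grepl(r$pattern, composition$description, ignore.case = TRUE)
      }
      sel <- sel & composition$food_code != r$replacement_code
      cand <- composition$food_code[sel]
      new <- rep(r$replacement_code, length(cand))
    }
    fresh <- !cand %in% taken
    if (any(fresh)) {
      out <- bind_rows(out, tibble(
        food_code = cand[fresh], new_code = new[fresh], rule_id = r$rule_id
      ))
      taken <- c(taken, cand[fresh])
    }
  }
  out
}

#' Apply gram-preserving food exchanges to diaries
#'
#' Each diary entry matched by a rule keeps its participant, day and grams
#' consumed and swaps only the food code for the rule's replacement — no
#' changes are made to the amounts of food consumed, only the food types.
#' Rules are applied in order with first-match-wins semantics and in a
#' single pass: replacement foods are never re-matched, so applying a rule
#' set twice equals applying it once.
#'
#' @param diaries Validated diary tibble.
#' @param rules An `fx_rules` rule set (see [default_rule_set()]).
#' @param composition Validated composition table; all replacement codes
#'   must resolve in it (checked before any mutation).
#' @return A list with `diaries` (the modelled diaries), `report` (tibble
#'   per rule: `rule_id`, `n_exchanged`, `grams_exchanged`) and
#'   `unmatched_rules` (rule ids that exchanged nothing).
#' @export
apply_exchanges <- function(diaries, rules, composition) {
  if (!inherits(rules, "fx_rules")) rules <- rule_set(rules)
  validate_rules(rules, composition)
  code_map <- build_code_map(rules, composition)

  modelled <- diaries |>
    left_join(code_map, by = "food_code") |>
    mutate(
      exchanged = !is.na(.data$new_code),
      food_code = ifelse(.data$exchanged, .data$new_code, .data$food_code)
    )
  report <- modelled |>
    filter(.data$exchanged) |>
    summarise(
      n_exchanged = n(), grams_exchanged = sum(.data$amount_g),
      .by = "rule_id"
    )
  all_ids <- vapply(rules, `[[`, character(1), "rule_id")
  report <- tibble(rule_id = all_ids) |>
    left_join(report, by = "rule_id") |>
    mutate(
      n_exchanged = ifelse(is.na(.data$n_exchanged), 0L, .data$n_exchanged),
      grams_exchanged = ifelse(is.na(.data$grams_exchanged), 0, .data$grams_exchanged)
    )
  list(
    diaries = modelled[, c("participant_id", "day", "is_weekend", "food_code", "amount_g")],
    report = report,
    unmatched_rules = report$rule_id[report$n_exchanged == 0]
  )
}

#' Default exchange rule set
#'
#' Builds the canonical rule set of the saturated-fat replacement model:
#' whole milk and full-fat cheeses to low-fat alternatives; butter and
#' butter spreads to a high-PUFA spread; fresh and processed meats to the
#' leaner/grilled counterpart of the same product; all biscuits including
#' cookies to a plain lower-SFA biscuit; and popcorn, cream crackers and
#' rice cakes to lower-fat alternatives (crisps and other savoury snacks
#' are deliberately untouched).
#'
#' Per-source meat and snack counterparts are located by the food-code
#' pairing convention of the composition table: a food `X` is paired with a
#' replacement coded `X_LEAN` (meats) or `X_LF` (snacks). Single
#' replacements are located by description: a low-fat milk, a low-fat
#' cheese, a high-PUFA spread and a plain biscuit must be present.
#'
#' @param composition Validated composition table containing the canonical
#'   replacement foods.
#' @return An ordered `fx_rules` object with at least 6 rule groups.
#' @export
default_rule_set <- function(composition) {
  find_one <- function(pattern, category) {
    hit <- composition$food_code[
      composition$category == category &
        grepl(pattern, composition$description, ignore.case = TRUE)
    ]
    if (length(hit) == 0) NA_character_ else hit[[1]]
  }
  lowfat_milk <- find_one("low-fat milk", "low-fat, skimmed and fortified milks")
  lowfat_cheese <- find_one("low-fat", "cheeses")
  pufa_spread <- find_one("high[- ]PUFA", "spreading fats and oils")
  plain_biscuit <- find_one("plain", "biscuits")

  missing <- c(
    if (is.na(lowfat_milk)) "low-fat milk",
    if (is.na(lowfat_cheese)) "low-fat cheese",
    if (is.na(pufa_spread)) "high-PUFA spread",
    if (is.na(plain_biscuit)) "plain biscuit"
  )

  pair_map <- function(category, suffix, pattern = NULL) {
    src <- composition$food_code[composition$category == category]
    if (!is.null(pattern)) {
      desc <- setNames(composition$description, composition$food_code)
      src <- src[grepl(pattern, desc[src], ignore.case = TRUE)]
    }
    paired <- paste0(src, suffix)
    keep <- paired %in% composition$food_code
    setNames(paired[keep], src[keep])
  }
  fresh_map <- pair_map("fresh meat", "_LEAN")
  proc_map <- pair_map("processed meats", "_LEAN")
  snack_map <- pair_map("savoury snacks", "_LF",
    pattern = "popcorn|cream cracker|rice cake"
  )
  if (!length(fresh_map)) missing <- c(missing, "lean fresh-meat counterparts (*_LEAN)")
  if (!length(proc_map)) missing <- c(missing, "lean processed-meat counterparts (*_LEAN)")
  if (!length(snack_map)) missing <- c(missing, "lower-fat snack counterparts (*_LF)")
  if (length(missing)) {
    abort(sprintf(
      "default_rule_set(): canonical replacement food(s) absent from composition: %s.",
      paste(missing, collapse = "; ")
    ), class = "fx_config_error")
  }

  rule_set(
    exchange_rule("whole_milk", category = "whole milk",
      replacement_code = lowfat_milk),
    exchange_rule("cheese", category = "cheeses", pattern = "full[- ]fat",
      replacement_code = lowfat_cheese),
    exchange_rule("butter", category = "butter",
      replacement_code = pufa_spread),
    exchange_rule("fresh_meat", category = "fresh meat",
      replacement_map = fresh_map),
    exchange_rule("processed_meat", category = "processed meats",
      replacement_map = proc_map),
    exchange_rule("biscuits", category = "biscuits",
      pattern = "biscuit|cookie|shortbread|wafer",
      replacement_code = plain_biscuit),
    exchange_rule("snacks", category = "savoury snacks",
      replacement_map = snack_map)
  )
}

#' Serialise or load an exchange rule set as YAML
#'
#' @param rules An `fx_rules` object.
#' @param path File path.
#' @return `read_rules()` returns an `fx_rules` object; `write_rules()`
#'   returns `path` invisibly.
#' @export
write_rules <- function(rules, path) {
  ser <- lapply(unclass(rules), function(r) {
    out <- list(rule_id = r$rule_id)
    if (!is.null(r$category)) out$category <- r$category
    if (!is.null(r$pattern)) out$pattern <- r$pattern
    if (!is.null(r$replacement_code)) out$replacement_code <- r$replacement_code
    if (!is.null(r$replacement_map)) out$replacement_map <- as.list(r$replacement_map)
    out
  })
  yaml::write_yaml(ser, path)
  invisible(path)
}

#' @rdname write_rules
#' @export
read_rules <- function(path) {
  raw <- yaml::read_yaml(path)
  rule_set(lapply(raw, function(r) {
    exchange_rule(
      rule_id = r$rule_id, category = r$category, pattern = r$pattern,
      replacement_code = r$replacement_code,
      replacement_map = if (!is.null(r$replacement_map)) {
        unlist(r$replacement_map)
      }
    )
  }))
}
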