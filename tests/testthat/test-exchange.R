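test_that("an empty rule set leaves the diary untouched", {
  sc <- small_cohort()
  ex <- apply_exchanges(sc$diaries, rule_set(list()), sc$composition)
  expect_equal(as.data.frame(ex$diaries), as.data.frame(sc$diaries))
  expect_equal(nrow(ex$report), 0L)
})

test_that("a matched entry swaps food code only, grams preserved", {
  comp <- tiny_composition()
  d <- tibble::tibble(
    participant_id = "A", day = 1L, is_weekend = TRUE,
    food_code = c("MILK", "APPLE"), amount_g = c(250, 100)
  )
  rules <- rule_set(exchange_rule("milk", category = "whole milk",
    replacement_code = "MILK_LF"))
  ex <- apply_exchanges(d, rules, comp)
  expect_equal(ex$diaries$food_code, c("MILK_LF", "APPLE"))
  expect_equal(ex$diaries$amount_g, c(250, 100))
  expect_equal(ex$report$n_exchanged, 1L)
  expect_equal(ex$report$grams_exchanged, 250)
})

test_that("first matching rule wins when two rules select the same food", {
  comp <- tiny_composition()
  d <- tibble::tibble(participant_id = "A", day = 1L, is_weekend = TRUE,
    food_code = "MILK", amount_g = 100)
  r1 <- exchange_rule("to_lowfat", category = "whole milk", replacement_code = "MILK_LF")
  r2 <- exchange_rule("to_apple", category = "whole milk", replacement_code = "APPLE")
  ex12 <- apply_exchanges(d, rule_set(r1, r2), comp)
  ex21 <- apply_exchanges(d, rule_set(r2, r1), comp)
  expect_equal(ex12$diaries$food_code, "MILK_LF")
  expect_equal(ex21$diaries$food_code, "APPLE")
  expect_equal(sum(ex12$report$n_exchanged), 1L)
  expect_true("to_apple" %in% ex12$unmatched_rules)
})

test_that("a rule with a missing replacement aborts before any mutation", {
  comp <- tiny_composition()
  rules <- rule_set(exchange_rule("bad", category = "whole milk",
    replacement_code = "GHOST"))
  expect_error(apply_exchanges(tiny_diary(), rules, comp),
    "GHOST", class = "fx_config_error")
  expect_error(exchange_rule("self", replacement_map = c(A = "A")),
    class = "fx_config_error")
})

test_that("default rules conserve grams and entry counts per participant-day", {
  sc <- small_cohort()
  rules <- default_rule_set(sc$composition)
  ex <- apply_exchanges(sc$diaries, rules, sc$composition)
  base <- sc$diaries |>
    dplyr::summarise(g = sum(amount_g), k = dplyr::n(),
      .by = c("participant_id", "day"))
  mod <- ex$diaries |>
    dplyr::summarise(g = sum(amount_g), k = dplyr::n(),
      .by = c("participant_id", "day"))
  expect_equal(as.data.frame(mod), as.data.frame(base))
})

test_that("fully matched categories vanish and SFA falls for every child", {
  sc <- small_cohort()
  rules <- default_rule_set(sc$composition)
  ex <- apply_exchanges(sc$diaries, rules, sc$composition)
  mx <- compute_intakes(ex$diaries, sc$composition, sc$roster)

  # complete removal: every whole-milk and butter food is matched, so the
  # categories contribute nothing after exchange
  post <- mx$by_category |> dplyr::filter(category %in% c("whole milk", "butter"))
  expect_equal(nrow(post), 0L)

  # directionality: every replacement has lower SFA density, so per-child
  # modelled SFA never exceeds baseline
  expect_true(all(mx$daily$sfa_g <= sc$intakes$daily$sfa_g + 1e-12))
})

test_that("replacements are strictly lower in SFA than the foods they replace", {
  sc <- small_cohort()
  comp <- sc$composition
  sfa <- setNames(comp$sfa_g, comp$food_code)
  map <- fatexchange:::build_code_map(default_rule_set(comp), comp)
  expect_true(all(sfa[map$new_code] < sfa[map$food_code]))
})

test_that("applying the rule set twice equals applying it once", {
  sc <- small_cohort()
  rules <- default_rule_set(sc$composition)
  once <- apply_exchanges(sc$diaries, rules, sc$composition)
  twice <- apply_exchanges(once$diaries, rules, sc$composition)
  expect_identical(once$diaries, twice$diaries)
  expect_equal(sum(twice$report$n_exchanged), 0L)
})

test_that("rule sets round-trip through YAML", {
  sc <- small_cohort()
  rules <- default_rule_set(sc$composition)
  path <- withr::local_tempfile(fileext = ".yaml")
  write_rules(rules, path)
  back <- read_rules(path)
  expect_equal(
    fatexchange:::build_code_map(back, sc$composition),
    fatexchange:::build_code_map(rules, sc$composition)
  )
})
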