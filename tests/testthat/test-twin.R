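test_that("a zero error model yields a twin identical on every compared variable", {
  g <- generate_cohort(cohort_config(n_infants = 120, seed = 41))
  e <- make_epr_twin(g, zero_error_model(), seed = 42)
  expect_equal(nrow(e$truth_log), 0)
  expect_false(any(is.na(e$id_map$epr_id)))

  gi <- derive_infants(g)
  ei <- derive_infants(e) |>
    dplyr::rename(epr_id = infant_id) |>
    dplyr::inner_join(e$id_map, by = "epr_id") |>
    dplyr::select(-epr_id) |>
    dplyr::arrange(match(infant_id, gi$infant_id)) |>
    dplyr::select(dplyr::all_of(names(gi)))
  expect_equal(as.data.frame(ei), as.data.frame(gi))
})

test_that("unknown variables in the error model are rejected", {
  expect_error(error_model(misclass_prob = c(nonexistent = 0.1)), "unknown variable")
  expect_error(error_model(missing_prob = c(frobnicate = 0.1)), "unknown variable")
  expect_error(error_model(day_jitter = list(sex = c(`1` = 1))), "unknown variable")
  expect_error(error_model(day_jitter = list(edd = c(`1` = 0.4))), "sum to 1")
  expect_error(error_model(linkage_failure_prob = -0.1), "linkage_failure_prob")
})

test_that("missing injections are conserved between the truth log and the tables", {
  g <- generate_cohort(cohort_config(n_infants = 400, seed = 43))
  e <- make_epr_twin(g, error_model(missing_prob = c(apgar5 = 0.2, edd = 0.1)),
                     seed = 44)
  log <- e$truth_log
  for (v in c("apgar5", "edd")) {
    injected <- sum(log$variable == v & log$error == "missing")
    diff_nonnull <- sum(!is.na(g$infants[[v]])) - sum(!is.na(e$infants[[v]]))
    expect_equal(injected, diff_nonnull)
  }
  expect_true(all(log$error == "missing"))
})

test_that("day jitter moves the derived count by the logged achieved offset", {
  g <- generate_cohort(cohort_config(n_infants = 150, seed = 47))
  e <- make_epr_twin(
    g, error_model(day_jitter = list(central_line_days = c(`0` = 0.5, `5` = 0.3, `-3` = 0.2))),
    seed = 48)
  gold_ep <- derive_episodes(g)
  epr_ep <- derive_episodes(e) |>
    dplyr::rename(epr_id = infant_id) |>
    dplyr::inner_join(e$id_map, by = "epr_id")
  cmpr <- dplyr::inner_join(
    dplyr::select(gold_ep, infant_id, episode, gold = central_line_days),
    dplyr::select(epr_ep, infant_id, episode, epr = central_line_days),
    by = c("infant_id", "episode"))
  log <- dplyr::filter(e$truth_log, variable == "central_line_days")
  expect_gt(nrow(log), 0)
  merged <- dplyr::left_join(cmpr, log, by = c("infant_id", "episode"))
  expect_equal(merged$epr - merged$gold,
               ifelse(is.na(merged$offset), 0L, merged$offset))
})

test_that("linkage failures are flagged and scale with the configured rate", {
  g <- generate_cohort(cohort_config(n_infants = 1310, seed = 49))
  e <- make_epr_twin(g, error_model(linkage_failure_prob = 0.02), seed = 50)
  n_fail <- sum(is.na(e$id_map$epr_id))
  expect_equal(n_fail, sum(e$truth_log$error == "unlinkable"))
  # 99% binomial band around p = 0.02 at n = 1310 (about 26 expected)
  band <- qbinom(c(0.005, 0.995), 1310, 0.02)
  expect_gte(n_fail, band[1])
  expect_lte(n_fail, band[2])
  # the registry still carries the unlinkable infants under internal ids
  expect_equal(nrow(e$infants), 1310)
})

test_that("binary misclassification flips exactly the logged infants", {
  g <- generate_cohort(cohort_config(n_infants = 500, seed = 51))
  e <- make_epr_twin(g, error_model(misclass_prob = c(hydrocephalus = 0.1)), seed = 52)
  flipped <- e$truth_log$infant_id[e$truth_log$variable == "hydrocephalus"]
  key <- setNames(e$id_map$epr_id, e$id_map$infant_id)
  gv <- setNames(g$infants$hydrocephalus, g$infants$infant_id)
  ev <- setNames(e$infants$hydrocephalus, e$infants$infant_id)
  disagree <- names(gv)[gv != ev[key[names(gv)]]]
  expect_setequal(disagree, flipped)
})
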