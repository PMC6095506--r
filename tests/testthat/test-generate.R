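test_that("config validation names the offending field", {
  expect_error(cohort_config(n_infants = 0), "n_infants")
  expect_error(cohort_config(transfer_prob = 1.2), "transfer_prob")
  expect_error(cohort_config(ga_range = c(20, 30)), "ga_range")
  expect_error(cohort_config(outcome_prevalences = c(bogus = 0.5)),
               "outcome_prevalences")
  expect_error(generate_cohort(list()), "config")
})

test_that("no transfers means exactly one episode per infant", {
  g <- generate_cohort(cohort_config(n_infants = 100, transfer_prob = 0, seed = 3))
  expect_equal(nrow(g$episodes), 100)
  expect_true(all(g$episodes$episode == 1))
  expect_true(all(!g$episodes$transfer_out))
})

test_that("the same seed reproduces the cohort exactly", {
  g1 <- generate_cohort(cohort_config(n_infants = 80, seed = 17))
  g2 <- generate_cohort(cohort_config(n_infants = 80, seed = 17))
  expect_identical(g1$infants, g2$infants)
  expect_identical(g1$episodes, g2$episodes)
  expect_identical(g1$daily, g2$daily)
  g3 <- generate_cohort(cohort_config(n_infants = 80, seed = 18))
  expect_false(identical(g1$infants, g3$infants))
})

test_that("generated cohorts satisfy their structural invariants", {
  g <- generate_cohort(cohort_config(n_infants = 250, seed = 23))
  inf <- g$infants

  # GA consistent with EDD and birth date, and inside the configured range
  expect_equal(280L - as.integer(inf$edd - inf$birth_date),
               inf$ga_weeks * 7L + inf$ga_extra_days)
  expect_true(all(inf$ga_weeks >= 23 & inf$ga_weeks <= 31))

  # birth order bounded by multiplicity
  mult_n <- c(singleton = 1L, twin = 2L, triplet = 3L)
  expect_true(all(inf$birth_order <= mult_n[inf$multiple]))

  # episodes per infant: ordered, non-overlapping, contiguous from birth
  eps <- dplyr::arrange(g$episodes, infant_id, episode)
  by_inf <- split(eps, eps$infant_id)
  for (e in by_inf[1:50]) {
    expect_true(all(e$discharge_date >= e$admission_date))
    if (nrow(e) > 1) {
      expect_true(all(e$admission_date[-1] > e$discharge_date[-nrow(e)]))
      expect_true(all(e$transfer_out[-nrow(e)]))
    }
    expect_false(e$transfer_out[nrow(e)])
  }
  expect_true(all(eps$episode <= 4))

  # one daily record per infant-date, each inside its episode
  expect_false(any(duplicated(g$daily[c("infant_id", "date")])))
  joined <- dplyr::inner_join(g$daily, eps, by = c("infant_id", "episode"))
  expect_true(all(joined$date >= joined$admission_date &
                    joined$date <= joined$discharge_date))

  # mechanical support implies intensive care under the default rule
  expect_true(all(default_care_rule(g$daily)[g$daily$mech_support] == "intensive"))
})

test_that("simulated survival matches the configured prevalence", {
  g <- generate_cohort(cohort_config(n_infants = 1258, seed = 29))
  surv <- derive_infants(g)$survival
  k <- sum(surv)
  # exact binomial 99% acceptance band around 0.921
  band <- qbinom(c(0.005, 0.995), 1258, 0.921)
  expect_gte(k, band[1])
  expect_lte(k, band[2])
})

test_that("transfer pathways reach the configured mean episode count", {
  g <- generate_cohort(cohort_config(n_infants = 1000, seed = 31))
  per <- table(g$episodes$infant_id)
  expect_gt(mean(per), 1.6)
  expect_lt(mean(per), 2.0)
  expect_true(any(per >= 3))  # includes A -> B -> A style paths
})
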