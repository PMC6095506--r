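mk_eps <- function(units, adm, dis = adm + 5, id = "x") {
  tibble::tibble(infant_id = id, episode = seq_along(units), unit_id = units,
                 admission_date = as.Date("2020-01-01") + adm,
                 discharge_date = as.Date("2020-01-01") + dis)
}

test_that("episode matching pairs a three-episode transfer path in order", {
  gold <- mk_eps(c("A", "B", "A"), c(0, 10, 30), c(9, 29, 40))
  mm <- match_episodes(gold, gold)
  expect_equal(mm$pairs$gold_episode, 1:3)
  expect_equal(mm$pairs$epr_episode, 1:3)
  expect_equal(nrow(mm$unmatched_gold), 0)
})

test_that("episode mismatches carry the intended reason codes", {
  gold <- mk_eps("A", 0)
  # admission beyond the tolerance
  late <- mk_eps("A", 3)
  mm <- match_episodes(gold, late, admission_tolerance = 1)
  expect_equal(mm$unmatched_gold$reason, "inconsistent_dates")
  expect_equal(nrow(match_episodes(gold, late, admission_tolerance = 3)$pairs), 1)
  # unit absent from the registry
  mm <- match_episodes(gold, mk_eps("B", 0))
  expect_equal(mm$unmatched_gold$reason, "inconsistent_hospital")
  # no registry episode at all
  empty <- mk_eps(character(0), numeric(0))
  mm <- match_episodes(gold, empty)
  expect_equal(mm$unmatched_gold$reason, "missing_episode")
  # overlapping episodes within one database
  bad <- mk_eps(c("A", "B"), c(0, 3), c(9, 12))
  mm <- match_episodes(bad, bad)
  expect_true(all(mm$unmatched_gold$reason == "inconsistent_dates"))
})

test_that("raising the admission tolerance never loses matched episodes", {
  set.seed(61)
  for (i in 1:25) {
    ng <- sample(1:4, 1); ne <- sample(1:4, 1)
    gold <- mk_eps(sample(LETTERS[1:3], ng, replace = TRUE),
                   cumsum(sample(3:10, ng, replace = TRUE)))
    epr <- mk_eps(sample(LETTERS[1:3], ne, replace = TRUE),
                  cumsum(sample(3:10, ne, replace = TRUE)))
    n_matched <- vapply(0:6, function(tol)
      nrow(match_episodes(gold, epr, tol)$pairs), integer(1))
    expect_true(all(diff(n_matched) >= 0))
  }
})

test_that("linking a database to itself excludes nothing and pairs every episode", {
  g <- generate_cohort(cohort_config(n_infants = 60, seed = 63))
  l <- link_infants(g, g)
  expect_equal(l$summary$n_linked, 60)
  expect_equal(l$summary$n_excluded, 0)
  expect_equal(l$summary$n_episode_pairs, nrow(g$episodes))
  expect_equal(nrow(l$excluded_episodes), 0)
})

test_that("every gold infant lands exactly once among linked or excluded", {
  g <- generate_cohort(cohort_config(n_infants = 300, seed = 65))
  e <- make_epr_twin(g, error_model(linkage_failure_prob = 0.05,
                                    episode_drop_prob = 0.03), seed = 66)
  l <- link_infants(g, e)
  expect_equal(sort(l$infants$infant_id), sort(g$infants$infant_id))
  expect_equal(l$summary$n_linked + l$summary$n_excluded, 300)
  expect_false(any(duplicated(l$episode_pairs[c("epr_id", "epr_episode")])))
  # audit file round-trip
  path <- withr::local_tempfile(fileext = ".csv")
  write_exclusion_audit(l, path)
  audit <- readr::read_csv(path, show_col_types = FALSE)
  expect_setequal(unique(audit$reason),
                  unique(c(l$infants$reason[l$infants$status == "excluded"],
                           l$excluded_episodes$reason)))
})

test_that("a study-shaped fixture reproduces the published linkage flow", {
  # 1310 recruited; 30 without a registry identifier; 22 more failing
  # episode checks; 1258 analysable
  g <- generate_cohort(cohort_config(n_infants = 1310, transfer_prob = 0.47, seed = 67))
  e <- make_epr_twin(g, zero_error_model(), seed = 68)
  no_id <- g$infants$infant_id[1:30]
  e$id_map$epr_id[e$id_map$infant_id %in% no_id] <- NA
  broken <- g$infants$infant_id[31:52]
  key <- setNames(e$id_map$epr_id, e$id_map$infant_id)
  for (i in seq_along(broken)) {
    eid <- key[[broken[i]]]
    rows <- which(e$episodes$infant_id == eid)
    r <- rows[length(rows)]
    if (i %% 3 == 0) {
      e$episodes$admission_date[r] <- e$episodes$admission_date[r] + 10  # date error
    } else if (i %% 3 == 1) {
      e$episodes$unit_id[r] <- "U99"                                     # name error
    } else {
      e$episodes <- e$episodes[-r, ]                                     # lost episode
    }
  }
  l <- link_infants(g, e)
  expect_equal(l$summary$n_no_id, 30)
  expect_equal(l$summary$n_excluded, 52)
  expect_equal(l$summary$n_linked, 1258)
  expect_setequal(
    unique(l$infants$reason[l$infants$status == "excluded"]),
    c("no_id", "inconsistent_dates", "inconsistent_hospital", "missing_episode"))
})

test_that("duplicate identifiers within one database are a hard error", {
  g <- generate_cohort(cohort_config(n_infants = 10, seed = 69))
  g2 <- g
  g2$infants$infant_id[2] <- g2$infants$infant_id[1]
  expect_error(link_infants(g2, g), "duplicate")
})
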