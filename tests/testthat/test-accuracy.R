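test_that("2x2 construction partitions comparable pairs and drops missing ones", {
  t <- two_by_two(c(TRUE, TRUE, FALSE, FALSE, NA, TRUE),
                  c(TRUE, FALSE, TRUE, FALSE, TRUE, NA))
  expect_equal(unlist(t[c("tp", "fn", "fp", "tn")]),
               c(tp = 1L, fn = 1L, fp = 1L, tn = 1L))
  expect_equal(sum(tidy(t)$n), 4)

  all_pos <- two_by_two(rep(TRUE, 7), rep(TRUE, 7))
  expect_equal(unlist(all_pos[c("tp", "fp", "fn", "tn")]),
               c(tp = 7L, fp = 0L, fn = 0L, tn = 0L))

  empty <- two_by_two(logical(0), logical(0))
  expect_equal(empty$tp + empty$fp + empty$fn + empty$tn, 0L)
  expect_error(accuracy_metrics(empty), "empty")
  expect_error(two_by_two(c(0, 2), c(0, 1)), "0/1")
})

test_that("cells reconstructed from marginals and sensitivity give the printed metrics", {
  # hydrocephalus-style row: 24/1234 gold, 18 index positives, sensitivity 50%
  t <- two_by_two_from_margins(24, 1234, 18, 50.0)
  expect_equal(unlist(t[c("tp", "fp", "fn", "tn")]),
               c(tp = 12L, fp = 6L, fn = 12L, tn = 1228L))
  m <- accuracy_metrics(t)
  est <- setNames(round(m$estimate, 1), m$metric)
  expect_equal(est[["sensitivity"]], 50.0)
  expect_equal(est[["specificity"]], 99.5)
  expect_equal(est[["ppv"]], 66.7)
  expect_equal(est[["prevalence_gold"]], 1.9)

  # survival-style row: 1159/99 gold, 1162 index positives, sensitivity 100%
  t <- two_by_two_from_margins(1159, 99, 1162, 100.0)
  m <- accuracy_metrics(t)
  est <- setNames(round(m$estimate, 1), m$metric)
  expect_equal(est[["sensitivity"]], 100.0)
  expect_equal(est[["specificity"]], 97.0)
  expect_equal(est[["ppv"]], 99.7)
  ci <- m[m$metric == "sensitivity", ]
  expect_equal(round(ci$lower, 1), 99.7)
  expect_equal(round(ci$upper, 1), 100.0)
})

test_that("undefined metrics are flagged, not coerced to 0 or 100", {
  m <- accuracy_metrics(as_two_by_two(tp = 0, fp = 0, fn = 0, tn = 25))
  expect_false(m$defined[m$metric == "ppv"])
  expect_true(is.na(m$estimate[m$metric == "ppv"]))
  expect_equal(m$estimate[m$metric == "specificity"], 100)
  g <- glance(m)
  expect_true(is.na(g$ppv))
})

test_that("accuracy table spans the binary rule variables of paired derived data", {
  gold <- tibble::tibble(infant_id = sprintf("g%02d", 1:40),
                         survival = rep(c(TRUE, FALSE), c(36, 4)),
                         hydrocephalus = rep(c(FALSE, TRUE), c(36, 4)))
  epr <- gold
  epr$hydrocephalus[1:2] <- TRUE  # two false positives
  tbl <- accuracy_table(gold, epr)
  expect_setequal(tbl$variable, c("survival", "hydrocephalus"))
  hy <- tbl[tbl$variable == "hydrocephalus", ]
  expect_equal(hy$sensitivity_estimate, 100)
  expect_equal(hy$specificity_estimate, 100 * 34 / 36)
  expect_equal(hy$index_pos, 6)
})

test_that("PPV obeys the Bayes identity in sens/spec/prevalence", {
  set.seed(42)
  for (i in 1:50) {
    cells <- as.list(rmultinom(1, 500, runif(4, 0.05, 1))[, 1])
    t <- as_two_by_two(tp = cells[[1]], fp = cells[[2]], fn = cells[[3]], tn = cells[[4]])
    m <- accuracy_metrics(t)
    est <- setNames(m$estimate / 100, m$metric)
    rhs <- est[["sensitivity"]] * est[["prevalence_gold"]] /
      (est[["sensitivity"]] * est[["prevalence_gold"]] +
         (1 - est[["specificity"]]) * (1 - est[["prevalence_gold"]]))
    expect_equal(unname(est[["ppv"]]), unname(rhs), tolerance = 1e-10)
  }
})
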