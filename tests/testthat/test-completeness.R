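test_that("completeness percentages count non-missing over group rows", {
  df <- tibble::tibble(
    year = rep(c(2011, 2012), each = 5),
    steroids = c(TRUE, NA, TRUE, NA, TRUE, rep(TRUE, 5)),
    sex = rep("male", 10),
    ga_weeks = c(rep(28, 5), rep(33, 5)))

  full <- completeness_table(df, "sex")
  expect_true(all(full$pct_complete == 100))

  ct <- completeness_table(df, c("steroids", "sex"))
  expect_equal(ct$pct_complete[ct$variable == "steroids"], 80)
  # joint completeness never exceeds the per-variable minimum
  expect_lte(ct$pct_complete[ct$variable == "all_variables"],
             min(ct$pct_complete[ct$variable != "all_variables"]))

  by_year <- completeness_table(df, "steroids", group_keys = "year")
  expect_equal(by_year$pct_complete[by_year$variable == "steroids"], c(60, 100))

  # subgroup rows never gain denominator
  sub <- completeness_table(df, "steroids",
                            subgroup_filter = function(d) d$ga_weeks < 32,
                            subgroup_label = "<32w")
  expect_true(all(sub$n[sub$subgroup == "<32w"] <=
                    sub$n[sub$subgroup == "all"]))
  expect_equal(sub$n[sub$subgroup == "<32w" & sub$variable == "steroids"], 5)

  expect_error(completeness_table(df, "nope"), "not in data")
})

test_that("sentinel-coded values count as missing", {
  df <- tibble::tibble(eth = c("White British", "Not stated", NA, "Mixed"))
  ct <- completeness_table(df, "eth")
  expect_equal(ct$pct_complete[ct$variable == "eth"], 50)
})

test_that("centre distributions match an independent sort-based quartile computation", {
  set.seed(77)
  n_centres <- 24
  df <- tibble::tibble(
    centre_id = rep(sprintf("U%02d", 1:n_centres), each = 40),
    apgar5 = 5L)
  # one centre with heavy injected missingness, the rest light and variable
  miss_rate <- c(0.3, runif(n_centres - 1, 0, 0.05))
  for (i in 1:n_centres) {
    rows <- which(df$centre_id == sprintf("U%02d", i))
    df$apgar5[sample(rows, round(miss_rate[i] * 40))] <- NA
  }
  cd <- centre_distribution(df, "apgar5")
  expect_equal(cd$summary$max, max(cd$by_centre$pct_missing))
  expect_equal(cd$by_centre$pct_missing[1], cd$summary$max)  # the heavy centre
  # oracle: sorted linear-interpolation quartiles
  x <- sort(cd$by_centre$pct_missing)
  h <- function(p) {
    pos <- (length(x) - 1) * p + 1
    lo <- floor(pos)
    x[lo] + (pos - lo) * (x[min(lo + 1, length(x))] - x[lo])
  }
  expect_equal(cd$summary$q1, h(0.25))
  expect_equal(cd$summary$median, h(0.5))
  expect_equal(cd$summary$q3, h(0.75))
  # aggregation: overall missing equals the sum over centres
  expect_equal(sum(cd$by_centre$n_missing), sum(is.na(df$apgar5)))

  single <- centre_distribution(df[df$centre_id == "U01", ], "apgar5")
  expect_equal(single$summary$min, single$summary$max)
})

test_that("coverage ratios require user-supplied denominators", {
  cv <- coverage_ratio(c(`23w` = 70, `24w` = 90), c(100, 100))
  expect_equal(cv$coverage_pct, c(70, 90))
  expect_error(coverage_ratio(1:3, 1:2), "length mismatch")
  expect_error(coverage_ratio(5, 0), "positive")
})
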