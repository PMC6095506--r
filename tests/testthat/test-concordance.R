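test_that("tolerance bands grade day counts, dates and binary items as preset", {
  rules <- default_rules()
  cl <- dplyr::filter(rules, variable == "central_line_days")
  expect_equal(as.character(classify_agreement(c(10, 10, 10, 10, 10),
                                               c(12, 13, 14, 15, NA), cl)),
               c("agree", "minor", "minor", "major", "not_comparable"))

  edd <- dplyr::filter(rules, variable == "edd")
  d0 <- as.Date("2020-06-01")
  expect_equal(as.character(classify_agreement(rep(d0, 3), d0 + c(2, 6, 7), edd)),
               c("agree", "minor", "major"))

  pda <- dplyr::filter(rules, variable == "pda_surgery")
  expect_equal(as.character(classify_agreement(c(TRUE, TRUE, NA),
                                               c(TRUE, FALSE, TRUE), pda)),
               c("agree", "major", "not_comparable"))

  milk <- dplyr::filter(rules, variable == "day_of_first_milk")
  expect_equal(as.character(classify_agreement(c(3, 3, 3), c(3, 4, 5), milk)),
               c("agree", "minor", "major"))
})

test_that("the rule table covers all 44 items with coherent bands", {
  rules <- default_rules()
  expect_equal(nrow(rules), 44)
  expect_equal(sum(rules$group == "characteristic"), 16)
  expect_equal(sum(rules$group %in% c("process", "process_14d")), 17)
  expect_equal(sum(rules$group == "outcome"), 11)
  banded <- rules[rules$kind %in% c("date", "count", "continuous"), ]
  expect_true(all(banded$minor_max >= banded$agree_max))
  # round-trip through CSV
  path <- withr::local_tempfile(fileext = ".csv")
  write_rules(rules, path)
  expect_equal(as.data.frame(read_rules(path)), as.data.frame(rules))
})

test_that("discordancy rates switch interval method at the 5% point estimate", {
  # 0 discordant of n: Poisson upper is -log(0.025)/n
  r0 <- discordancy_rate(make_classes(400), "any")
  expect_equal(r0$rate, 0)
  expect_equal(r0$ci_method, "poisson")
  expect_equal(r0$upper, 100 * (-log(0.025)) / 400, tolerance = 1e-10)

  below <- discordancy_rate(make_classes(951, n_major = 49), "major")
  at <- discordancy_rate(make_classes(950, n_major = 50), "major")
  expect_equal(below$ci_method, "poisson")
  expect_equal(at$ci_method, "agresti_coull")

  # printed worked example: 2 major of 1258 -> 0.2% (0.02-0.6)
  r <- discordancy_rate(make_classes(1256, n_major = 2), "major")
  expect_equal(round(r$rate, 1), 0.2)
  expect_equal(round(r$lower, 2), 0.02)
  expect_equal(round(r$upper, 1), 0.6)

  # any = minor + major, and not_comparable pairs leave the denominator
  r <- discordancy_rate(make_classes(90, n_minor = 6, n_major = 4, n_nc = 50), "any")
  expect_equal(r$n_comparable, 100L)
  expect_equal(r$k, 10L)
  und <- discordancy_rate(make_classes(0, n_nc = 5), "any")
  expect_true(is.na(und$rate))
  expect_equal(und$ci_method, "undefined")
})

test_that("limits of agreement follow mean +/- 1.96 SD of the differences", {
  ident <- limits_of_agreement(rep(0, 10))
  expect_equal(unlist(ident[c("mean_diff", "median_diff", "loa_lower", "loa_upper")]),
               c(mean_diff = 0, median_diff = 0, loa_lower = 0, loa_upper = 0))

  tri <- limits_of_agreement(c(-1, 0, 1))
  expect_equal(tri$mean_diff, 0)
  expect_equal(tri$loa_upper, 1.96)
  expect_equal(tri$loa_lower, -1.96)

  set.seed(5)
  big <- limits_of_agreement(rnorm(1e5))
  expect_equal(big$loa_lower, -1.96, tolerance = 0.02)
  expect_equal(big$loa_upper, 1.96, tolerance = 0.02)
  expect_error(limits_of_agreement(c(1, 2)), "at least 3")
})
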