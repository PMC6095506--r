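test_that("gestational age follows 280 days minus the EDD interval", {
  d0 <- as.Date("2021-05-01")
  ga <- gestational_age(c(d0, d0 + 70, d0 + 105), rep(d0, 3))
  expect_equal(ga$weeks, c(40L, 30L, 25L))
  expect_equal(ga$days, c(0L, 0L, 0L))
  ga2 <- gestational_age(d0 + 66, d0)
  expect_equal(c(ga2$weeks, ga2$days), c(30L, 4L))
  expect_error(gestational_age(d0 + 200, d0), "out of range")
})

test_that("count_days counts qualifying non-missing days inside the window", {
  co <- tiny_cohort()
  abx <- count_days(co$daily, antibiotics, window = c(1, 14), infants = co$infants)
  expect_equal(abx$n_days[abx$infant_id == "i1"], 6L)   # days 1-5 and 9
  expect_equal(abx$n_days[abx$infant_id == "i2"], 0L)
  expect_equal(abx$n_days[abx$infant_id == "i3"], 6L)
  cl <- count_days(co$daily, central_line)
  expect_equal(cl$n_days[cl$infant_id == "i1"], 10L)

  # window discipline: flags beyond day 14 never move a 14-day count
  co2 <- co
  co2$daily$antibiotics[co2$daily$infant_id == "i1"] <-
    co2$daily$antibiotics[co2$daily$infant_id == "i1"] |
    seq_len(50) > 20
  abx2 <- count_days(co2$daily, antibiotics, window = c(1, 14), infants = co2$infants)
  expect_equal(abx2$n_days[abx2$infant_id == "i1"], 6L)

  # a missing daily record cannot qualify
  co3 <- co
  co3$daily$missing[co3$daily$infant_id == "i1" & co3$daily$date == co3$infants$birth_date[1]] <- TRUE
  abx3 <- count_days(co3$daily, antibiotics, window = c(1, 14), infants = co3$infants)
  expect_equal(abx3$n_days[abx3$infant_id == "i1"], 5L)
})

test_that("milk profile resolves first feed, masking and the 14-day summary", {
  co <- tiny_cohort()
  mp <- milk_profile(co$infants, co$daily)
  i1 <- mp[mp$infant_id == "i1", ]
  expect_equal(i1$day_of_first_milk, 3L)
  expect_equal(i1$first_milk_types, "MBM")
  expect_equal(i1$milk_summary_14d, "MBM+formula")

  # i3 never fed: excluded from the first-feed comparison
  i3 <- mp[mp$infant_id == "i3", ]
  expect_equal(i3$first_feed_status, "no_feed")
  expect_true(is.na(i3$day_of_first_milk))

  # a missing day before the first observed feed masks the first-feed fields
  co2 <- co
  co2$daily$missing[co2$daily$infant_id == "i1"][2] <- TRUE
  mp2 <- milk_profile(co2$infants, co2$daily)
  i1b <- mp2[mp2$infant_id == "i1", ]
  expect_equal(i1b$first_feed_status, "masked")
  expect_true(is.na(i1b$day_of_first_milk))
  expect_equal(i1b$milk_summary_14d, "MBM+formula")  # summary survives
})

test_that("36-week PMA status distinguishes assessed, not in care, and missing record", {
  co <- tiny_cohort()
  st <- pma36_status(co$infants, co$episodes, co$daily)
  expect_equal(st$pma36_status, c("assessed", "assessed", "not_in_care"))
  expect_true(st$oxygen_at_36w[st$infant_id == "i1"])
  expect_false(st$mech_support_at_36w[st$infant_id == "i1"])
  expect_false(st$oxygen_at_36w[st$infant_id == "i2"])
  expect_true(is.na(st$oxygen_at_36w[st$infant_id == "i3"]))

  # blank the i1 assessment-day record: distinct missing_record status
  co2 <- co
  co2$daily$missing[co2$daily$infant_id == "i1" &
                      co2$daily$date == co2$infants$edd[1] - 28] <- TRUE
  st2 <- pma36_status(co2$infants, co2$episodes, co2$daily)
  expect_equal(st2$pma36_status[st2$infant_id == "i1"], "missing_record")
  st3 <- pma36_status(co2$infants, co2$episodes, co2$daily, policy = "any_record")
  expect_equal(st3$pma36_status[st3$infant_id == "i1"], "missing_record")
})

test_that("episode derivations respect length of stay and the care-level rule", {
  co <- tiny_cohort()
  ep <- derive_episodes(co)
  i1 <- ep[ep$infant_id == "i1", ]
  expect_equal(i1$length_of_stay, 50L)
  expect_equal(i1$intensive_days, 5L)         # ventilated days
  expect_equal(i1$high_dependency_days, 40L)  # oxygen or line, not ventilated
  expect_equal(i1$central_line_days, 10L)
  expect_true(all(ep$intensive_days + ep$high_dependency_days <= ep$length_of_stay))
  expect_equal(sum(ep$length_of_stay[ep$infant_id == "i2"]), 42L)

  # an alternative care rule changes the categorised counts only
  all_special <- function(daily) rep("special", nrow(daily))
  ep2 <- derive_episodes(co, care_rule = all_special)
  expect_equal(sum(ep2$intensive_days), 0L)
  expect_equal(ep2$central_line_days, ep$central_line_days)
})

test_that("infant composites combine episodes as any/sum/max and survival from the last", {
  expect_equal(infant_composite(c(10, 25, 7), "sum"), 42)
  expect_equal(infant_composite(c(1L, 3L, 2L), "max"), 3L)
  expect_true(infant_composite(c(FALSE, TRUE, FALSE), "any"))
  expect_true(infant_composite(c(TRUE, TRUE, TRUE), "survival"))
  expect_false(infant_composite(c(TRUE, FALSE), "survival"))
  expect_error(infant_composite(c(FALSE, TRUE), "survival"), "death")

  co <- tiny_cohort()
  inf <- derive_infants(co)
  i2 <- inf[inf$infant_id == "i2", ]
  expect_true(i2$pda_surgery)              # true in episode 2 of 3
  expect_equal(i2$length_of_stay_total, 42L)
  expect_equal(inf$survival, c(TRUE, TRUE, FALSE))
  expect_equal(inf$ga_days, c(210L, 238L, 175L))
})
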