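# hand-built three-infant cohort with known derived values
#
# i1: single episode, survives, oxygen-dependent at 36w PMA
# i2: A -> B -> A transfer path, survives, assessed at 36w PMA without oxygen
# i3: dies on postnatal day 6
tiny_cohort <- function() {
  d0 <- as.Date("2020-01-01")
  infants <- tibble::tibble(
    infant_id = c("i1", "i2", "i3"),
    centre_id = c("U01", "U01", "U02"),
    birth_date = d0,
    edd = d0 + c(70, 42, 105),          # GA 30+0, 34+0, 25+0
    ga_weeks = c(30L, 34L, 25L),
    ga_extra_days = 0L,
    birth_weight = c(1340L, 2100L, 720L),
    sex = c("male", "female", "male"),
    apgar5 = c(9L, 10L, 4L),
    multiple = c("singleton", "twin", "singleton"),
    birth_order = c(1L, 2L, 1L),
    maternal_yob = c(1988L, 1990L, 1985L),
    maternal_ethnicity = "White British",
    maternal_lsoa = "E01000001",
    antenatal_steroids = c(TRUE, TRUE, FALSE),
    delivery_mode = c("caesarean", "vaginal", "vaginal"),
    instrumental = c(FALSE, TRUE, FALSE),
    born_here = TRUE,
    rop_worst_stage = c(1L, 0L, 3L),
    nec_perforation = FALSE,
    gi_perforation = c(FALSE, FALSE, TRUE),
    nec_surgery = FALSE,
    hpi = FALSE,
    hydrocephalus = FALSE,
    pvl = FALSE,
    porencephalic_cyst = FALSE)
  episodes <- tibble::tibble(
    infant_id = c("i1", "i2", "i2", "i2", "i3"),
    episode = c(1L, 1L, 2L, 3L, 1L),
    unit_id = c("U01", "U01", "U03", "U01", "U02"),
    admission_date = d0 + c(0, 0, 10, 35, 0),
    discharge_date = d0 + c(49, 9, 34, 41, 5),  # LOS 50, 10+25+7, 6
    transfer_out = c(FALSE, TRUE, TRUE, FALSE, FALSE),
    discharge_alive = c(TRUE, TRUE, TRUE, TRUE, FALSE),
    pda_surgery = c(FALSE, FALSE, TRUE, FALSE, FALSE),
    pda_medical = FALSE,
    rop_treatment = c(TRUE, FALSE, FALSE, FALSE, FALSE))
  stays <- c(i1 = 50L, i2 = 42L, i3 = 6L)
  daily <- dplyr::bind_rows(purrr::imap(stays, function(len, id) {
    t <- seq_len(len)
    tibble::tibble(
      infant_id = id, date = d0 + t - 1L,
      # i1 ventilated 5 days and on oxygen through 36w PMA (day 43)
      mech_support = id == "i1" & t <= 5,
      oxygen = (id == "i1" & t <= 45) | (id == "i3" & t <= 6),
      central_line = (id == "i1" & t <= 10) | (id == "i3" & t <= 6),
      antibiotics = (id == "i1" & (t <= 5 | t == 9)) | (id == "i3" & t <= 6),
      antacid = id == "i2" & t >= 20 & t <= 29,
      mbm = (id == "i1" & t >= 3) | (id == "i2" & t >= 2),
      hdm = FALSE,
      formula = id == "i1" & t >= 5,
      missing = FALSE)
  }))
  # attach episodes to days
  daily <- daily |>
    dplyr::inner_join(dplyr::select(episodes, "infant_id", "episode",
                                    "admission_date", "discharge_date"),
                      by = "infant_id", relationship = "many-to-many") |>
    dplyr::filter(date >= admission_date, date <= discharge_date) |>
    dplyr::select(-"admission_date", -"discharge_date")
  structure(list(infants = infants, episodes = episodes, daily = daily,
                 config = NULL),
            class = "neo_cohort")
}

# independent bisection oracles for the interval machinery ------------------

# Clopper-Pearson bounds by vectorised bisection on binomial tails
cp_bisect <- function(k, n, alpha = 0.05) {
  bisect <- function(f, lo, hi, iters = 60) {
    for (i in seq_len(iters)) {
      mid <- (lo + hi) / 2
      up <- f(mid)
      lo <- ifelse(up, lo, mid)
      hi <- ifelse(up, mid, hi)
    }
    (lo + hi) / 2
  }
  lower <- ifelse(k == 0, 0,
                  bisect(function(p) pbinom(k - 1, n, p, lower.tail = FALSE) > alpha / 2,
                         rep(0, length(k)), rep(1, length(k))))
  upper <- ifelse(k == n, 1,
                  bisect(function(p) pbinom(k, n, p) < alpha / 2,
                         rep(0, length(k)), rep(1, length(k))))
  list(lower = lower, upper = upper)
}

# exact Poisson interval for a count by bisection on Poisson tails
pois_bisect <- function(k, alpha = 0.05) {
  hi0 <- k + 10 * sqrt(k + 1) + 20
  bisect <- function(f, lo, hi, iters = 60) {
    for (i in seq_len(iters)) {
      mid <- (lo + hi) / 2
      up <- f(mid)
      lo <- ifelse(up, lo, mid)
      hi <- ifelse(up, mid, hi)
    }
    (lo + hi) / 2
  }
  lower <- ifelse(k == 0, 0,
                  bisect(function(mu) ppois(k - 1, mu, lower.tail = FALSE) > alpha / 2,
                         rep(0, length(k)), hi0))
  upper <- bisect(function(mu) ppois(k, mu) < alpha / 2, rep(0, length(k)), hi0)
  list(lower = lower, upper = upper)
}

make_classes <- function(n_agree, n_minor = 0, n_major = 0, n_nc = 0) {
  factor(rep(c("agree", "minor", "major", "not_comparable"),
             c(n_agree, n_minor, n_major, n_nc)),
         levels = c("agree", "minor", "major", "not_comparable"))
}
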