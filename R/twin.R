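#' Build a perturbed EPR registry twin of a gold cohort
#'
#' Copies the gold cohort, re-keys it with opaque registry identifiers and
#' injects the errors described by an [error_model()]: unlinkable infants,
#' dropped episodes, blanked values, categorical swaps and day jitter.
#' Every perturbed cell is recorded in the truth log, so the twin differs
#' from the gold data only where the log says it does — a zero error model
#' yields a twin identical to the gold cohort on every compared variable.
#'
#' Day jitter on count variables edits the underlying daily grid (flag
#' days are added or removed at the boundary of the existing run, within
#' the episode or the 14-day window), so the derived count moves by the
#' sampled offset; where the grid cannot absorb the full offset the
#' achieved offset is logged. Jitter on `length_of_stay` is applied to the
#' final episode so episodes stay non-overlapping.
#'
#' @param gold A `neo_cohort` from [generate_cohort()] (or any
#'   schema-conformant cohort list).
#' @param error_model An [error_model()].
#' @param seed Integer seed for the injection randomness.
#' @return A list of class `neo_epr`: tibbles `infants`, `episodes`,
#'   `daily` keyed by registry id, `id_map` (gold `infant_id` to registry
#'   `epr_id`, `NA` where linkage failed), and `truth_log` (one row per
#'   injection: `infant_id`, `variable`, `episode`, `error`, `offset`,
#'   `detail`).
#' @export
make_epr_twin <- function(gold, error_model = zero_error_model(), seed = NULL) {
  if (!inherits(error_model, "error_model")) stop_field("error_model", "must be an error_model")
  if (!is.null(seed)) set.seed(seed)
  infants <- gold$infants
  episodes <- gold$episodes
  daily <- gold$daily
  n <- nrow(infants)
  log <- list()
  note <- function(infant_id, variable, error, episode = NA_integer_,
                   offset = NA_integer_, detail = NA_character_) {
    log[[length(log) + 1L]] <<- tibble::tibble(
      infant_id = infant_id, variable = variable, episode = as.integer(episode),
      error = error, offset = as.integer(offset), detail = detail)
  }

  # registry identifiers; a small fraction cannot be supplied
  epr_id <- sprintf("B%05d", sample.int(n))
  id_map <- tibble::tibble(infant_id = infants$infant_id, epr_id = epr_id)
  fail <- runif(n) < error_model$linkage_failure_prob
  if (any(fail)) {
    id_map$epr_id[fail] <- NA_character_
    note(infants$infant_id[fail], "linkage", "unlinkable")
  }

  # dropped episodes
  if (error_model$episode_drop_prob > 0) {
    drop <- runif(nrow(episodes)) < error_model$episode_drop_prob
    if (any(drop)) {
      note(episodes$infant_id[drop], "episode", "dropped",
           episode = episodes$episode[drop])
      keys <- paste(episodes$infant_id, episodes$episode)
      daily <- daily[!paste(daily$infant_id, daily$episode) %in% keys[drop], ]
      episodes <- episodes[!drop, ]
    }
  }

  # blanked values
  for (row in seq_len(nrow(missing_spec(error_model$missing_prob)))) {
    ms <- missing_spec(error_model$missing_prob)[row, ]
    eligible <- if (is.na(ms$centre_id)) rep(TRUE, n) else infants$centre_id == ms$centre_id
    hit <- eligible & runif(n) < ms$prob
    if (!any(hit)) next
    ids <- infants$infant_id[hit]
    if (ms$variable == "daily") {
      for (id in ids) {
        bd <- infants$birth_date[infants$infant_id == id]
        rows <- which(daily$infant_id == id &
                        daily$date >= bd & daily$date <= bd + 13L & !daily$missing)
        if (!length(rows)) next
        pick <- rows[sample.int(length(rows), 1)]
        daily$missing[pick] <- TRUE
        note(id, "daily", "missing",
             detail = sprintf("day %d", as.integer(daily$date[pick] - bd) + 1L))
      }
    } else if (ms$variable == "ga") {
      infants$ga_weeks[hit] <- NA_integer_
      infants$ga_extra_days[hit] <- NA_integer_
      note(ids, "ga", "missing")
    } else {
      infants[[ms$variable]][hit] <- NA
      note(ids, ms$variable, "missing")
    }
  }

  # categorical swaps and binary flips
  for (v in names(error_model$misclass_prob)) {
    hit <- which(runif(n) < error_model$misclass_prob[[v]])
    if (!length(hit)) next
    ids <- infants$infant_id[hit]
    if (v %in% c("nec_perforation", "gi_perforation", "nec_surgery", "hpi",
                 "hydrocephalus", "pvl", "porencephalic_cyst",
                 "born_here", "antenatal_steroids", "instrumental")) {
      infants[[v]][hit] <- !infants[[v]][hit]
      note(ids, v, "misclassified")
    } else if (v == "sex") {
      infants$sex[hit] <- ifelse(infants$sex[hit] == "male", "female", "male")
      note(ids, v, "misclassified")
    } else if (v == "delivery_mode") {
      infants$delivery_mode[hit] <- ifelse(infants$delivery_mode[hit] == "caesarean",
                                           "vaginal", "caesarean")
      note(ids, v, "misclassified")
    } else if (v == "multiple") {
      opts <- c("singleton", "twin", "triplet")
      infants$multiple[hit] <- vapply(infants$multiple[hit], function(cur)
        sample(setdiff(opts, cur), 1), character(1))
      note(ids, v, "misclassified")
    } else if (v == "maternal_ethnicity") {
      opts <- unique(infants$maternal_ethnicity)
      if (length(opts) > 1) {
        infants$maternal_ethnicity[hit] <- vapply(infants$maternal_ethnicity[hit],
          function(cur) sample(setdiff(opts, cur), 1), character(1))
        note(ids, v, "misclassified")
      }
    } else if (v == "maternal_lsoa") {
      infants$maternal_lsoa[hit] <- sprintf("E01%06d", sample.int(32844, length(hit)))
      note(ids, v, "misclassified")
    } else if (v == "maternal_yob") {
      infants$maternal_yob[hit] <- infants$maternal_yob[hit] +
        sample(c(-3:-1, 1:3), length(hit), replace = TRUE)
      note(ids, v, "misclassified")
    } else if (v == "rop_worst_stage") {
      cur <- infants$rop_worst_stage[hit]
      shift <- ifelse(cur == 0L, 1L, ifelse(cur >= 4L, -1L,
                      sample(c(-1L, 1L), length(cur), replace = TRUE)))
      infants$rop_worst_stage[hit] <- cur + shift
      note(ids, v, "misclassified")
    } else if (v == "survival") {
      for (id in ids) {
        last <- which(episodes$infant_id == id)
        if (!length(last)) next
        last <- last[which.max(episodes$episode[last])]
        episodes$discharge_alive[last] <- !episodes$discharge_alive[last]
        note(id, v, "misclassified")
      }
    } else if (v %in% c("pda_surgery", "pda_medical", "rop_treatment")) {
      for (id in ids) {
        rows <- which(episodes$infant_id == id)
        if (!length(rows)) next
        if (any(episodes[[v]][rows])) {
          episodes[[v]][rows] <- FALSE
        } else {
          episodes[[v]][rows[sample.int(length(rows), 1)]] <- TRUE
        }
        note(id, v, "misclassified")
      }
    } else if (v %in% c("oxygen_at_36w", "mech_support_at_36w")) {
      flag <- if (v == "oxygen_at_36w") "oxygen" else "mech_support"
      for (id in ids) {
        assess <- infants$edd[infants$infant_id == id] - 28L
        row <- which(daily$infant_id == id & daily$date == assess & !daily$missing)
        if (!length(row)) next
        daily[[flag]][row] <- !daily[[flag]][row]
        if (flag == "mech_support" && daily$mech_support[row]) daily$oxygen[row] <- TRUE
        if (flag == "oxygen" && !daily$oxygen[row]) daily$mech_support[row] <- FALSE
        note(id, v, "misclassified")
      }
    } else if (v %in% c("first_milk_types", "milk_summary_14d")) {
      for (id in ids) {
        bd <- infants$birth_date[infants$infant_id == id]
        win <- which(daily$infant_id == id & daily$date >= bd &
                       daily$date <= bd + 13L & !daily$missing)
        fed <- win[daily$mbm[win] | daily$hdm[win] | daily$formula[win]]
        if (!length(fed)) next
        if (v == "first_milk_types") {
          first <- fed[which.min(daily$date[fed])]
          if (daily$formula[first] && !daily$mbm[first] && !daily$hdm[first]) {
            daily$mbm[first] <- TRUE
          } else {
            daily$formula[first] <- !daily$formula[first]
          }
        } else {
          # flip whether formula appears anywhere in the window
          if (any(daily$formula[win])) daily$formula[win] <- FALSE
          else daily$formula[fed[length(fed)]] <- TRUE
        }
        note(id, v, "misclassified")
      }
    }
  }

  # day jitter
  for (v in names(error_model$day_jitter)) {
    dist <- error_model$day_jitter[[v]]
    offsets <- as.integer(names(dist))
    res <- inject_jitter(v, infants, episodes, daily, offsets, dist, note)
    infants <- res$infants; episodes <- res$episodes; daily <- res$daily
  }

  truth_log <- if (length(log)) dplyr::bind_rows(log) else
    tibble::tibble(infant_id = character(), variable = character(),
                   episode = integer(), error = character(),
                   offset = integer(), detail = character())

  # re-key all registry tables by the opaque registry id
  key <- setNames(id_map$epr_id, id_map$infant_id)
  # infants without a supplied id still exist in the registry under an internal id
  orphan <- is.na(key)
  key[orphan] <- sprintf("X%05d", seq_len(sum(orphan)))
  infants$infant_id <- unname(key[infants$infant_id])
  episodes$infant_id <- unname(key[episodes$infant_id])
  daily$infant_id <- unname(key[daily$infant_id])

  structure(list(infants = infants, episodes = episodes, daily = daily,
                 id_map = id_map, truth_log = truth_log, config = gold$config),
            class = "neo_epr")
}

missing_spec <- function(missing_prob) {
  if (is.null(missing_prob)) {
    return(tibble::tibble(variable = character(), centre_id = character(),
                          prob = numeric()))
  }
  if (is.data.frame(missing_prob)) return(tibble::as_tibble(missing_prob))
  tibble::tibble(variable = names(missing_prob), centre_id = NA_character_,
                 prob = unname(missing_prob))
}

# move a derived day count by `offset` days by editing flag days at the run
# boundary; returns the achieved offset
shift_flag_days <- function(flags, usable, offset) {
  if (offset > 0) {
    candidates <- which(!flags & usable)
    take <- head(candidates, offset)
    flags[take] <- TRUE
    list(flags = flags, achieved = length(take))
  } else {
    on <- which(flags & usable)
    take <- tail(on, -offset)
    flags[take] <- FALSE
    list(flags = flags, achieved = -length(take))
  }
}

inject_jitter <- function(v, infants, episodes, daily, offsets, dist, note) {
  n <- nrow(infants)
  if (v == "edd") {
    off <- sample(offsets, n, replace = TRUE, prob = dist)
    hit <- which(off != 0L & !is.na(infants$edd))
    infants$edd[hit] <- infants$edd[hit] + off[hit]
    if (length(hit)) note(infants$infant_id[hit], v, "jittered", offset = off[hit])
  } else if (v == "length_of_stay") {
    # applied to the final episode so episodes stay ordered and disjoint
    for (i in seq_len(n)) {
      off <- sample(offsets, 1, prob = dist)
      if (off == 0L) next
      id <- infants$infant_id[i]
      rows <- which(episodes$infant_id == id)
      if (!length(rows)) next
      last <- rows[which.max(episodes$episode[rows])]
      old <- episodes$discharge_date[last]
      new <- max(episodes$admission_date[last], old + off)
      achieved <- as.integer(new - old)
      if (achieved == 0L) next
      episodes$discharge_date[last] <- new
      if (achieved < 0L) {
        daily <- daily[!(daily$infant_id == id & daily$episode == episodes$episode[last] &
                           daily$date > new), ]
      } else {
        extra <- tibble::tibble(
          infant_id = id, date = old + seq_len(achieved),
          mech_support = FALSE, oxygen = FALSE, central_line = FALSE,
          antibiotics = FALSE, antacid = FALSE,
          mbm = TRUE, hdm = FALSE, formula = FALSE, missing = FALSE,
          episode = episodes$episode[last])
        daily <- dplyr::bind_rows(daily, extra)
      }
      note(id, v, "jittered", episode = episodes$episode[last], offset = achieved)
    }
  } else if (v %in% c("central_line_days", "intensive_days")) {
    flag <- if (v == "central_line_days") "central_line" else "mech_support"
    for (r in seq_len(nrow(episodes))) {
      off <- sample(offsets, 1, prob = dist)
      if (off == 0L) next
      rows <- which(daily$infant_id == episodes$infant_id[r] &
                      daily$episode == episodes$episode[r])
      if (!length(rows)) next
      res <- shift_flag_days(daily[[flag]][rows], !daily$missing[rows], off)
      if (res$achieved == 0L) next
      daily[[flag]][rows] <- res$flags
      if (flag == "mech_support") {
        daily$oxygen[rows] <- daily$oxygen[rows] | daily$mech_support[rows]
      }
      note(episodes$infant_id[r], v, "jittered", episode = episodes$episode[r],
           offset = res$achieved)
    }
  } else if (v %in% c("antibiotic_days_14d", "antacid_days_14d", "day_of_first_milk")) {
    for (i in seq_len(n)) {
      off <- sample(offsets, 1, prob = dist)
      if (off == 0L) next
      id <- infants$infant_id[i]
      bd <- infants$birth_date[i]
      rows <- which(daily$infant_id == id & daily$date >= bd & daily$date <= bd + 13L)
      if (!length(rows)) next
      if (v == "day_of_first_milk") {
        fed <- daily$mbm[rows] | daily$hdm[rows] | daily$formula[rows]
        if (!any(fed)) next
        first <- min(which(fed))
        if (off > 0) {
          clear <- rows[seq(first, min(first + off - 1L, length(rows)))]
          daily$mbm[clear] <- FALSE; daily$hdm[clear] <- FALSE; daily$formula[clear] <- FALSE
          achieved <- length(clear)
        } else {
          add <- rows[seq(max(1L, first + off), first - 1L)]
          if (!length(add)) next
          daily$mbm[add] <- TRUE
          achieved <- -length(add)
        }
        note(id, v, "jittered", offset = achieved)
      } else {
        flag <- if (v == "antibiotic_days_14d") "antibiotics" else "antacid"
        res <- shift_flag_days(daily[[flag]][rows], !daily$missing[rows], off)
        if (res$achieved == 0L) next
        daily[[flag]][rows] <- res$flags
        note(id, v, "jittered", offset = res$achieved)
      }
    }
  }
  list(infants = infants, episodes = episodes, daily = daily)
}

#' @export
print.neo_epr <- function(x, ...) {
  cat(sprintf("EPR registry twin: %d infants (%d unlinkable), %d episodes, %d injections logged\n",
              nrow(x$infants), sum(is.na(x$id_map$epr_id)), nrow(x$episodes),
              nrow(x$truth_log)))
  invisible(x)
}
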