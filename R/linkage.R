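#' Match episodes of care between two databases for one infant
#'
#' Episodes are matched order-preservingly on admission time: a gold and a
#' registry episode are compatible when they are at the same unit (matched
#' on canonical unit codes, not free-text names) and their admission dates
#' differ by at most `admission_tolerance` days. The maximum
#' order-preserving matching is found by dynamic programming, so raising
#' the tolerance can only keep or increase the number of matched pairs.
#' Unmatched gold episodes carry a reason code: `inconsistent_dates` when
#' a same-unit registry episode exists but fell outside the window (or
#' when episodes within one database overlap), `inconsistent_hospital`
#' when only differently-coded units remain, `missing_episode` when the
#' registry holds no candidate at all.
#'
#' @param gold_eps,epr_eps Episode tibbles for a single infant (`episode`,
#'   `unit_id`, `admission_date`, `discharge_date`).
#' @param admission_tolerance Maximum admission-date difference in days,
#'   default 1.
#' @return A list with `pairs` (tibble `gold_episode`, `epr_episode`),
#'   `unmatched_gold` (tibble `episode`, `reason`) and `unmatched_epr`
#'   (tibble `episode`).
#' @export
match_episodes <- function(gold_eps, epr_eps, admission_tolerance = 1) {
  gold_eps <- dplyr::arrange(gold_eps, .data$admission_date)
  epr_eps <- dplyr::arrange(epr_eps, .data$admission_date)
  overlap <- function(eps) {
    nrow(eps) > 1 && any(eps$admission_date[-1] <= eps$discharge_date[-nrow(eps)])
  }
  if (overlap(gold_eps) || overlap(epr_eps)) {
    return(list(pairs = tibble::tibble(gold_episode = integer(), epr_episode = integer()),
                unmatched_gold = tibble::tibble(episode = gold_eps$episode,
                                                reason = "inconsistent_dates"),
                unmatched_epr = tibble::tibble(episode = epr_eps$episode)))
  }
  ng <- nrow(gold_eps); ne <- nrow(epr_eps)
  comp <- outer(seq_len(ng), seq_len(ne), function(i, j) {
    gold_eps$unit_id[i] == epr_eps$unit_id[j] &
      abs(as.numeric(gold_eps$admission_date[i] - epr_eps$admission_date[j])) <=
        admission_tolerance
  })
  # longest order-preserving matching
  m <- matrix(0L, ng + 1L, ne + 1L)
  for (i in seq_len(ng)) for (j in seq_len(ne)) {
    m[i + 1L, j + 1L] <- max(m[i, j + 1L], m[i + 1L, j],
                             m[i, j] + as.integer(comp[i, j]))
  }
  pairs <- list()
  i <- ng; j <- ne
  while (i > 0L && j > 0L) {
    if (comp[i, j] && m[i + 1L, j + 1L] == m[i, j] + 1L) {
      pairs[[length(pairs) + 1L]] <- c(i, j)
      i <- i - 1L; j <- j - 1L
    } else if (m[i, j + 1L] >= m[i + 1L, j]) {
      i <- i - 1L
    } else {
      j <- j - 1L
    }
  }
  pairs <- if (length(pairs)) do.call(rbind, rev(pairs)) else
    matrix(integer(0), 0, 2)
  matched_g <- pairs[, 1]; matched_e <- pairs[, 2]
  un_g <- setdiff(seq_len(ng), matched_g)
  un_e <- setdiff(seq_len(ne), matched_e)
  reason <- vapply(un_g, function(i) {
    same_unit <- un_e[epr_eps$unit_id[un_e] == gold_eps$unit_id[i]]
    if (length(same_unit)) "inconsistent_dates"
    else if (length(un_e)) "inconsistent_hospital"
    else "missing_episode"
  }, character(1))
  list(pairs = tibble::tibble(gold_episode = gold_eps$episode[matched_g],
                              epr_episode = epr_eps$episode[matched_e]),
       unmatched_gold = tibble::tibble(episode = gold_eps$episode[un_g], reason = reason),
       unmatched_epr = tibble::tibble(episode = epr_eps$episode[un_e]))
}

#' Link infants and episodes across the gold and registry databases
#'
#' Pairs each gold infant with its registry counterpart through the opaque
#' registry identifier, then requires every gold episode of care to match
#' a registry episode (see [match_episodes()]). An infant without a
#' supplied identifier is excluded with code `no_id`; an infant with one
#' or more unmatched gold episodes is wholly excluded, carrying the first
#' unmatched episode's reason code. Every gold infant appears exactly once
#' among the linked or the excluded.
#'
#' @param gold A cohort list (`infants`, `episodes`).
#' @param epr A registry list (`infants`, `episodes`), with an `id_map`
#'   tibble (`infant_id`, `epr_id`) as produced by [make_epr_twin()]; if
#'   absent, identifiers are assumed shared (self-linkage).
#' @param admission_tolerance Days of admission-date tolerance for episode
#'   matching.
#' @return A list of class `neo_linked`: `infants` (tibble `infant_id`,
#'   `epr_id`, `status`, `reason`), `episode_pairs`, `excluded_episodes`,
#'   and `summary` (linked/excluded counts).
#' @export
link_infants <- function(gold, epr, admission_tolerance = 1) {
  if (anyDuplicated(gold$infants$infant_id)) stop_field("gold", "duplicate infant_id")
  if (anyDuplicated(epr$infants$infant_id)) stop_field("epr", "duplicate infant_id")
  id_map <- epr$id_map %||%
    tibble::tibble(infant_id = gold$infants$infant_id,
                   epr_id = gold$infants$infant_id)
  ids <- gold$infants$infant_id
  eids <- id_map$epr_id[match(ids, id_map$infant_id)]
  eids[!eids %in% epr$infants$infant_id] <- NA_character_
  no_id <- tibble::tibble(infant_id = ids[is.na(eids)], epr_id = NA_character_,
                          status = "excluded", reason = "no_id")

  # fast path: positionally aligned, non-overlapping, compatible episode runs
  seq_tag <- function(eps) {
    eps |>
      dplyr::arrange(.data$infant_id, .data$admission_date) |>
      dplyr::group_by(.data$infant_id) |>
      dplyr::mutate(.idx = dplyr::row_number(),
                    .overlap = dplyr::n() > 1 &&
                      any(.data$admission_date[-1] <= .data$discharge_date[-dplyr::n()])) |>
      dplyr::ungroup()
  }
  ge <- seq_tag(gold$episodes) |>
    dplyr::mutate(epr_id = eids[match(.data$infant_id, ids)]) |>
    dplyr::filter(!is.na(.data$epr_id))
  ee <- seq_tag(epr$episodes) |>
    dplyr::rename(epr_id = "infant_id")
  aligned <- dplyr::full_join(
    dplyr::select(ge, "infant_id", "epr_id", gold_episode = "episode", ".idx",
                  g_unit = "unit_id", g_adm = "admission_date", g_ov = ".overlap"),
    dplyr::select(ee, "epr_id", epr_episode = "episode", ".idx",
                  e_unit = "unit_id", e_adm = "admission_date", e_ov = ".overlap"),
    by = c("epr_id", ".idx"))
  status <- aligned |>
    dplyr::group_by(.data$epr_id) |>
    dplyr::summarise(clean = !any(is.na(.data$gold_episode)) &&
                       !any(is.na(.data$epr_episode)) &&
                       !any(.data$g_ov) && !any(.data$e_ov) &&
                       all(.data$g_unit == .data$e_unit &
                             abs(as.numeric(.data$g_adm - .data$e_adm)) <=
                               admission_tolerance),
                     .groups = "drop")
  clean_eids <- status$epr_id[status$clean]
  fast_pairs <- aligned |>
    dplyr::filter(.data$epr_id %in% clean_eids) |>
    dplyr::select("infant_id", "epr_id", "gold_episode", "epr_episode")
  fast_infants <- tibble::tibble(
    infant_id = ids[!is.na(eids) & eids %in% clean_eids],
    epr_id = eids[!is.na(eids) & eids %in% clean_eids],
    status = "linked", reason = NA_character_)

  # slow path: full order-preserving matching with reason codes
  slow_ids <- ids[!is.na(eids) & !eids %in% clean_eids]
  empty_eps <- tibble::tibble(episode = integer(), unit_id = character(),
                              admission_date = as.Date(character()),
                              discharge_date = as.Date(character()))
  split_eps <- function(eps, who) {
    eps <- eps[eps$infant_id %in% who, ]
    g <- dplyr::group_by(eps, .data$infant_id)
    setNames(as.list(dplyr::group_split(g)), dplyr::group_keys(g)$infant_id)
  }
  slow_eids <- eids[match(slow_ids, ids)]
  gold_eps <- split_eps(gold$episodes, slow_ids)
  epr_eps <- split_eps(epr$episodes, slow_eids)
  rows <- purrr::map2(slow_ids, slow_eids, function(id, eid) {
    mm <- match_episodes(
      if (id %in% names(gold_eps)) gold_eps[[id]] else empty_eps,
      if (eid %in% names(epr_eps)) epr_eps[[eid]] else empty_eps,
      admission_tolerance)
    if (nrow(mm$unmatched_gold)) {
      list(infant = tibble::tibble(infant_id = id, epr_id = eid, status = "excluded",
                                   reason = mm$unmatched_gold$reason[1]),
           pairs = NULL,
           unmatched = dplyr::mutate(mm$unmatched_gold, infant_id = id))
    } else {
      list(infant = tibble::tibble(infant_id = id, epr_id = eid, status = "linked",
                                   reason = NA_character_),
           pairs = dplyr::mutate(mm$pairs, infant_id = id, epr_id = eid),
           unmatched = NULL)
    }
  })
  infants <- dplyr::bind_rows(no_id, fast_infants,
                              dplyr::bind_rows(purrr::map(rows, "infant"))) |>
    dplyr::arrange(match(.data$infant_id, ids))
  episode_pairs <- dplyr::bind_rows(fast_pairs,
                                    purrr::compact(purrr::map(rows, "pairs")))
  excluded_episodes <- dplyr::bind_rows(purrr::compact(purrr::map(rows, "unmatched")))
  if (nrow(excluded_episodes) == 0L) {
    excluded_episodes <- tibble::tibble(episode = integer(), reason = character(),
                                        infant_id = character())
  }
  out <- list(
    infants = infants,
    episode_pairs = episode_pairs,
    excluded_episodes = excluded_episodes,
    summary = tibble::tibble(
      n_gold = nrow(infants),
      n_linked = sum(infants$status == "linked"),
      n_excluded = sum(infants$status == "excluded"),
      n_no_id = sum(infants$reason == "no_id", na.rm = TRUE),
      n_episode_pairs = nrow(episode_pairs)))
  class(out) <- "neo_linked"
  out
}

#' @export
print.neo_linked <- function(x, ...) {
  s <- x$summary
  cat(sprintf("linked cohort: %d of %d infants linked (%d excluded, of which %d without identifier); %d episode pairs\n",
              s$n_linked, s$n_gold, s$n_excluded, s$n_no_id, s$n_episode_pairs))
  invisible(x)
}

#' Write the exclusion audit to CSV
#'
#' One row per excluded infant and per unmatched gold episode, with the
#' closed set of reason codes (`no_id`, `missing_episode`,
#' `inconsistent_dates`, `inconsistent_hospital`).
#'
#' @param linked A `neo_linked` object.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_exclusion_audit <- function(linked, path) {
  inf <- linked$infants |>
    dplyr::filter(.data$status == "excluded") |>
    dplyr::transmute(.data$infant_id, level = "infant", reason = .data$reason,
                     detail = NA_character_)
  eps <- linked$excluded_episodes
  eps <- if (nrow(eps)) dplyr::transmute(eps, .data$infant_id, level = "episode",
                                         reason = .data$reason,
                                         detail = sprintf("episode %d", .data$episode))
         else NULL
  readr::write_csv(dplyr::bind_rows(inf, eps), path)
  invisible(path)
}
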