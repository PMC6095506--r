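#' Cross-classify paired binary values into a 2x2 table
#'
#' Treats the gold database as truth and the EPR-derived value as the index
#' test. Pairs with either side missing are dropped before counting (the
#' audit excludes them from all accuracy calculations).
#'
#' @param gold,index Logical (or 0/1) vectors of equal length.
#' @return An object of class `two_by_two` with counts `tp`, `fp`, `fn`,
#'   `tn`. The counts partition the comparable pairs: `tp + fn` are the
#'   gold positives and `tp + fp` the index positives.
#' @examples
#' two_by_two(c(TRUE, TRUE, FALSE, FALSE), c(TRUE, FALSE, FALSE, TRUE))
#' @export
two_by_two <- function(gold, index) {
  if (length(gold) != length(index)) stop_field("index", "gold and index lengths differ")
  gold <- as_binary(gold, "gold")
  index <- as_binary(index, "index")
  keep <- !is.na(gold) & !is.na(index)
  gold <- gold[keep]
  index <- index[keep]
  as_two_by_two(tp = sum(gold & index), fp = sum(!gold & index),
                fn = sum(gold & !index), tn = sum(!gold & !index))
}

as_binary <- function(x, what) {
  if (is.logical(x)) return(x)
  if (is.numeric(x) && all(x %in% c(0, 1, NA))) return(x == 1)
  stop_field(what, "must be logical or 0/1")
}

#' @rdname two_by_two
#' @param tp,fp,fn,tn Non-negative cell counts.
#' @export
as_two_by_two <- function(tp, fp, fn, tn) {
  cells <- c(tp, fp, fn, tn)
  if (any(is.na(cells)) || any(cells < 0)) stop_field("counts", "cells must be non-negative")
  cells <- as.integer(cells)
  structure(list(tp = cells[1], fp = cells[2], fn = cells[3], tn = cells[4]),
            class = "two_by_two")
}

#' Reconstruct a 2x2 table from marginals and sensitivity
#'
#' Published accuracy tables often print only the row/column marginals and
#' the sensitivity; those determine the four cells: `tp = round(sens *
#' gold_pos)`, `fn = gold_pos - tp`, `fp = index_pos - tp`,
#' `tn = gold_neg - fp`.
#'
#' @param gold_pos,gold_neg Gold-standard positive and negative counts.
#' @param index_pos Index-test positive count.
#' @param sensitivity Sensitivity in percent.
#' @return A `two_by_two` object.
#' @examples
#' two_by_two_from_margins(24, 1234, 18, 50.0)
#' @export
two_by_two_from_margins <- function(gold_pos, gold_neg, index_pos, sensitivity) {
  tp <- round(sensitivity / 100 * gold_pos)
  as_two_by_two(tp = tp, fn = gold_pos - tp,
                fp = index_pos - tp, tn = gold_neg - (index_pos - tp))
}

#' @export
print.two_by_two <- function(x, ...) {
  m <- matrix(c(x$tp, x$fn, x$fp, x$tn), 2, 2,
              dimnames = list(gold = c("pos", "neg"), index = c("pos", "neg")))
  cat("2x2 cross-classification (gold rows, index columns)\n")
  print(t(m))
  invisible(x)
}

#' Diagnostic-accuracy metrics with exact binomial intervals
#'
#' Computes both prevalences, sensitivity, specificity, PPV and NPV from a
#' 2x2 table, each as a percentage with its 95% Clopper–Pearson interval.
#' A metric whose denominator is zero is reported as explicitly undefined
#' (`defined = FALSE`, estimate `NA`) — never silently 0 or 100 — while
#' the remaining metrics are still returned.
#'
#' @param t A `two_by_two` object.
#' @param conf Confidence level.
#' @return An object of class `accuracy_metrics`: a tibble with one row
#'   per metric (`prevalence_gold`, `prevalence_index`, `sensitivity`,
#'   `specificity`, `ppv`, `npv`) holding `k`, `n`, `estimate`, `lower`,
#'   `upper` in percent, and `defined`.
#' @examples
#' accuracy_metrics(as_two_by_two(tp = 12, fp = 6, fn = 12, tn = 1228))
#' @export
accuracy_metrics <- function(t, conf = 0.95) {
  stopifnot(inherits(t, "two_by_two"))
  total <- t$tp + t$fp + t$fn + t$tn
  if (total == 0L) stop_field("t", "empty table: no comparable pairs")
  spec <- list(
    prevalence_gold  = c(t$tp + t$fn, total),
    prevalence_index = c(t$tp + t$fp, total),
    sensitivity      = c(t$tp, t$tp + t$fn),
    specificity      = c(t$tn, t$tn + t$fp),
    ppv              = c(t$tp, t$tp + t$fp),
    npv              = c(t$tn, t$tn + t$fn))
  out <- purrr::imap(spec, function(kn, metric) {
    k <- kn[1]; n <- kn[2]
    if (n == 0L) {
      tibble::tibble(metric = metric, k = k, n = n, estimate = NA_real_,
                     lower = NA_real_, upper = NA_real_, defined = FALSE)
    } else {
      ci <- ci_clopper_pearson(k, n, conf)
      tibble::tibble(metric = metric, k = k, n = n, estimate = 100 * k / n,
                     lower = 100 * ci$lower, upper = 100 * ci$upper, defined = TRUE)
    }
  })
  out <- dplyr::bind_rows(out)
  class(out) <- c("accuracy_metrics", class(out))
  out
}

#' @export
tidy.two_by_two <- function(x, ...) {
  tibble::tibble(gold = c(TRUE, TRUE, FALSE, FALSE),
                 index = c(TRUE, FALSE, TRUE, FALSE),
                 n = c(x$tp, x$fn, x$fp, x$tn))
}

#' @export
tidy.accuracy_metrics <- function(x, ...) {
  tibble::as_tibble(x)
}

#' @export
glance.accuracy_metrics <- function(x, ...) {
  wide <- setNames(round_rate(x$estimate), x$metric)
  dplyr::bind_cols(tibble::tibble(n = x$n[x$metric == "prevalence_gold"]),
                   tibble::as_tibble(as.list(wide)))
}

#' Accuracy table across all binary variables
#'
#' Builds the full diagnostic-accuracy report from paired infant-level
#' derived tables: for every binary rule variable present in both tables,
#' a 2x2 table and the accuracy metrics.
#'
#' @inheritParams concordance_table
#' @return A tibble of class `neo_accuracy`: one row per variable with
#'   marginal counts and each metric's estimate and bounds in percent.
#' @export
accuracy_table <- function(gold_df, epr_df, rules = default_rules(),
                           by = "infant_id", conf = 0.95) {
  validate_rules(rules)
  rules <- dplyr::filter(rules, .data$kind == "binary",
                         .data$variable %in% names(gold_df),
                         .data$variable %in% names(epr_df))
  paired <- dplyr::inner_join(
    dplyr::select(gold_df, dplyr::all_of(c(by, rules$variable))),
    dplyr::select(epr_df, dplyr::all_of(c(by, rules$variable))),
    by = by, suffix = c("_gold", "_epr"))
  out <- purrr::map(rules$variable, function(v) {
    t <- two_by_two(paired[[paste0(v, "_gold")]], paired[[paste0(v, "_epr")]])
    m <- accuracy_metrics(t, conf)
    wide <- tidyr::pivot_wider(dplyr::select(m, "metric", "estimate", "lower", "upper"),
                               names_from = "metric",
                               values_from = c("estimate", "lower", "upper"),
                               names_glue = "{metric}_{.value}")
    dplyr::bind_cols(
      tibble::tibble(variable = v,
                     gold_pos = t$tp + t$fn, gold_neg = t$fp + t$tn,
                     index_pos = t$tp + t$fp, index_neg = t$fn + t$tn,
                     n_comparable = t$tp + t$fp + t$fn + t$tn),
      wide)
  })
  out <- dplyr::bind_rows(out)
  class(out) <- c("neo_accuracy", class(out))
  out
}
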