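#' Binomial and Poisson-approximation confidence intervals
#'
#' The three interval methods used throughout the audit reports.
#'
#' * `ci_clopper_pearson()` — exact (Clopper–Pearson) binomial interval via
#'   beta quantiles; the lower bound is 0 when `k = 0` and the upper bound
#'   is 1 when `k = n`. Used for sensitivity, specificity, predictive
#'   values and prevalences.
#' * `ci_agresti_coull()` — adjusted-Wald interval adding \eqn{z^2/2}
#'   pseudo-successes; good coverage for moderate proportions. Used for
#'   discordancy rates at or above 5%.
#' * `ci_poisson_exact()` — exact Poisson interval for the discordant count
#'   (gamma quantiles), scaled by the comparable `n`. The Poisson
#'   approximation to the binomial is preferred for rates below 5%; for
#'   `k = 0` the upper bound is \eqn{-\log(\alpha/2)/n}.
#'
#' @param k Number of successes (discordant pairs), non-negative integer
#'   vector.
#' @param n Number of trials (comparable pairs), positive integer vector.
#' @param conf Confidence level, default 0.95.
#' @return A tibble with columns `lower` and `upper` on the proportion
#'   scale, clipped to \[0, 1\].
#' @examples
#' ci_clopper_pearson(12, 24)        # 0.291, 0.709
#' ci_poisson_exact(2, 1258)         # 0.0002, 0.0057
#' ci_agresti_coull(117, 877)        # 0.112, 0.158
#' @name intervals
NULL

#' @rdname intervals
#' @export
ci_clopper_pearson <- function(k, n, conf = 0.95) {
  check_kn(k, n)
  alpha <- 1 - conf
  lower <- ifelse(k == 0, 0, qbeta(alpha / 2, k, n - k + 1))
  upper <- ifelse(k == n, 1, qbeta(1 - alpha / 2, k + 1, n - k))
  tibble::tibble(lower = lower, upper = upper)
}

#' @rdname intervals
#' @export
ci_agresti_coull <- function(k, n, conf = 0.95) {
  check_kn(k, n)
  z <- qnorm(1 - (1 - conf) / 2)
  n_t <- n + z^2
  p_t <- (k + z^2 / 2) / n_t
  half <- z * sqrt(p_t * (1 - p_t) / n_t)
  tibble::tibble(lower = clamp(p_t - half, 0, 1), upper = clamp(p_t + half, 0, 1))
}

#' @rdname intervals
#' @export
ci_poisson_exact <- function(k, n, conf = 0.95) {
  check_kn(k, n)
  alpha <- 1 - conf
  lower <- ifelse(k == 0, 0, qgamma(alpha / 2, k)) / n
  upper <- qgamma(1 - alpha / 2, k + 1) / n
  tibble::tibble(lower = clamp(lower, 0, 1), upper = clamp(upper, 0, 1))
}

check_kn <- function(k, n) {
  if (any(is.na(k)) || any(is.na(n)) || any(k < 0) || any(n < 1) || any(k > n)) {
    stop("require 0 <= k <= n and n >= 1", call. = FALSE)
  }
  invisible(NULL)
}
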