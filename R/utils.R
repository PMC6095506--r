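# shared internal helpers

# report rounding: one decimal place, except values below 0.1% which keep
# two decimals so small lower bounds don't collapse to 0.0
round_rate <- function(x) {
  out <- round(x, 1)
  small <- !is.na(x) & x > 0 & x < 0.1
  out[small] <- round(x[small], 2)
  out
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

is_prob <- function(x) is.numeric(x) && all(!is.na(x)) && all(x >= 0 & x <= 1)

stop_field <- function(field, msg) {
  stop(sprintf("invalid `%s`: %s", field, msg), call. = FALSE)
}

# canonical string for a set of milk types, e.g. "HDM+MBM"
milk_set <- function(mbm, hdm, formula) {
  vapply(seq_along(mbm), function(i) {
    types <- c("HDM", "MBM", "formula")[c(hdm[i], mbm[i], formula[i])]
    if (length(types) == 0L) "" else paste(sort(types), collapse = "+")
  }, character(1))
}
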