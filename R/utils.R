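## Truncated-normal sampling by inverse CDF. Degenerate sd draws still
## consume n uniforms so the RNG stream stays aligned across cells.
rtruncnorm <- function(n, mean, sd, lower = 0, upper = Inf) {
  stopifnot(sd >= 0, lower <= upper)
  u <- stats::runif(n)
  if (sd == 0) {
    return(rep(pmin(pmax(mean, lower), upper), n))
  }
  plo <- stats::pnorm(lower, mean, sd)
  phi <- stats::pnorm(upper, mean, sd)
  stats::qnorm(plo + u * (phi - plo), mean, sd)
}

#' Format a value in 3-significant-figure scientific notation
#'
#' Renders risk indices the way the publication-style tables print them,
#' e.g. `1.87E-03`.
#'
#' @param x numeric vector.
#' @return character vector; `NA` elements render as `NA`.
#' @export
format_sci <- function(x) {
  out <- ifelse(is.na(x), NA_character_, sprintf("%.2E", x))
  out
}

## Internal assertion helpers ------------------------------------------------

assert_positive <- function(x, name) {
  if (!is.numeric(x) || any(!is.finite(x)) || any(x <= 0)) {
    stop(sprintf("`%s` must be a finite positive number", name), call. = FALSE)
  }
  invisible(x)
}

assert_nonnegative <- function(x, name) {
  if (!is.numeric(x) || any(!is.finite(x)) || any(x < 0)) {
    stop(sprintf("`%s` must be a finite non-negative number", name), call. = FALSE)
  }
  invisible(x)
}
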