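#' @keywords internal
"_PACKAGE"

# Structured error helper so callers can distinguish failure modes
# (format/validation/packing/degenerate-input) with tryCatch.
ssf_stop <- function(class, fmt, ...) {
  msg <- sprintf(fmt, ...)
  stop(structure(
    class = c(class, "ssf_error", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}

#' Derive a reproducible sub-seed from a master seed and stream indices
#'
#' Polynomial hash of the integer parts, kept below 2^31 so the result is a
#' valid R seed. Used to give every (radius, simulation) task its own RNG
#' stream so results are identical regardless of execution order.
#'
#' @param ... integer components (master seed first, then stream indices).
#' @return A single integer seed.
#' @export
derive_seed <- function(...) {
  parts <- c(...)
  stopifnot(length(parts) >= 1, all(is.finite(parts)))
  h <- 17
  for (v in parts) {
    h <- (h * 1000003 + (as.numeric(v) %% 2147483629)) %% 2147483629
  }
  as.integer(h + 1)
}

#' Wilson score confidence interval for a binomial proportion
#'
#' Preferred over the Wald interval for the small counts that arise at low
#' false-positive rates.
#'
#' @param k number of successes.
#' @param n number of trials.
#' @param conf confidence level (default 0.95).
#' @return Numeric vector `c(lower, upper)`.
#' @export
wilson_ci <- function(k, n, conf = 0.95) {
  stopifnot(n >= 1, k >= 0, k <= n)
  z <- stats::qnorm(1 - (1 - conf) / 2)
  p <- k / n
  denom <- 1 + z^2 / n
  center <- (p + z^2 / (2 * n)) / denom
  half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / denom
  c(lower = max(0, center - half), upper = min(1, center + half))
}

# Euclidean coordinates of a sample table as an n x 3 matrix.
coord_matrix <- function(table) {
  as.matrix(table[, c("x", "y", "z")])
}
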