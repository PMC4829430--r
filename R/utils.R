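# Error-function family expressed through the normal CDF; used throughout for
# washout detection, the catastrophe speed transition and comet fitting.

#' Error function and relatives
#'
#' `erf(x)` is the standard error function, `erfc(x) = 1 - erf(x)`, and
#' `erfinv(p)` its inverse on (-1, 1). All are thin wrappers around
#' [stats::pnorm()] / [stats::qnorm()].
#'
#' @param x,p Numeric vectors.
#' @return Numeric vector of the same length.
#' @export
erf <- function(x) 2 * stats::pnorm(x * sqrt(2)) - 1

#' @rdname erf
#' @export
erfc <- function(x) 2 * stats::pnorm(x * sqrt(2), lower.tail = FALSE)

#' @rdname erf
#' @export
erfinv <- function(p) {
  stopifnot(all(is.finite(p)), all(abs(p) < 1))
  stats::qnorm((p + 1) / 2) / sqrt(2)
}

# scalar argument checks -----------------------------------------------------

stop_invalid <- function(...) {
  stop(errorCondition(paste0(...), class = c("ebcap_invalid_argument", "error")))
}

stop_numerical <- function(...) {
  stop(errorCondition(paste0(...), class = c("ebcap_numerical_failure", "error")))
}

check_scalar <- function(x, name, positive = FALSE, nonneg = FALSE) {
  if (length(x) != 1L || !is.numeric(x) || !is.finite(x))
    stop_invalid(name, " must be a finite numeric scalar")
  if (positive && x <= 0) stop_invalid(name, " must be > 0, got ", x)
  if (nonneg && x < 0) stop_invalid(name, " must be >= 0, got ", x)
  invisible(as.numeric(x))
}

check_vector <- function(x, name, nonneg = FALSE) {
  if (!is.numeric(x) || any(!is.finite(x)))
    stop_invalid(name, " must be finite numeric")
  if (nonneg && any(x < 0)) stop_invalid(name, " must be >= 0")
  invisible(as.numeric(x))
}
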