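# Cohort-level correlation statistics and the relative-variance statistic D.

#' Spearman rank correlation with t-approximation p-value
#'
#' Rank correlation with midranks for ties; the two-sided p-value uses the
#' t-distribution approximation `t = rho sqrt((n - 2) / (1 - rho^2))` with
#' `n - 2` degrees of freedom. For small samples (`n <= 8`) an exact
#' permutation p-value can be requested instead.
#'
#' @param x,y Paired numeric samples (n >= 5 recommended).
#' @param exact Use full permutation enumeration for the p-value (n <= 8).
#' @return An object of class `correlation_result`: list with `rho`, `p`,
#'   `n`, and `method`.
#' @examples
#' spearman_cor(1:5, c(2, 1, 4, 3, 5))$rho  # 0.8
#' @export
spearman_cor <- function(x, y, exact = FALSE) {
  ok <- stats::complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3L) stop_invalid("need at least 3 complete pairs, got ", n)
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop(errorCondition("correlation undefined for constant input",
                        class = c("ebcap_undefined_correlation", "error")))
  rho_of <- function(a, b) stats::cor(rank(a), rank(b))
  rho <- rho_of(x, y)
  if (exact) {
    if (n > 8L) stop_invalid("exact permutation p limited to n <= 8")
    perms <- permutations_of(n)
    rhos <- apply(perms, 1, function(idx) rho_of(x, y[idx]))
    p <- if (rho >= 0) 2 * mean(rhos >= rho - 1e-12) else
      2 * mean(rhos <= rho + 1e-12)
    p <- min(1, p)
    method <- "exact permutation"
  } else {
    if (abs(rho) >= 1) {
      p <- 0
    } else {
      tstat <- rho * sqrt((n - 2) / (1 - rho^2))
      p <- 2 * stats::pt(abs(tstat), df = n - 2, lower.tail = FALSE)
    }
    method <- "t approximation"
  }
  structure(list(rho = rho, p = p, n = n, method = method,
                 shift = NA_real_),
            class = "correlation_result")
}

# all n! permutations of 1..n as rows (n small)
permutations_of <- function(n) {
  if (n == 1L) return(matrix(1L, 1, 1))
  sub <- permutations_of(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(k)
    cbind(k, ifelse(sub >= k, sub + 1L, sub))))
}

#' @export
print.correlation_result <- function(x, ...) {
  cat(sprintf("Spearman rho = %.3f (n = %d, p = %.3g, %s)\n",
              x$rho, x$n, x$p, x$method))
  invisible(x)
}

#' Correlation of delay with a quantity measured in shifted windows
#'
#' Recomputes a pre-washout quantity in windows shifted progressively away
#' from the washout time and correlates it with the delay time: growth speed
#' over 10 s windows, or EB end intensity over 1 s windows. Tracks whose
#' shifted window exits the record are dropped for that shift (reported in
#' `n`). A decay of `rho` with shift shows that stability reflects the
#' momentary growth state at washout.
#'
#' @param tracks List of [mt_track()] objects.
#' @param metrics Metrics table from [analyze_cohort()].
#' @param quantity `"growth_speed"` or `"gfp_intensity"`.
#' @param shifts Window shifts (s).
#' @param speed_window Window for growth speeds (s), default 10.
#' @param intensity_window Window for intensities (s), default 1.
#' @return A `data.frame` with columns `quantity`, `shift_s`, `rho`, `p`, `n`.
#' @export
correlation_vs_shift <- function(tracks, metrics,
                                 quantity = c("growth_speed", "gfp_intensity"),
                                 shifts = seq(0, 14, by = 2),
                                 speed_window = 10, intensity_window = 1) {
  quantity <- match.arg(quantity)
  tracks <- tracks[match(metrics$id, vapply(tracks, `[[`, "", "id"))]
  rows <- lapply(shifts, function(sh) {
    vals <- vapply(seq_along(tracks), function(i) {
      tr <- tracks[[i]]; m <- metrics[i, ]
      tryCatch({
        if (quantity == "growth_speed") {
          growth_speed(tr, m$t_wo, window = speed_window, shift = sh)
        } else {
          if (is.null(tr$gfp_end)) return(NA_real_)
          lo <- m$t_wo - sh - intensity_window; hi <- m$t_wo - sh
          if (lo < tr$time[1]) return(NA_real_)
          sel <- tr$time >= lo & tr$time <= hi
          if (!any(sel)) NA_real_ else mean(tr$gfp_end[sel])
        }
      }, error = function(e) NA_real_)
    }, numeric(1))
    ok <- stats::complete.cases(vals, metrics$delay)
    cr <- spearman_cor(vals[ok], metrics$delay[ok])
    data.frame(quantity = quantity, shift_s = sh, rho = cr$rho, p = cr$p,
               n = cr$n, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Relative variance D of intensity series
#'
#' `D = var / mean` of the per-frame EB intensity of one microtubule; a
#' variance-over-mean statistic that separates microtubules with a variable
#' number of EB binding sites (GTP growth, fluctuating cap size, large D)
#' from mimics with a constant site density (GTPgammaS lattice, small D).
#' Given a list of series, per-microtubule D values plus their cohort mean
#' and sd are returned.
#'
#' @param series A numeric vector (one microtubule's intensity series,
#'   length >= 100) or a list of such vectors.
#' @return For a single series, the scalar D. For a list: list with `D`
#'   (per-microtubule), `mean`, `sd`, `n`.
#' @export
relative_variance <- function(series) {
  one <- function(v) {
    check_vector(v, "series")
    if (length(v) < 100L)
      stop_invalid("series must have at least 100 frames, got ", length(v))
    m <- mean(v)
    if (m <= 0) stop_invalid("series mean must be positive, got ", m)
    stats::var(v) / m
  }
  if (is.list(series)) {
    D <- vapply(series, one, numeric(1))
    list(D = D, mean = mean(D), sd = stats::sd(D), n = length(D))
  } else {
    one(series)
  }
}
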