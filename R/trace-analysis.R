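# Per-track analysis of tubulin-washout traces: washout-time detection from
# the background channel, pre-washout growth speed, catastrophe detection by
# an error-function speed-transition fit, and shrinkage/intensity metrics.

# Antiderivative of erf((t0 - t) / (2 sigma)) in t, so the position model can
# be fitted in closed form: d/dt G = erf((t0 - t)/(2 sigma)).
erf_antideriv <- function(t, t0, sigma) {
  u <- (t0 - t) / (2 * sigma)
  -2 * sigma * (u * erf(u) + exp(-u^2) / sqrt(pi))
}

# Fitted position model after washout: slow shrinkage v1 transitioning to
# fast depolymerisation v2 through an erf centred at t0 with width sigma.
catastrophe_position <- function(t, x_wo, t_wo, v1, v2, t0, sigma) {
  x_wo + 0.5 * (v1 + v2) * (t - t_wo) +
    0.5 * (v1 - v2) * (erf_antideriv(t, t0, sigma) -
                         erf_antideriv(t_wo, t0, sigma))
}

#' Detect the tubulin washout time from the background channel
#'
#' Fits `I(t) = I_lo + 0.5 (I_hi - I_lo) (1 - erf((t - t_wo) / (2 tau)))` to
#' the soluble-tubulin background intensity and returns the inflection point
#' `t_wo` together with the 5-95% exchange interval
#' `exchange_90 = 4 tau erfinv(0.9)`.
#'
#' @param track An [mt_track()].
#' @return List with `t_wo` (s), `exchange_90` (s), `tau` (s) and the fitted
#'   plateau levels `I_hi`, `I_lo`.
#' @export
detect_washout <- function(track) {
  t <- track$time; y <- track$background
  n <- length(y)
  q <- max(3L, n %/% 10L)
  hi0 <- mean(y[seq_len(q)]); lo0 <- mean(y[seq.int(n - q + 1L, n)])
  noise_sd <- stats::sd(diff(y[seq_len(max(q, 8L))])) / sqrt(2)
  if (!is.finite(noise_sd) || noise_sd == 0) noise_sd <- .Machine$double.eps
  if ((hi0 - lo0) < 5 * noise_sd)
    stop(errorCondition(
      sprintf("no washout transition detected (amplitude %.3g < 5 x noise sd %.3g)",
              hi0 - lo0, noise_sd),
      class = c("ebcap_no_washout", "error")))
  dt <- mean(diff(t))
  t0 <- t[which.min(diff(y))] + dt / 2
  model <- function(par)
    par[["lo"]] + 0.5 * (par[["hi"]] - par[["lo"]]) *
      (1 - erf((t - par[["two"]]) / (2 * par[["tau"]])))
  # nls.lm rather than nls: with a sub-frame exchange time the gradient in
  # tau is near-singular at the start values, which nlsModel() rejects
  fit <- tryCatch(
    minpack.lm::nls.lm(
      par = c(lo = lo0, hi = hi0, two = t0, tau = dt / 2),
      fn = function(par) y - model(par),
      lower = c(-Inf, -Inf, min(t), 1e-6),
      upper = c(Inf, Inf, max(t), diff(range(t))),
      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit) || fit$info %in% c(0, 9))
    stop(errorCondition("washout error-function fit failed to converge",
                        class = c("ebcap_no_washout", "error")))
  cf <- fit$par
  if ((cf[["hi"]] - cf[["lo"]]) < 5 * noise_sd)
    stop(errorCondition("no washout transition detected (fitted amplitude below 5 x noise sd)",
                        class = c("ebcap_no_washout", "error")))
  list(t_wo = unname(cf[["two"]]),
       exchange_90 = unname(4 * cf[["tau"]] * erfinv(0.9)),
       tau = unname(cf[["tau"]]),
       I_hi = unname(cf[["hi"]]), I_lo = unname(cf[["lo"]]))
}

#' Pre-washout growth speed
#'
#' Ordinary least-squares slope of the end position over a time window ending
#' `shift` seconds before washout (the window is
#' `[t_wo - shift - window, t_wo - shift]`; default the 10 s directly before
#' washout).
#'
#' @param track An [mt_track()].
#' @param t_wo Washout time (s), e.g. from [detect_washout()].
#' @param window Window length (s), default 10.
#' @param shift Shift of the window away from washout (s), default 0.
#' @return Growth speed (nm/s).
#' @export
growth_speed <- function(track, t_wo, window = 10, shift = 0) {
  check_scalar(window, "window", positive = TRUE)
  check_scalar(shift, "shift", nonneg = TRUE)
  lo <- t_wo - shift - window; hi <- t_wo - shift
  dt <- mean(diff(track$time))
  if (lo < track$time[1] - dt / 2)
    stop(errorCondition(
      sprintf("growth-speed window [%.3g, %.3g] s not covered by the record", lo, hi),
      class = c("ebcap_insufficient_data", "error")))
  sel <- track$time >= lo & track$time <= hi
  if (sum(sel) < 2L)
    stop(errorCondition("fewer than 2 samples in the growth-speed window",
                        class = c("ebcap_insufficient_data", "error")))
  unname(stats::coef(stats::lm(track$end_pos[sel] ~ track$time[sel]))[2])
}

#' Fit the catastrophe speed transition to the post-washout positions
#'
#' Nonlinear least squares of the analytic time-integral of the speed model
#' `v(t) = 0.5 (v1 + v2) + 0.5 (v1 - v2) erf((t0 - t) / (2 sigma))` to the
#' end positions after washout: a slow linear shrinkage `v1` transitioning to
#' fast depolymerisation `v2` through an error function centred at `t0` with
#' width `sigma`. Initialisation: `t0` from the most negative 3-frame
#' position drop, `v1` from an OLS fit to the first half of the post-washout
#' segment, `v2` from the last second, `sigma = 0.5` s, with 5 multi-starts
#' jittering `t0` by up to +/- 1 s.
#'
#' @inheritParams growth_speed
#' @return An object of class `catastrophe_fit`: `v1`, `v2` (nm/s, signed),
#'   `t0` (s), `sigma` (s), `t_cat` (s, the 25% criterion), `x_wo`, `rss`
#'   (nm^2) and the model function.
#' @export
fit_catastrophe <- function(track, t_wo) {
  sel <- track$time >= t_wo
  if (sum(sel) < 8L)
    stop(errorCondition("post-washout segment has fewer than 8 samples",
                        class = c("ebcap_insufficient_data", "error")))
  t <- track$time[sel]; x <- track$end_pos[sel]
  dt <- mean(diff(t))
  # init t0 at the steepest 3-frame drop
  d3 <- x[-(1:3)] - x[seq_len(length(x) - 3L)]
  t0_init <- t[which.min(d3) + 1L]
  half <- t <= t_wo + (t0_init - t_wo) / 2
  v1_init <- if (sum(half) >= 2)
    unname(stats::coef(stats::lm(x[half] ~ t[half]))[2]) else -10
  tail1 <- t >= max(t) - 1
  v2_init <- if (sum(tail1) >= 2)
    unname(stats::coef(stats::lm(x[tail1] ~ t[tail1]))[2]) else -480
  df <- data.frame(t = t, x = x)
  jitters <- c(0, -1, -0.5, 0.5, 1)
  best <- NULL
  for (j in jitters) {
    fit <- tryCatch(
      minpack.lm::nlsLM(
        x ~ catastrophe_position(t, xw, t_wo, v1, v2, t0, sigma),
        data = df,
        start = list(xw = x[1], v1 = v1_init, v2 = v2_init,
                     t0 = max(t_wo + dt, t0_init + j), sigma = 0.5),
        lower = c(-Inf, -Inf, -Inf, t_wo, 1e-3),
        upper = c(Inf, Inf, Inf, max(t) + 2, diff(range(t))),
        control = minpack.lm::nls.lm.control(maxiter = 300)),
      error = function(e) NULL)
    if (!is.null(fit)) {
      rss <- sum(stats::resid(fit)^2)
      if (is.null(best) || rss < best$rss)
        best <- list(fit = fit, rss = rss)
    }
  }
  if (is.null(best))
    stop(errorCondition("catastrophe fit failed to converge from all starts",
                        class = c("ebcap_fit_failure", "error")))
  cf <- as.list(stats::coef(best$fit))
  if (abs(cf$v2) <= abs(cf$v1))
    stop(errorCondition(
      sprintf("no catastrophe: fitted |v2| = %.3g <= |v1| = %.3g nm/s",
              abs(cf$v2), abs(cf$v1)),
      class = c("ebcap_no_catastrophe", "error")))
  out <- list(v1 = cf$v1, v2 = cf$v2, t0 = cf$t0, sigma = cf$sigma,
              x_wo = cf$xw, t_wo = t_wo, rss = best$rss)
  out$t_cat <- catastrophe_time(out)
  class(out) <- "catastrophe_fit"
  out
}

#' @export
print.catastrophe_fit <- function(x, ...) {
  cat(sprintf(paste0("Catastrophe fit: v1 = %.3g, v2 = %.3g nm/s, ",
                     "t0 = %.4g s, sigma = %.3g s -> t_cat = %.4g s (rss %.3g nm^2)\n"),
              x$v1, x$v2, x$t0, x$sigma, x$t_cat, x$rss))
  invisible(x)
}

#' Catastrophe time from the 25% speed criterion
#'
#' The catastrophe point is where the fitted speed has completed 25% of the
#' transition from `v1` to `v2`, i.e. `erf((t0 - t)/(2 sigma)) = 1/2`, giving
#' the closed form `t_cat = t0 - 2 sigma erfinv(0.5)`. Independent of `v1`
#' and `v2`.
#'
#' @param fit A `catastrophe_fit` (or any list with `t0` and `sigma`).
#' @return Catastrophe time (s).
#' @export
catastrophe_time <- function(fit) {
  fit$t0 - 2 * fit$sigma * erfinv(0.5)
}

#' Shrinkage metrics between washout and catastrophe
#'
#' `v_s` is the magnitude of the OLS slope of the raw positions on
#' `[t_wo, t_cat]`; `v_f = |v2|`; the measured shrinkage length is the
#' fitted-model position difference `x(t_wo) - x(t_cat)` and the predicted
#' one is `v_s (t_cat - t_wo)`. With fewer than 4 samples between washout
#' and catastrophe the metrics are flagged `low_confidence` (and `v_s` falls
#' back to `|v1|`), not an error.
#'
#' @inheritParams growth_speed
#' @param fit A `catastrophe_fit`.
#' @param t_cat Catastrophe time (s).
#' @return List with `v_s`, `v_f` (nm/s, magnitudes), `L_shrink_meas`,
#'   `L_shrink_pred` (nm), `low_confidence`.
#' @export
shrinkage_metrics <- function(track, fit, t_wo, t_cat) {
  if (t_cat < t_wo)
    stop_invalid("t_cat (", t_cat, ") precedes t_wo (", t_wo, ")")
  sel <- track$time >= t_wo & track$time <= t_cat
  low <- sum(sel) < 4L
  v_s <- if (sum(sel) >= 2L)
    abs(stats::coef(stats::lm(track$end_pos[sel] ~ track$time[sel]))[[2]])
  else abs(fit$v1)
  xm <- catastrophe_position(c(t_wo, t_cat), fit$x_wo, fit$t_wo,
                             fit$v1, fit$v2, fit$t0, fit$sigma)
  list(v_s = v_s, v_f = abs(fit$v2),
       L_shrink_meas = xm[1] - xm[2],
       L_shrink_pred = v_s * (t_cat - t_wo),
       low_confidence = low)
}

#' EB intensity metrics at washout and catastrophe
#'
#' `I_wo` and `I_cat` are the end-channel intensities averaged over 1 s
#' windows centred at the washout and catastrophe times; `I_lat` is the
#' time-average of the lattice channel. The cap fraction remaining at
#' catastrophe is `(I_cat - I_lat) / (I_wo - I_lat)`.
#'
#' @inheritParams shrinkage_metrics
#' @param window Averaging window (s), default 1.
#' @return List with `I_wo`, `I_cat`, `I_lat` (a.u.) and `cap_fraction_cat`.
#' @export
intensity_metrics <- function(track, t_wo, t_cat, window = 1) {
  if (is.null(track$gfp_end) || is.null(track$gfp_lattice))
    stop_invalid("intensity metrics require gfp_end and gfp_lattice channels")
  win_mean <- function(centre) {
    sel <- track$time >= centre - window / 2 & track$time <= centre + window / 2
    if (!any(sel)) stop_invalid("intensity window at ", centre, " s is empty")
    mean(track$gfp_end[sel])
  }
  I_wo <- win_mean(t_wo); I_cat <- win_mean(t_cat)
  I_lat <- mean(track$gfp_lattice)
  if (I_wo <= I_lat)
    stop(errorCondition(
      "cap fraction undefined: end intensity at washout does not exceed lattice level",
      class = c("ebcap_undefined_fraction", "error")))
  list(I_wo = I_wo, I_cat = I_cat, I_lat = I_lat,
       cap_fraction_cat = (I_cat - I_lat) / (I_wo - I_lat))
}

#' Analyse one track end to end
#'
#' Runs washout detection, growth-speed measurement, the catastrophe fit,
#' the 25% criterion, and the shrinkage/intensity/orientation metrics on one
#' track, returning a one-row data frame of per-track metrics.
#'
#' @param track An [mt_track()].
#' @param speed_window Growth-speed window (s), default 10.
#' @return A one-row `data.frame` with columns `id`, `t_wo`, `exchange_90`,
#'   `v_g`, `t_cat`, `delay`, `v_s`, `v_f`, `L_shrink_meas`, `L_shrink_pred`,
#'   `I_wo`, `I_cat`, `I_lat`, `cap_fraction_cat`, `orient_mean`, `x_cat`,
#'   `t0`, `sigma`, `low_confidence`.
#' @export
analyze_track <- function(track, speed_window = 10) {
  wo <- detect_washout(track)
  v_g <- growth_speed(track, wo$t_wo, window = speed_window)
  fit <- fit_catastrophe(track, wo$t_wo)
  t_cat <- fit$t_cat
  shr <- shrinkage_metrics(track, fit, wo$t_wo, t_cat)
  has_gfp <- !is.null(track$gfp_end) && !is.null(track$gfp_lattice)
  ints <- if (has_gfp) intensity_metrics(track, wo$t_wo, t_cat) else
    list(I_wo = NA_real_, I_cat = NA_real_, I_lat = NA_real_,
         cap_fraction_cat = NA_real_)
  orient_mean <- if (!is.null(track$orientation)) {
    sel <- track$time >= wo$t_wo - 10 & track$time <= wo$t_wo
    mean(track$orientation[sel])
  } else NA_real_
  x_cat <- catastrophe_position(t_cat, fit$x_wo, fit$t_wo, fit$v1, fit$v2,
                                fit$t0, fit$sigma)
  data.frame(id = track$id, t_wo = wo$t_wo, exchange_90 = wo$exchange_90,
             v_g = v_g, t_cat = t_cat, delay = t_cat - wo$t_wo,
             v_s = shr$v_s, v_f = shr$v_f,
             L_shrink_meas = shr$L_shrink_meas,
             L_shrink_pred = shr$L_shrink_pred,
             I_wo = ints$I_wo, I_cat = ints$I_cat, I_lat = ints$I_lat,
             cap_fraction_cat = ints$cap_fraction_cat,
             orient_mean = orient_mean, x_cat = x_cat,
             t0 = fit$t0, sigma = fit$sigma,
             low_confidence = shr$low_confidence,
             stringsAsFactors = FALSE)
}

#' Analyse a cohort of tracks
#'
#' Applies [analyze_track()] to every track; tracks whose analysis fails are
#' excluded from the metrics table and reported in the `status` attribute
#' (and via one log line each when `verbose = TRUE`), never silently dropped.
#'
#' @param tracks List of [mt_track()] objects.
#' @param speed_window Growth-speed window (s).
#' @param verbose Print one status line per track.
#' @return A `data.frame` of per-track metrics (one row per analysed track)
#'   with attribute `status`: a data frame of `id`, `status`
#'   (`"ok"` or the failure class) and `message`.
#' @export
analyze_cohort <- function(tracks, speed_window = 10, verbose = FALSE) {
  rows <- list(); status <- list()
  for (tr in tracks) {
    res <- tryCatch(analyze_track(tr, speed_window = speed_window),
                    error = function(e) e)
    if (inherits(res, "error")) {
      cls <- setdiff(class(res), c("error", "condition"))[1]
      status[[length(status) + 1L]] <-
        data.frame(id = tr$id, status = if (is.na(cls)) "error" else cls,
                   message = conditionMessage(res), stringsAsFactors = FALSE)
      if (verbose) message(sprintf("[%s] FAILED: %s", tr$id, conditionMessage(res)))
    } else {
      rows[[length(rows) + 1L]] <- res
      status[[length(status) + 1L]] <-
        data.frame(id = tr$id, status = "ok", message = "", stringsAsFactors = FALSE)
      if (verbose) message(sprintf("[%s] fitted: delay %.2f s", tr$id, res$delay))
    }
  }
  if (length(rows) == 0L)
    stop(errorCondition("all tracks failed analysis",
                        class = c("ebcap_pipeline_error", "error")))
  out <- do.call(rbind, rows)
  attr(out, "status") <- do.call(rbind, status)
  out
}

#' Align tracks at catastrophe and average
#'
#' Linearly interpolates each track's chosen channel onto a common grid of
#' times relative to its catastrophe time (position traces are additionally
#' aligned at the fitted catastrophe end position) and returns the pointwise
#' mean and standard error. The grid is restricted to times covered by at
#' least half of the tracks. For the intensity channel a mono-exponential
#' `I_lat + A exp(-k (t - t_align))` is additionally fitted to the mean trace
#' over `[mean(t_wo) - t_cat, 0]`, returning the decay rate `k`.
#'
#' @param tracks List of [mt_track()] objects.
#' @param metrics Metrics table from [analyze_cohort()] (rows matched by id).
#' @param channel `"position"` or `"gfp_end"`.
#' @param grid_dt Grid pitch (s), default 0.25.
#' @param coverage Minimum fraction of tracks that must cover a grid point.
#' @return List with `time` (s relative to catastrophe), `mean`, `sem`, `n`
#'   (tracks per point) and, for the intensity channel, `decay`:
#'   list(`k`, `A`, `lattice`).
#' @export
align_and_average <- function(tracks, metrics,
                              channel = c("position", "gfp_end"),
                              grid_dt = 0.25, coverage = 0.5) {
  channel <- match.arg(channel)
  tracks <- tracks[match(metrics$id, vapply(tracks, `[[`, "", "id"))]
  if (length(tracks) < 5L)
    stop(errorCondition("alignment needs at least 5 analysable tracks",
                        class = c("ebcap_insufficient_data", "error")))
  rel <- lapply(seq_along(tracks), function(i) {
    tr <- tracks[[i]]; m <- metrics[i, ]
    y <- if (channel == "position") tr$end_pos - m$x_cat else {
      if (is.null(tr$gfp_end)) return(NULL)
      tr$gfp_end
    }
    list(t = tr$time - m$t_cat, y = y)
  })
  keep_idx <- !vapply(rel, is.null, logical(1))
  rel <- rel[keep_idx]
  metrics <- metrics[keep_idx, , drop = FALSE]
  lo <- min(vapply(rel, function(r) r$t[1], 0))
  hi <- max(vapply(rel, function(r) r$t[length(r$t)], 0))
  grid <- seq(floor(lo / grid_dt) * grid_dt, hi, by = grid_dt)
  mat <- vapply(rel, function(r)
    stats::approx(r$t, r$y, xout = grid, rule = 1)$y,
    numeric(length(grid)))
  n_cov <- rowSums(!is.na(mat))
  keep <- n_cov >= coverage * length(rel)
  grid <- grid[keep]; mat <- mat[keep, , drop = FALSE]; n_cov <- n_cov[keep]
  mu <- rowMeans(mat, na.rm = TRUE)
  sem <- apply(mat, 1, function(r) stats::sd(r, na.rm = TRUE)) / sqrt(n_cov)
  out <- list(time = grid, mean = mu, sem = sem, n = n_cov, channel = channel)
  if (channel == "gfp_end") {
    # Decay fit on the post-washout portions only: before its own washout a
    # track sits on its growth plateau, which would flatten the fitted rate.
    mat_post <- vapply(seq_along(rel), function(i) {
      r <- rel[[i]]
      keep <- r$t >= metrics$t_wo[i] - metrics$t_cat[i]
      stats::approx(r$t[keep], r$y[keep], xout = grid, rule = 1)$y
    }, numeric(length(grid)))
    n_post <- rowSums(!is.na(mat_post))
    mu_post <- rowMeans(mat_post, na.rm = TRUE)
    t_align <- -mean(metrics$delay)
    sel <- grid >= t_align & grid <= 0 & n_post >= pmax(3, 0.1 * length(rel))
    df <- data.frame(s = grid[sel], I = mu_post[sel])
    # the lattice level is measured independently on the lattice channel;
    # fixing it avoids the lattice/rate degeneracy of a short exponential
    have_lat <- any(is.finite(metrics$I_lat))
    lat0 <- if (have_lat) mean(metrics$I_lat, na.rm = TRUE) else min(df$I)
    amp0 <- max(df$I) - lat0
    fit <- tryCatch(
      if (have_lat)
        minpack.lm::nlsLM(I ~ lat0 + A * exp(-k * (s - t_align)), data = df,
                          start = list(A = amp0, k = 0.3),
                          lower = c(0, 1e-4),
                          control = minpack.lm::nls.lm.control(maxiter = 200))
      else
        minpack.lm::nlsLM(I ~ lat + A * exp(-k * (s - t_align)), data = df,
                          start = list(lat = lat0, A = amp0, k = 0.3),
                          lower = c(-Inf, 0, 1e-4),
                          control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (is.null(fit))
      stop(errorCondition("mono-exponential decay fit failed",
                          class = c("ebcap_fit_failure", "error")))
    cf <- stats::coef(fit)
    out$decay <- list(k = unname(cf[["k"]]), A = unname(cf[["A"]]),
                      lattice = if (have_lat) lat0 else unname(cf[["lat"]]),
                      t_align = t_align)
  }
  out
}

#' Orientation analysis
#'
#' Per-track mean end-region orientation over the 10 s before washout, its
#' magnitude relative to the cohort mean, and the Pearson correlation of that
#' magnitude with the delay time (a mechanical-stress control: no correlation
#' is expected when bending does not influence stability).
#'
#' @inheritParams align_and_average
#' @return List with `orient_mean`, `orient_mag` (deg, per track), `r`, `p`,
#'   `n`, and `flag` (`NA_character_` or a reason the correlation is
#'   undefined/skipped).
#' @export
orientation_analysis <- function(tracks, metrics) {
  om <- metrics$orient_mean
  if (all(is.na(om)))
    return(list(orient_mean = om, orient_mag = om, r = NA_real_, p = NA_real_,
                n = 0L, flag = "orientation channel missing"))
  mag <- abs(om - mean(om, na.rm = TRUE))
  ok <- stats::complete.cases(mag, metrics$delay)
  if (stats::sd(mag[ok]) == 0)
    return(list(orient_mean = om, orient_mag = mag, r = NA_real_, p = NA_real_,
                n = sum(ok), flag = "all orientations identical"))
  ct <- stats::cor.test(mag[ok], metrics$delay[ok], method = "pearson")
  list(orient_mean = om, orient_mag = mag,
       r = unname(ct$estimate), p = ct$p.value, n = sum(ok),
       flag = NA_character_)
}
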