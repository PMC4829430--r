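# Averaged EB comet profiles and the exponential-convolved-Gaussian fit that
# yields the comet length L_comet = v_g / k_m, hence the maturation rate.

#' Analytic comet intensity model
#'
#' The spatial EB-site profile behind a growing end is an exponential decay
#' of length `L_comet` riding on a lattice step, both starting at `xc`:
#' `n(s) = amp exp(-s / L_comet) 1{s >= 0} + lattice_level 1{s >= 0}` with
#' `s = x - xc`. The measured profile is its convolution with the microscope
#' point-spread function, a unit-area Gaussian of width `sigma_psf`, which
#' has the closed form (exponentially-modified Gaussian plus an erf step)
#' `I(x) = amp exp(sigma^2/(2 L^2) - s/L) Phi((s - sigma^2/L)/sigma)
#'        + lattice_level Phi(s / sigma)`
#' with `Phi` the standard normal CDF. `x` increases from beyond the tip
#' (intensity -> 0) toward the lattice (intensity -> `lattice_level`).
#'
#' @param x Positions relative to the detected end (nm), increasing toward
#'   the lattice; vectorised.
#' @param L_comet Comet decay length (nm), > 0.
#' @param sigma_psf Gaussian PSF width (nm), > 0.
#' @param xc Offset of the binding-region start from the detected end (nm).
#' @param amp Comet amplitude (a.u.).
#' @param lattice_level Lattice intensity level (a.u.).
#' @return Intensity (a.u.) at each `x`.
#' @export
comet_model <- function(x, L_comet, sigma_psf, xc = 0, amp = 1,
                        lattice_level = 0) {
  check_scalar(L_comet, "L_comet", positive = TRUE)
  check_scalar(sigma_psf, "sigma_psf", positive = TRUE)
  s <- x - xc
  # log-scale evaluation keeps the EMG finite far in front of the tip
  log_emg <- sigma_psf^2 / (2 * L_comet^2) - s / L_comet +
    stats::pnorm((s - sigma_psf^2 / L_comet) / sigma_psf, log.p = TRUE)
  amp * exp(log_emg) + lattice_level * stats::pnorm(s / sigma_psf)
}

#' Average a stack of aligned comet profiles
#'
#' Pointwise mean over per-frame intensity line profiles that were aligned at
#' the detected end position (rows = frames, columns = positions).
#'
#' @param stack Numeric matrix, one row per frame; its `"x"` attribute (or
#'   the `x` argument) gives the common position axis (nm, uniform pitch).
#' @param x Position axis (nm); defaults to `attr(stack, "x")`.
#' @return An object of class `comet_profile`: list with `x`, `intensity`
#'   (the mean profile), `sem` and `n_frames`.
#' @export
build_average_comet <- function(stack, x = attr(stack, "x")) {
  if (is.null(dim(stack)) || nrow(stack) < 1L)
    stop_invalid("profile stack must be a non-empty matrix of frames")
  if (is.null(x) || length(x) != ncol(stack))
    stop_invalid("position axis x must match the stack columns")
  px <- diff(x)
  if ((max(px) - min(px)) > 1e-6 * mean(px))
    stop_invalid("position axis must have uniform pitch")
  n <- nrow(stack)
  structure(
    list(x = as.numeric(x), intensity = colMeans(stack),
         sem = apply(stack, 2, stats::sd) / sqrt(n), n_frames = n),
    class = "comet_profile")
}

#' @export
print.comet_profile <- function(x, ...) {
  cat(sprintf("Comet profile: %d points over [%.4g, %.4g] nm, %d frames averaged\n",
              length(x$x), min(x$x), max(x$x), x$n_frames))
  invisible(x)
}

#' Fit the comet model to an averaged profile
#'
#' Unweighted nonlinear least squares of [comet_model()] to an averaged
#' comet profile (after heavy frame averaging the point-wise errors are
#' nearly uniform). The maturation rate follows from the fitted decay length
#' as `k_m = v_g / L_comet`.
#'
#' @param profile A `comet_profile` (from [build_average_comet()]), or any
#'   list with `x` and `intensity`.
#' @param v_g Growth speed (nm/s) of the microtubules behind the profile.
#' @return An object of class `comet_fit`: `L_comet`, `sigma_psf`, `xc`,
#'   `amp`, `lattice_level`, `k_m`, `rss`.
#' @export
fit_comet <- function(profile, v_g) {
  check_scalar(v_g, "v_g", positive = TRUE)
  x <- profile$x; y <- profile$intensity
  span <- diff(range(x))
  lat0 <- mean(y[x >= max(x) - span / 5])
  amp0 <- max(y) - lat0
  noise <- stats::sd(diff(y)) / sqrt(2)
  if (!is.finite(amp0) || amp0 <= max(5 * noise, 1e-12))
    stop(errorCondition("no comet above the lattice level (flat profile)",
                        class = c("ebcap_fit_failure", "error")))
  xpk <- x[which.max(y)]
  # crude decay-length guess: distance over which the excess falls by e
  tail_x <- x[x > xpk & (y - lat0) < amp0 / exp(1)]
  L0 <- if (length(tail_x)) max(min(tail_x) - xpk, span / 50) else span / 4
  pitch <- mean(diff(x))
  df <- data.frame(x = x, y = y)
  fit <- tryCatch(
    minpack.lm::nlsLM(
      y ~ comet_model(x, L, sig, xc, A, lat),
      data = df,
      start = list(L = L0, sig = max(pitch, L0 / 2), xc = xpk, A = amp0,
                   lat = lat0),
      lower = c(pitch / 10, pitch / 10, min(x) - span, 0, -Inf),
      upper = c(10 * span, span, max(x) + span, Inf, Inf),
      control = minpack.lm::nls.lm.control(maxiter = 500)),
    error = function(e) NULL)
  if (is.null(fit))
    stop(errorCondition("comet fit failed to converge",
                        class = c("ebcap_fit_failure", "error")))
  cf <- as.list(stats::coef(fit))
  if (cf$L <= pitch / 10 * 1.01 || cf$L >= 10 * span * 0.99)
    stop(errorCondition("comet decay length hit a fit bound",
                        class = c("ebcap_fit_failure", "error")))
  # the comet model must explain the profile far better than a constant;
  # on a flat profile the 5-parameter fit only chases noise
  rss <- sum(stats::resid(fit)^2)
  rss_const <- sum((y - mean(y))^2)
  if (rss > 0.2 * rss_const)
    stop(errorCondition("no significant comet structure in the profile",
                        class = c("ebcap_fit_failure", "error")))
  structure(
    list(L_comet = cf$L, sigma_psf = cf$sig, xc = cf$xc, amp = cf$A,
         lattice_level = cf$lat, k_m = v_g / cf$L,
         rss = rss),
    class = "comet_fit")
}

#' @export
print.comet_fit <- function(x, ...) {
  cat(sprintf(paste0("Comet fit: L_comet = %.4g nm, sigma_psf = %.4g nm, ",
                     "xc = %.3g nm -> k_m = %.4g 1/s\n"),
              x$L_comet, x$sigma_psf, x$xc, x$k_m))
  invisible(x)
}
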