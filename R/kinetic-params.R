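#' Kinetic parameters of one growth condition
#'
#' Bundles the rates and speeds that determine the post-washout kinetics of
#' the EB-binding-site cap: the growth speed before washout `v_g`, the slow
#' shrinkage speed after washout `v_s`, the maturation rate `k_m` at which EB
#' binding sites convert into mature lattice, an optional fast first
#' maturation step `k_1` (two-step maturation), and the lattice geometry
#' (`n_pf` protofilaments of `l_dim`-long dimers). The derived maximal linear
#' site density is `n_x0 = n_pf / l_dim` (1.625 sites/nm at defaults).
#'
#' Units are fixed package-wide: nm, s, sites; intensities are arbitrary
#' units with an explicit proportionality factor where needed.
#'
#' @param v_g Growth speed before washout (nm/s), > 0.
#' @param v_s Slow shrinkage speed after washout (nm/s), >= 0.
#' @param k_m Maturation rate (1/s), > 0.
#' @param k_1 Optional first-step maturation rate (1/s); must exceed `k_m`.
#' @param n_pf Protofilament count (default 13).
#' @param l_dim Tubulin dimer length (nm, default 8).
#' @return An object of class `kinetic_params`, a list with the fields above
#'   plus `n_x0`.
#' @examples
#' p <- kinetic_params(v_g = 33, v_s = 40, k_m = 0.16)
#' p$n_x0             # 1.625 sites/nm
#' cap_decay_rate(p)  # ~0.35 1/s
#' @export
kinetic_params <- function(v_g, v_s, k_m, k_1 = NULL, n_pf = 13, l_dim = 8) {
  check_scalar(v_g, "v_g", positive = TRUE)
  check_scalar(v_s, "v_s", nonneg = TRUE)
  check_scalar(k_m, "k_m", positive = TRUE)
  check_scalar(n_pf, "n_pf", positive = TRUE)
  check_scalar(l_dim, "l_dim", positive = TRUE)
  if (!is.null(k_1)) {
    check_scalar(k_1, "k_1", positive = TRUE)
    if (k_1 <= k_m)
      stop_invalid("k_1 must exceed k_m (fast first step); got k_1 = ", k_1,
                   ", k_m = ", k_m)
  }
  structure(
    list(v_g = v_g, v_s = v_s, k_m = k_m, k_1 = k_1,
         n_pf = n_pf, l_dim = l_dim, n_x0 = n_pf / l_dim),
    class = "kinetic_params")
}

#' @export
print.kinetic_params <- function(x, ...) {
  cat("Kinetic parameters (nm, s):\n")
  cat(sprintf("  v_g = %g nm/s, v_s = %g nm/s, k_m = %g 1/s", x$v_g, x$v_s, x$k_m))
  if (!is.null(x$k_1)) cat(sprintf(", k_1 = %g 1/s", x$k_1))
  cat(sprintf("\n  n_pf = %g, l_dim = %g nm  (n_x0 = %g sites/nm)\n",
              x$n_pf, x$l_dim, x$n_x0))
  cat(sprintf("  cap decay rate k_Mal3 = %.4g 1/s, comet length v_g/k_m = %.4g nm\n",
              cap_decay_rate(x), x$v_g / x$k_m))
  invisible(x)
}

#' Catastrophe threshold specification
#'
#' Identifies one of the kinetic threshold models of catastrophe and its free
#' parameter:
#' * `end_density` — catastrophe when the linear density of EB sites at the
#'   (shrinking) end falls to a fraction `f_crit` of its maximum `n_x0`;
#' * `total_number` — when the total number of EB sites in the whole cap
#'   falls to `N_crit`;
#' * `window_L` — when the number of sites within a length `L` from the end
#'   falls to `NL_crit`;
#' * `end_density_2step` / `total_number_2step` — the same thresholds for
#'   two-step maturation (states A -> B -> C at rates `k_1`, `k_m`), applied
#'   to the sum of A and B sites (`f_crit` fractional, `N_crit` absolute).
#'
#' @param model One of `"end_density"`, `"total_number"`, `"window_L"`,
#'   `"end_density_2step"`, `"total_number_2step"`.
#' @param f_crit Fractional end-density threshold in (0, 1].
#' @param N_crit Critical total site number (> 0).
#' @param L Window length from the end (nm, > 0).
#' @param NL_crit Critical site number within `L` (> 0).
#' @return An object of class `threshold_spec`.
#' @export
threshold_spec <- function(model = c("end_density", "total_number", "window_L",
                                     "end_density_2step", "total_number_2step"),
                           f_crit = NULL, N_crit = NULL, L = NULL,
                           NL_crit = NULL) {
  model <- match.arg(model)
  need <- switch(model,
    end_density = "f_crit", end_density_2step = "f_crit",
    total_number = "N_crit", total_number_2step = "N_crit",
    window_L = c("L", "NL_crit"))
  given <- c("f_crit", "N_crit", "L", "NL_crit")[
    !vapply(list(f_crit, N_crit, L, NL_crit), is.null, logical(1))]
  if (!setequal(given, need))
    stop_invalid("model '", model, "' requires exactly {",
                 paste(need, collapse = ", "), "}; got {",
                 paste(given, collapse = ", "), "}")
  if (!is.null(f_crit)) {
    check_scalar(f_crit, "f_crit", positive = TRUE)
    if (f_crit > 1) stop_invalid("f_crit must lie in (0, 1], got ", f_crit)
  }
  if (!is.null(N_crit)) check_scalar(N_crit, "N_crit", positive = TRUE)
  if (!is.null(L)) check_scalar(L, "L", positive = TRUE)
  if (!is.null(NL_crit)) check_scalar(NL_crit, "NL_crit", positive = TRUE)
  structure(list(model = model, f_crit = f_crit, N_crit = N_crit,
                 L = L, NL_crit = NL_crit),
            class = "threshold_spec")
}

cap_prediction <- function(delay, p, decay_rate = cap_decay_rate(p),
                           delay_sd = NA_real_, shrink_sd = NA_real_) {
  structure(
    list(delay = delay, shrink_length = p$v_s * delay,
         decay_rate = decay_rate, delay_sd = delay_sd,
         shrink_sd = if (is.na(shrink_sd) && !is.na(delay_sd))
           p$v_s * delay_sd else shrink_sd),
    class = "cap_prediction")
}

#' @export
print.cap_prediction <- function(x, ...) {
  cat(sprintf("Predicted delay %.4g s", x$delay))
  if (!is.na(x$delay_sd)) cat(sprintf(" (sd %.3g s)", x$delay_sd))
  cat(sprintf(", shrinkage %.4g nm", x$shrink_length))
  if (!is.na(x$shrink_sd)) cat(sprintf(" (sd %.3g nm)", x$shrink_sd))
  cat(sprintf(", cap decay rate %.4g 1/s\n", x$decay_rate))
  invisible(x)
}
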