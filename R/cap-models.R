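# Closed-form kinetics of the EB-binding-site cap after tubulin washout and
# the kinetic threshold models of catastrophe.
#
# At washout (t = 0) a microtubule grown at speed v_g carries an exponential
# spatial profile of EB binding sites, n(x) = n_x0 exp(-x k_m / v_g), the
# comet. Afterwards every site matures at rate k_m and the end additionally
# shrinks at v_s, so both the density at the shrinking end and the total site
# number decay at the cap decay rate k_Mal3 = k_m (v_s/v_g + 1). A threshold
# on the end density, the total number, or the number within a window L from
# the end converts that decay into a predicted washout-to-catastrophe delay.

#' Linear EB-site density behind the cap origin
#'
#' Density of EB binding sites a distance `x` behind the position the cap
#' front had at washout, a time `t` after washout:
#' `n(x, t) = n_x0 exp(-x k_m / v_g) exp(-k_m t)`.
#' Coordinates are anchored at the washout-time cap origin; the front itself
#' has moved to `x = v_s t` by time `t` (handled inside [total_sites()]).
#'
#' @param x Distance behind the cap origin (nm), >= 0; vectorised.
#' @param t Time since washout (s), >= 0; vectorised (recycled with `x`).
#' @param p A [kinetic_params()] object.
#' @return Linear site density (sites/nm).
#' @examples
#' p <- kinetic_params(v_g = 33, v_s = 40, k_m = 0.16)
#' site_density(0, 0, p)  # n_x0 = 1.625
#' @export
site_density <- function(x, t, p) {
  check_vector(x, "x", nonneg = TRUE)
  check_vector(t, "t", nonneg = TRUE)
  p$n_x0 * exp(-x * p$k_m / p$v_g) * exp(-p$k_m * t)
}

#' Total number of EB binding sites in the cap
#'
#' Integrates the site density from the shrinking end (`x = v_s t` in
#' lab-frame coordinates) to infinity:
#' `N(t) = n_x0 (v_g / k_m) exp(-k_m (v_s/v_g + 1) t)`.
#' At `t = 0` this is `n_x0 v_g / k_m = n_x0 L_comet`.
#'
#' @param t Time since washout (s), >= 0; vectorised.
#' @inheritParams site_density
#' @return Site count (dimensionless).
#' @export
total_sites <- function(t, p) {
  check_vector(t, "t", nonneg = TRUE)
  p$n_x0 * (p$v_g / p$k_m) * exp(-cap_decay_rate(p) * t)
}

#' Cap decay rate k_Mal3
#'
#' The first-order rate at which both the end density and the total number of
#' EB binding sites decay after washout, `k_Mal3 = k_m (v_s / v_g + 1)`:
#' maturation everywhere in the cap plus loss of sites to the shrinking end.
#' Always >= `k_m`, with equality iff `v_s = 0`.
#'
#' @inheritParams site_density
#' @return Decay rate (1/s).
#' @examples
#' cap_decay_rate(kinetic_params(v_g = 33, v_s = 40, k_m = 0.16)) # ~0.35
#' @export
cap_decay_rate <- function(p) {
  if (p$v_g <= 0) stop_invalid("v_g must be > 0")
  p$k_m * (p$v_s / p$v_g + 1)
}

#' Delay implied by an intensity ratio
#'
#' Inverts the mono-exponential intensity decay
#' `I(t) = I(0) exp(-k t)` for the time at which the lattice-subtracted cap
#' intensity has fallen from `I0` to `Icat`: `T = -ln(Icat / I0) / k`.
#'
#' @param I0 Cap intensity at washout (a.u., lattice-subtracted), > 0.
#' @param Icat Cap intensity at catastrophe (a.u., lattice-subtracted),
#'   0 < `Icat` <= `I0`.
#' @param k Decay rate (1/s), > 0.
#' @return Delay (s).
#' @examples
#' delay_from_intensity_ratio(1, 0.29, 0.35)  # ~3.5 s
#' @export
delay_from_intensity_ratio <- function(I0, Icat, k) {
  check_scalar(I0, "I0", positive = TRUE)
  check_scalar(Icat, "Icat", positive = TRUE)
  check_scalar(k, "k", positive = TRUE)
  if (Icat > I0) stop_invalid("Icat must not exceed I0 (", Icat, " > ", I0, ")")
  -log(Icat / I0) / k
}

#' Dispersion of the predicted delay from intensity dispersions
#'
#' Propagates the measured dispersion of cap intensities at washout and
#' catastrophe into a rough standard deviation of the predicted delay.
#' The lattice-intensity dispersion is treated as measurement noise, so the
#' intrinsic cap-size dispersion at each time point is
#' `sigma_EB = sqrt(sigma_Mal3^2 - sigma_lattice^2)` (clamped to 0 with a
#' warning if the lattice dispersion exceeds the end dispersion). First-order
#' propagation through `T = -ln(Icat/I0)/k` then gives
#' `sd(T) = (1/k) sqrt((sigma_EB,0 / I0)^2 + (sigma_EB,cat / Icat)^2)`.
#'
#' @param mean_I0,sd_I0 Mean and sd of the lattice-subtracted cap intensity
#'   at washout (a.u.).
#' @param mean_Icat,sd_Icat Same at catastrophe.
#' @param sd_lattice Sd of the lattice intensity (a.u.), the noise estimate.
#' @param k Decay rate (1/s).
#' @param v_s Slow shrinkage speed (nm/s) used to convert the delay sd into a
#'   shrinkage-length sd; `NULL` to skip.
#' @return List with `delay_sd` (s), `shrink_sd` (nm or `NA`), and the two
#'   intrinsic dispersions `sd_EB_wo`, `sd_EB_cat`.
#' @export
delay_dispersion <- function(mean_I0, sd_I0, mean_Icat, sd_Icat, sd_lattice,
                             k, v_s = NULL) {
  check_scalar(mean_I0, "mean_I0", positive = TRUE)
  check_scalar(mean_Icat, "mean_Icat", positive = TRUE)
  check_scalar(sd_I0, "sd_I0", nonneg = TRUE)
  check_scalar(sd_Icat, "sd_Icat", nonneg = TRUE)
  check_scalar(sd_lattice, "sd_lattice", nonneg = TRUE)
  check_scalar(k, "k", positive = TRUE)
  intrinsic <- function(s, label) {
    if (s < sd_lattice) {
      warning("lattice dispersion exceeds end dispersion at ", label,
              "; intrinsic sd clamped to 0", call. = FALSE)
      return(0)
    }
    sqrt(s^2 - sd_lattice^2)
  }
  s0 <- intrinsic(sd_I0, "washout")
  sc <- intrinsic(sd_Icat, "catastrophe")
  delay_sd <- sqrt((s0 / mean_I0)^2 + (sc / mean_Icat)^2) / k
  list(delay_sd = delay_sd,
       shrink_sd = if (is.null(v_s)) NA_real_ else v_s * delay_sd,
       sd_EB_wo = s0, sd_EB_cat = sc)
}

#' Delay under the end-density threshold model
#'
#' Catastrophe occurs when the EB-site density at the shrinking end,
#' `n_x0 exp(-k_Mal3 t)`, reaches the fraction `f_crit` of its maximum:
#' `T_end = -ln(f_crit) / k_Mal3`. The delay is independent of the cap
#' length `v_g / k_m` at fixed `k_Mal3`.
#'
#' @inheritParams site_density
#' @param f_crit Fractional end-density threshold in (0, 1].
#' @return A `cap_prediction` (delay, shrinkage length `v_s * T`, decay rate).
#' @examples
#' p <- kinetic_params(v_g = 28, v_s = 0.28 * 28 + 22, k_m = 0.16)
#' delay_end_density(p, f_crit = 0.20)$delay  # ~4.87 s
#' @export
delay_end_density <- function(p, f_crit) {
  check_scalar(f_crit, "f_crit", positive = TRUE)
  if (f_crit > 1) stop_invalid("f_crit must lie in (0, 1], got ", f_crit)
  cap_prediction(-log(f_crit) / cap_decay_rate(p), p)
}

#' Delay under the total-number threshold model
#'
#' Catastrophe occurs when the total number of EB sites in the cap reaches a
#' fixed count `N_crit`:
#' `T_tot = -ln(N_crit (k_m / v_g) / n_x0) / k_Mal3`. Unlike the end-density
#' model this delay grows with the initial cap size `n_x0 v_g / k_m`, which
#' is what discriminates the two models on speed-sorted data.
#'
#' @inheritParams site_density
#' @param N_crit Critical total site number, 0 < `N_crit` <= `N(0)`.
#' @return A `cap_prediction`.
#' @export
delay_total_number <- function(p, N_crit) {
  check_scalar(N_crit, "N_crit", positive = TRUE)
  N0 <- total_sites(0, p)
  if (N_crit > N0)
    stop_invalid("N_crit (", N_crit, ") exceeds the initial site number N(0) = ",
                 signif(N0, 6), "; catastrophe would precede washout")
  cap_prediction(-log(N_crit / N0) / cap_decay_rate(p), p)
}

#' Number of EB sites within a window L from the end
#'
#' `N_L(t) = n_x0 (v_g/k_m) (1 - exp(-k_m L / v_g)) exp(-k_Mal3 t)`: the
#' exponential profile integrated over a constant length `L` measured from
#' the (shrinking) end. Recovers [total_sites()] as `L -> Inf` and
#' `n_x0 L` as `L -> 0`.
#'
#' @inheritParams total_sites
#' @param L Window length from the end (nm), > 0.
#' @return Site count.
#' @export
sites_in_window <- function(t, p, L) {
  check_scalar(L, "L", positive = TRUE)
  check_vector(t, "t", nonneg = TRUE)
  p$n_x0 * (p$v_g / p$k_m) * (1 - exp(-p$k_m * L / p$v_g)) *
    exp(-cap_decay_rate(p) * t)
}

#' Delay under the window-L threshold model
#'
#' Catastrophe occurs when the number of sites within `L` from the end
#' reaches `NL_crit`: `T_L = -ln(NL_crit / N_L(0)) / k_Mal3`.
#'
#' @inheritParams sites_in_window
#' @param NL_crit Critical site number within `L`, 0 < `NL_crit` <= `N_L(0)`.
#' @return A `cap_prediction`.
#' @export
delay_window_L <- function(p, L, NL_crit) {
  check_scalar(NL_crit, "NL_crit", positive = TRUE)
  NL0 <- sites_in_window(0, p, L)
  if (NL_crit > NL0)
    stop_invalid("NL_crit (", NL_crit, ") exceeds N_L(0) = ", signif(NL0, 6))
  cap_prediction(-log(NL_crit / NL0) / cap_decay_rate(p), p)
}

#' Predicted cap intensities at washout and catastrophe (window-L model)
#'
#' With a camera proportionality factor `F`, the lattice-subtracted cap
#' intensity at washout is `I(0) = F v_g` (intensity proportional to cap
#' size, which is proportional to growth speed), and at the window-L
#' catastrophe time it is
#' `I(T_L) = F NL_crit (l_dim / n_pf) k_m / (1 - exp(-k_m L / v_g))`.
#'
#' @param F_factor Proportionality factor (a.u. * s / nm), > 0.
#' @inheritParams delay_window_L
#' @return List with `I_wo` and `I_cat` (a.u.).
#' @export
intensity_predictions <- function(F_factor, p, L, NL_crit) {
  check_scalar(F_factor, "F_factor", positive = TRUE)
  check_scalar(L, "L", positive = TRUE)
  check_scalar(NL_crit, "NL_crit", positive = TRUE)
  list(I_wo = F_factor * p$v_g,
       I_cat = F_factor * NL_crit * (p$l_dim / p$n_pf) * p$k_m /
         (1 - exp(-p$k_m * L / p$v_g)))
}

# two-step maturation --------------------------------------------------------

check_two_step <- function(p) {
  if (is.null(p$k_1)) stop_invalid("two-step kinetics require k_1 in kinetic_params")
  if (p$k_1 == p$k_m) stop_invalid("k_1 = k_m is singular; perturb k_1")
}

#' End density and total number under two-step maturation
#'
#' For the maturation chain A -> B -> C (rates `k_1`, then `k_m`), where A is
#' a non-binding but stabilising end state and B the EB-binding state, the
#' density of A+B sites at the shrinking end is
#' `n_x0 / (k_1 - k_m) * (k_1 exp(-k_m r t) - k_m exp(-k_1 r t))` with
#' `r = v_s/v_g + 1`, and the total A+B number is
#' `n_x0 v_g / (k_1 - k_m) * ((k_1/k_m) exp(-k_m r t) - (k_m/k_1) exp(-k_1 r t))`.
#' Both reduce to the one-step expressions as `k_1 / k_m -> Inf`.
#'
#' @inheritParams total_sites
#' @param p A [kinetic_params()] with `k_1` set (`k_1 > k_m`).
#' @return Density (sites/nm) for `two_step_end_density()`; count for
#'   `two_step_total()`.
#' @export
two_step_end_density <- function(t, p) {
  check_two_step(p)
  check_vector(t, "t", nonneg = TRUE)
  r <- p$v_s / p$v_g + 1
  p$n_x0 / (p$k_1 - p$k_m) *
    (p$k_1 * exp(-p$k_m * r * t) - p$k_m * exp(-p$k_1 * r * t))
}

#' @rdname two_step_end_density
#' @export
two_step_total <- function(t, p) {
  check_two_step(p)
  check_vector(t, "t", nonneg = TRUE)
  r <- p$v_s / p$v_g + 1
  p$n_x0 * p$v_g / (p$k_1 - p$k_m) *
    ((p$k_1 / p$k_m) * exp(-p$k_m * r * t) -
       (p$k_m / p$k_1) * exp(-p$k_1 * r * t))
}

#' Delay under the two-step threshold models
#'
#' Solves `two_step_end_density(T) = f_crit * n_x0` (model
#' `"end_density_2step"`) or `two_step_total(T) = N_crit`
#' (`"total_number_2step"`) for the delay `T` by bracketed root-finding on
#' `[0, 10 / k_m]` (tolerance 1e-9 s); the left side is strictly decreasing
#' for `k_1 > k_m`, so the root is unique.
#'
#' @inheritParams two_step_end_density
#' @param spec A [threshold_spec()] with a two-step model.
#' @return A `cap_prediction`.
#' @export
delay_two_step <- function(p, spec) {
  check_two_step(p)
  if (!inherits(spec, "threshold_spec") ||
      !spec$model %in% c("end_density_2step", "total_number_2step"))
    stop_invalid("spec must be a threshold_spec with a two-step model")
  fn <- if (spec$model == "end_density_2step") {
    thr <- spec$f_crit * p$n_x0
    function(t) two_step_end_density(t, p) - thr
  } else {
    thr <- spec$N_crit
    function(t) two_step_total(t, p) - thr
  }
  f0 <- fn(0)
  if (f0 < 0)
    stop_invalid("threshold exceeds the value at t = 0; catastrophe would precede washout")
  if (f0 == 0) return(cap_prediction(0, p))
  upper <- 10 / p$k_m
  if (fn(upper) > 0)
    stop_numerical("no sign change on [0, ", upper, " s]; threshold never reached")
  root <- stats::uniroot(fn, c(0, upper), tol = 1e-9)
  cap_prediction(root$root, p)
}
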