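# Closed-form cap kinetics and the threshold models, checked against
# quadrature and root-finding oracles.

test_that("site density has the right maximum, decay length and integral", {
  p <- mal3_params()
  expect_equal(site_density(0, 0, p), 1.625)
  expect_equal(site_density(p$v_g / p$k_m, 0, p), 1.625 / exp(1))
  # quadrature oracle: integral over the whole cap equals the closed form
  quad <- stats::integrate(function(x) site_density(x, 0, p), 0, Inf,
                           rel.tol = 1e-10)$value
  expect_equal(quad, 335.15625, tolerance = 1e-8)
  expect_equal(total_sites(0, p), quad, tolerance = 1e-8)
  # monotone non-increasing in x and t
  xs <- seq(0, 500, by = 25)
  expect_true(all(diff(site_density(xs, 0, p)) <= 0))
  expect_true(all(diff(site_density(0, xs / 100, p)) <= 0))
  expect_error(site_density(-1, 0, p), class = "ebcap_invalid_argument")
  expect_error(site_density(0, NaN, p), class = "ebcap_invalid_argument")
})

test_that("total site number decays at the cap decay rate", {
  p <- mal3_params()
  k <- cap_decay_rate(p)
  expect_equal(total_sites(1 / k, p) / total_sites(0, p), exp(-1))
  # no-shrinkage limit: decay at exactly k_m
  p0 <- kinetic_params(v_g = 33, v_s = 0, k_m = 0.16)
  expect_equal(cap_decay_rate(p0), p0$k_m)
  expect_equal(total_sites(2, p0) / total_sites(0, p0), exp(-2 * 0.16))
  expect_error(total_sites(-0.1, p), class = "ebcap_invalid_argument")
})

test_that("cap decay rate matches the measured-parameter prediction", {
  # k_m (v_s/v_g + 1) with k_m = 0.16, v_s = 40, v_g = 33 -> 0.35 1/s
  expect_equal(cap_decay_rate(mal3_params()), 0.16 * (40 / 33 + 1))
  expect_equal(round(cap_decay_rate(mal3_params()), 2), 0.35)
  p <- kinetic_params(v_g = 25, v_s = 25, k_m = 0.2)
  expect_equal(cap_decay_rate(p), 2 * p$k_m)   # v_s = v_g doubles the rate
})

test_that("intensity-ratio delay inverts the exponential decay", {
  expect_equal(delay_from_intensity_ratio(1, 0.29, 0.3539394), 3.4974,
               tolerance = 1e-4)
  expect_equal(delay_from_intensity_ratio(50, 50, 0.3), 0)
  expect_equal(delay_from_intensity_ratio(1, exp(-1), 1), 1)
  expect_error(delay_from_intensity_ratio(1, 1.2, 0.3),
               class = "ebcap_invalid_argument")
  expect_error(delay_from_intensity_ratio(1, -0.1, 0.3),
               class = "ebcap_invalid_argument")
})

test_that("delay dispersion propagates intrinsic intensity spread", {
  # 3-4-5: lattice noise 3 subtracted from total 5 leaves intrinsic 4
  d <- delay_dispersion(100, 5, 50, 5, 3, k = 1)
  expect_equal(d$sd_EB_wo, 4)
  expect_equal(delay_dispersion(100, 2, 50, 2, 2, k = 1)$delay_sd, 0)
  # frozen first-order value for the Mal3-like statistics
  d2 <- delay_dispersion(100, 30, 29, 15, 0, k = 0.33, v_s = 40)
  expect_equal(d2$delay_sd, sqrt((30 / 100)^2 + (15 / 29)^2) / 0.33)
  expect_equal(d2$delay_sd, 1.812, tolerance = 1e-3)
  expect_equal(d2$shrink_sd, 40 * d2$delay_sd)
  # Monte-Carlo propagation oracle; the nonlinearity of -log at this noise
  # level leaves the first-order value ~10-15% low
  set.seed(101)
  I0 <- stats::rnorm(2e5, 100, 30); Ic <- stats::rnorm(2e5, 29, 15)
  ok <- I0 > 1 & Ic > 1 & Ic < I0
  mc <- stats::sd(-log(Ic[ok] / I0[ok]) / 0.33)
  expect_lt(abs(mc - d2$delay_sd) / mc, 0.15)
  expect_warning(delay_dispersion(100, 2, 50, 5, 3, k = 1), "clamped")
})

test_that("end-density delay matches its root-finding oracle", {
  p <- washout_params()
  expect_equal(delay_end_density(p, 1)$delay, 0)
  pred <- delay_end_density(p, 0.20)
  expect_equal(pred$delay, 4.8695, tolerance = 1e-4)
  # oracle: root of end density (site_density at the moving front) = f n_x0
  k <- cap_decay_rate(p)
  root <- stats::uniroot(function(t) p$n_x0 * exp(-k * t) - 0.2 * p$n_x0,
                         c(0, 60), tol = 1e-12)$root
  expect_equal(pred$delay, root, tolerance = 1e-9)
  expect_equal(pred$shrink_length, p$v_s * pred$delay)
  expect_error(delay_end_density(p, 0), class = "ebcap_invalid_argument")
  expect_error(delay_end_density(p, 1.2), class = "ebcap_invalid_argument")
})

test_that("total-number delay matches root-finding on the site count", {
  p <- washout_params()
  expect_equal(total_sites(0, p), 284.375)
  expect_equal(delay_total_number(p, total_sites(0, p))$delay, 0)
  pred <- delay_total_number(p, 100)
  expect_equal(pred$delay, 3.1618, tolerance = 1e-4)
  root <- stats::uniroot(function(t) total_sites(t, p) - 100, c(0, 60),
                         tol = 1e-12)$root
  expect_equal(pred$delay, root, tolerance = 1e-9)
  expect_error(delay_total_number(p, 300), class = "ebcap_invalid_argument")
})

test_that("total-number delays rise faster with speed than end-density", {
  # the model-discrimination signature: at fixed thresholds, the
  # total-number delay grows more steeply with v_g
  vg <- seq(20, 80, by = 5)
  d_end <- d_tot <- numeric(length(vg))
  for (i in seq_along(vg)) {
    p <- kinetic_params(vg[i], 0.28 * vg[i] + 22, 0.16)
    d_end[i] <- delay_end_density(p, 0.2)$delay
    d_tot[i] <- delay_total_number(p, 40)$delay
  }
  expect_true(all(diff(d_tot) > diff(d_end)))
})

test_that("window-L site count interpolates between n_x0*L and the total", {
  p <- washout_params()
  expect_equal(sites_in_window(0, p, 80), 104.3401, tolerance = 1e-4)
  quad <- stats::integrate(function(x) site_density(x, 0, p), 0, 80,
                           rel.tol = 1e-10)$value
  expect_equal(sites_in_window(0, p, 80), quad, tolerance = 1e-8)
  expect_equal(sites_in_window(3, p, 1e7), total_sites(3, p), tolerance = 1e-9)
  expect_equal(sites_in_window(0, p, 1e-4) / 1e-4, p$n_x0, tolerance = 1e-5)
  expect_error(sites_in_window(0, p, -5), class = "ebcap_invalid_argument")
})

test_that("window-L delay reduces to the other models in its limits", {
  p <- washout_params()
  NL0 <- sites_in_window(0, p, 80)
  expect_equal(delay_window_L(p, 80, NL0)$delay, 0)
  expect_equal(delay_window_L(p, 1e7, 100)$delay,
               delay_total_number(p, 100)$delay, tolerance = 1e-9)
  # L = one dimer: equivalent to an end-density threshold with
  # f = NL/(n_x0 L_eff), L_eff = (v_g/k_m)(1 - exp(-k_m L / v_g))
  for (vg in seq(20, 80, by = 10)) {
    pp <- kinetic_params(vg, 0.28 * vg + 22, 0.16)
    L_eff <- (vg / 0.16) * (1 - exp(-0.16 * 8 / vg))
    NL <- 0.3 * pp$n_x0 * L_eff
    expect_equal(delay_window_L(pp, 8, NL)$delay,
                 delay_end_density(pp, 0.3)$delay, tolerance = 0.03)
  }
})

test_that("predicted intensities follow the proportionality relations", {
  p <- mal3_params()
  i1 <- intensity_predictions(2, p, 80, 50)
  i2 <- intensity_predictions(2, kinetic_params(66, 40, 0.16), 80, 50)
  expect_equal(i2$I_wo, 2 * i1$I_wo)          # I(0) linear in v_g
  expect_equal(intensity_predictions(1, p, 80, 50)$I_cat, 15.314,
               tolerance = 1e-3)
  # direct evaluation oracle: I_cat equals F * N_L(T_L) * l_dim/n_pf * per-site
  # intensity, i.e. the window count at the fitted delay time
  TL <- delay_window_L(p, 80, 50)$delay
  expect_equal(sites_in_window(TL, p, 80), 50, tolerance = 1e-6)
  # L -> Inf: intensity ratio equals the site-number ratio
  iL <- intensity_predictions(1, p, 1e8, 50)
  expect_equal(iL$I_cat / iL$I_wo, 50 / total_sites(0, p), tolerance = 1e-6)
})

test_that("two-step expressions start at the printed t = 0 values", {
  p <- washout_params(k_1 = 0.8)
  expect_equal(two_step_end_density(0, p), 1.625)
  # Eq as printed: n_x0 v_g/(k_1-k_m) (k_1/k_m - k_m/k_1); differs from the
  # one-step N(0) by a factor (1 + k_m/k_1)/(1) * ... of order (k_m/k_1)^2
  expect_equal(two_step_total(0, p),
               1.625 * 28 / (0.8 - 0.16) * (0.8 / 0.16 - 0.16 / 0.8))
  expect_equal(two_step_total(0, p), 341.25)
  expect_error(two_step_end_density(0, washout_params()),
               class = "ebcap_invalid_argument")
})

test_that("two-step kinetics collapse onto one-step for k_1 >> k_m", {
  p <- washout_params(k_1 = 1000 * 0.16)
  k <- cap_decay_rate(p)
  tt <- seq(0, 10, by = 0.05)
  one <- p$n_x0 * exp(-k * tt)
  expect_lt(max(abs(two_step_end_density(tt, p) - one) / one), 0.002)
  # monotone decreasing for k_1 > k_m
  p2 <- washout_params(k_1 = 5 * 0.16)
  expect_true(all(diff(two_step_end_density(tt, p2)) < 0))
  expect_true(all(diff(two_step_total(tt, p2)) < 0))
})

test_that("two-step delays agree with a dense grid scan", {
  p <- washout_params(k_1 = 5 * 0.16)
  spec <- threshold_spec("end_density_2step", f_crit = 0.25)
  d <- delay_two_step(p, spec)$delay
  tt <- seq(0, 30, by = 1e-3)
  grid_root <- tt[which.min(abs(two_step_end_density(tt, p) -
                                  0.25 * p$n_x0))]
  expect_equal(d, grid_root, tolerance = 2e-3)
  # threshold at the initial value -> zero delay
  spec0 <- threshold_spec("total_number_2step", N_crit = two_step_total(0, p))
  expect_equal(delay_two_step(p, spec0)$delay, 0)
  # k_1 >> k_m limit reproduces the one-step delay
  pl <- washout_params(k_1 = 1000 * 0.16)
  dl <- delay_two_step(pl, threshold_spec("end_density_2step", f_crit = 0.2))
  expect_equal(dl$delay, delay_end_density(pl, 0.2)$delay, tolerance = 0.01)
  expect_error(
    delay_two_step(p, threshold_spec("end_density_2step", f_crit = 1)),
    NA)  # exactly at the t=0 value is allowed (delay 0)
  expect_error(
    delay_two_step(p, threshold_spec("total_number_2step", N_crit = 1e5)),
    class = "ebcap_invalid_argument")
})

test_that("every delay formula reproduces its threshold on back-substitution", {
  set.seed(7)
  for (i in 1:100) {
    p <- random_params()
    f <- stats::runif(1, 0.05, 0.95)
    d <- delay_end_density(p, f)$delay
    expect_equal(site_density(0, d, p) * exp(-p$k_m * (p$v_s / p$v_g) * d),
                 f * p$n_x0, tolerance = 1e-9)
    N <- stats::runif(1, 0.05, 0.95) * total_sites(0, p)
    expect_equal(total_sites(delay_total_number(p, N)$delay, p), N,
                 tolerance = 1e-9)
    L <- stats::runif(1, 8, 500)
    NL <- stats::runif(1, 0.05, 0.95) * sites_in_window(0, p, L)
    expect_equal(sites_in_window(delay_window_L(p, L, NL)$delay, p, L), NL,
                 tolerance = 1e-9)
    p2 <- random_params(two_step = TRUE)
    f2 <- stats::runif(1, 0.05, 0.95)
    d2 <- delay_two_step(p2, threshold_spec("end_density_2step",
                                            f_crit = f2))$delay
    expect_equal(two_step_end_density(d2, p2), f2 * p2$n_x0,
                 tolerance = 1e-7)
  }
})

test_that("closed forms agree with quadrature on random parameter draws", {
  set.seed(11)
  for (i in 1:100) {
    p <- random_params()
    t <- stats::runif(1, 0, 8)
    # lab frame: the front has advanced to x = v_s t
    quad <- stats::integrate(function(x) site_density(x, t, p), p$v_s * t,
                             Inf, rel.tol = 1e-10)$value
    expect_equal(total_sites(t, p), quad, tolerance = 1e-8)
    L <- stats::runif(1, 10, 400)
    quadL <- stats::integrate(function(x) site_density(x, t, p), p$v_s * t,
                              p$v_s * t + L, rel.tol = 1e-10)$value
    expect_equal(sites_in_window(t, p, L), quadL, tolerance = 1e-8)
  }
})

test_that("end-density delay is invariant at fixed k_Mal3, total-number is not", {
  f <- 0.2
  base <- kinetic_params(30, 30, 0.2)
  k_target <- cap_decay_rate(base)          # 0.4
  d0 <- delay_end_density(base, f)$delay
  for (vg in c(15, 45, 75)) {
    # choose k_m so that k_m (v_s/v_g + 1) stays fixed with v_s = v_g
    p <- kinetic_params(vg, vg, k_target / 2)
    expect_equal(cap_decay_rate(p), k_target)
    expect_equal(delay_end_density(p, f)$delay, d0, tolerance = 1e-12)
  }
  p_a <- kinetic_params(15, 15, k_target / 2)
  p_b <- kinetic_params(75, 75, k_target / 2)
  expect_gt(abs(delay_total_number(p_b, 10)$delay -
                  delay_total_number(p_a, 10)$delay), 1)
})

test_that("parameter containers validate their invariants", {
  expect_error(kinetic_params(-1, 10, 0.1), class = "ebcap_invalid_argument")
  expect_error(kinetic_params(30, 10, 0.2, k_1 = 0.1),
               class = "ebcap_invalid_argument")
  expect_equal(kinetic_params(30, 10, 0.2)$n_x0, 13 / 8)
  expect_error(threshold_spec("end_density", N_crit = 5),
               class = "ebcap_invalid_argument")
  expect_error(threshold_spec("window_L", L = 80),
               class = "ebcap_invalid_argument")
  s <- threshold_spec("window_L", L = 80, NL_crit = 40)
  expect_identical(s$model, "window_L")
  expect_error(threshold_spec("end_density", f_crit = 1.5),
               class = "ebcap_invalid_argument")
})
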