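# Washout detection, catastrophe fitting, and per-track metric extraction.

test_that("washout detection recovers the erf inflection and exchange time", {
  # finely sampled noiseless erf drop: t_wo = 50 s, tau = 0.0428 s so the
  # 5-95% exchange interval is 4 tau erfinv(0.9) = 0.199 s
  time <- seq(40, 60, by = 0.02)
  bg <- 10 + 45 * (1 - erf((time - 50) / (2 * 0.0428)))
  tr <- mt_track(time, end_pos = 28 * time, background = bg)
  wo <- detect_washout(tr)
  expect_equal(wo$t_wo, 50, tolerance = 1e-4)
  expect_equal(wo$exchange_90, 0.19912, tolerance = 1e-3)
  expect_equal(4 * erfinv(0.9), 4.65235, tolerance = 1e-5)
})

test_that("washout detection rejects records without a transition", {
  time <- seq(0, 60, by = 0.25)
  set.seed(3)
  tr <- mt_track(time, end_pos = 28 * time,
                 background = 50 + stats::rnorm(length(time), 0, 1))
  expect_error(detect_washout(tr), class = "ebcap_no_washout")
})

test_that("a step-like washout is located within one frame", {
  time <- seq(0, 100, by = 0.25)
  bg <- ifelse(time < 50.1, 100, 10)
  tr <- mt_track(time, end_pos = 28 * time, background = bg)
  wo <- detect_washout(tr)
  expect_lt(abs(wo$t_wo - 50.1), 0.25)
  expect_lt(wo$exchange_90, 0.25)
})

test_that("growth speed is the OLS slope over the requested window", {
  tr <- clean_track(v_g = 28, t_wo = 50)
  expect_equal(growth_speed(tr, 50), 28, tolerance = 1e-9)
  expect_equal(growth_speed(tr, 50, shift = 14), 28, tolerance = 1e-9)
  expect_error(growth_speed(tr, 50, window = 0))
  expect_error(growth_speed(tr, 50, window = 10, shift = 45),
               class = "ebcap_insufficient_data")
})

test_that("noisy growth-speed estimates match the OLS slope-variance law", {
  # 30 nm noise, 4 Hz, 10 s window: sd = sigma sqrt(12/(n(n^2-1))) / dt
  set.seed(5)
  t <- seq(0, 10, by = 0.25); n <- length(t)
  slopes <- replicate(400, {
    x <- 28 * t + stats::rnorm(n, 0, 30)
    sum((t - mean(t)) * (x - mean(x))) / sum((t - mean(t))^2)
  })
  theo <- 30 * sqrt(12 / (n * (n^2 - 1))) / 0.25
  expect_equal(mean(slopes), 28, tolerance = 0.01)
  expect_equal(stats::sd(slopes), theo, tolerance = 0.15)
})

test_that("catastrophe fit recovers exact model parameters", {
  tr <- clean_track(v_g = 28, v_s = 26, v_f = 480, t_wo = 50, delay = 7,
                    sigma = 0.5)
  fit <- fit_catastrophe(tr, 50)
  t0_true <- 57 + 2 * 0.5 * erfinv(0.5)
  expect_equal(fit$v1, -26, tolerance = 1e-6)
  expect_equal(fit$v2, -480, tolerance = 1e-6)
  expect_equal(fit$t0, t0_true, tolerance = 1e-6)
  expect_equal(fit$sigma, 0.5, tolerance = 1e-6)
  expect_equal(fit$t_cat, 57, tolerance = 1e-6)
})

test_that("catastrophe fit fails cleanly without a fast phase", {
  time <- seq(50, 70, by = 0.25)
  tr <- mt_track(time, end_pos = -26 * (time - 50),
                 background = rep(10, length(time)), id = "mono")
  expect_error(fit_catastrophe(tr, 50), class = "ebcap_no_catastrophe")
})

test_that("catastrophe time under noise is accurate to a fraction of a frame", {
  set.seed(9)
  errs <- replicate(200, {
    delay <- stats::runif(1, 4, 9)
    tr <- clean_track(v_g = 28, v_s = 26, t_wo = 50, delay = delay,
                      pos_noise = 30, id = "noisy")
    fit_catastrophe(tr, 50)$t_cat - (50 + delay)
  })
  expect_lt(stats::median(abs(errs)), 0.15)
})

test_that("the 25% criterion has the closed form t0 - 2 sigma erfinv(1/2)", {
  expect_equal(catastrophe_time(list(t0 = 10, sigma = 1)), 9.0461,
               tolerance = 1e-4)
  expect_equal(catastrophe_time(list(t0 = 10, sigma = 1e-9)), 10)
  # numeric oracle: solve v(t) = v1 + 0.25 (v2 - v1) directly
  for (sg in c(0.2, 0.5, 1.5)) {
    v1 <- -26; v2 <- -480; t0 <- 12
    num <- stats::uniroot(function(t)
      0.5 * (v1 + v2) + 0.5 * (v1 - v2) * erf((t0 - t) / (2 * sg)) -
        (v1 + 0.25 * (v2 - v1)), c(0, 30), tol = 1e-12)$root
    expect_equal(catastrophe_time(list(t0 = t0, sigma = sg)), num,
                 tolerance = 1e-9)
    # independent of the speeds themselves
    num2 <- stats::uniroot(function(t)
      0.5 * (-5 - 100) + 0.5 * (-5 + 100) * erf((t0 - t) / (2 * sg)) -
        (-5 + 0.25 * (-100 + 5)), c(0, 30), tol = 1e-12)$root
    expect_equal(num, num2, tolerance = 1e-9)
  }
})

test_that("shrinkage metrics are consistent for a sharp catastrophe", {
  tr <- clean_track(v_g = 28, v_s = 26, t_wo = 50, delay = 8.46,
                    sigma = 0.02)
  fit <- fit_catastrophe(tr, 50)
  shr <- shrinkage_metrics(tr, fit, 50, fit$t_cat)
  expect_equal(shr$v_s, 26, tolerance = 1e-3)
  expect_equal(shr$v_f, 480, tolerance = 1e-3)
  expect_equal(shr$L_shrink_meas, 26 * 8.46, tolerance = 0.01)
  expect_equal(shr$L_shrink_pred, shr$L_shrink_meas, tolerance = 0.01)
  expect_false(shr$low_confidence)
})

test_that("erf-smoothed catastrophes make measured shrinkage exceed predicted", {
  # with a soft transition the fitted positions keep falling between the 25%
  # point and the transition centre, so the measured length is larger
  tr <- clean_track(v_g = 28, v_s = 26, t_wo = 50, delay = 6, sigma = 0.8)
  fit <- fit_catastrophe(tr, 50)
  shr <- shrinkage_metrics(tr, fit, 50, fit$t_cat)
  expect_gt(shr$L_shrink_meas, shr$L_shrink_pred)
})

test_that("intensity metrics subtract lattice and form the cap fraction", {
  time <- seq(0, 60, by = 0.25)
  gfp <- ifelse(time <= 30, 100, 49.6)
  tr <- mt_track(time, end_pos = time, background = rep(10, length(time)),
                 gfp_end = gfp, gfp_lattice = rep(20, length(time)))
  im <- intensity_metrics(tr, t_wo = 20, t_cat = 40)
  expect_equal(im$I_lat, 20)
  expect_equal(im$cap_fraction_cat, (49.6 - 20) / (100 - 20))
  # fraction endpoints
  tr2 <- mt_track(time, end_pos = time, background = rep(10, length(time)),
                  gfp_end = rep(100, length(time)),
                  gfp_lattice = rep(20, length(time)))
  expect_equal(intensity_metrics(tr2, 20, 40)$cap_fraction_cat, 1)
  tr3 <- mt_track(time, end_pos = time, background = rep(10, length(time)),
                  gfp_end = rep(15, length(time)),
                  gfp_lattice = rep(20, length(time)))
  expect_error(intensity_metrics(tr3, 20, 40),
               class = "ebcap_undefined_fraction")
})

test_that("a noiseless sharp-catastrophe track is recovered exactly", {
  cfg <- synthetic_config(n_tracks = 1, seed = 21, pos_noise_sd = 0,
                          vs_sd = 0, cap_scale_sd = 0, intensity_cv = 0,
                          bg_noise_sd = 0, orient_frame_sd = 0,
                          sigma_cat = 0.02)
  g <- generate_track(cfg, 1)
  m <- analyze_track(g$track)
  tru <- g$truth
  expect_equal(m$t_wo, tru$t_wo_true, tolerance = 1e-3)
  expect_equal(m$v_g, tru$v_g_true, tolerance = 1e-3)
  expect_lt(abs(m$delay - tru$delay_true), 0.25)   # < 1 frame
  expect_equal(m$v_s, tru$v_s_true, tolerance = 1e-3)
  expect_equal(m$v_f, 480, tolerance = 1e-3)
  expect_equal(m$L_shrink_pred, tru$v_s_true * tru$delay_true,
               tolerance = 0.01)
})

test_that("the noiseless cap fraction reflects the generating threshold", {
  # default erf transition width; the 1 s intensity windows leave a few
  # percent of window-averaging bias around the exact value f_crit/xi
  cfg <- synthetic_config(n_tracks = 1, seed = 21, pos_noise_sd = 0,
                          vs_sd = 0, cap_scale_sd = 0, intensity_cv = 0,
                          bg_noise_sd = 0, orient_frame_sd = 0)
  g <- generate_track(cfg, 1)
  m <- analyze_track(g$track)
  expect_equal(m$cap_fraction_cat, 0.2, tolerance = 0.12)
})

test_that("cohort analysis reports failures instead of dropping them", {
  cfg <- synthetic_config(n_tracks = 6, seed = 2)
  coh <- generate_cohort(cfg)
  # corrupt one track's background so washout detection fails
  bad <- coh$tracks[[3]]
  bad$background <- rep(50, length(bad$time))
  coh$tracks[[3]] <- bad
  met <- analyze_cohort(coh$tracks)
  st <- attr(met, "status")
  expect_equal(nrow(met), 5)
  expect_equal(sum(st$status == "ok"), 5)
  expect_match(st$status[st$id == bad$id], "no_washout")
})

test_that("parameter recovery is unbiased at cohort scale", {
  cfg <- synthetic_config(n_tracks = 500, seed = 17)
  coh <- generate_cohort(cfg)
  met <- analyze_cohort(coh$tracks)
  tru <- coh$truth[match(met$id, coh$truth$id), ]
  expect_gt(nrow(met), 480)
  expect_lt(abs(mean(met$delay - tru$delay_true)), 0.2)
  expect_lt(abs(mean(met$v_g / tru$v_g_true - 1)), 0.02)
})

test_that("identical tracks average to themselves with zero sem", {
  tr <- clean_track(t_wo = 50, delay = 6, id = "a")
  tracks <- lapply(1:6, function(i) { t2 <- tr; t2$id <- paste0("a", i); t2 })
  met <- analyze_cohort(tracks)
  aa <- align_and_average(tracks, met, "position")
  expect_true(all(aa$sem < 1e-8))
  # the mean equals any single aligned track on the grid interior
  ref <- stats::approx(tr$time - met$t_cat[1], tr$end_pos - met$x_cat[1],
                       xout = aa$time)$y
  expect_equal(aa$mean, ref, tolerance = 1e-6)
  expect_error(align_and_average(tracks[1:3], met[1:3, ], "position"),
               class = "ebcap_insufficient_data")
})

test_that("aligned averaging respects the coverage rule", {
  coh <- std_cohort()
  aa <- align_and_average(coh$tracks, coh$metrics, "position")
  expect_true(all(aa$n >= 0.5 * nrow(coh$metrics)))
})

test_that("the aligned intensity decay rate is recovered", {
  # cohort built so every track's cap decays at exactly 0.33 1/s
  cfg <- synthetic_config(n_tracks = 100, seed = 1, vs_a = 0.33 / 0.16 - 1,
                          vs_b = 0, vs_sd = 0)
  coh <- generate_cohort(cfg)
  met <- analyze_cohort(coh$tracks)
  aa <- align_and_average(coh$tracks, met, "gfp_end")
  expect_true(all(abs(coh$truth$k_Mal3_true - 0.33) < 1e-12))
  expect_gt(aa$decay$k, 0.30)
  expect_lt(aa$decay$k, 0.36)
})

test_that("orientation magnitudes do not correlate with delay by construction", {
  coh <- std_cohort()
  oa <- orientation_analysis(coh$tracks, coh$metrics)
  expect_lt(abs(oa$r), 0.2)
  expect_true(is.na(oa$flag))
  # identical orientations -> flagged, undefined r
  tracks2 <- lapply(coh$tracks[1:6], function(tr) {
    tr$orientation <- rep(3, length(tr$time)); tr })
  met2 <- analyze_cohort(tracks2)
  oa2 <- orientation_analysis(tracks2, met2)
  expect_true(is.na(oa2$r))
  expect_match(oa2$flag, "identical")
})
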