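# Seeded generator of synthetic tubulin-washout cohorts with the statistical
# structure the analysis assumes: growth at (optionally mean-reverting)
# speed, an error-function background drop at washout, slow shrinkage
# transitioning to fast depolymerisation through an erf-smoothed catastrophe,
# and an EB end intensity proportional to the cap size that decays at
# k_Mal3 = k_m (v_s/v_g + 1) after washout. Every track is emitted together
# with its ground truth for parameter-recovery tests.

#' Configuration of a synthetic washout cohort
#'
#' Defaults emulate the experimental conditions the analysis targets:
#' 4 Hz sampling, ~100 s of growth before washout, ~30 nm tracking noise,
#' growth speeds around 33 nm/s (sd 12), slow shrinkage `v_s = 0.28 v_g + 22`
#' (nm/s), fast depolymerisation at 480 nm/s, maturation at `k_m = 0.16` 1/s,
#' an end-density catastrophe threshold, a 199 ms 5-95% buffer exchange
#' (`tau = 0.0428` s), and an end-region orientation scatter of sd 7.3 deg.
#' Per-track dispersion of the initial cap size enters through a lognormal
#' factor `xi` with `sdlog = cap_scale_sd`.
#'
#' @param n_tracks Number of tracks.
#' @param seed Integer seed; every randomness in the cohort derives from it.
#' @param frame_rate Sampling rate (Hz).
#' @param t_grow Growth duration before washout (s).
#' @param t_post Record length after washout (s).
#' @param pos_noise_sd Gaussian position noise (nm).
#' @param vg_mean,vg_sd Growth-speed distribution (nm/s); truncated normal
#'   (at `vg_min`) unless `vg_dist = "uniform"`.
#' @param vg_dist `"truncnorm"` or `"uniform"`.
#' @param vg_range Range for the uniform speed distribution (nm/s).
#' @param vg_min Lower truncation of the normal speed distribution (nm/s).
#' @param tau_mem Optional memory time (s) of a mean-reverting
#'   (Ornstein-Uhlenbeck) speed process around `vg_mean` with stationary sd
#'   `vg_sd`; `NULL` for a constant per-track speed draw.
#' @param vs_a,vs_b,vs_sd Slow-shrinkage relation `v_s = a v_g + b` plus a
#'   Gaussian residual sd (nm/s).
#' @param v_f Fast depolymerisation speed (nm/s).
#' @param k_m Maturation rate (1/s).
#' @param threshold A [threshold_spec()] (one-step models only) defining
#'   catastrophe; default end density with `f_crit = 0.2`.
#' @param cap_scale_sd Lognormal sdlog of the per-track cap-size factor `xi`.
#' @param sigma_cat Erf width of the catastrophe speed transition (s).
#' @param tau_exchange Washout exchange time constant (s); the 5-95%
#'   interval is `4 tau erfinv(0.9) ~ 4.652 tau`.
#' @param F_factor Intensity per unit growth speed (a.u. s / nm).
#' @param lattice_level EB lattice intensity (a.u.).
#' @param intensity_cv Multiplicative Gaussian intensity noise (CV).
#' @param bg_hi,bg_lo,bg_noise_sd Background plateau levels and noise (a.u.).
#' @param orient_mean,orient_sd,orient_frame_sd Orientation mean, per-track
#'   scatter, and per-frame noise (deg).
#' @return An object of class `synthetic_config` (a validated list).
#' @export
synthetic_config <- function(n_tracks = 100, seed = 1,
                             frame_rate = 4, t_grow = 100, t_post = 25,
                             pos_noise_sd = 30,
                             vg_mean = 33, vg_sd = 12,
                             vg_dist = c("truncnorm", "uniform"),
                             vg_range = c(20, 80), vg_min = 5,
                             tau_mem = NULL,
                             vs_a = 0.28, vs_b = 22, vs_sd = 3,
                             v_f = 480, k_m = 0.16,
                             threshold = threshold_spec("end_density",
                                                        f_crit = 0.2),
                             cap_scale_sd = 0.3, sigma_cat = 0.5,
                             tau_exchange = 0.0428,
                             F_factor = 1, lattice_level = 10,
                             intensity_cv = 0.15,
                             bg_hi = 100, bg_lo = 10, bg_noise_sd = 1.5,
                             orient_mean = 3.1, orient_sd = 7.3,
                             orient_frame_sd = 1) {
  vg_dist <- match.arg(vg_dist)
  check_scalar(n_tracks, "n_tracks", positive = TRUE)
  check_scalar(seed, "seed")
  for (nm in c("frame_rate", "t_grow", "t_post", "vg_mean", "v_f",
               "k_m", "sigma_cat", "tau_exchange", "F_factor"))
    check_scalar(get(nm), nm, positive = TRUE)
  for (nm in c("pos_noise_sd", "vg_sd", "vs_sd", "cap_scale_sd",
               "intensity_cv", "bg_noise_sd", "orient_sd", "orient_frame_sd",
               "vs_b"))
    check_scalar(get(nm), nm, nonneg = TRUE)
  if (!is.null(tau_mem)) check_scalar(tau_mem, "tau_mem", positive = TRUE)
  if (!inherits(threshold, "threshold_spec") ||
      !threshold$model %in% c("end_density", "total_number", "window_L"))
    stop_invalid("threshold must be a one-step threshold_spec")
  if (frame_rate * t_grow < 40)
    stop_invalid("need at least 40 pre-washout samples (frame_rate * t_grow)")
  cfg <- as.list(environment())
  structure(cfg, class = "synthetic_config")
}

# ground-truth delay for a cap scaled by xi under a one-step threshold model
truth_delay <- function(p, threshold, xi) {
  k <- cap_decay_rate(p)
  switch(threshold$model,
    end_density = (log(xi) - log(threshold$f_crit)) / k,
    total_number = -log(threshold$N_crit / (xi * total_sites(0, p))) / k,
    window_L = -log(threshold$NL_crit /
                      (xi * sites_in_window(0, p, threshold$L))) / k)
}

#' Generate one synthetic washout track
#'
#' Draws the track's kinetic truth (growth speed, shrinkage speed, cap-size
#' factor `xi`), builds the noiseless trace — growth, washout, slow shrinkage
#' transitioning to fast depolymerisation through an erf of width
#' `sigma_cat` centred so that the 25% speed criterion falls exactly at
#' `t_wo + delay_true` — and adds the configured noises. The EB end intensity
#' is `lattice + F xi v_ema(t)` before washout (`v_ema` is the speed averaged
#' with an exponential kernel of rate `k_m`, i.e. the cap-size proxy), decays
#' at `k_Mal3` until the transition centre, and sits at the lattice level
#' once fast depolymerisation has destroyed the cap.
#'
#' @param config A [synthetic_config()].
#' @param track_index Index used for the id and the per-track seed stream.
#' @return List with `track` (an [mt_track()]) and `truth` (a one-row
#'   `data.frame`: `id`, `v_g_true`, `v_s_true`, `t_wo_true`, `delay_true`,
#'   `cap_scale`, `k_Mal3_true`, `I_wo_true`, `short_delay`).
#' @export
generate_track <- function(config, track_index = 1L) {
  cfg <- config
  set.seed((cfg$seed * 1000L + track_index) %% .Machine$integer.max)
  dt <- 1 / cfg$frame_rate
  time <- seq(0, cfg$t_grow + cfg$t_post, by = dt)
  t_wo <- cfg$t_grow
  pre <- time <= t_wo

  # instantaneous growth speed over the pre-washout record
  if (is.null(cfg$tau_mem)) {
    v0 <- if (cfg$vg_dist == "uniform")
      stats::runif(1, cfg$vg_range[1], cfg$vg_range[2])
    else {
      repeat {
        v0 <- stats::rnorm(1, cfg$vg_mean, cfg$vg_sd)
        if (v0 > cfg$vg_min) break
      }
      v0
    }
    v_inst <- rep(v0, sum(pre))
  } else {
    # stationary OU around the cohort mean: exponential autocorrelation
    n_pre <- sum(pre)
    a <- exp(-dt / cfg$tau_mem)
    innov_sd <- cfg$vg_sd * sqrt(1 - a^2)
    v_inst <- numeric(n_pre)
    v_inst[1] <- stats::rnorm(1, cfg$vg_mean, cfg$vg_sd)
    for (k in 2:n_pre)
      v_inst[k] <- cfg$vg_mean + a * (v_inst[k - 1] - cfg$vg_mean) +
        stats::rnorm(1, 0, innov_sd)
    v_inst <- pmax(v_inst, cfg$vg_min)
  }
  # measured-equivalent growth speed: mean over the last 10 s of growth
  last10 <- time[pre] >= t_wo - 10
  v_g <- mean(v_inst[last10])
  v_s <- max(0, cfg$vs_a * v_g + cfg$vs_b + stats::rnorm(1, 0, cfg$vs_sd))
  xi <- stats::rlnorm(1, 0, cfg$cap_scale_sd)
  p <- kinetic_params(v_g = v_g, v_s = v_s, k_m = cfg$k_m)
  k_Mal3 <- cap_decay_rate(p)
  delay <- truth_delay(p, cfg$threshold, xi)
  short <- delay < 2 * dt
  delay <- max(delay, 0)
  t_cat <- t_wo + delay
  t0 <- t_cat + 2 * cfg$sigma_cat * erfinv(0.5)

  # positions: integrate the growth speed, then the erf speed transition
  x <- numeric(length(time))
  x[pre] <- c(0, cumsum((v_inst[-1] + v_inst[-length(v_inst)]) / 2 * dt))
  x_wo <- x[sum(pre)]
  post <- !pre
  x[post] <- catastrophe_position(time[post], x_wo, t_wo,
                                  v1 = -v_s, v2 = -cfg$v_f,
                                  t0 = t0, sigma = cfg$sigma_cat)
  x <- x + stats::rnorm(length(x), 0, cfg$pos_noise_sd)

  # EB end intensity: cap-size proxy = exponential moving average of the
  # speed with rate k_m (the comet integrates recent growth history)
  a_ema <- exp(-cfg$k_m * dt)
  v_ema <- numeric(length(v_inst))
  v_ema[1] <- v_inst[1]
  for (k in seq_along(v_inst)[-1])
    v_ema[k] <- a_ema * v_ema[k - 1] + (1 - a_ema) * v_inst[k]
  I_cap0 <- cfg$F_factor * xi * v_ema[length(v_ema)]
  cap <- numeric(length(time))
  cap[pre] <- cfg$F_factor * xi * v_ema
  cap[post] <- ifelse(time[post] < t0,
                      I_cap0 * exp(-k_Mal3 * (time[post] - t_wo)), 0)
  gfp_true <- cfg$lattice_level + cap
  mnoise <- function(v) v * (1 + stats::rnorm(length(v), 0, cfg$intensity_cv))
  gfp_end <- mnoise(gfp_true)
  gfp_lattice <- mnoise(rep(cfg$lattice_level, length(time)))

  background <- cfg$bg_lo + 0.5 * (cfg$bg_hi - cfg$bg_lo) *
    (1 - erf((time - t_wo) / (2 * cfg$tau_exchange))) +
    stats::rnorm(length(time), 0, cfg$bg_noise_sd)

  orient <- stats::rnorm(1, cfg$orient_mean, cfg$orient_sd) +
    stats::rnorm(length(time), 0, cfg$orient_frame_sd)

  id <- sprintf("mt%04d", track_index)
  list(track = mt_track(time = time, end_pos = x, background = background,
                        gfp_end = gfp_end, gfp_lattice = gfp_lattice,
                        orientation = orient, id = id),
       truth = data.frame(id = id, v_g_true = v_g, v_s_true = v_s,
                          t_wo_true = t_wo, delay_true = delay,
                          cap_scale = xi, k_Mal3_true = k_Mal3,
                          I_wo_true = cfg$lattice_level + I_cap0,
                          short_delay = short, stringsAsFactors = FALSE))
}

#' Generate a cohort of synthetic tracks with ground truth
#'
#' @param config A [synthetic_config()].
#' @return List with `tracks` (list of [mt_track()]) and `truth` (one row per
#'   track).
#' @export
generate_cohort <- function(config) {
  out <- lapply(seq_len(config$n_tracks), function(i)
    generate_track(config, i))
  tracks <- lapply(out, `[[`, "track")
  names(tracks) <- vapply(tracks, `[[`, "", "id")
  list(tracks = tracks, truth = do.call(rbind, lapply(out, `[[`, "truth")))
}

#' Generate a stack of synthetic comet frames
#'
#' Each frame is the analytic [comet_model()] evaluated on a pixel grid plus
#' white Gaussian noise; optional Gaussian jitter of the detected-end
#' alignment shifts each frame's origin.
#'
#' @param n_frames Number of frames.
#' @param L_comet Comet decay length (nm).
#' @param sigma_psf PSF width (nm).
#' @param x Pixel grid (nm); default 107 nm/pixel spanning -1.6 to +3.2 um.
#' @param amp,lattice_level Comet amplitude and lattice level (a.u.).
#' @param noise_sd White noise sd per pixel, as a fraction of the peak of
#'   the noiseless profile.
#' @param jitter_sd Alignment jitter sd (nm).
#' @param seed Integer seed.
#' @return Matrix (frames x pixels) with attribute `"x"`; feed to
#'   [build_average_comet()].
#' @export
generate_comet_frames <- function(n_frames, L_comet, sigma_psf,
                                  x = seq(-1605, 3210, by = 107),
                                  amp = 1, lattice_level = 0.2,
                                  noise_sd = 0.5, jitter_sd = 0, seed = 1) {
  check_scalar(n_frames, "n_frames", positive = TRUE)
  set.seed(seed %% .Machine$integer.max)
  peak <- max(comet_model(x, L_comet, sigma_psf, xc = 0, amp = amp,
                          lattice_level = lattice_level))
  stack <- t(vapply(seq_len(n_frames), function(i) {
    xc <- if (jitter_sd > 0) stats::rnorm(1, 0, jitter_sd) else 0
    comet_model(x, L_comet, sigma_psf, xc = xc, amp = amp,
                lattice_level = lattice_level) +
      stats::rnorm(length(x), 0, noise_sd * peak)
  }, numeric(length(x))))
  attr(stack, "x") <- x
  stack
}

#' Generate a constant-density intensity series (GTPgammaS mimic)
#'
#' A stationary intensity series with measurement noise only — the mimic of
#' a lattice with a constant density of EB binding sites, used as the low-D
#' control for [relative_variance()].
#'
#' @param n_frames Number of frames (default 15000).
#' @param mean_intensity Mean intensity (a.u.).
#' @param cv Multiplicative measurement noise (CV).
#' @param seed Integer seed.
#' @return Numeric intensity series.
#' @export
generate_constant_density_series <- function(n_frames = 15000,
                                             mean_intensity = 100,
                                             cv = 0.15, seed = 1) {
  check_scalar(n_frames, "n_frames", positive = TRUE)
  check_scalar(mean_intensity, "mean_intensity", positive = TRUE)
  set.seed(seed %% .Machine$integer.max)
  mean_intensity * (1 + stats::rnorm(n_frames, 0, cv))
}
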