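# Shared fixtures. Heavy cohorts are generated once per test run and cached.

.fixtures <- new.env(parent = emptyenv())

mal3_params <- function(...) kinetic_params(v_g = 33, v_s = 40, k_m = 0.16, ...)

# the washout condition used for delay-formula examples:
# v_g = 28 nm/s, v_s = 0.28 v_g + 22 = 29.84 nm/s, k_m = 0.16 1/s
washout_params <- function(...) {
  kinetic_params(v_g = 28, v_s = 0.28 * 28 + 22, k_m = 0.16, ...)
}

# random valid kinetic parameters for property sweeps
random_params <- function(two_step = FALSE) {
  k_m <- stats::runif(1, 0.05, 0.5)
  kinetic_params(v_g = stats::runif(1, 10, 90),
                 v_s = stats::runif(1, 0, 60),
                 k_m = k_m,
                 k_1 = if (two_step) k_m * stats::runif(1, 2, 30))
}

# a clean synthetic track built from the analytic position model: linear
# growth, then the erf speed transition (all noise off unless asked)
clean_track <- function(v_g = 28, v_s = 26, v_f = 480, t_wo = 50, delay = 8,
                        sigma = 0.5, frame_rate = 4, t_post = 20,
                        pos_noise = 0, id = "clean") {
  time <- seq(0, t_wo + t_post, by = 1 / frame_rate)
  t_cat <- t_wo + delay
  t0 <- t_cat + 2 * sigma * erfinv(0.5)
  pre <- time <= t_wo
  x <- numeric(length(time))
  x[pre] <- v_g * (time[pre] - t_wo)
  x[!pre] <- ebcap:::catastrophe_position(time[!pre], 0, t_wo, -v_s, -v_f,
                                          t0, sigma)
  bg <- 10 + 45 * (1 - erf((time - t_wo) / (2 * 0.0428)))
  mt_track(time = time, end_pos = x + stats::rnorm(length(x), 0, pos_noise),
           background = bg, id = id)
}

cached <- function(name, expr) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- force(expr)
  .fixtures[[name]]
}

# default Mal3-like cohort (n = 100) with its metrics, shared across files
std_cohort <- function() {
  cached("std_cohort", {
    cfg <- synthetic_config(n_tracks = 100, seed = 1)
    coh <- generate_cohort(cfg)
    coh$metrics <- analyze_cohort(coh$tracks)
    coh$config <- cfg
    coh
  })
}
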