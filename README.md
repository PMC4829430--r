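# ebcap

Kinetic threshold analysis of the microtubule EB cap after tubulin washout.

## The problem

Growing microtubules are protected from catastrophe — the abrupt switch to
fast depolymerisation — by a "cap" at their plus end, the region of
freshly-added tubulin that end-binding (EB) proteins recognise. In a tubulin
washout experiment the soluble tubulin is removed in a fraction of a second,
growth stops, and the time until catastrophe (the *delay time*) measures the
momentary stability conferred by the cap that existed at the moment of
washout. `ebcap` implements the complete quantitative analysis of such
experiments for single-microtubule TIRF traces:

* **Cap kinetics.** At washout a microtubule grown at speed `v_g` with
  maturation rate `k_m` carries an exponential EB-site profile
  `n(x) = n_x0 exp(-x k_m / v_g)` with maximal density
  `n_x0 = n_pf / l_dim = 13/8 nm⁻¹`. Afterwards every site matures at `k_m`
  and the end shrinks slowly at `v_s`, so the end density and the total site
  number both decay at the **cap decay rate**

  `k_Mal3 = k_m (v_s / v_g + 1)`.

* **Threshold models of catastrophe.** Catastrophe is triggered when the
  decaying cap reaches a threshold — a critical *end density*
  (`T_end = -ln(f_crit)/k_Mal3`), a critical *total number*
  (`T_tot = -ln[N_crit k_m/(n_x0 v_g)]/k_Mal3`), a critical number within a
  window `L` from the end, or their two-step maturation variants
  (`A →k1 B →km C`, solved numerically). The models predict different
  speed-dependence of the delay, so weighted fits to speed-sorted delay data
  discriminate between them.

* **Trace analysis.** Washout time from an error-function fit to the
  background channel; growth speed from a 10 s pre-washout window;
  catastrophe time from a nonlinear fit of the position trace with the
  integral of `v(t) = (v1+v2)/2 + (v1-v2)/2 · erf((t0-t)/(2σ))` and a 25%
  speed-change criterion (`t_cat = t0 - 2σ·erfinv(0.5)`); shrinkage and
  lattice-subtracted EB intensity metrics; catastrophe-aligned cohort
  averages with a mono-exponential decay fit.

* **Comet analysis.** Averaged EB comet profiles are fitted with the
  analytic convolution of the exponential site profile with a Gaussian PSF
  (an exponentially-modified Gaussian plus an erf step), yielding the comet
  length `L_comet = v_g / k_m` and hence `k_m`.

* **Synthetic cohorts.** A fully seeded generator produces washout cohorts
  (4 Hz sampling, ~30 nm tracking noise, erf-smoothed catastrophes,
  `v_s = 0.28 v_g + 22` nm/s, 480 nm/s fast depolymerisation, a 199 ms
  buffer exchange, lognormal cap-size dispersion, optional mean-reverting
  growth-speed memory) together with per-track ground truth, so every stage
  of the pipeline is testable by parameter recovery.

## Worked example

```r
library(ebcap)

# closed-form predictions for the Mal3 condition
p <- kinetic_params(v_g = 33, v_s = 40, k_m = 0.16)
cap_decay_rate(p)                       # 0.3539394  (prints as 0.35 1/s)
delay_from_intensity_ratio(1, 0.29, 0.35)  # 3.536784 s

# a synthetic Mal3-like cohort through the full pipeline
cfg <- synthetic_config(n_tracks = 139, seed = 1,
                        threshold = threshold_spec("end_density", f_crit = 0.28))
res <- run_pipeline(synthetic = cfg, k_m = 0.16, n_groups = 4,
                    fit_models = "end_density")
mean(res$metrics$delay)                       # 4.07424 s
100 * mean(res$metrics$cap_fraction_cat)      # 29.54798 %
res$fits$end_density
# Threshold fit [end_density, one_step]: f_crit = 0.2417 +/- 0.0073,
#   chi2_red = 1.83 (4 points)
```

The first two numbers say: with the measured maturation rate, shrinkage and
growth speeds, the cap intensity is predicted to decay at 0.35 s⁻¹, and a
cap reduced to 29% of its washout size at catastrophe implies a mean delay
of ≈ 3.5 s. The pipeline numbers show the generator/analysis round trip: a
cohort built with an end-density threshold of 0.28 is measured back at a
~29.5% mean cap fraction; the speed-sorted fit on this narrow-speed cohort
comes in slightly low (0.24) — the threshold is best constrained on the
wide-speed cohort, where the recovery is unbiased (see the tests and
`scripts/acceptance.R`).

The numbered scripts under `analysis/` run the full study on simulated
cohorts (simulation → trace analysis → comet analysis → model fits →
correlations) and write their tables under `results/`:

```sh
Rscript analysis/01_simulate.R
Rscript analysis/02_trace_analysis.R   # mean delay 4.00 s, cap fraction 30.1 %,
                                       # aligned decay 0.330 1/s for the Mal3 cohort
Rscript analysis/03_comet.R            # L = 210.8 nm -> k_m = 0.157 1/s
Rscript analysis/04_model_fits.R       # end density beats total number:
                                       # chi2_red 0.15 vs 45 on the speed series
Rscript analysis/05_correlations.R     # rho(I_wo, delay) = 0.88, orientation r = 0.07
```

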