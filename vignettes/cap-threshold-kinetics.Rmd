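---
title: "Kinetic threshold models of microtubule cap loss after tubulin washout"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Kinetic threshold models of microtubule cap loss after tubulin washout}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ebcap)
```

## The model

A microtubule growing at speed $v_g$ continuously creates high-affinity EB
binding sites at its plus end, which mature into ordinary lattice at a
first-order rate $k_m$. In steady growth this produces an exponential
spatial profile of sites — the comet —

$$n(x) = n_{x0}\, e^{-x k_m / v_g}, \qquad n_{x0} = \frac{n_{pf}}{l_{dim}} = \frac{13}{8\,\mathrm{nm}},$$

with decay length $L_{comet} = v_g / k_m$. Treating the $n_{pf}$
protofilaments as a single effective filament is the coarsest useful
description; it ignores protofilament-level stochasticity and taper, which
is one reason real delay-time dispersion exceeds the model's.

When soluble tubulin is removed at $t = 0$ two processes erode the cap:
every site keeps maturing at $k_m$, and the end itself shrinks slowly at
$v_s$, removing the densest part of the profile. Both the site density at
the (moving) end and the total site number
$N(t) = n_{x0}(v_g/k_m)\,e^{-k_{Mal3} t}$ then decay at the single rate

$$k_{Mal3} = k_m\left(\frac{v_s}{v_g} + 1\right),$$

which is also the decay rate of the lattice-subtracted EB intensity at the
end ([`cap_decay_rate()`], [`total_sites()`]). With the measured
$k_m = 0.16\ \mathrm{s^{-1}}$, $v_s = 40$ and $v_g = 33\ \mathrm{nm/s}$ this
gives $0.35\ \mathrm{s^{-1}}$. (Reported shrinkage speeds for this
condition range over 38–40 nm/s; both are plain inputs here — nothing in
the package pins either.)

### Threshold models

Catastrophe is modelled as the moment a decaying cap quantity crosses a
fixed threshold:

* **end density** — fraction $f_{crit}$ of $n_{x0}$ at the end:
  $T = -\ln(f_{crit})/k_{Mal3}$. Independent of the cap length; the delay
  depends on $v_g$ only through $k_{Mal3}$.
* **total number** — fixed count $N_{crit}$ anywhere in the cap:
  $T = -\ln[N_{crit} k_m/(n_{x0} v_g)]/k_{Mal3}$. Longer caps (faster
  growth) take disproportionately longer to reach it.
* **window L** — fixed count within a length $L$ of the end; interpolates
  between the two above as $L$ goes from one dimer to infinity, and is the
  model behind the global $\chi^2_{red}(L)$ scan ([`global_fit_L()`]).
* **two-step maturation** — a fast first step $k_1 > k_m$
  ($A \to B \to C$) delays site creation; thresholds on $A+B$ are solved by
  bracketed root-finding (the closed forms are monotone). The singular
  point $k_1 = k_m$ is rejected rather than patched with its analytic
  limit: the fits only ever use $k_1 = 5 k_m$ or $20 k_m$, and silently
  accepting near-singular ratios would mask user error.

Because the two one-parameter models predict different speed dependence,
fitting the *speed-sorted* group means (weighted by $1/\mathrm{sem}^2$)
discriminates them; fitting group averages rather than individual tracks is
deliberate — the observed track-to-track dispersion contains physics the
deterministic threshold models do not claim to capture, so an
individual-track likelihood would be over-committed.

## Trace analysis choices

* **Washout time**: inflection of an error-function fit to the
  soluble-tubulin background, over the full record (the exchange is fast
  and well-separated; no sub-window is needed). The 5–95% exchange interval
  is $4\tau\,\mathrm{erfinv}(0.9) \approx 4.652\tau$. At 4 Hz the ~0.2 s
  exchange is sub-frame, so `exchange_90` is only quantitative when the
  background is sampled faster (as in the dedicated exchange calibration).
* **Catastrophe**: the position trace after washout is fitted with the
  analytic integral of
  $v(t) = \tfrac{1}{2}(v_1+v_2) + \tfrac{1}{2}(v_1-v_2)\,
  \mathrm{erf}[(t_0-t)/(2\sigma)]$. The erf argument divides by $2\sigma$
  exactly as written — the alternative reading $(t_0-t)/2\cdot\sigma$ is
  dimensionally absurd. Initialisation: $t_0$ at the steepest 3-frame drop,
  $v_1$ from the first half of the post-washout segment, $v_2$ from the
  last second, $\sigma = 0.5$ s, five multi-starts jittering $t_0$ by
  $\pm 1$ s; the best residual wins. A fit with $|v_2| \le |v_1|$ is a
  *no-catastrophe* error, not a result.
* **Catastrophe time**: the 25% speed-change criterion has the closed form
  $t_{cat} = t_0 - 2\sigma\,\mathrm{erfinv}(0.5)$, independent of the
  speeds themselves.
* **Intensities**: $I_{wo}$ and $I_{cat}$ average the end channel over 1 s
  windows centred on the washout and catastrophe times (matching the 1 s
  windows used for the shifted-intensity correlations); the lattice level
  is the time-average of the lattice channel 1.5 µm behind the end.
* **Aligned averages**: tracks are aligned at their detected catastrophe
  time (and fitted catastrophe position, for the position channel),
  linearly interpolated to a 0.25 s grid, and averaged where at least half
  of the tracks have data — the coverage rule trims end-of-record bias.
  The mono-exponential decay fit uses only each track's post-washout
  samples: before its own washout a track sits on its growth plateau, and
  averaging that plateau into the decay would flatten the fitted rate. The
  lattice level in that fit is fixed to the measured lattice mean; over a
  window of only $\sim 1.6/k$ the rate and a free offset are degenerate,
  and the lattice channel measures the offset directly.
* **Exclusions**: every track failure (no washout, no catastrophe,
  non-convergence) is recorded in a status table; only clean fits enter the
  metrics. Nothing is dropped silently.

## The synthetic generator

The generator ([`synthetic_config()`], [`generate_cohort()`]) emulates the
study conditions: 4 Hz sampling with ~100 s of growth; ~30 nm Gaussian
tracking noise; growth speeds around 33 nm/s (sd 12, truncated normal; a
uniform 20–80 nm/s option reproduces the pooled concentration-series
design); slow shrinkage $v_s = 0.28 v_g + 22$ nm/s with a 3 nm/s residual;
fast depolymerisation at 480 nm/s; an erf background drop with
$\tau = 42.8$ ms (199 ms 5–95%); catastrophe transitions of width
$\sigma = 0.5$ s placed so that the 25% criterion falls exactly at
$t_{wo} + T_{true}$; end-region orientations scattered with sd 7.3°.

Design choices that are *modelling decisions*, not measured facts:

* **Cap-size dispersion.** The deterministic threshold model predicts a
  single delay per speed, far narrower than observed. Dispersion is
  injected through a lognormal per-track cap-scale factor $\xi$
  (sdlog 0.3), making the ground-truth delay
  $T = (\ln\xi - \ln f_{crit})/k_{Mal3}$ under the end-density default.
  The value 0.3 was chosen once to give washout-intensity spread of the
  qualitative breadth seen in the measured histograms.
* **Intensity trace.** The end intensity is
  $\mathrm{lattice} + F\,\xi\,\bar v(t)$ before washout, where $\bar v$ is
  the speed averaged with an exponential kernel of rate $k_m$ — the comet
  integrates recent growth history, which is what makes shifted-window
  intensity correlations decay. After washout it decays at $k_{Mal3}$
  until the transition centre $t_0$, where fast depolymerisation destroys
  the remaining cap within much less than a frame, then sits at the
  lattice level. Noise is multiplicative Gaussian (CV 0.15), not a photon
  model.
* **Speed memory.** Optionally the speed follows a stationary
  mean-reverting (Ornstein–Uhlenbeck) process around the cohort mean with
  memory time $\tau_{mem} = 5$ s — enough structure to make the
  correlation-decay analysis testable; the real memory kinetics are not
  experimentally parameterised, so this is a contract (exponential
  autocorrelation), not a claim.
* **Coupled-delay cohorts.** For properties about delay–cap-size
  correlations the generator is run with a *total-number* threshold, which
  couples the delay to the full initial cap ($v_g \xi$) rather than to
  $\xi$ alone — the configuration in which "bigger caps live longer" holds
  track by track.

What passing recovery tests on these cohorts shows: the pipeline is
unbiased and correctly calibrated *for data generated by its own model
class with Gaussian noises*. What it cannot show: robustness to taper,
bending, photobleaching, stage drift, or non-exponential cap profiles —
none of which the generator emulates.

## Numerical choices

* All nonlinear fits use Levenberg–Marquardt (`minpack.lm`), with analytic
  model expressions (the erf integral has the closed form
  $G(t) = -2\sigma[u\,\mathrm{erf}(u) + e^{-u^2}/\sqrt{\pi}]$,
  $u = (t_0-t)/(2\sigma)$). The washout fit drops to the raw
  Levenberg–Marquardt driver because a sub-frame exchange makes the
  gradient in $\tau$ near-singular at the start values.
* The comet model is evaluated in log space
  ($\log\mathrm{EMG} = \sigma^2/2L^2 - s/L + \log\Phi(\cdot)$) so the
  exponentially-growing prefactor never overflows ahead of the tip. The
  Gaussian kernel is normalised to unit area (a reparameterisation of the
  unnormalised convention, absorbed by the amplitude); a fitted profile
  must beat a constant model by $R^2 \ge 0.8$, otherwise the "comet" is an
  offset in disguise and the fit is refused.
* One-parameter threshold fits profile the weighted SSR on a 60-point log
  grid and refine the best bracket with Brent's method; thresholds are
  bounded ($f_{crit} \in (10^{-3}, 1]$, counts below the smallest initial
  value across groups) and a fit at a bound is flagged. Two-step delays use
  bracketed `uniroot` on $[0, 10/k_m]$ at $10^{-9}$ s tolerance so that
  back-substitution reproduces thresholds to $10^{-9}$ relative.
* Spearman p-values use the t-approximation (the tabulated exact null is
  pointless at the $p < 10^{-15}$ magnitudes involved); an exact
  permutation p is available for $n \le 8$ and anchors the approximation
  in tests. Ties get midranks.
* Speed sorting splits the speed-ordered tracks into contiguous groups,
  remainder to the slowest groups; with 210 tracks and 7 groups that is
  30 per group (a 7 × 31 grouping would need 217 tracks; floor-equal
  groups are used throughout).

## Problem sizes

Simulated studies use the cohort sizes of the real conditions (139 / 101 /
210 tracks; 5500 comet frames; 500 tracks for the bias check), which keep
every script and the test suite in the minutes range on a laptop.

## Known limitations

* The 1 s intensity windows bias the measured cap fraction upward by a few
  percent (the washout window averages plateau and decay); the effect is
  part of the measurement definition, visible in the noiseless
  self-consistency test, and matches how the real analysis was done.
* `exchange_90` is not quantitative at 4 Hz (sub-frame transition).
* The measured $v_s$ over $[t_{wo}, t_{cat}]$ includes the first quarter of
  the erf transition, inflating it by a few percent for soft transitions —
  consequently measured shrinkage lengths systematically exceed
  $v_s \cdot T$, as in the real data.
* Delay-time *dispersion* is injected, not predicted; only its mean
  structure is a model output.
* The relative-variance statistic D is scale-dependent (var/mean);
  comparisons are only meaningful at matched mean intensity and noise, as
  in `analysis/05_correlations.R`.
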