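# Speed-sorted fitting of the kinetic threshold models to washout delay data
# and the global window-L fit with reduced chi-square model comparison.

#' Sort tracks into speed groups and average
#'
#' Sorts per-track metrics by pre-washout growth speed and splits them into
#' `n_groups` contiguous groups of (as near as divisibility allows) equal
#' size, the remainder going to the slowest groups. Speed sorting overcomes
#' strongly overlapping speed distributions across conditions before
#' averaging.
#'
#' @param metrics Metrics table (needs at least `v_g` and `delay` columns).
#' @param n_groups Number of speed groups (>= 2).
#' @return An object of class `speed_groups`: a `data.frame` with one row per
#'   group holding `n` and mean/sem pairs of every numeric metric present
#'   (`v_g`, `delay`, `v_s`, `I_wo`, `I_cat`, ...).
#' @export
speed_sort <- function(metrics, n_groups) {
  check_scalar(n_groups, "n_groups")
  if (n_groups < 2L) stop_invalid("n_groups must be >= 2")
  n <- nrow(metrics)
  if (n < 2L * n_groups)
    stop(errorCondition(
      sprintf("need at least %d tracks for %d groups, got %d",
              2L * n_groups, n_groups, n),
      class = c("ebcap_insufficient_data", "error")))
  ord <- order(metrics$v_g)           # stable sort: ties keep input order
  metrics <- metrics[ord, , drop = FALSE]
  base <- n %/% n_groups; rem <- n %% n_groups
  sizes <- rep(base, n_groups) + c(rep(1L, rem), rep(0L, n_groups - rem))
  grp <- rep(seq_len(n_groups), times = sizes)
  num_cols <- names(metrics)[vapply(metrics, is.numeric, logical(1))]
  num_cols <- setdiff(num_cols, c("t0", "sigma", "x_cat"))
  rows <- lapply(split(seq_len(n), grp), function(idx) {
    g <- metrics[idx, , drop = FALSE]
    out <- data.frame(n = length(idx))
    for (cn in num_cols) {
      v <- g[[cn]]
      out[[cn]] <- mean(v, na.rm = TRUE)
      out[[paste0(cn, "_sem")]] <-
        stats::sd(v, na.rm = TRUE) / sqrt(sum(is.finite(v)))
    }
    out
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("speed_groups", "data.frame")
  out
}

#' Empirical relation between slow shrinkage and growth speed
#'
#' OLS fit of `v_s = a v_g + b` across tracks; the fitted relation supplies
#' the shrinkage speed inside the threshold-model predictions when fitting
#' data spanning a wide speed range.
#'
#' @param metrics Metrics table with `v_s` and `v_g` columns.
#' @return List with `a` (dimensionless), `b` (nm/s), their standard errors
#'   `a_se`, `b_se`, and `n`.
#' @export
vs_vg_relation <- function(metrics) {
  ok <- stats::complete.cases(metrics$v_s, metrics$v_g)
  if (sum(ok) < 10L)
    stop(errorCondition("need at least 10 tracks with valid v_s and v_g",
                        class = c("ebcap_insufficient_data", "error")))
  if (stats::sd(metrics$v_g[ok]) == 0)
    stop_invalid("degenerate v_g spread; relation unidentifiable")
  fit <- stats::lm(v_s ~ v_g, data = metrics[ok, ])
  cf <- suppressWarnings(summary(fit))$coefficients  # sd 0 residuals allowed
  list(a = cf["v_g", 1], b = cf["(Intercept)", 1],
       a_se = cf["v_g", 2], b_se = cf["(Intercept)", 2], n = sum(ok))
}

# v_s for a group-mean v_g under a vs model: either list(a, b) or a fixed value
vs_from_model <- function(v_g, vs_model) {
  if (is.list(vs_model)) vs_model$a * v_g + vs_model$b
  else rep(vs_model, length(v_g))
}

# predicted delay for one group under a threshold model
predict_group_delay <- function(v_g, vs_model, k_m, theta, model, maturation,
                                k1_ratio) {
  vapply(seq_along(v_g), function(i) {
    p <- kinetic_params(v_g = v_g[i], v_s = vs_from_model(v_g[i], vs_model),
                        k_m = k_m,
                        k_1 = if (maturation == "two_step") k1_ratio * k_m)
    switch(model,
      end_density = if (maturation == "one_step")
        delay_end_density(p, theta)$delay
      else delay_two_step(p, threshold_spec("end_density_2step",
                                            f_crit = theta))$delay,
      total_number = if (maturation == "one_step")
        delay_total_number(p, theta)$delay
      else delay_two_step(p, threshold_spec("total_number_2step",
                                            N_crit = theta))$delay)
  }, numeric(1))
}

#' Fit a threshold model to speed-sorted delay data
#'
#' Weighted least squares (weights `1/sem^2`) of the predicted
#' washout-to-catastrophe delay against the group mean delays over the group
#' mean growth speeds. The single free parameter is the threshold: the
#' end-density fraction `f_crit` or the total number `N_crit` (their
#' two-step analogues under `maturation = "two_step"`, solved numerically).
#' The search profiles the weighted SSR on a log-spaced grid and refines the
#' best bracket with [stats::optimize()].
#'
#' @param groups A [speed_sort()] table with `v_g`, `delay`, `delay_sem`.
#' @param k_m Maturation rate (1/s), fixed (from comet analysis).
#' @param vs_model Either `list(a = , b = )` for `v_s = a v_g + b`, or a
#'   single fixed `v_s` (nm/s).
#' @param model `"end_density"` or `"total_number"`.
#' @param maturation `"one_step"` or `"two_step"`.
#' @param k1_ratio Ratio `k_1 / k_m` for two-step maturation (default 5).
#' @return An object of class `fit_result`: `model`, `maturation`, `par`
#'   (named threshold value), `se`, `chi2_red`, `n_points`, `n_free`,
#'   `predicted`, `at_bound`.
#' @export
fit_threshold <- function(groups, k_m, vs_model,
                          model = c("end_density", "total_number"),
                          maturation = c("one_step", "two_step"),
                          k1_ratio = 5) {
  model <- match.arg(model)
  maturation <- match.arg(maturation)
  check_scalar(k_m, "k_m", positive = TRUE)
  v_g <- groups$v_g; obs <- groups$delay; sem <- groups$delay_sem
  if (any(!is.finite(sem)) || any(sem <= 0))
    stop_invalid("group delay sems must be positive and finite")
  w <- 1 / sem^2
  # parameter bounds: fractional threshold in (1e-3, 1); count threshold
  # below the smallest initial site number among the groups
  if (model == "end_density") {
    lo <- 1e-3; hi <- 1
  } else {
    N0 <- vapply(v_g, function(v)
      total_sites(0, kinetic_params(v, vs_from_model(v, vs_model), k_m)),
      numeric(1))
    lo <- 1e-3; hi <- min(N0) * 0.9999
  }
  ssr <- function(theta) {
    pred <- tryCatch(
      predict_group_delay(v_g, vs_model, k_m, theta, model, maturation,
                          k1_ratio),
      error = function(e) NULL)
    if (is.null(pred)) return(Inf)
    sum(w * (obs - pred)^2)
  }
  grid <- exp(seq(log(lo), log(hi), length.out = 60))
  vals <- vapply(grid, ssr, numeric(1))
  k <- which.min(vals)
  bracket <- c(grid[max(1L, k - 1L)], grid[min(length(grid), k + 1L)])
  opt <- stats::optimize(ssr, interval = bracket, tol = 1e-9 * diff(bracket))
  theta <- opt$minimum
  pred <- predict_group_delay(v_g, vs_model, k_m, theta, model, maturation,
                              k1_ratio)
  chi2 <- reduced_chi2(obs, pred, sem, n_free = 1)
  # linearised standard error from the weighted Jacobian
  h <- theta * 1e-5
  J <- (predict_group_delay(v_g, vs_model, k_m, theta + h, model, maturation,
                            k1_ratio) - pred) / h
  se <- sqrt(1 / sum(w * J^2))
  at_bound <- theta <= lo * 1.01 || theta >= hi * 0.99
  if (at_bound) warning("fitted threshold is at a parameter bound", call. = FALSE)
  par_name <- paste0(
    switch(model, end_density = "f_crit", total_number = "N_crit"),
    if (maturation == "two_step") "_2step" else "")
  structure(
    list(model = model, maturation = maturation,
         par = stats::setNames(theta, par_name), se = se,
         chi2_red = chi2, n_points = length(obs), n_free = 1L,
         predicted = pred, at_bound = at_bound),
    class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf("Threshold fit [%s, %s]: %s = %.4g +/- %.2g, chi2_red = %.3g (%d points)\n",
              x$model, x$maturation, names(x$par), x$par, x$se, x$chi2_red,
              x$n_points))
  invisible(x)
}

#' Reduced chi-square
#'
#' `sum(((obs - pred) / sem)^2) / (n_points - n_free)`.
#'
#' @param observed,predicted,sems Numeric vectors of equal length; `sems > 0`.
#' @param n_free Number of fitted parameters (< number of points).
#' @return The reduced chi-square value.
#' @export
reduced_chi2 <- function(observed, predicted, sems, n_free) {
  check_vector(observed, "observed"); check_vector(predicted, "predicted")
  if (any(sems <= 0)) stop_invalid("sems must all be positive")
  n <- length(observed)
  if (n <= n_free) stop_invalid("need more points than free parameters")
  sum(((observed - predicted) / sems)^2) / (n - n_free)
}

#' Global window-L fit across delay and intensity datasets
#'
#' For each candidate window length `L`, simultaneously fits the window-L
#' threshold model to all speed-sorted delay datasets and the corresponding
#' intensity predictions (`I_wo = F v_g`,
#' `I_cat = F NL_crit (l_dim/n_pf) k_m / (1 - exp(-k_m L / v_g))`) to the
#' speed-sorted intensity data. Free parameters are one `NL_crit` per delay
#' dataset (shared with the intensity dataset linked to it) and one
#' proportionality factor `F` per intensity dataset; all residuals are
#' weighted by `1/sem^2`. The resulting reduced chi-square as a function of
#' `L` locates the cap region that matters for stability.
#'
#' @param delay_datasets List of datasets, each a list with elements
#'   `groups` (a [speed_sort()] table), `k_m` (1/s) and `vs_model`
#'   (as in [fit_threshold()]).
#' @param intensity_datasets List (possibly empty) of datasets, each a list
#'   with `groups` (needs `v_g`, `I_wo`, `I_wo_sem`, `I_cat`, `I_cat_sem`),
#'   `k_m`, `vs_model` and `link` (index of the delay dataset whose
#'   `NL_crit` it shares).
#' @param L_grid Candidate window lengths (nm).
#' @return List with `table` (a `data.frame` of `L`, `chi2_red`) and `fits`
#'   (per-L lists of fitted `NL_crit` and `F` values).
#' @export
global_fit_L <- function(delay_datasets, intensity_datasets = list(),
                         L_grid = c(8, 16, 40, 80, 160, 320)) {
  if (length(delay_datasets) < 1L) stop_invalid("need at least one delay dataset")
  check_vector(L_grid, "L_grid")
  if (any(L_grid <= 0)) stop_invalid("L_grid must be positive")
  nd <- length(delay_datasets); ni <- length(intensity_datasets)
  fit_one_L <- function(L) {
    resid_fn <- function(logpar) {
      NL <- exp(logpar[seq_len(nd)])
      Fs <- if (ni) exp(logpar[nd + seq_len(ni)]) else numeric(0)
      res <- numeric(0)
      for (i in seq_len(nd)) {
        ds <- delay_datasets[[i]]; g <- ds$groups
        pred <- tryCatch(vapply(g$v_g, function(v) {
          p <- kinetic_params(v, vs_from_model(v, ds$vs_model), ds$k_m)
          delay_window_L(p, L, NL[i])$delay
        }, numeric(1)), error = function(e) NULL)
        if (is.null(pred)) return(rep(1e6, 1))
        res <- c(res, (g$delay - pred) / g$delay_sem)
      }
      for (j in seq_len(ni)) {
        ds <- intensity_datasets[[j]]; g <- ds$groups
        NLj <- NL[ds$link]
        p0 <- kinetic_params(mean(g$v_g), 0, ds$k_m)
        pred_wo <- Fs[j] * g$v_g
        pred_cat <- Fs[j] * NLj * (p0$l_dim / p0$n_pf) * ds$k_m /
          (1 - exp(-ds$k_m * L / g$v_g))
        res <- c(res, (g$I_wo - pred_wo) / g$I_wo_sem,
                 (g$I_cat - pred_cat) / g$I_cat_sem)
      }
      res
    }
    start <- log(c(
      vapply(delay_datasets, function(ds) {
        NL0 <- min(vapply(ds$groups$v_g, function(v)
          sites_in_window(0, kinetic_params(v, vs_from_model(v, ds$vs_model),
                                            ds$k_m), L),
          numeric(1)))
        0.3 * NL0
      }, numeric(1)),
      vapply(intensity_datasets, function(ds)
        mean(ds$groups$I_wo) / mean(ds$groups$v_g), numeric(1))))
    fit <- minpack.lm::nls.lm(par = start, fn = resid_fn,
                              control = minpack.lm::nls.lm.control(maxiter = 300))
    res <- resid_fn(fit$par)
    n_free <- length(start)
    chi2 <- sum(res^2) / (length(res) - n_free)
    pars <- exp(fit$par)
    list(chi2_red = chi2,
         NL_crit = pars[seq_len(nd)],
         F = if (ni) pars[nd + seq_len(ni)] else numeric(0))
  }
  fits <- lapply(L_grid, fit_one_L)
  list(table = data.frame(L = L_grid,
                          chi2_red = vapply(fits, `[[`, 0, "chi2_red")),
       fits = stats::setNames(fits, paste0("L", L_grid)))
}
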