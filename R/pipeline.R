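# End-to-end pipeline: (synthetic or supplied) tracks -> per-track metrics ->
# speed sorting, threshold fits, correlations and aligned averages, with all
# tables writable as delimited text.

#' Run the full washout-analysis pipeline
#'
#' Executes washout detection, growth-speed measurement, catastrophe fitting
#' and metric extraction on every track, then the cohort-level stages:
#' speed sorting, the `v_s(v_g)` relation, threshold-model fits, Spearman
#' correlations of delay with growth speed and EB intensity, and
#' catastrophe-aligned averages. Stages that need EB channels are skipped
#' when those channels are absent; per-track failures are reported in the
#' `status` element, and the run fails only if every track fails.
#'
#' @param tracks List of [mt_track()] objects; alternatively pass
#'   `synthetic` to generate them.
#' @param synthetic Optional [synthetic_config()]; generated tracks and
#'   truth are included in the result.
#' @param k_m Maturation rate (1/s) used in the threshold-model fits
#'   (typically from comet analysis).
#' @param n_groups Number of speed groups (default 7).
#' @param fit_models Threshold models to fit (subset of
#'   `c("end_density", "total_number")`).
#' @param shifts Window shifts (s) for the correlation-decay analysis;
#'   `NULL` to skip.
#' @param out_dir Optional directory; all tables are written there as CSV
#'   together with the configuration (including the seed).
#' @param verbose Per-track status lines.
#' @return List with `metrics`, `status`, `groups`, `vs_rel`, `fits`,
#'   `correlations`, `cor_vs_shift`, `aligned_position`, `aligned_intensity`,
#'   `orientation`, and (for synthetic runs) `truth`.
#' @export
run_pipeline <- function(tracks = NULL, synthetic = NULL, k_m = 0.16,
                         n_groups = 7, fit_models = c("end_density",
                                                      "total_number"),
                         shifts = NULL, out_dir = NULL, verbose = FALSE) {
  truth <- NULL
  if (is.null(tracks)) {
    if (is.null(synthetic))
      stop_invalid("supply tracks or a synthetic_config")
    coh <- generate_cohort(synthetic)
    tracks <- coh$tracks; truth <- coh$truth
  }
  if (n_groups > length(tracks) / 2)
    stop_invalid("n_groups (", n_groups, ") exceeds n_tracks/2 (",
                 length(tracks) / 2, ")")
  metrics <- analyze_cohort(tracks, verbose = verbose)
  status <- attr(metrics, "status")
  has_gfp <- any(is.finite(metrics$I_wo))

  groups <- speed_sort(metrics, n_groups)
  vs_rel <- tryCatch(vs_vg_relation(metrics), error = function(e) NULL)
  vs_model <- if (!is.null(vs_rel)) list(a = vs_rel$a, b = vs_rel$b)
    else mean(metrics$v_s, na.rm = TRUE)
  fits <- lapply(fit_models, function(m)
    tryCatch(fit_threshold(groups, k_m = k_m, vs_model = vs_model, model = m),
             error = function(e) e))
  names(fits) <- fit_models

  correlations <- list(
    vg_delay = spearman_cor(metrics$v_g, metrics$delay),
    vg_Lshrink = tryCatch(spearman_cor(metrics$v_g, metrics$L_shrink_meas),
                          error = function(e) NULL))
  if (has_gfp)
    correlations$Iwo_delay <- spearman_cor(metrics$I_wo, metrics$delay)

  cor_vs_shift <- if (!is.null(shifts)) {
    cvs <- correlation_vs_shift(tracks, metrics, "growth_speed", shifts)
    if (has_gfp)
      cvs <- rbind(cvs,
                   correlation_vs_shift(tracks, metrics, "gfp_intensity",
                                        shifts))
    cvs
  }

  aligned_position <- tryCatch(
    align_and_average(tracks, metrics, "position"), error = function(e) NULL)
  aligned_intensity <- if (has_gfp) tryCatch(
    align_and_average(tracks, metrics, "gfp_end"), error = function(e) NULL)
  orientation <- orientation_analysis(tracks, metrics)

  out <- list(metrics = metrics, status = status, groups = groups,
              vs_rel = vs_rel, fits = fits, correlations = correlations,
              cor_vs_shift = cor_vs_shift,
              aligned_position = aligned_position,
              aligned_intensity = aligned_intensity,
              orientation = orientation, truth = truth, k_m = k_m)
  if (!is.null(out_dir)) write_pipeline_results(out, out_dir, synthetic)
  invisible(out)
}

write_pipeline_results <- function(results, out_dir, synthetic = NULL) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  wcsv <- function(df, name)
    utils::write.csv(df, file.path(out_dir, name), row.names = FALSE)
  wcsv(results$metrics, "metrics.csv")
  wcsv(results$status, "track_status.csv")
  wcsv(as.data.frame(results$groups), "speed_groups.csv")
  if (!is.null(results$cor_vs_shift)) wcsv(results$cor_vs_shift,
                                           "correlation_vs_shift.csv")
  if (!is.null(results$truth)) wcsv(results$truth, "truth.csv")
  lines <- c(sprintf("k_m = %g", results$k_m))
  if (!is.null(results$vs_rel))
    lines <- c(lines, sprintf("vs_relation: v_s = %.4g * v_g + %.4g",
                              results$vs_rel$a, results$vs_rel$b))
  for (nm in names(results$fits)) {
    f <- results$fits[[nm]]
    lines <- c(lines, if (inherits(f, "error"))
      sprintf("fit %s: FAILED (%s)", nm, conditionMessage(f))
      else sprintf("fit %s: %s = %.5g +/- %.3g, chi2_red = %.4g",
                   nm, names(f$par), f$par, f$se, f$chi2_red))
  }
  for (nm in names(results$correlations)) {
    cr <- results$correlations[[nm]]
    if (!is.null(cr))
      lines <- c(lines, sprintf("spearman %s: rho = %.4g, p = %.3g, n = %d",
                                nm, cr$rho, cr$p, cr$n))
  }
  writeLines(lines, file.path(out_dir, "fit_report.txt"))
  if (!is.null(synthetic)) {
    cfg <- synthetic[!vapply(synthetic, is.null, logical(1))]
    flat <- vapply(names(cfg), function(nm) {
      v <- cfg[[nm]]
      if (inherits(v, "threshold_spec"))
        v <- paste0(v$model, ":", paste(unlist(v[-1]), collapse = ","))
      paste0(nm, " = ", paste(format(v), collapse = " "))
    }, character(1))
    writeLines(flat, file.path(out_dir, "config.txt"))
  }
  invisible(out_dir)
}
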