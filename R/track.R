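#' One microtubule's multichannel time series
#'
#' A validated container for one tracked microtubule: uniformly sampled time
#' (default 4 Hz), plus-end position along the growth axis, optional EB-GFP
#' intensity at the end and 1.5 um behind it on the lattice, the
#' soluble-tubulin background used to detect washout, and an optional
#' end-region orientation.
#'
#' @param time Sampled instants (s); strictly increasing, uniform within 1%.
#' @param end_pos Plus-end position (nm); same length as `time`.
#' @param background Soluble-tubulin background intensity (a.u.).
#' @param gfp_end Optional EB-GFP intensity at the end (a.u.).
#' @param gfp_lattice Optional EB-GFP lattice intensity (a.u.).
#' @param orientation Optional end-region orientation (deg).
#' @param id Track label.
#' @return An object of class `mt_track`.
#' @export
mt_track <- function(time, end_pos, background, gfp_end = NULL,
                     gfp_lattice = NULL, orientation = NULL, id = "track") {
  check_vector(time, "time")
  check_vector(end_pos, "end_pos")
  check_vector(background, "background")
  n <- length(time)
  if (n < 2L) stop_invalid("a track needs at least 2 samples")
  dt <- diff(time)
  if (any(dt <= 0)) stop_invalid("time must be strictly increasing")
  if ((max(dt) - min(dt)) > 0.01 * mean(dt))
    stop_invalid("time must be uniformly sampled within 1%")
  chk_len <- function(x, name) {
    if (!is.null(x)) {
      check_vector(x, name)
      if (length(x) != n) stop_invalid(name, " must have length ", n)
    }
    x
  }
  chk_len(end_pos, "end_pos"); chk_len(background, "background")
  structure(
    list(time = as.numeric(time), end_pos = as.numeric(end_pos),
         background = as.numeric(background),
         gfp_end = chk_len(gfp_end, "gfp_end"),
         gfp_lattice = chk_len(gfp_lattice, "gfp_lattice"),
         orientation = chk_len(orientation, "orientation"),
         id = as.character(id)),
    class = "mt_track")
}

#' @export
print.mt_track <- function(x, ...) {
  cat(sprintf("Microtubule track '%s': %d samples at %.3g Hz, %.4g-%.4g s\n",
              x$id, length(x$time), 1 / mean(diff(x$time)),
              min(x$time), max(x$time)))
  opt <- c("gfp_end", "gfp_lattice", "orientation")
  have <- opt[!vapply(x[opt], is.null, logical(1))]
  cat("  optional channels:", if (length(have)) paste(have, collapse = ", ")
      else "none", "\n")
  invisible(x)
}

track_columns <- c("time_s", "end_pos_nm", "gfp_end", "gfp_lattice",
                   "background", "orientation_deg")

#' Read and write microtubule track tables
#'
#' Track tables are delimited text with header columns
#' `time_s,end_pos_nm,gfp_end,gfp_lattice,background,orientation_deg`;
#' the optional channels (`gfp_end`, `gfp_lattice`, `orientation_deg`) may be
#' absent. `read_tracks()` accepts a single file or a directory of files
#' (one per microtubule) and returns a list of [mt_track()] objects;
#' `write_tracks()` writes one file per track into `dir`.
#'
#' @param path A track file or a directory containing `*.csv`/`*.tsv` files.
#' @param sep Field separator; inferred from the extension by default.
#' @return `read_tracks()`: a named list of `mt_track` objects.
#' @export
read_tracks <- function(path, sep = NULL) {
  files <- if (dir.exists(path))
    list.files(path, pattern = "\\.(csv|tsv|txt)$", full.names = TRUE)
  else path
  if (length(files) == 0L) stop_invalid("no track files found under ", path)
  out <- lapply(files, read_one_track, sep = sep)
  names(out) <- vapply(out, function(tr) tr$id, character(1))
  out
}

read_one_track <- function(file, sep = NULL) {
  if (is.null(sep))
    sep <- if (grepl("\\.tsv$", file)) "\t" else ","
  df <- utils::read.table(file, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE)
  required <- c("time_s", "end_pos_nm", "background")
  missing <- setdiff(required, names(df))
  if (length(missing))
    stop_invalid("track file ", file, " lacks required column(s): ",
                 paste(missing, collapse = ", "))
  bad <- which(!stats::complete.cases(df[required]))
  if (length(bad))
    stop_invalid("track file ", file, " has non-finite required values at line(s) ",
                 paste(utils::head(bad + 1L, 5), collapse = ", "))
  grab <- function(col) if (col %in% names(df)) df[[col]] else NULL
  mt_track(time = df$time_s, end_pos = df$end_pos_nm,
           background = df$background, gfp_end = grab("gfp_end"),
           gfp_lattice = grab("gfp_lattice"),
           orientation = grab("orientation_deg"),
           id = sub("\\.[a-z]+$", "", basename(file)))
}

#' @rdname read_tracks
#' @param tracks List of `mt_track` objects.
#' @param dir Output directory (created if needed).
#' @export
write_tracks <- function(tracks, dir, sep = ",") {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  for (tr in tracks) {
    df <- data.frame(time_s = tr$time, end_pos_nm = tr$end_pos)
    if (!is.null(tr$gfp_end)) df$gfp_end <- tr$gfp_end
    if (!is.null(tr$gfp_lattice)) df$gfp_lattice <- tr$gfp_lattice
    df$background <- tr$background
    if (!is.null(tr$orientation)) df$orientation_deg <- tr$orientation
    utils::write.table(df, file.path(dir, paste0(tr$id, ".csv")),
                       sep = sep, row.names = FALSE, quote = FALSE)
  }
  invisible(file.path(dir, paste0(vapply(tracks, `[[`, "", "id"), ".csv")))
}
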