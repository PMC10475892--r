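# Delimited-matrix formats: every file starts with a single header line
# "#" + one-line JSON carrying the metadata (fs, labels, alignment), followed
# by a plain CSV numeric matrix written at full double precision, so each
# writer/reader pair round-trips losslessly.

write_header_csv <- function(mat, header, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("#", jsonlite::toJSON(header, auto_unbox = TRUE, digits = NA)),
             con)
  utils::write.table(format(mat, digits = 17, trim = TRUE, scientific = TRUE),
                     con, sep = ",", row.names = FALSE, col.names = FALSE,
                     quote = FALSE)
}

read_header_csv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  first <- readLines(path, n = 1L)
  if (!startsWith(first, "#"))
    stop("missing JSON header line in ", path)
  header <- jsonlite::fromJSON(substring(first, 2L))
  mat <- as.matrix(utils::read.table(path, sep = ",", skip = 1L,
                                     colClasses = "numeric"))
  dimnames(mat) <- NULL
  list(header = header, mat = mat)
}

#' Write / read a multichannel beat series
#'
#' CSV with one column per channel (rows = time) and a one-line JSON header
#' (`#{"fs": ..., "channel_labels": [...]}`). The EDF format is not
#' supported by this implementation; requesting it raises an informative
#' error.
#'
#' @param series A [beat_series()].
#' @param path Output/input file path.
#' @param format `"csv"`.
#' @return `read_series()` returns a [beat_series()]; `write_series()` the
#'   path, invisibly.
#' @export
write_series <- function(series, path, format = "csv") {
  if (!identical(format, "csv")) stop("unsupported format: ", format)
  stopifnot(inherits(series, "beat_series"))
  write_header_csv(t(series$samples),
                   list(fs = series$fs, channel_labels = series$channel_labels),
                   path)
  invisible(path)
}

#' @rdname write_series
#' @export
read_series <- function(path, format = "csv") {
  if (!identical(format, "csv")) stop("unsupported format: ", format)
  r <- read_header_csv(path)
  if (is.null(r$header$fs)) stop("header missing required key 'fs' in ", path)
  beat_series(t(r$mat), as.numeric(r$header$fs), r$header$channel_labels)
}

#' Write / read an epoch stack
#'
#' CSV matrix (rows = beats) with a JSON header carrying `fs`,
#' `qrs_onset_idx`, and `beat_indices`.
#'
#' @param stack An [epoch_stack()].
#' @param path File path.
#' @return `read_epoch_stack()` returns an [epoch_stack()].
#' @export
write_epoch_stack <- function(stack, path) {
  stopifnot(inherits(stack, "epoch_stack"))
  write_header_csv(stack$epochs,
                   list(fs = stack$fs, qrs_onset_idx = stack$qrs_onset_idx,
                        beat_indices = stack$beat_indices),
                   path)
  invisible(path)
}

#' @rdname write_epoch_stack
#' @export
read_epoch_stack <- function(path) {
  r <- read_header_csv(path)
  h <- r$header
  if (is.null(h$fs)) stop("header missing required key 'fs' in ", path)
  epoch_stack(r$mat, as.numeric(h$fs), qrs_onset_idx = h$qrs_onset_idx,
              beat_indices = h$beat_indices)
}

#' Serialize / restore a threshold specification
#'
#' JSON with the wavelet name, levels, epoch geometry, per-level thresholds,
#' preserved-coefficient indices, zeroed levels, and preserve intervals in
#' ms, so the identical stored "threshold function" can be re-applied to any
#' epoch of the recording.
#'
#' @param spec A [build_threshold_spec()] result.
#' @param path File path.
#' @return `read_threshold_spec()` returns a `threshold_spec`.
#' @export
write_threshold_spec <- function(spec, path) {
  stopifnot(inherits(spec, "threshold_spec"))
  obj <- list(wavelet = spec$wavelet, levels = spec$levels,
              n = spec$n, fs = spec$fs,
              level_thresholds = ifelse(is.finite(spec$level_thresholds),
                                        spec$level_thresholds, -1),
              preserved_indices = lapply(spec$preserve_masks, which),
              mask_lengths = vapply(spec$preserve_masks, length, 0L),
              zeroed_levels = spec$zeroed_levels,
              preserve_intervals_ms = spec$preserve_intervals_ms,
              margin_sd = spec$margin_sd)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_threshold_spec
#' @export
read_threshold_spec <- function(path) {
  o <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  thr <- as.numeric(o$level_thresholds)
  thr[thr < 0] <- Inf
  masks <- lapply(seq_len(o$levels), function(j) {
    m <- rep(FALSE, o$mask_lengths[j])
    idx <- if (is.list(o$preserved_indices)) o$preserved_indices[[j]] else o$preserved_indices[j, ]
    m[as.integer(idx)] <- TRUE
    m
  })
  iv <- o$preserve_intervals_ms
  if (is.matrix(iv)) iv <- lapply(seq_len(nrow(iv)), function(i) iv[i, ])
  if (!is.list(iv)) iv <- list(as.numeric(iv))
  structure(list(wavelet = o$wavelet, levels = as.integer(o$levels),
                 n = as.integer(o$n), fs = o$fs,
                 level_thresholds = thr, preserve_masks = masks,
                 zeroed_levels = as.integer(o$zeroed_levels),
                 preserve_intervals_ms = iv,
                 margin_sd = o$margin_sd),
            class = "threshold_spec")
}

#' Write / read simulator ground truth as a JSON sidecar
#'
#' @param gt A simulator `ground_truth`.
#' @param path File path.
#' @param config The generating [sim_config()] (recorded for provenance,
#'   including the seed).
#' @return `read_ground_truth()` returns the `ground_truth` (with `config`
#'   attached when present).
#' @export
write_ground_truth <- function(gt, path, config = NULL) {
  obj <- list(hbs_onset_idx = gt$hbs_onset_idx, hv_ms = gt$hv_ms,
              fs = gt$clean_hbs$fs,
              clean_hbs = gt$clean_hbs$samples,
              clean_atrial = gt$clean_atrial$samples)
  if (!is.null(config)) obj$config <- unclass(config)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_ground_truth
#' @export
read_ground_truth <- function(path) {
  o <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  gt <- list(hbs_onset_idx = as.integer(o$hbs_onset_idx),
             hv_ms = as.numeric(o$hv_ms),
             clean_hbs = sampled_trace(o$clean_hbs, as.numeric(o$fs)),
             clean_atrial = sampled_trace(o$clean_atrial, as.numeric(o$fs)))
  class(gt) <- "ground_truth"
  if (!is.null(o$config)) attr(gt, "config") <- o$config
  gt
}

#' Inter-beat contour matrix
#'
#' Arranges a segment of extracted epochs as a beats-by-time matrix for
#' heatmap display: each row is one beat verbatim (no smoothing across
#' beats), the time axis is in ms relative to the QRS onset (negative before
#' it, 0 at the onset sample). The default segment is the first ~25 beats,
#' the length used for display.
#'
#' @param stack An `hbs_stack` (or any [epoch_stack()]).
#' @param segment Integer vector of beat row indices, within `[1, m]`;
#'   `NULL` for the first `min(25, m)` beats.
#' @return An object of class `contour_matrix` with `values`, `beat_axis`,
#'   `time_axis`.
#' @export
interbeat_contour <- function(stack, segment = NULL) {
  stopifnot(inherits(stack, "epoch_stack"))
  m <- nrow(stack$epochs)
  if (is.null(segment)) segment <- seq_len(min(25L, m))
  segment <- as.integer(segment)
  if (length(segment) == 0L) stop("interbeat_contour: empty segment")
  if (any(segment < 1L | segment > m)) stop("interbeat_contour: segment out of range")
  time_axis <- (seq_len(ncol(stack$epochs)) - stack$qrs_onset_idx) /
    stack$fs * 1000
  structure(list(values = stack$epochs[segment, , drop = FALSE],
                 beat_axis = stack$beat_indices[segment],
                 time_axis = time_axis),
            class = "contour_matrix")
}

#' @export
print.contour_matrix <- function(x, ...) {
  cat(sprintf("<contour_matrix> %d beat(s) x %d samples, time %g..%g ms\n",
              nrow(x$values), ncol(x$values),
              min(x$time_axis), max(x$time_axis)))
  invisible(x)
}

#' Write a contour matrix as CSV
#'
#' Header row holds the time axis (ms relative to QRS onset); the first
#' column the beat ordinals.
#'
#' @param cm A [interbeat_contour()] result.
#' @param path File path.
#' @export
write_contour <- function(cm, path) {
  stopifnot(inherits(cm, "contour_matrix"))
  df <- data.frame(beat = cm$beat_axis, cm$values)
  names(df) <- c("beat", sprintf("t%g", cm$time_axis))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
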