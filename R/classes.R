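#' Uniformly sampled single-channel trace
#'
#' Lightweight container for one channel's amplitude series together with its
#' sampling rate. All stage outputs that are a single waveform (averaged PR
#' trace, clean reference His deflection, extracted single-beat trace) are
#' `sampled_trace` objects.
#'
#' @param samples Numeric vector of amplitudes (arbitrary units).
#' @param fs Sampling rate in Hz (single positive number).
#' @return An object of class `sampled_trace` with fields `samples` and `fs`.
#' @export
sampled_trace <- function(samples, fs) {
  samples <- as.numeric(samples)
  stopifnot(is.numeric(fs), length(fs) == 1L, fs > 0)
  if (any(!is.finite(samples))) stop("sampled_trace: non-finite samples")
  structure(list(samples = samples, fs = fs), class = "sampled_trace")
}

#' @export
print.sampled_trace <- function(x, ...) {
  cat(sprintf("<sampled_trace> %d samples @ %g Hz (%.1f ms)\n",
              length(x$samples), x$fs, 1000 * length(x$samples) / x$fs))
  invisible(x)
}

#' @export
length.sampled_trace <- function(x) length(x$samples)

as_samples <- function(x) {
  if (inherits(x, "sampled_trace")) x$samples else as.numeric(x)
}

#' Multichannel beat series
#'
#' A continuous channels-by-time amplitude matrix with a common sampling rate,
#' the ingest form of a raw MCG/BSPM recording.
#'
#' @param samples Numeric matrix, channels x time.
#' @param fs Sampling rate in Hz.
#' @param channel_labels Character vector, one label per channel.
#' @return An object of class `beat_series`.
#' @export
beat_series <- function(samples, fs, channel_labels = NULL) {
  samples <- as.matrix(samples)
  storage.mode(samples) <- "double"
  stopifnot(is.numeric(fs), length(fs) == 1L, fs > 0)
  if (any(!is.finite(samples))) {
    bad <- which(!is.finite(samples), arr.ind = TRUE)[1L, ]
    stop(sprintf("beat_series: non-finite sample at channel %d, sample %d",
                 bad[1L], bad[2L]))
  }
  if (is.null(channel_labels)) channel_labels <- paste0("ch", seq_len(nrow(samples)))
  stopifnot(length(channel_labels) == nrow(samples))
  structure(list(samples = samples, fs = fs,
                 channel_labels = as.character(channel_labels)),
            class = "beat_series")
}

#' @export
print.beat_series <- function(x, ...) {
  cat(sprintf("<beat_series> %d channel(s) x %d samples @ %g Hz (%.1f s)\n",
              nrow(x$samples), ncol(x$samples), x$fs,
              ncol(x$samples) / x$fs))
  invisible(x)
}

#' Stack of QRS-onset-aligned PR-interval epochs
#'
#' Rows are beats; every row is aligned so that the QRS onset falls on the
#' same sample index (`qrs_onset_idx`, by construction the final sample of
#' each row). This alignment is the stack's defining property: it is what
#' makes signal averaging and beat-by-beat comparison meaningful.
#'
#' @param epochs Numeric matrix, beats x time.
#' @param fs Sampling rate in Hz.
#' @param qrs_onset_idx 1-based sample index of the QRS onset within each row;
#'   defaults to the last column.
#' @param beat_indices Original beat ordinals for the rows.
#' @return An object of class `epoch_stack`.
#' @export
epoch_stack <- function(epochs, fs, qrs_onset_idx = ncol(epochs),
                        beat_indices = seq_len(nrow(epochs))) {
  epochs <- as.matrix(epochs)
  storage.mode(epochs) <- "double"
  stopifnot(nrow(epochs) >= 1L,
            is.numeric(fs), length(fs) == 1L, fs > 0,
            length(qrs_onset_idx) == 1L,
            qrs_onset_idx >= 1L, qrs_onset_idx <= ncol(epochs),
            length(beat_indices) == nrow(epochs))
  if (any(!is.finite(epochs))) stop("epoch_stack: non-finite samples")
  structure(list(epochs = epochs, fs = fs,
                 qrs_onset_idx = as.integer(qrs_onset_idx),
                 beat_indices = as.integer(beat_indices)),
            class = "epoch_stack")
}

#' @export
print.epoch_stack <- function(x, ...) {
  cat(sprintf("<epoch_stack> %d beat(s) x %d samples @ %g Hz, QRS onset at sample %d\n",
              nrow(x$epochs), ncol(x$epochs), x$fs, x$qrs_onset_idx))
  invisible(x)
}

#' Template annotation of the signal-averaged PR trace
#'
#' Records the manual markers placed on the averaged trace: T1 and T2 flank
#' the candidate His bump, `preserve_intervals` are the time windows whose
#' wavelet detail coefficients the interval-dependent thresholding leaves
#' untouched, and `hbs_onset_ms` is the chosen onset of the deflection. The
#' HV interval of the template is derived as the distance from T1 to the QRS
#' onset (the end of the trace).
#'
#' @param avg_trace `sampled_trace`, the signal-averaged PR epoch.
#' @param t1_ms,t2_ms Manual markers (ms from epoch start) before/after the bump.
#' @param preserve_intervals List of `c(start, end)` windows in ms kept by the
#'   thresholding, disjoint and ordered.
#' @param hbs_onset_ms Chosen onset of the His deflection (ms from epoch start).
#' @return An object of class `template_annotation`.
#' @export
template_annotation <- function(avg_trace, t1_ms, t2_ms, preserve_intervals,
                                hbs_onset_ms) {
  stopifnot(inherits(avg_trace, "sampled_trace"))
  t_end <- 1000 * (length(avg_trace$samples) - 1L) / avg_trace$fs
  if (!(t1_ms < hbs_onset_ms && hbs_onset_ms < t2_ms && t2_ms <= t_end))
    stop("template_annotation: need t1_ms < hbs_onset_ms < t2_ms <= QRS-onset time")
  iv <- lapply(preserve_intervals, function(p) {
    stopifnot(length(p) == 2L, p[1] < p[2])
    as.numeric(p)
  })
  if (length(iv) < 1L) stop("template_annotation: at least one preserve interval required")
  starts <- vapply(iv, `[`, 0, 1L); ends <- vapply(iv, `[`, 0, 2L)
  o <- order(starts); iv <- iv[o]; starts <- starts[o]; ends <- ends[o]
  if (any(starts < 0) || any(ends > 1000 * length(avg_trace$samples) / avg_trace$fs))
    stop("template_annotation: preserve interval outside the epoch")
  if (length(iv) > 1L && any(starts[-1L] < ends[-length(iv)]))
    stop("template_annotation: preserve intervals overlap")
  covered <- any(starts <= hbs_onset_ms & ends >= hbs_onset_ms)
  if (!covered) stop("template_annotation: no preserve interval contains hbs_onset_ms")
  structure(list(avg_trace = avg_trace, t1_ms = t1_ms, t2_ms = t2_ms,
                 preserve_intervals = iv, hbs_onset_ms = hbs_onset_ms,
                 hv_ms = t_end - t1_ms),
            class = "template_annotation")
}

#' @export
print.template_annotation <- function(x, ...) {
  cat(sprintf("<template_annotation> T1 = %g ms, T2 = %g ms, HBS onset = %g ms, HV = %g ms\n",
              x$t1_ms, x$t2_ms, x$hbs_onset_ms, x$hv_ms))
  cat(sprintf("  %d preserve interval(s): %s\n", length(x$preserve_intervals),
              paste(vapply(x$preserve_intervals,
                           function(p) sprintf("[%g, %g)", p[1], p[2]), ""),
                    collapse = ", ")))
  invisible(x)
}
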