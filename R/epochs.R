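#' Detect QRS onsets in a continuous series
#'
#' Band-passes the chosen channel to the QRS band (5-40 Hz), forms a
#' smoothed squared-derivative envelope, thresholds it at a configurable
#' fraction of a rolling (2 s block) maximum, enforces a refractory spacing,
#' and backtracks from each detection to the last sub-threshold envelope
#' sample, reported as the QRS onset. Any detector recovering simulated
#' onsets within +/-5 ms would serve; this one is deliberately simple.
#'
#' @param series A [beat_series()] at least 2 s long, `fs >= 250` Hz.
#' @param channel Channel index or label.
#' @param threshold_frac Fraction of the rolling envelope maximum used as
#'   detection threshold.
#' @param refractory_ms Minimum spacing between detected beats, ms.
#' @param onset_frac Fraction of the beat's peak envelope whose crossing on
#'   the steep rising edge is reported as the onset (the envelope rises
#'   through ~30-40% of its peak at the QRS onset; a crossing on the steep
#'   edge is insensitive to morphology and noise).
#' @return Strictly increasing integer vector of onset sample indices.
#' @export
detect_qrs_onsets <- function(series, channel = 1L, threshold_frac = 0.3,
                              refractory_ms = 200, onset_frac = 0.3) {
  stopifnot(inherits(series, "beat_series"))
  fs <- series$fs
  if (fs < 250) stop("detect_qrs_onsets: fs must be >= 250 Hz")
  if (ncol(series$samples) / fs < 2) stop("detect_qrs_onsets: series shorter than 2 s")
  if (is.character(channel)) channel <- match(channel, series$channel_labels)
  x <- series$samples[channel, ]
  bf <- signal::butter(2, c(5, 40) / (fs / 2), type = "pass")
  xb <- signal::filtfilt(bf, x)
  env <- c(0, diff(xb))^2
  k <- max(3L, round(0.02 * fs))           # 20 ms moving-average smoothing
  env <- stats::filter(env, rep(1 / k, k), sides = 2)
  env[is.na(env)] <- 0
  env <- as.numeric(env)
  # rolling maximum over 2 s blocks (step threshold)
  block <- max(1L, round(2 * fs))
  nblk <- ceiling(length(env) / block)
  thr <- numeric(length(env))
  for (b in seq_len(nblk)) {
    i0 <- (b - 1L) * block + 1L
    i1 <- min(b * block, length(env))
    lo <- max(1L, i0 - block); hi <- min(length(env), i1 + block)
    thr[i0:i1] <- threshold_frac * max(env[lo:hi])
  }
  above <- env > thr & env > 0
  if (!any(above)) stop("no beats detected")
  runs <- rle(above)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  cand_start <- starts[runs$values]
  cand_end <- ends[runs$values]
  refr <- round(refractory_ms / 1000 * fs)
  onsets <- integer(0)
  last_peak <- -Inf
  for (r in seq_along(cand_start)) {
    seg <- cand_start[r]:cand_end[r]
    pk <- seg[which.max(env[seg])]
    if (pk - last_peak < refr) next
    last_peak <- pk
    # backtrack from the peak to the onset_frac crossing on the rising edge
    floor_lvl <- onset_frac * env[pk]
    i <- pk
    while (i > 1L && env[i - 1L] > floor_lvl) i <- i - 1L
    onsets <- c(onsets, i)
  }
  if (length(onsets) == 0L) stop("no beats detected")
  sort(unique(onsets))
}

#' Extract QRS-onset-aligned PR epochs
#'
#' Cuts, for each onset, the `pre_window_ms` window ending at the onset
#' sample (inclusive: the QRS onset is the final sample of each row). Beats
#' whose window would cross the start of the series are dropped and reported
#' via a warning and the `dropped` attribute.
#'
#' @param series A [beat_series()].
#' @param onsets Integer onset sample indices (e.g. from
#'   [detect_qrs_onsets()]).
#' @param channel Channel index or label.
#' @param pre_window_ms Epoch length, ms.
#' @return An [epoch_stack()]; `beat_indices` hold the ordinals of the kept
#'   beats.
#' @export
extract_pr_epochs <- function(series, onsets, channel = 1L, pre_window_ms = 350) {
  stopifnot(inherits(series, "beat_series"), length(onsets) >= 1L)
  if (is.character(channel)) channel <- match(channel, series$channel_labels)
  fs <- series$fs
  T_ <- as.integer(round(pre_window_ms * fs / 1000))
  keep <- which(onsets - T_ + 1L >= 1L & onsets <= ncol(series$samples))
  if (length(keep) < length(onsets))
    warning(sprintf("extract_pr_epochs: dropped %d beat(s) whose window crosses the series bounds",
                    length(onsets) - length(keep)))
  if (length(keep) == 0L) stop("extract_pr_epochs: no epochs remain")
  x <- series$samples[channel, ]
  ep <- t(vapply(onsets[keep],
                 function(o) x[(o - T_ + 1L):o], numeric(T_)))
  out <- epoch_stack(ep, fs, qrs_onset_idx = T_, beat_indices = keep)
  attr(out, "dropped") <- setdiff(seq_along(onsets), keep)
  out
}

#' Signal-average an epoch stack
#'
#' Element-wise mean across beats; trigger-locked averaging attenuates
#' uncorrelated noise by `sqrt(m)` and yields the representative PR trace
#' used as the thresholding template.
#'
#' @param stack An [epoch_stack()].
#' @return A [sampled_trace()].
#' @export
signal_average <- function(stack) {
  stopifnot(inherits(stack, "epoch_stack"))
  sampled_trace(colMeans(stack$epochs), stack$fs)
}

#' Partition an epoch stack into consecutive analysis bins
#'
#' Non-overlapping bins of `bin_size` beats in beat order (as used to track
#' the His deflection through a stress recording); a trailing partial bin is
#' dropped with a warning.
#'
#' @param stack An [epoch_stack()].
#' @param bin_size Beats per bin (default 30).
#' @return List of [epoch_stack()]s.
#' @export
bin_epochs <- function(stack, bin_size = 30L) {
  stopifnot(inherits(stack, "epoch_stack"))
  if (bin_size < 1L) stop("bin_epochs: bin_size must be >= 1")
  m <- nrow(stack$epochs)
  nb <- m %/% bin_size
  if (nb * bin_size < m)
    warning(sprintf("bin_epochs: dropped trailing %d beat(s)", m - nb * bin_size))
  lapply(seq_len(nb), function(b) {
    rows <- ((b - 1L) * bin_size + 1L):(b * bin_size)
    epoch_stack(stack$epochs[rows, , drop = FALSE], stack$fs,
                qrs_onset_idx = stack$qrs_onset_idx,
                beat_indices = stack$beat_indices[rows])
  })
}

#' Per-beat heart-rate series from QRS onsets
#'
#' @param onsets Integer onset sample indices, strictly increasing, >= 2.
#' @param fs Sampling rate, Hz.
#' @return Numeric vector of beats per minute, one per RR interval.
#' @export
heart_rate_series <- function(onsets, fs) {
  if (length(onsets) < 2L) stop("heart_rate_series: need at least 2 onsets")
  60 * fs / diff(as.numeric(onsets))
}

# slope (amplitude units per ms) and its standard error for a least-squares
# line over a time window
.fit_slope <- function(x, fs, from_ms, to_ms) {
  i0 <- max(1L, as.integer(round(from_ms * fs / 1000)) + 1L)
  i1 <- min(length(x), as.integer(round(to_ms * fs / 1000)) + 1L)
  if (i1 - i0 < 2L) return(c(slope = NA_real_, se = NA_real_))
  t_ms <- (seq.int(i0, i1) - 1) / fs * 1000
  fit <- summary(stats::lm(x[i0:i1] ~ t_ms))$coefficients
  c(slope = fit[2L, 1L], se = fit[2L, 2L])
}

#' Objective criteria for identifying a His bump on averaged traces
#'
#' Evaluates, on per-channel signal-averaged PR traces with their template
#' annotations, the four identification criteria: (1) the chosen bump's
#' peak-to-peak amplitude exceeds `k` times the RMS of the pre-P noise
#' window, where no cardiac activity is expected; (2) the bump's onset lies
#' after the P-wave offset in every channel; (3) the bump is flanked by
#' ramp-like signals on both sides (the fitted slope differs from zero by
#' more than three of its standard errors); (4) the ramp slope at
#' T2 changes polarity across measurement channels. Criterion 4 needs at
#' least two channels and is reported as `NA` ("not evaluable") otherwise.
#'
#' @param templates List of [template_annotation()], one per channel.
#' @param noise_window_ms `c(start, end)` ms window before the P wave used as
#'   the noise floor.
#' @param k Noise-floor multiple for criterion 1.
#' @param ramp_window_ms Window length (ms) used for the slope fits of
#'   criteria 3 and 4.
#' @return A list with logical `criterion1..criterion4` (`criterion4` may be
#'   `NA`), `all_pass`, and the per-channel diagnostics.
#' @export
check_hbs_criteria <- function(templates, noise_window_ms = c(0, 40), k = 2,
                               ramp_window_ms = 15) {
  stopifnot(length(templates) >= 1L)
  lapply(templates, function(tp) stopifnot(inherits(tp, "template_annotation")))
  per <- lapply(templates, function(tp) {
    x <- tp$avg_trace$samples; fs <- tp$avg_trace$fs
    i0 <- as.integer(round(noise_window_ms[1] * fs / 1000)) + 1L
    i1 <- as.integer(round(noise_window_ms[2] * fs / 1000))
    noise_rms <- sqrt(mean(x[i0:i1]^2))
    b0 <- as.integer(round(tp$t1_ms * fs / 1000)) + 1L
    b1 <- as.integer(round(tp$t2_ms * fs / 1000))
    bump_pp <- diff(range(x[b0:b1]))
    # P-wave offset: where the trace first falls below 10% of the P peak
    # after the peak (P assumed the dominant early deflection)
    half <- seq_len(max(b0 - 1L, 2L))
    pk <- which.max(abs(x[half]))
    off <- pk
    while (off < length(x) && abs(x[off]) > 0.1 * abs(x[pk])) off <- off + 1L
    p_offset_ms <- (off - 1) / fs * 1000
    pre_slope <- .fit_slope(x, fs, tp$t1_ms - ramp_window_ms, tp$t1_ms)
    post_slope <- .fit_slope(x, fs, tp$t2_ms, tp$t2_ms + ramp_window_ms)
    list(noise_rms = noise_rms, bump_pp = bump_pp, p_offset_ms = p_offset_ms,
         pre_slope = pre_slope, post_slope = post_slope)
  })
  noise_rms <- vapply(per, `[[`, 0, "noise_rms")
  bump_pp <- vapply(per, `[[`, 0, "bump_pp")
  onset_ms <- vapply(templates, `[[`, 0, "hbs_onset_ms")
  p_off <- vapply(per, `[[`, 0, "p_offset_ms")
  pre_s <- vapply(per, function(p) p$pre_slope[["slope"]], 0)
  pre_se <- vapply(per, function(p) p$pre_slope[["se"]], 0)
  post_s <- vapply(per, function(p) p$post_slope[["slope"]], 0)
  post_se <- vapply(per, function(p) p$post_slope[["se"]], 0)
  c1 <- all(bump_pp > k * noise_rms)
  c2 <- all(onset_ms > p_off)
  c3 <- all(abs(pre_s) > 3 * pre_se & abs(post_s) > 3 * post_se)
  c4 <- if (length(templates) >= 2L) {
    sgn <- sign(post_s)
    any(sgn == 1) && any(sgn == -1)
  } else NA
  list(criterion1 = c1, criterion2 = c2, criterion3 = c3, criterion4 = c4,
       all_pass = isTRUE(c1) && isTRUE(c2) && isTRUE(c3) &&
         (is.na(c4) || isTRUE(c4)),
       channels = per)
}
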