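#' Peak-referenced signal-to-noise ratio
#'
#' `20 log10(|x[signal_idx]| / RMS(x[noise_window]))`: the signal magnitude
#' is read at a single sample (the P-wave peak, or the extracted His peak)
#' and the noise floor is the RMS of a window before the P-wave onset, where
#' no cardiac activity is expected.
#'
#' @param trace A [sampled_trace()] or numeric vector.
#' @param signal_idx 1-based index of the signal peak.
#' @param noise_window Integer indices of the noise window (disjoint from
#'   `signal_idx`).
#' @return SNR in dB.
#' @export
snr_db <- function(trace, signal_idx, noise_window) {
  x <- as_samples(trace)
  stopifnot(length(noise_window) >= 1L, !(signal_idx %in% noise_window))
  rms <- sqrt(mean(x[noise_window]^2))
  if (rms == 0) stop("noise floor undefined: zero RMS in the noise window")
  20 * log10(abs(x[signal_idx]) / rms)
}

#' Welch-averaged power spectral density
#'
#' Hann-windowed, 50%-overlapped averaged periodogram; the band-power
#' backend of [ser()]. One-sided density; `sum(psd) * df` recovers the
#' signal's mean square power.
#'
#' @param x Numeric vector or [sampled_trace()].
#' @param fs Sampling rate, Hz (taken from the trace if omitted).
#' @param seg_len Segment length in samples (capped at `length(x)`).
#' @return A list with `freq` (Hz) and `psd` (power per Hz).
#' @export
welch_psd <- function(x, fs = NULL, seg_len = 256L) {
  if (inherits(x, "sampled_trace")) { fs <- x$fs; x <- x$samples }
  if (is.null(fs)) stop("welch_psd: fs required")
  n <- length(x)
  seg_len <- min(seg_len, n)
  step <- max(1L, seg_len %/% 2L)
  starts <- seq.int(1L, n - seg_len + 1L, by = step)
  w <- 0.5 * (1 - cos(2 * pi * seq_len(seg_len) / (seg_len + 1)))
  scale <- fs * sum(w^2)
  nf <- seg_len %/% 2L + 1L
  acc <- numeric(nf)
  for (s in starts) {
    seg <- x[s:(s + seg_len - 1L)] * w
    P <- abs(stats::fft(seg))^2 / scale
    p1 <- P[seq_len(nf)]
    # one-sided: double all bins except DC (and Nyquist when seg_len even)
    dbl <- seq.int(2L, nf - if (seg_len %% 2L == 0L) 1L else 0L)
    p1[dbl] <- 2 * p1[dbl]
    acc <- acc + p1
  }
  list(freq = (seq_len(nf) - 1L) * fs / seg_len, psd = acc / length(starts))
}

band_power <- function(x, fs, band, seg_len = 256L) {
  ps <- welch_psd(x, fs, seg_len)
  sel <- ps$freq >= band[1] & ps$freq <= band[2]
  if (!any(sel)) stop("band_power: no spectral bins in the requested band")
  df <- ps$freq[2L] - ps$freq[1L]
  sum(ps$psd[sel]) * df
}

#' Band-limited signal-to-error ratio
#'
#' `SER = P_extracted / (P_raw - P_extracted)` with band-integrated Welch
#' PSD powers. High SER in a band means the extraction preserved that band's
#' content; low SER means it was suppressed. The canonical bands are the
#' P wave (5-30 Hz), the His deflection (75-100 Hz), and noise (150-200 Hz).
#'
#' @param raw,extracted [sampled_trace()]s or numeric vectors of equal
#'   length (before/after extraction).
#' @param band `c(low, high)` Hz, inside `(0, fs/2)`.
#' @param fs Sampling rate, Hz (taken from the traces if omitted).
#' @param seg_len Welch segment length.
#' @return Dimensionless SER (>= 0 when defined).
#' @export
ser <- function(raw, extracted, band, fs = NULL, seg_len = 256L) {
  if (inherits(raw, "sampled_trace")) { fs <- raw$fs }
  r <- as_samples(raw); e <- as_samples(extracted)
  if (is.null(fs)) stop("ser: fs required")
  stopifnot(length(r) == length(e))
  if (!(band[1] > 0 && band[2] < fs / 2 && band[1] < band[2]))
    stop("ser: band must lie within (0, fs/2)")
  pr <- band_power(r, fs, band, seg_len)
  pe <- band_power(e, fs, band, seg_len)
  if (pe == pr) stop("SER undefined: extracted power equals raw power in band")
  if (pe > pr) stop("extracted exceeds raw in band")
  pe / (pr - pe)
}

#' Pearson correlation over a sample window
#'
#' @param a,b [sampled_trace()]s or numeric vectors.
#' @param window Integer indices of the comparison window (length >= 3); the
#'   full overlap by default.
#' @return Product-moment correlation in `[-1, 1]`.
#' @export
pearson_corr <- function(a, b, window = NULL) {
  x <- as_samples(a); y <- as_samples(b)
  if (is.null(window)) window <- seq_len(min(length(x), length(y)))
  stopifnot(length(window) >= 3L)
  x <- x[window]; y <- y[window]
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("undefined correlation: constant input on the window")
  stats::cor(x, y)
}

#' Measure the HV interval on an extracted His trace
#'
#' Finds the last supra-threshold deflection complex before the QRS onset
#' (threshold `k` times the supplied noise floor; samples closer together
#' than `min_gap_ms` belong to one complex), takes its first downward limb -
#' the first contiguous negative excursion whose trough reaches both the
#' threshold and `limb_frac` of the complex's peak magnitude, so sub-noise
#' dips ahead of the deflection are not mistaken for it - and backtracks to
#' the preceding zero crossing as the His onset: the "onset of the first
#' downward deflection" rule. HV is the distance from that onset to the QRS
#' onset.
#'
#' @param hbs_epoch A [sampled_trace()] or numeric vector: one extracted
#'   epoch, aligned with the QRS onset at `qrs_onset_idx`.
#' @param qrs_onset_idx 1-based QRS-onset sample (the final sample under the
#'   stack convention).
#' @param fs Sampling rate, Hz.
#' @param noise_floor Amplitude scale of the residual noise (e.g. RMS of an
#'   early, activity-free window of the extracted epoch).
#' @param k Threshold multiple of `noise_floor`.
#' @param min_gap_ms Gap merging supra-threshold samples into one complex.
#' @param limb_frac Fraction of the complex's peak magnitude a negative
#'   excursion must reach to count as a limb of the deflection.
#' @return HV interval in ms.
#' @export
measure_hv <- function(hbs_epoch, qrs_onset_idx = NULL, fs = NULL,
                       noise_floor, k = 2, min_gap_ms = 10, limb_frac = 0.3) {
  if (inherits(hbs_epoch, "sampled_trace")) { fs <- hbs_epoch$fs }
  x <- as_samples(hbs_epoch)
  if (is.null(fs)) stop("measure_hv: fs required")
  if (is.null(qrs_onset_idx)) qrs_onset_idx <- length(x)
  thr <- k * noise_floor
  idx <- which(abs(x[seq_len(qrs_onset_idx)]) > thr)
  if (length(idx) == 0L || thr <= 0) stop("no HBS detected")
  gap <- round(min_gap_ms / 1000 * fs)
  brk <- which(diff(idx) > gap)
  starts <- idx[c(1L, brk + 1L)]
  ends <- idx[c(brk, length(idx))]
  s <- starts[length(starts)]; e <- ends[length(ends)]   # last complex
  seg <- s:e
  peak <- max(abs(x[seg]))
  limb_thr <- max(thr, limb_frac * peak)
  dn <- seg[x[seg] < -limb_thr]
  anchor <- if (length(dn)) dn[1L] else s
  onset <- anchor
  while (onset > 1L && x[onset - 1L] < 0) onset <- onset - 1L
  if (onset > 1L) onset <- onset - 1L       # the preceding zero-crossing sample
  (qrs_onset_idx - onset) / fs * 1000
}

#' Spearman rank correlation (rank-difference formula)
#'
#' `rho = 1 - 6 sum(d_i^2) / (n (n^2 - 1))` with `d_i` the rank differences;
#' ties receive average ranks (for tie-free data the formula is exact and
#' equals Pearson correlation of the ranks).
#'
#' @param x,y Numeric vectors of equal length, `n >= 2`.
#' @return Spearman's rho.
#' @export
spearman_rho <- function(x, y) {
  stopifnot(length(x) == length(y))
  n <- length(x)
  if (n < 2L) stop("spearman_rho: need n >= 2")
  d <- rank(x, ties.method = "average") - rank(y, ties.method = "average")
  1 - 6 * sum(d^2) / (n * (n^2 - 1))
}

#' Bland-Altman agreement analysis
#'
#' Differences `obs - ref`: reports their mean (bias) and the limits of
#' agreement at +/- 1.96 sample standard deviations.
#'
#' @param ref,obs Numeric vectors of equal length, `n >= 2`.
#' @return A list of class `agreement_report` with `mean_diff`, `sd_diff`,
#'   `loa_low`, `loa_high`, `n`, and the per-pair `differences` and `means`.
#' @export
bland_altman <- function(ref, obs) {
  stopifnot(length(ref) == length(obs))
  if (length(ref) < 2L) stop("bland_altman: need n >= 2")
  d <- obs - ref
  m <- mean(d); s <- stats::sd(d)
  structure(list(mean_diff = m, sd_diff = s,
                 loa_low = m - 1.96 * s, loa_high = m + 1.96 * s,
                 n = length(d), differences = d, means = (obs + ref) / 2),
            class = "agreement_report")
}

#' @export
print.agreement_report <- function(x, ...) {
  cat(sprintf("<agreement_report> bias %.3f, limits of agreement [%.3f, %.3f], n = %d\n",
              x$mean_diff, x$loa_low, x$loa_high, x$n))
  invisible(x)
}

#' Build a template annotation from simulator ground truth
#'
#' Emulates the manual T1/T2 placement for simulated recordings: the
#' preserve interval is the true His support dilated by `pad_ms`, T1/T2 sit
#' `marker_pad_ms` outside it, and the annotated onset is the true onset.
#'
#' @param stack An [epoch_stack()] of simulated epochs.
#' @param ground_truth The simulator's ground truth.
#' @param hbs_dur_ms Support of the His deflection, ms.
#' @param pad_ms Dilation of the preserve interval on each side, ms.
#' @param marker_pad_ms Distance of T1/T2 outside the preserve interval, ms.
#' @return A [template_annotation()] on the signal-averaged trace.
#' @export
annotation_from_truth <- function(stack, ground_truth, hbs_dur_ms = 20,
                                  pad_ms = 5, marker_pad_ms = 3) {
  avg <- signal_average(stack)
  fs <- stack$fs
  onset_ms <- (ground_truth$hbs_onset_idx - 1) / fs * 1000
  t_end <- 1000 * (length(avg$samples) - 1) / fs
  lo <- max(0, onset_ms - pad_ms)
  hi <- min(1000 * length(avg$samples) / fs, onset_ms + hbs_dur_ms + pad_ms)
  template_annotation(avg,
                      t1_ms = max(0, lo - marker_pad_ms),
                      t2_ms = min(t_end, hi + marker_pad_ms),
                      preserve_intervals = list(c(lo, hi)),
                      hbs_onset_ms = onset_ms)
}

#' Mean extraction correlation across an SNR sweep
#'
#' For each SNR in the grid: simulate `n_reps` PR epochs of the requested
#' PTa type (independent noise on a shared clean signal), build the
#' threshold template from their signal average, run the full IDWT-SSP
#' pipeline, and correlate every extracted epoch with the clean reference
#' His deflection over the His window. Returns the per-SNR mean and SD of
#' the Pearson correlation.
#'
#' @param pta_type `"type1"`, `"type2"`, or `"type3"`.
#' @param snr_grid SNR points in dB (the study range is 5-28 dB).
#' @param n_reps Noise replicates per grid point.
#' @param seed Base RNG seed; point `i` uses `seed + i - 1`.
#' @param config Base [sim_config()] supplying all non-SNR parameters.
#' @param window `"hbs"` to correlate over the dilated His support (default)
#'   or `"full"` for the whole epoch.
#' @param pad_ms Dilation of the His correlation window, ms.
#' @return A data.frame with `snr_db`, `mean_r`, `sd_r`, `n`, plus the raw
#'   replicate correlations as attribute `"replicates"`.
#' @export
correlation_vs_snr_curve <- function(pta_type = "type1",
                                     snr_grid = c(5, 8, 11, 14, 17, 20, 23, 25, 28),
                                     n_reps = 100L, seed = 1L,
                                     config = NULL,
                                     window = c("hbs", "full"), pad_ms = 5) {
  window <- match.arg(window)
  if (is.null(config)) config <- sim_config(pta_type = pta_type)
  reps <- vector("list", length(snr_grid))
  for (i in seq_along(snr_grid)) {
    cfg <- sim_config(fs = config$fs, epoch_len = config$epoch_len,
                      p_center = config$p_center, p_width = config$p_width,
                      p_amp = config$p_amp, pta_type = pta_type,
                      hbs_hv = config$hbs_hv, hbs_freq = config$hbs_freq,
                      hbs_amp = config$hbs_amp, hbs_dur = config$hbs_dur,
                      hbs_edge_ms = config$hbs_edge_ms,
                      snr_db = snr_grid[i], seed = seed + i - 1L,
                      n_epochs = n_reps)
    sim <- simulate_pr_epoch(cfg)
    tpl <- annotation_from_truth(sim$stack, sim$ground_truth,
                                 hbs_dur_ms = cfg$hbs_dur, pad_ms = pad_ms)
    spec <- build_threshold_spec(tpl, epochs = sim$stack)
    hbs <- run_pipeline(sim$stack, spec)
    ref <- sim$ground_truth$clean_hbs$samples
    win <- if (window == "full") seq_along(ref) else {
      o <- sim$ground_truth$hbs_onset_idx
      w0 <- max(1L, o - round(pad_ms * cfg$fs / 1000))
      w1 <- min(length(ref), o + round((cfg$hbs_dur + pad_ms) * cfg$fs / 1000))
      w0:w1
    }
    reps[[i]] <- apply(hbs$epochs, 1L, function(e)
      tryCatch(pearson_corr(e, ref, win), error = function(err) NA_real_))
  }
  ok <- vapply(reps, function(r) sum(!is.na(r)), 0L)
  out <- data.frame(snr_db = snr_grid,
                    mean_r = vapply(reps, function(r) mean(r, na.rm = TRUE), 0),
                    sd_r = vapply(reps, function(r) stats::sd(r, na.rm = TRUE), 0),
                    n = ok)
  attr(out, "replicates") <- reps
  out
}
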