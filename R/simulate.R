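#' Configuration of a synthetic PR-interval epoch
#'
#' Defines the generative model of the evaluation study: a Gaussian-bump
#' P wave, a ramp-like atrial-repolarization (PTa) waveform of one of three
#' canonical types, a compact biphasic ~100 Hz His deflection placed a fixed
#' HV interval before the QRS onset, and additive white Gaussian noise whose
#' level is referenced to the P-wave peak. The QRS onset is defined as the
#' final sample of the epoch.
#'
#' The three PTa types fix the ramp's extreme relative to the P peak:
#' type 1 is one-third of the P amplitude with opposite polarity
#' (ratio -1/3), type 2 is one-half with the same polarity (+1/2), and
#' type 3 exceeds one-half in the positive direction (default +0.6).
#' `pta_type = "custom"` uses `pta_ratio` verbatim (any value, including 0).
#'
#' @param fs Sampling rate, Hz.
#' @param epoch_len Epoch duration, ms.
#' @param p_center Time of the P-wave peak, ms.
#' @param p_width Gaussian SD of the P wave, ms. The P-wave offset is taken
#'   as `p_center + 2 * p_width`; the PTa ramp starts there.
#' @param p_amp P-wave peak amplitude (arbitrary units; the SNR reference).
#' @param pta_type One of `"type1"`, `"type2"`, `"type3"`, `"custom"`.
#' @param pta_ratio Signed PTa extreme as a fraction of `p_amp`. Fixed at
#'   -1/3 (+1/2) for types 1 (2); for type 3 must exceed +1/2.
#' @param hbs_hv True HV interval: distance from the His-deflection onset to
#'   the QRS onset, ms.
#' @param hbs_freq Center frequency of the His deflection, Hz.
#' @param hbs_amp Peak amplitude of the His deflection.
#' @param hbs_dur Support of the deflection, ms (<= 20 ms; 15 ms gives a
#'   triphasic ~100 Hz spike).
#' @param hbs_edge_ms Raised-cosine attack/release of the deflection's
#'   window, ms. The short edges make the spike sharp, so its first downward
#'   limb is prominent and the first-downward-deflection onset rule is
#'   well-posed.
#' @param snr_db Target SNR in dB, `20*log10(p_amp / noise RMS)`; `Inf` for a
#'   noiseless epoch.
#' @param seed Integer RNG seed.
#' @param n_epochs Number of independent noise realizations sharing one clean
#'   signal.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(fs = 1000, epoch_len = 350,
                       p_center = 80, p_width = 20, p_amp = 1,
                       pta_type = c("type1", "type2", "type3", "custom"),
                       pta_ratio = NULL,
                       hbs_hv = 60, hbs_freq = 100, hbs_amp = 0.2,
                       hbs_dur = 15, hbs_edge_ms = 3,
                       snr_db = Inf, seed = 1L, n_epochs = 1L) {
  pta_type <- match.arg(pta_type)
  stopifnot(fs > 0, epoch_len > 0, p_width > 0, p_amp >= 0,
            hbs_hv > 0, hbs_dur > 0, hbs_dur <= 20,
            hbs_edge_ms > 0, hbs_edge_ms <= hbs_dur / 2,
            n_epochs >= 1, is.finite(seed))
  if (hbs_freq >= fs / 2) stop("sim_config: hbs_freq must be below fs/2")
  pta_ratio <- switch(pta_type,
    type1 = {
      if (!is.null(pta_ratio) && abs(pta_ratio - (-1 / 3)) > 1e-12)
        stop("sim_config: type 1 fixes pta_ratio = -1/3")
      -1 / 3
    },
    type2 = {
      if (!is.null(pta_ratio) && abs(pta_ratio - 0.5) > 1e-12)
        stop("sim_config: type 2 fixes pta_ratio = +1/2")
      0.5
    },
    type3 = {
      r <- if (is.null(pta_ratio)) 0.6 else pta_ratio
      if (r <= 0.5) stop("sim_config: type 3 requires pta_ratio > +1/2")
      r
    },
    custom = {
      if (is.null(pta_ratio)) stop("sim_config: pta_type 'custom' needs pta_ratio")
      pta_ratio
    })
  if (!(hbs_hv < epoch_len - p_center - p_width))
    stop("sim_config: hbs_hv must satisfy hbs_hv < epoch_len - p_center - p_width")
  structure(list(fs = fs, epoch_len = epoch_len,
                 p_center = p_center, p_width = p_width, p_amp = p_amp,
                 pta_type = pta_type, pta_ratio = pta_ratio,
                 hbs_hv = hbs_hv, hbs_freq = hbs_freq, hbs_amp = hbs_amp,
                 hbs_dur = hbs_dur, hbs_edge_ms = hbs_edge_ms, snr_db = snr_db,
                 seed = as.integer(seed), n_epochs = as.integer(n_epochs)),
            class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf("<sim_config> %s PTa (ratio %+.3f), HV = %g ms, SNR = %g dB, fs = %g Hz, %d epoch(s)\n",
              x$pta_type, x$pta_ratio, x$hbs_hv, x$snr_db, x$fs, x$n_epochs))
  invisible(x)
}

epoch_samples <- function(config) as.integer(round(config$epoch_len * config$fs / 1000))

#' Noiseless atrial waveform: P wave plus PTa ramp
#'
#' The P wave is a positive Gaussian bump peaking at `p_center`; the atrial
#' repolarization is a linear ramp starting at zero at the P-wave offset
#' (`p_center + 2 p_width`) and reaching `pta_ratio * p_amp` at the QRS onset
#' (final sample). With `pta_ratio = 0` the trace is the bare P wave.
#'
#' @param config A [sim_config()].
#' @return A [sampled_trace()] with the noiseless atrial component.
#' @export
make_atrial <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  n <- epoch_samples(config)
  t_ms <- (seq_len(n) - 1) / config$fs * 1000
  p <- config$p_amp * exp(-0.5 * ((t_ms - config$p_center) / config$p_width)^2)
  offset_ms <- config$p_center + 2 * config$p_width
  end_ms <- t_ms[n]
  ramp <- numeric(n)
  idx <- t_ms >= offset_ms
  if (end_ms > offset_ms)
    ramp[idx] <- config$pta_ratio * config$p_amp *
      (t_ms[idx] - offset_ms) / (end_ms - offset_ms)
  sampled_trace(p + ramp, config$fs)
}

#' Noiseless reference His deflection and its ground truth
#'
#' The His bundle signal is modeled as a windowed sinusoid at `hbs_freq`: a
#' compact "M"-like bi/triphasic spike of support `hbs_dur` ms, whose window
#' is flat-topped with raised-cosine edges of `hbs_edge_ms` so the spike has
#' a sharp, prominent first downward limb. The trace is normalized to peak
#' amplitude `hbs_amp` and signed so its first deflection is downward; its
#' onset lies exactly `hbs_hv` ms before the epoch's final sample, the QRS
#' onset.
#'
#' @param config A [sim_config()].
#' @return A list with `trace` ([sampled_trace()]) and `ground_truth`, the
#'   latter holding `hbs_onset_idx` (1-based), `hv_ms`, `clean_hbs`, and
#'   `clean_atrial`.
#' @export
make_reference_hbs <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  n <- epoch_samples(config)
  onset_idx <- n - as.integer(round(config$hbs_hv * config$fs / 1000))  # 1-based
  if (onset_idx < 1L) stop("make_reference_hbs: hbs_hv exceeds the epoch length")
  s <- numeric(n)
  dur_smp <- as.integer(round(config$hbs_dur * config$fs / 1000))
  k <- seq.int(0L, dur_smp)
  keep <- onset_idx + k <= n & onset_idx + k >= 1L
  k <- k[keep]
  tau <- k / config$fs                      # seconds since onset
  tau_ms <- k / config$fs * 1000
  edge <- config$hbs_edge_ms
  dur_ms <- dur_smp / config$fs * 1000
  w <- rep(1, length(k))                    # flat top, raised-cosine edges
  up <- tau_ms < edge
  dn <- tau_ms > dur_ms - edge
  w[up] <- 0.5 * (1 - cos(pi * tau_ms[up] / edge))
  w[dn] <- 0.5 * (1 - cos(pi * (dur_ms - tau_ms[dn]) / edge))
  burst <- -sin(2 * pi * config$hbs_freq * tau) * w
  if (max(abs(burst)) > 0) burst <- burst / max(abs(burst))
  s[onset_idx + k] <- config$hbs_amp * burst
  gt <- list(hbs_onset_idx = onset_idx,
             hv_ms = (n - onset_idx) / config$fs * 1000,
             clean_hbs = sampled_trace(s, config$fs),
             clean_atrial = make_atrial(config))
  class(gt) <- "ground_truth"
  list(trace = gt$clean_hbs, ground_truth = gt)
}

#' @export
print.ground_truth <- function(x, ...) {
  cat(sprintf("<ground_truth> HBS onset at sample %d, HV = %g ms\n",
              x$hbs_onset_idx, x$hv_ms))
  invisible(x)
}

#' Simulate a stack of noisy PR-interval epochs
#'
#' Each epoch is the shared clean signal (atrial + His deflection) plus an
#' independent realization of white Gaussian noise with RMS
#' `p_amp / 10^(snr_db/20)`, so the P-wave peak is the signal reference of
#' the stated SNR. The RNG is seeded from `config$seed`, making the whole
#' stack reproducible.
#'
#' @param config A [sim_config()].
#' @return A list with `stack` ([epoch_stack()] of `n_epochs` rows) and
#'   `ground_truth` (shared across rows).
#' @export
simulate_pr_epoch <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  ref <- make_reference_hbs(config)
  clean <- ref$ground_truth$clean_atrial$samples + ref$trace$samples
  n <- length(clean)
  sigma <- if (is.infinite(config$snr_db)) 0 else config$p_amp / 10^(config$snr_db / 20)
  set.seed(config$seed)
  noise <- if (sigma > 0) {
    matrix(stats::rnorm(config$n_epochs * n, sd = sigma),
           nrow = config$n_epochs, ncol = n)
  } else matrix(0, config$n_epochs, n)
  epochs <- sweep(noise, 2L, clean, `+`)
  list(stack = epoch_stack(epochs, config$fs, qrs_onset_idx = n),
       ground_truth = ref$ground_truth)
}

#' Simulate a continuous multi-beat, optionally multichannel series
#'
#' Concatenates beats at (optionally jittered) RR spacing: each beat is a PR
#' epoch whose final sample is the QRS onset, followed by a stylized
#' high-amplitude R-S complex. In multichannel mode the sign of the PTa ramp
#' alternates across channels (guaranteeing at least one polarity flip of the
#' post-His ramp, the multichannel identification criterion) while the His
#' deflection's timing and polarity are identical in all channels.
#'
#' @param config A [sim_config()]; `n_epochs` is ignored here.
#' @param n_beats Number of beats (>= 1).
#' @param rr_ms Mean RR interval, ms; must exceed `epoch_len`.
#' @param rr_jitter_ms SD of Gaussian RR jitter, ms.
#' @param n_channels Channel count.
#' @param qrs_amp_rel QRS peak amplitude as a multiple of `p_amp`.
#' @return A list with `series` ([beat_series()]), `qrs_onsets` (1-based
#'   sample indices of the true QRS onsets), and `ground_truth` (the shared
#'   per-beat clean-epoch truth of channel 1).
#' @export
simulate_beat_series <- function(config, n_beats = 200L, rr_ms = 750,
                                 rr_jitter_ms = 0, n_channels = 1L,
                                 qrs_amp_rel = 8) {
  stopifnot(inherits(config, "sim_config"), n_beats >= 1L, n_channels >= 1L)
  if (rr_ms <= config$epoch_len)
    stop("simulate_beat_series: rr_ms must exceed epoch_len")
  fs <- config$fs
  set.seed(config$seed)
  t_epoch <- epoch_samples(config)
  rr_smp <- round((rr_ms + stats::rnorm(max(n_beats - 1L, 0L), sd = rr_jitter_ms)) *
                    fs / 1000)
  lead_in <- round(0.05 * fs)               # 50 ms margin before the first epoch
  onsets <- cumsum(c(t_epoch + lead_in, rr_smp))
  qrs_dur <- round(0.07 * fs)               # 70 ms stylized R-S complex
  # trailing baseline up to where the next beat would start, so even a
  # single-beat series has a realistic tail
  total <- onsets[n_beats] + max(qrs_dur + round(0.1 * fs),
                                 round(rr_ms * fs / 1000))
  # stylized R-S: linear rise to +qrs_amp in 20 ms, fall to -qrs_amp/2, return
  tq <- seq_len(qrs_dur) / fs * 1000
  qrs_amp <- qrs_amp_rel * config$p_amp
  qrs_shape <- ifelse(tq <= 20, qrs_amp * tq / 20,
                ifelse(tq <= 45, qrs_amp - 1.5 * qrs_amp * (tq - 20) / 25,
                       -0.5 * qrs_amp * (1 - (tq - 45) / 25)))
  sigma <- if (is.infinite(config$snr_db)) 0 else config$p_amp / 10^(config$snr_db / 20)
  ref <- make_reference_hbs(config)
  signs <- if (n_channels == 1L) 1 else rep_len(c(1, -1), n_channels)
  x <- matrix(0, n_channels, total)
  for (ch in seq_len(n_channels)) {
    clean_epoch <- signs[ch] * ref$ground_truth$clean_atrial$samples + ref$trace$samples
    for (b in seq_len(n_beats)) {
      o <- onsets[b]
      x[ch, (o - t_epoch + 1L):o] <- clean_epoch
      x[ch, o + seq_len(qrs_dur)] <- qrs_shape
    }
    if (sigma > 0) x[ch, ] <- x[ch, ] + stats::rnorm(total, sd = sigma)
  }
  list(series = beat_series(x, fs),
       qrs_onsets = as.integer(onsets),
       ground_truth = ref$ground_truth)
}
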