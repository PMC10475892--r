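# Synthetic PR-epoch generator: waveform contracts, noise calibration,
# determinism, and the multichannel ramp-polarity structure.

test_that("PTa types fix the ramp extreme relative to the P peak", {
  for (case in list(list(type = "type1", ratio = -1 / 3),
                    list(type = "type2", ratio = 0.5),
                    list(type = "type3", ratio = 0.6))) {
    cfg <- sim_config(pta_type = case$type, p_amp = 1)
    atr <- make_atrial(cfg)
    p_only <- make_atrial(sim_config(pta_type = "custom", pta_ratio = 0, p_amp = 1))
    ramp <- atr$samples - p_only$samples
    extreme <- ramp[which.max(abs(ramp))]
    expect_equal(extreme, case$ratio, tolerance = 1e-12)
  }
  # zero-ratio config yields the bare P wave
  cfg0 <- sim_config(pta_type = "custom", pta_ratio = 0)
  atr0 <- make_atrial(cfg0)
  t_ms <- (seq_along(atr0$samples) - 1) / cfg0$fs * 1000
  expect_equal(atr0$samples,
               exp(-0.5 * ((t_ms - cfg0$p_center) / cfg0$p_width)^2),
               tolerance = 1e-12)
  # invalid configs are rejected
  expect_error(sim_config(pta_type = "type3", pta_ratio = 0.4), "pta_ratio")
  expect_error(sim_config(hbs_hv = 260), "hbs_hv")
  expect_error(sim_config(hbs_freq = 600), "fs/2")
})

test_that("reference His deflection is placed exactly at the stated HV", {
  cfg <- sim_config(hbs_hv = 60, epoch_len = 350, fs = 1000)
  ref <- make_reference_hbs(cfg)
  expect_equal(ref$ground_truth$hbs_onset_idx, 290L)   # 0-based 289 = 349 - 60
  expect_equal(ref$ground_truth$hv_ms, 60)
  # first deflection is downward and starts at the onset
  s <- ref$trace$samples
  expect_equal(max(abs(s[seq_len(289)])), 0)
  expect_lt(s[292], 0)
  expect_equal(max(abs(s)), cfg$hbs_amp, tolerance = 1e-12)
  # zero amplitude: silent trace, truth still reports the nominal onset
  ref0 <- make_reference_hbs(sim_config(hbs_amp = 0))
  expect_true(all(ref0$trace$samples == 0))
  expect_equal(ref0$ground_truth$hbs_onset_idx, 290L)
  # noiseless synthesis is deterministic
  expect_identical(make_reference_hbs(cfg)$trace$samples, s)
})

test_that("epoch decomposes exactly into atrial + His + noise at calibrated SNR", {
  cfg <- sim_config(snr_db = 20, n_epochs = 4, seed = 5)
  sim <- simulate_pr_epoch(cfg)
  clean <- sim$ground_truth$clean_atrial$samples + sim$ground_truth$clean_hbs$samples
  noise <- sweep(sim$stack$epochs, 2L, clean, `-`)
  # decomposition: epoch - noise = atrial + hbs sample-wise, exactly
  expect_equal(sweep(sim$stack$epochs, 2L, clean, `-`), noise, tolerance = 0)
  # 20 dB with p_amp = 1: noise RMS 0.1 within 5%
  expect_equal(sqrt(mean(noise^2)), 0.1, tolerance = 0.05)
  # noiseless limit is the clean sum exactly
  sim_inf <- simulate_pr_epoch(sim_config(snr_db = Inf))
  expect_equal(as.vector(sim_inf$stack$epochs[1L, ]), clean, tolerance = 0)
  # seeded RNG contract
  sim2 <- simulate_pr_epoch(cfg)
  expect_identical(sim$stack$epochs, sim2$stack$epochs)
})

test_that("realized SNR matches the target within 0.5 dB on average", {
  snrs <- vapply(1:50, function(s) {
    cfg <- sim_config(snr_db = 15, n_epochs = 1, seed = s)
    sim <- simulate_pr_epoch(cfg)
    clean <- sim$ground_truth$clean_atrial$samples + sim$ground_truth$clean_hbs$samples
    20 * log10(cfg$p_amp / sqrt(mean((sim$stack$epochs[1L, ] - clean)^2)))
  }, 0)
  expect_lt(abs(mean(snrs) - 15), 0.5)
  expect_lt(max(abs(snrs - 15)), 2)
})

test_that("noise magnitude decreases monotonically with SNR", {
  rms_at <- vapply(c(5, 10, 15, 20, 25, 28), function(snr) {
    cfg <- sim_config(snr_db = snr, n_epochs = 10, seed = 77)
    sim <- simulate_pr_epoch(cfg)
    clean <- sim$ground_truth$clean_atrial$samples + sim$ground_truth$clean_hbs$samples
    sqrt(mean(sweep(sim$stack$epochs, 2L, clean, `-`)^2))
  }, 0)
  expect_true(all(diff(rms_at) < 0))
})

test_that("beat series has exact onsets, polarity flips across channels", {
  cfg <- sim_config(snr_db = Inf, seed = 2)
  bs <- simulate_beat_series(cfg, n_beats = 20, rr_ms = 750, rr_jitter_ms = 0)
  # zero jitter: onsets exactly periodic
  expect_equal(length(bs$qrs_onsets), 20L)
  expect_true(all(diff(bs$qrs_onsets) == 750L))
  # single beat
  bs1 <- simulate_beat_series(cfg, n_beats = 1, rr_ms = 700)
  expect_equal(length(bs1$qrs_onsets), 1L)
  expect_error(simulate_beat_series(cfg, n_beats = 5, rr_ms = 300), "rr_ms")
  # multichannel: post-His ramp slope flips sign between channels,
  # His deflection identical everywhere
  bs8 <- simulate_beat_series(cfg, n_beats = 3, rr_ms = 800, n_channels = 8)
  o <- bs8$qrs_onsets[2]
  slopes <- vapply(1:8, function(ch) {
    seg <- bs8$series$samples[ch, (o - 20):(o - 1)]
    unname(coef(lm(seg ~ seq_along(seg)))[2])
  }, 0)
  expect_true(any(slopes > 0) && any(slopes < 0))
  hbs_win <- (o - 60):(o - 40)
  hbs_only <- bs8$ground_truth$clean_hbs$samples
  on_idx <- bs8$ground_truth$hbs_onset_idx
  ref_seg <- hbs_only[on_idx:(on_idx + 20)]
  for (ch in c(1, 2)) {
    seg <- bs8$series$samples[ch, (o - 60):(o - 40)]
    atr <- bs8$ground_truth$clean_atrial$samples[on_idx:(on_idx + 20)]
    resid <- seg - ref_seg
    # removing the (possibly sign-flipped) atrial part leaves the shared HBS
    expect_true(max(abs(resid - atr)) < 1e-12 || max(abs(resid + atr)) < 1e-12)
  }
})
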