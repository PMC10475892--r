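# Shared fixtures, generated in code (no stored data files).

default_cfg <- function(...) {
  sim_config(pta_type = "type1", snr_db = 28, n_epochs = 50, seed = 101, ...)
}

# Simulated stack + ground-truth-derived annotation + threshold spec,
# the standard entry into the pipeline for tests.
sim_with_spec <- function(cfg = default_cfg()) {
  sim <- simulate_pr_epoch(cfg)
  tpl <- annotation_from_truth(sim$stack, sim$ground_truth,
                               hbs_dur_ms = cfg$hbs_dur)
  spec <- build_threshold_spec(tpl, epochs = sim$stack)
  list(cfg = cfg, sim = sim, tpl = tpl, spec = spec)
}

# Correlation window over the (dilated) His support.
hbs_window <- function(sim, cfg, pad_ms = 5) {
  o <- sim$ground_truth$hbs_onset_idx
  n <- length(sim$ground_truth$clean_hbs$samples)
  max(1L, o - round(pad_ms * cfg$fs / 1000)):
    min(n, o + round((cfg$hbs_dur + pad_ms) * cfg$fs / 1000))
}

# A deterministic multitone trace for transform-level checks.
multitone <- function(n = 352) {
  t <- seq_len(n) - 1
  sin(2 * pi * 7 * t / n) + 0.5 * sin(2 * pi * 40 * t / n) +
    0.2 * cos(2 * pi * 111 * t / n)
}
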