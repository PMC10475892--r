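# Interval-dependent wavelet thresholding: the soft-shrink operator, the
# fixed-form threshold construction, preserve-mask semantics, and the
# reconstruction contracts.

test_that("soft thresholding shrinks toward zero and preserves sign", {
  expect_equal(soft_threshold(1.5, 1.0), 0.5)
  expect_equal(soft_threshold(-0.3, 1.0), 0.0)
  expect_equal(soft_threshold(-2.0, 0.5), -1.5)
  expect_error(soft_threshold(1, -0.1), "negative")
  x <- rnorm(100)
  expect_true(all(abs(soft_threshold(x, 0.3)) <= abs(x)))
})

test_that("fixed-form thresholds follow sigma * sqrt(2 ln N) on white noise", {
  # Monte-Carlo against the closed form, template-only path: a white-noise
  # template of known SD must produce a d1 threshold near the universal rule.
  n <- 350L
  n1 <- hisbeat:::pad_len(n, 5L) / 2L
  sigma <- 0.7
  ratios <- vapply(1:50, function(s) {
    set.seed(s)
    tr <- sampled_trace(rnorm(n, sd = sigma), 1000)
    tpl <- template_annotation(tr, t1_ms = 280, t2_ms = 320,
                               preserve_intervals = list(c(285, 315)),
                               hbs_onset_ms = 290)
    spec <- build_threshold_spec(tpl)
    spec$level_thresholds[1L] / (sigma * sqrt(2 * log(n1)))
  }, 0)
  expect_lt(abs(mean(ratios) - 1), 0.15)
  # an all-zero template yields zero thresholds on the non-zeroed levels
  zt <- sampled_trace(numeric(n), 1000)
  ztpl <- template_annotation(zt, 280, 320, list(c(285, 315)), 290)
  zspec <- build_threshold_spec(ztpl)
  expect_equal(zspec$level_thresholds[1:3], rep(0, 3))
})

test_that("preserve interval covering the whole epoch keeps d1-d3 intact", {
  cfg <- default_cfg()
  sim <- simulate_pr_epoch(cfg)
  tpl <- template_annotation(signal_average(sim$stack), t1_ms = 280,
                             t2_ms = 320, preserve_intervals = list(c(0, 350)),
                             hbs_onset_ms = 290)
  spec <- build_threshold_spec(tpl, epochs = sim$stack)
  for (j in 1:3) expect_true(all(spec$preserve_masks[[j]]))
  for (j in 4:5) expect_false(any(spec$preserve_masks[[j]]))
  # the shrink step changes only d4/d5 planes
  x <- sim$stack$epochs[1L, ]
  wx <- hisbeat:::pdwt(hisbeat:::edge_detrend(matrix(x, 1))$detrended, 5L)
  wy <- hisbeat:::shrink_details(wx, spec)
  for (j in 1:3) expect_identical(wy$d[[j]], wx$d[[j]])
  for (j in 4:5) expect_true(all(wy$d[[j]] == 0))
  expect_identical(wy$a, wx$a)
})

test_that("zero thresholds with no zeroed levels reproduce the input", {
  cfg <- default_cfg()
  sim <- simulate_pr_epoch(cfg)
  tpl <- annotation_from_truth(sim$stack, sim$ground_truth,
                               hbs_dur_ms = cfg$hbs_dur)
  spec <- build_threshold_spec(tpl, epochs = sim$stack, zeroed_levels = integer(0))
  spec$level_thresholds[] <- 0
  x <- sim$stack$epochs[1:5, ]
  y <- apply_threshold(x, spec)
  expect_lt(max(abs(y - x)) / max(abs(x)), 1e-8)
})

test_that("preserved coefficients pass through bit-identical", {
  cfg <- default_cfg()
  s <- sim_with_spec(cfg)
  x <- s$sim$stack$epochs[1L, ]
  wx <- hisbeat:::pdwt(hisbeat:::edge_detrend(matrix(x, 1))$detrended, 5L)
  wy <- hisbeat:::shrink_details(wx, s$spec)
  for (j in 1:3) {
    m <- s$spec$preserve_masks[[j]]
    expect_gt(sum(m), 0L)
    expect_identical(as.vector(wy$d[[j]])[m], as.vector(wx$d[[j]])[m])
    # non-expansiveness on the shrunk coefficients
    expect_true(all(abs(as.vector(wy$d[[j]])[!m]) <=
                      abs(as.vector(wx$d[[j]])[!m]) + 1e-12))
  }
  # approximation untouched
  expect_identical(wy$a, wx$a)
})

test_that("thresholding reduces out-of-window noise energy", {
  cfg <- default_cfg()
  s <- sim_with_spec(cfg)
  x <- s$sim$stack$epochs
  y <- apply_threshold(x, s$spec)
  win <- hbs_window(s$sim, cfg)
  out_idx <- setdiff(seq_len(ncol(x)), win)
  clean <- s$sim$ground_truth$clean_atrial$samples +
    s$sim$ground_truth$clean_hbs$samples
  rms_before <- sqrt(mean(sweep(x, 2, clean)[, out_idx]^2))
  rms_after <- sqrt(mean(sweep(y, 2, clean)[, out_idx]^2))
  expect_lt(rms_after, rms_before)
})

test_that("applying the shrink twice matches a direct two-pass oracle", {
  cfg <- default_cfg()
  s <- sim_with_spec(cfg)
  x <- s$sim$stack$epochs[1L, ]
  w0 <- hisbeat:::pdwt(hisbeat:::edge_detrend(matrix(x, 1))$detrended,
                       s$spec$levels)
  twice <- hisbeat:::shrink_details(hisbeat:::shrink_details(w0, s$spec), s$spec)
  # oracle: shrink every coefficient plane twice by hand
  w <- w0
  for (pass in 1:2) {
    for (j in seq_len(s$spec$levels)) {
      m <- s$spec$preserve_masks[[j]]
      if (j %in% s$spec$zeroed_levels) {
        w$d[[j]][, ] <- 0
      } else if (any(!m)) {
        w$d[[j]][, !m] <- soft_threshold(w$d[[j]][, !m, drop = FALSE],
                                         s$spec$level_thresholds[j])
      }
    }
  }
  for (j in seq_len(s$spec$levels))
    expect_identical(twice$d[[j]], w$d[[j]])
  # and the end-to-end second application changes the trace only slightly
  y1 <- apply_threshold(x, s$spec)
  y2 <- apply_threshold(y1, s$spec)
  expect_lt(max(abs(y2 - y1)), max(abs(y1 - x)))
})

test_that("length mismatches and bad intervals are rejected", {
  cfg <- default_cfg()
  s <- sim_with_spec(cfg)
  expect_error(apply_threshold(rnorm(100), s$spec), "length")
  tr <- signal_average(s$sim$stack)
  expect_error(template_annotation(tr, 280, 320, list(c(300, 400)), 290),
               "outside")
  expect_error(template_annotation(tr, 300, 290, list(c(285, 315)), 295),
               "t1_ms")
})
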