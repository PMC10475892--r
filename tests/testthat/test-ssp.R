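# Signal space projection: Savitzky-Golay over-smoothing, the SVD atrial
# basis, projector algebra, and the assembled extraction pipeline.

test_that("over-smoothing is exact on cubics and crushes 100 Hz content", {
  t <- seq_len(400)
  cubic <- 2 + 0.01 * t - 3e-5 * t^2 + 5e-8 * t^3
  sm <- oversmooth(cubic, order = 3, frame_ms = 23, fs = 1000)
  interior <- 30:370
  expect_lt(max(abs(sm[interior] - cubic[interior])), 1e-6)
  expect_equal(oversmooth(rep(2.5, 100), fs = 1000), rep(2.5, 100),
               tolerance = 1e-10)
  # 100 Hz sine at 1 kHz: response magnitude from the filter's own impulse
  # response (independent route) must match the observed attenuation, < 50%
  s100 <- sin(2 * pi * 100 * t / 1000)
  sm100 <- oversmooth(s100, fs = 1000)
  att <- max(abs(sm100[interior])) / 1
  b <- signal::sgolay(p = 3, n = 23)[12L, ]   # center row = FIR coefficients
  H <- abs(sum(b * exp(-2i * pi * 0.1 * (seq_along(b) - 12L))))
  expect_lt(att, 0.5)
  expect_equal(att, H, tolerance = 0.05)
  expect_error(oversmooth(rnorm(50), order = 3, frame_ms = 2, fs = 1000),
               "frame")
})

test_that("atrial basis rank tracks the true subspace dimension", {
  t <- seq_len(300) / 300
  shape1 <- exp(-0.5 * ((t - 0.3) / 0.1)^2)
  shape2 <- t
  # identical epochs: rank 1, basis vector proportional to the epoch
  st1 <- epoch_stack(matrix(rep(shape1, 10), 10, byrow = TRUE), 1000)
  b1 <- build_atrial_basis(st1)
  expect_equal(b1$n, 1L)
  u <- b1$U[, 1]; v <- shape1 / sqrt(sum(shape1^2))
  expect_lt(min(max(abs(u - v)), max(abs(u + v))), 1e-8)
  # two independent shapes, noiseless: rank 2
  mix <- t(sapply(1:12, function(i) i * shape1 + (13 - i) * shape2))
  b2 <- build_atrial_basis(epoch_stack(mix, 1000))
  expect_equal(b2$n, 2L)
  # orthonormality for random inputs
  set.seed(6)
  br <- build_atrial_basis(epoch_stack(matrix(rnorm(20 * 64), 20), 1000),
                           energy_rule = 0.8)
  expect_lt(max(abs(crossprod(br$U) - diag(br$n))), 1e-8)
  expect_lt(br$n, 20L)
  expect_error(build_atrial_basis(epoch_stack(matrix(0, 5, 10), 1000)),
               "atrial subspace undefined")
})

test_that("projector satisfies the defining algebra", {
  # axis-aligned case: P removes the first coordinate
  basis <- structure(list(U = matrix(c(1, 0), 2), n = 1L,
                          singular_values = 1, energy_rule = 0.99),
                     class = "atrial_basis")
  P <- projection_operator(basis)
  expect_equal(P, matrix(c(0, 0, 0, 1), 2), tolerance = 1e-15)
  expect_equal(as.vector(P %*% c(3, 7)), c(0, 7), tolerance = 1e-15)
  # random orthonormal 64 x 3 basis: symmetry, idempotence, annihilation
  set.seed(9)
  U <- qr.Q(qr(matrix(rnorm(64 * 3), 64)))
  b <- structure(list(U = U, n = 3L, singular_values = rep(1, 3),
                      energy_rule = 0.99), class = "atrial_basis")
  P <- projection_operator(b)
  expect_lt(max(abs(P %*% P - P)), 1e-10)
  expect_lt(max(abs(t(P) - P)), 1e-12)
  expect_lt(max(abs(P %*% U)), 1e-10)
})

test_that("extraction annihilates the atrial span, is idempotent and linear", {
  set.seed(13)
  U <- qr.Q(qr(matrix(rnorm(128 * 2), 128)))
  b <- structure(list(U = U, n = 2L, singular_values = rep(1, 2),
                      energy_rule = 0.99), class = "atrial_basis")
  in_span <- t(U %*% matrix(rnorm(2 * 5), 2))     # 5 epochs inside the span
  st_in <- epoch_stack(in_span, 1000)
  out <- extract_hbs(st_in, b)
  expect_lt(max(abs(out$epochs)), 1e-8 * max(abs(in_span)))
  # idempotence
  x <- matrix(rnorm(3 * 128), 3)
  once <- extract_hbs(epoch_stack(x, 1000), b)$epochs
  twice <- extract_hbs(epoch_stack(once, 1000), b)$epochs
  expect_equal(twice, once, tolerance = 1e-10)
  # linearity
  y <- matrix(rnorm(3 * 128), 3)
  lhs <- extract_hbs(epoch_stack(2 * x + 3 * y, 1000), b)$epochs
  rhs <- 2 * once + 3 * extract_hbs(epoch_stack(y, 1000), b)$epochs
  expect_equal(lhs, rhs, tolerance = 1e-10)
  # implicit form agrees with the materialized projector
  P <- projection_operator(b)
  expect_lt(max(abs(once - x %*% P)), 1e-10)
  expect_error(extract_hbs(epoch_stack(matrix(rnorm(10 * 64), 10), 1000), b),
               "length")
})

test_that("pipeline suppresses atrial-only epochs and retains the His spike", {
  # no His deflection: the pipeline output must be a small residue
  cfg0 <- sim_config(pta_type = "type1", hbs_amp = 0, snr_db = Inf,
                     n_epochs = 8, seed = 31)
  sim0 <- simulate_pr_epoch(cfg0)
  tpl0 <- template_annotation(signal_average(sim0$stack), 280, 320,
                              list(c(285, 310)), 290)
  spec0 <- build_threshold_spec(tpl0, epochs = sim0$stack)
  out0 <- run_pipeline(sim0$stack, spec0)
  expect_lt(max(abs(out0$epochs)), 0.05 * cfg0$p_amp)
  # noiseless with His: the deflection survives with at least half its peak
  cfg1 <- sim_config(pta_type = "type1", snr_db = Inf, n_epochs = 8, seed = 31)
  sim1 <- simulate_pr_epoch(cfg1)
  spec1 <- build_threshold_spec(
    annotation_from_truth(sim1$stack, sim1$ground_truth,
                          hbs_dur_ms = cfg1$hbs_dur),
    epochs = sim1$stack)
  out1 <- run_pipeline(sim1$stack, spec1)
  win <- hbs_window(sim1, cfg1)
  expect_gt(max(abs(out1$epochs[1L, win])), 0.5 * cfg1$hbs_amp)
  # determinism: identical inputs give identical outputs
  out1b <- run_pipeline(sim1$stack, spec1)
  expect_identical(out1$epochs, out1b$epochs)
})

test_that("pipeline raises atrial-band suppression and His-band preservation", {
  cfg <- default_cfg()
  s <- sim_with_spec(cfg)
  out <- run_pipeline(s$sim$stack, s$spec)
  raw_avg <- signal_average(s$sim$stack)$samples
  ext_avg <- signal_average(out)$samples
  fs <- cfg$fs
  ser_p <- ser(raw_avg, ext_avg, c(5, 30), fs)
  ser_h <- ser(raw_avg, ext_avg, c(75, 100), fs)
  ser_n <- ser(raw_avg, ext_avg, c(150, 200), fs)
  expect_gt(ser_h, ser_p)
  expect_gt(ser_h, ser_n)
})

test_that("extraction correlation does not degrade with increasing SNR", {
  cur <- correlation_vs_snr_curve("type1", snr_grid = c(5, 14, 28),
                                  n_reps = 30, seed = 17)
  expect_true(all(diff(cur$mean_r) > -0.05))
  expect_gt(cur$mean_r[3], cur$mean_r[1])
})
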