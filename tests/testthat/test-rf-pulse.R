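test_that("sinc pulse design satisfies the time-bandwidth relation", {
  p <- design_sinc_pulse(30 * pi / 180, kappa = 10, delta = 5e-3, T_ex = 1e-3,
                         n_samples = 200)
  expect_equal(2 * pi * p$kappa, gamma_1h * p$G * p$T_ex * p$delta,
               tolerance = 1e-12)
  # zero flip -> zero envelope; amplitude scaling is linear
  expect_true(all(Mod(design_sinc_pulse(0, n_samples = 64)$b1) == 0))
  p2 <- design_sinc_pulse(60 * pi / 180, kappa = 10, delta = 5e-3,
                          T_ex = 1e-3, n_samples = 200)
  expect_equal(p2$b1, 2 * p$b1, tolerance = 1e-12)
})

test_that("hard-pulse flips integrate the envelope", {
  p <- design_sinc_pulse(70 * pi / 180, n_samples = 1000)
  hp <- hard_pulse_flips(p)
  expect_true(all(hp$alpha >= 0))
  # signed sum reproduces the nominal flip exactly (amplitude calibration)
  expect_equal(sum(hp$alpha * cos(hp$phi)), 70 * pi / 180, tolerance = 1e-12)
  # the n = 1000 midpoint quadrature of the analytic Hann-sinc envelope
  # agrees with a dense trapezoidal oracle to better than 0.1%
  shape <- function(t, T_ex, kappa) {
    x <- (t - T_ex / 2) / (T_ex / kappa)
    s <- ifelse(abs(x) < 1e-12, 1, sin(pi * x) / (pi * x))
    s * (0.5 - 0.5 * cos(2 * pi * t / T_ex))
  }
  tt <- seq(0, 1e-3, length.out = 20001)
  dense <- sum((shape(tt[-1], 1e-3, 10) + shape(tt[-length(tt)], 1e-3, 10)) / 2) *
    diff(tt)[1]
  coarse <- sum(shape((1:1000 - 0.5) * 1e-6, 1e-3, 10)) * 1e-6
  expect_equal(coarse, dense, tolerance = 1e-3)
  # constant envelope: identical flips summing to gamma * B1 * T_ex
  pc <- p; pc$b1 <- rep(1e-6 + 0i, 100); pc$dt <- 1e-5; pc$T_ex <- 1e-3
  hpc <- hard_pulse_flips(pc)
  expect_equal(length(unique(hpc$alpha)), 1L)
  expect_equal(sum(hpc$alpha), gamma_1h * 1e-6 * 1e-3, tolerance = 1e-12)
})

test_that("focus point sits at the pulse center and is locally optimal", {
  p <- design_sinc_pulse(5 * pi / 180, n_samples = 128)
  g <- spatial_grid(201, 3 * p$delta)
  tf <- focus_point(p, g)
  expect_lt(abs(tf - p$T_ex / 2), p$dt)
  # local optimality of the FID objective
  eff <- effective_rf(p, gradient_scheme(0, 0), g)
  obj <- function(t) Mod(sum(exp(-1i * gamma_1h * p$G * t * g$centers) * eff$ops[, 7]))
  expect_gte(obj(tf) + 1e-12, obj(tf + p$dt))
  expect_gte(obj(tf) + 1e-12, obj(tf - p$dt))
  # amplitude invariance in the small-tip regime
  p8 <- design_sinc_pulse(8 * pi / 180, n_samples = 128)
  expect_lt(abs(focus_point(p8, g) - tf), p$dt)
  expect_error(focus_point(design_sinc_pulse(0, n_samples = 64), g),
               "degenerate")
})

test_that("effective RF reduces correctly in degenerate configurations", {
  p0 <- design_sinc_pulse(0, n_samples = 64)
  g <- spatial_grid(51, 15e-3)
  grads <- default_gradient_scheme(p0, k_post = -gamma_1h * p0$G * p0$T_ex / 2)
  # zero envelope with moment-balanced gradients: identity at every z
  eff <- effective_rf(p0, grads, g)
  id9 <- rep(c(1, 0, 0, 0, 1, 0, 0, 0, 1), each = g$n_bins)
  expect_equal(as.vector(eff$ops), id9 + 0i, tolerance = 1e-12)
  # on-axis bin: pure composition of the hard pulses, no precession
  p <- design_sinc_pulse(40 * pi / 180, n_samples = 64)
  eff <- effective_rf(p, grads, g)
  hp <- hard_pulse_flips(p)
  acc <- diag(3) + 0i
  for (i in seq_along(hp$alpha)) {
    acc <- rotation_operator(hp$alpha[i], hp$phi[i])[1:3, 1:3] %*% acc
  }
  center <- (g$n_bins + 1) / 2
  expect_equal(as.complex(eff$ops[center, ]), as.complex(as.vector(acc)),
               tolerance = 1e-10)
})

test_that("effective RF operators are rotations matching the small-tip profile", {
  p <- design_sinc_pulse(5 * pi / 180, n_samples = 128)
  g <- spatial_grid(201, 3 * p$delta)
  grads <- default_gradient_scheme(p, grid = g)
  eff <- effective_rf(p, grads, g)
  expect_lt(max(Mod(blochepg:::op_determinant(eff$ops) - 1)), 1e-9)
  dec <- euler_decompose(eff)
  t <- (seq_along(p$b1) - 0.5) * p$dt
  oracle <- vapply(g$centers, function(zz) {
    Mod(sum(gamma_1h * p$b1 * p$dt * exp(1i * gamma_1h * p$G * zz * t)))
  }, 0)
  band <- abs(g$centers) <= 0.45 * p$delta
  expect_lt(max(abs(dec$alpha_profile[band] - oracle[band])) / max(oracle), 0.02)
})

test_that("Euler decomposition round-trips and respects its gauge", {
  g1 <- spatial_grid(1, 1e-3)
  # identity -> (0, 0, 0)
  eff_id <- ideal_pulse_rf(g1, 0)
  dec <- euler_decompose(eff_id)
  expect_equal(unlist(dec), c(0, 0, 0), ignore_attr = TRUE)
  # exact round trip of T_{pi/4}(pi/3)
  ops <- recompose_rf(pi / 3, pi / 4, 0)
  dec <- euler_decompose(ops)
  expect_equal(dec$alpha_profile, pi / 3, tolerance = 1e-12)
  expect_equal(dec$phase_profile, pi / 4, tolerance = 1e-12)
  expect_equal(dec$prephase_profile, 0, tolerance = 1e-12)
  # random rotations recompose to the same matrix
  set.seed(3)
  for (rep in 1:25) {
    ops <- recompose_rf(runif(1, 0, pi), runif(1, -pi, pi), runif(1, -pi, pi))
    dec <- euler_decompose(ops)
    rec <- recompose_rf(dec$alpha_profile, dec$phase_profile,
                        dec$prephase_profile)
    expect_lt(max(Mod(rec - ops)), 1e-9)
  }
  # a non-rotation is rejected
  bad <- recompose_rf(1, 0, 0) * 1.01
  expect_error(euler_decompose(bad), "not a rotation")
})

test_that("hard-pulse refinement converges and high flips amplify side lobes", {
  g <- spatial_grid(101, 15e-3)
  ref_pulse <- design_sinc_pulse(70 * pi / 180, n_samples = 2048)
  grads <- default_gradient_scheme(ref_pulse,
                                   k_post = -gamma_1h * ref_pulse$G * ref_pulse$T_ex / 2)
  ref <- euler_decompose(effective_rf(ref_pulse, grads, g))$alpha_profile
  errs <- vapply(c(64, 128, 256), function(ns) {
    p <- design_sinc_pulse(70 * pi / 180, n_samples = ns)
    max(abs(euler_decompose(effective_rf(p, grads, g))$alpha_profile - ref))
  }, 0)
  expect_true(all(diff(errs) < 0))
  # side lobes of the 70 deg profile exceed the linearly scaled 30 deg ones
  p70 <- design_sinc_pulse(70 * pi / 180, n_samples = 256)
  p30 <- design_sinc_pulse(30 * pi / 180, n_samples = 256)
  a70 <- euler_decompose(effective_rf(p70, grads, g))$alpha_profile
  a30 <- euler_decompose(effective_rf(p30, grads, g))$alpha_profile
  lobe <- abs(g$centers) > p70$delta
  expect_gt(max(a70[lobe]), (70 / 30) * max(a30[lobe]))
  # pre-phase profile is flip-independent at small tip
  p2 <- design_sinc_pulse(2 * pi / 180, n_samples = 256)
  p8 <- design_sinc_pulse(8 * pi / 180, n_samples = 256)
  pre2 <- euler_decompose(effective_rf(p2, grads, g))$prephase_profile
  pre8 <- euler_decompose(effective_rf(p8, grads, g))$prephase_profile
  band <- abs(g$centers) <= 0.45 * p2$delta
  expect_lt(max(abs(pre2[band] - pre8[band])), 0.02)
})

test_that("pulse waveform files round-trip", {
  p <- design_sinc_pulse(33 * pi / 180, n_samples = 64)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_pulse_waveform(p, path)
  q <- read_pulse_waveform(path)
  expect_equal(q$b1, p$b1, tolerance = 1e-15)
  expect_equal(q$G, p$G)
  expect_equal(q$kappa, p$kappa)
  expect_equal(q$T_ex, p$T_ex)
  expect_equal(q$nominal_flip, p$nominal_flip)
})
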