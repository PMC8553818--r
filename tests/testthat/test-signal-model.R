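test_that("weighting function matches its closed forms and limits", {
  TR <- 15e-3
  # trivial weight is 1
  sp <- weighting_spec(TR = TR, TE = 0, T2 = 0.05)
  expect_equal(weight(0L, sp), 1 + 0i)
  # Lorentzian read-off: magnitude and phase
  sp <- weighting_spec(TR = TR, TE = 5e-3, T2 = 0.05, omega = 2 * pi * 40,
                       r2prime = 25)
  k <- -3:3
  t <- k * TR + sp$TE
  w <- weight(k, sp)
  expect_equal(Mod(w), exp(-25 * abs(t) - sp$TE / 0.05), tolerance = 1e-12)
  expect_equal(Arg(w), blochepg:::wrap_pi(sp$omega * t), tolerance = 1e-12)
  # Gaussian and spherical reduce to the R2' = 0 Lorentzian as sigma -> 0
  base <- weight(k, weighting_spec(TR = TR, TE = 5e-3, T2 = 0.05,
                                   omega = 2 * pi * 40))
  sigma <- 1e-4 / max(abs(t))   # sigma * t <= 1e-4
  for (kind in c("gaussian", "spherical")) {
    wk <- weight(k, weighting_spec(TR = TR, TE = 5e-3, T2 = 0.05,
                                   omega = 2 * pi * 40, kind = kind,
                                   sigma = sigma))
    expect_lt(max(Mod(wk - base)), 1e-8)
  }
  # multipeak with a single on-resonance peak is the plain Lorentzian
  mp <- weighting_spec(TR = TR, TE = 5e-3, T2 = 0.05, omega = 2 * pi * 40,
                       kind = "multipeak",
                       peaks = data.frame(w = 1, omega = 0, r2prime = 25))
  expect_equal(weight(k, mp), w, tolerance = 1e-12)
  expect_error(weighting_spec(TR = TR, TE = 2 * TR), "TE")
  expect_error(weighting_spec(TR = TR, kind = "multipeak",
                              peaks = data.frame(w = 0.5, omega = 0,
                                                 r2prime = 0)),
               "sum to 1")
})

test_that("discretization kernel has the stated damping structure", {
  g <- spatial_grid(25, 15e-3)
  # k = 0: dz for every bin
  expect_equal(kernel_fourier(0L, 5000, g), rep(g$dz + 0i, 25))
  # damping factor vanishes exactly at the aliasing onset k*k_sp*dz = 2*pi
  k_sp <- 2 * pi / (3 * g$dz)
  expect_lt(max(Mod(kernel_fourier(3L, k_sp, g))), 1e-15)
  # large spoiling suppresses all k != 0 (pEPG limit of the kernel):
  # |sinc(x)| <= 1/x, so the damping shrinks as 1/k_sp
  big <- 1e12
  expect_lt(max(Mod(kernel_fourier(2L, big, g))) / g$dz, 1 / (big * g$dz))
  expect_equal(kernel_fourier(0L, big, g), rep(g$dz + 0i, 25))
})

test_that("signal assembly reduces to the expected closed forms", {
  # single-bin grid, one ideal 90: s = -i * dz
  g1 <- spatial_grid(1, 1e-3)
  st <- epg_apply_rf(init_states(g1, 2), ideal_pulse_rf(g1, pi / 2))
  st$n_index <- 1L
  sp <- trivial_spec()
  expect_equal(epg_signal(st, k_sp = 1234, q = 0L, spec = sp),
               -1i * g1$dz, tolerance = 1e-12)
  expect_error(epg_signal(st, 0, q = 5L, spec = sp), "echo order")
})

test_that("bSSFP specialization equals the k_sp = 0 signal and is periodic in omega", {
  fx <- mini_fixture(n_pulses = 12L)
  rf <- effective_rf_train(fx$pulse, fx$seq, fx$grads, fx$grid)
  run <- run_sr_epg(fx$seq, fx$tissue, rf)
  st <- run$states
  TR <- fx$seq$TR
  for (omega in c(0, 70, -211)) {
    sp <- weighting_spec(TR = TR, T2 = fx$tissue$T2, omega = omega)
    expect_equal(signal_bssfp(st, sp), epg_signal(st, 0, 0L, sp),
                 tolerance = 1e-14)
    # echo-order degeneracy at k_sp = 0
    for (q in c(-1L, 1L, -2L)) {
      expect_equal(epg_signal(st, 0, q, sp), signal_bssfp(st, sp),
                   tolerance = 1e-12)
    }
    # 2*pi/TR periodicity of the frequency response at TE = 0
    sp2 <- weighting_spec(TR = TR, T2 = fx$tissue$T2, omega = omega + 2 * pi / TR)
    expect_equal(signal_bssfp(st, sp2), signal_bssfp(st, sp), tolerance = 1e-10)
  }
  # with only order 0 occupied the bSSFP signal is omega-independent at TE = 0
  g <- mini_grid(11)
  st0 <- epg_apply_rf(init_states(g, 2), ideal_pulse_rf(g, pi / 3))
  st0$n_index <- 1L
  expect_equal(signal_bssfp(st0, weighting_spec(TR = 0.015, T2 = 0.05, omega = 500)),
               signal_bssfp(st0, weighting_spec(TR = 0.015, T2 = 0.05)),
               tolerance = 1e-14)
})

test_that("pEPG is the strong-spoiling limit with omega-invariant magnitude", {
  fx <- mini_fixture(n_pulses = 12L, n_bins = 300L, round_moments = FALSE)
  rf <- effective_rf_train(fx$pulse, fx$seq, fx$grads, fx$grid)
  st <- run_sr_epg(fx$seq, fx$tissue, rf)$states
  # on a commensurate grid (k_sp * dz a multiple of 2*pi) the damping factor
  # kills every k != q exactly, so the identity is machine-precision
  ksp_big <- 1e6 * 2 * pi / fx$pulse$delta
  for (q in c(0L, -1L)) {
    sp <- weighting_spec(TR = fx$seq$TR, T2 = fx$tissue$T2, omega = 120)
    expect_lt(Mod(epg_signal(st, ksp_big, q, sp) - signal_pepg(st, q, sp)) /
                Mod(signal_pepg(st, q, sp)), 1e-9)
  }
  # |s_pepg| does not depend on omega
  mags <- vapply(c(0, 50, -300, 1000), function(w) {
    Mod(signal_pepg(st, 0L, weighting_spec(TR = fx$seq$TR, T2 = fx$tissue$T2,
                                           omega = w)))
  }, 0)
  expect_lt(diff(range(mags)), 1e-15)
  # unoccupied order gives zero
  expect_equal(signal_pepg(st, 13L, trivial_spec()), 0 + 0i)
})

test_that("profile and k-space recovery are mutually consistent", {
  fx <- mini_fixture(n_pulses = 10L)
  rf <- effective_rf_train(fx$pulse, fx$seq, fx$grads, fx$grid)
  st <- run_sr_epg(fx$seq, fx$tissue, rf)$states
  sp <- weighting_spec(TR = fx$seq$TR, T2 = fx$tissue$T2, omega = 80)
  ksp <- fx$seq$k_sp
  # uniform ideal 90: M+ = -i everywhere
  g <- mini_grid(11)
  st90 <- epg_apply_rf(init_states(g, 2), ideal_pulse_rf(g, pi / 2))
  st90$n_index <- 1L
  expect_equal(recover_bloch_profile(st90, 500, 0L, trivial_spec()),
               rep(-1i, g$n_bins), tolerance = 1e-12)
  # DC component of the k-space equals the signal
  s <- epg_signal(st, ksp, 0L, sp)
  expect_equal(recover_kspace(st, ksp, 0L, sp, 0), s, tolerance = 1e-12)
  # single occupied order: k-space is the plain DFT of that order
  stq <- init_states(fx$grid, 3)
  set.seed(5)
  stq$f_plus[, stq$k0] <- complex(real = rnorm(fx$grid$n_bins),
                                  imaginary = rnorm(fx$grid$n_bins))
  stq$n_index <- 1L
  kp <- seq(-3, 3, length.out = 11) * 2 * pi / fx$grid$fov
  got <- recover_kspace(stq, ksp, 0L, trivial_spec(), kp)
  oracle <- vapply(kp, function(k) {
    fx$grid$dz * sum(exp(-1i * k * fx$grid$centers) * stq$f_plus[, stq$k0])
  }, 0i)
  expect_equal(got, oracle, tolerance = 1e-12)
  # at k_sp = 0 and TE = 0 the profile is the order sum weighted by e^{i k w TR}
  prof <- recover_bloch_profile(st, 0, 0L, sp)
  ks <- state_orders(st)
  w <- weight(ks, sp)
  manual <- as.vector(st$f_plus[, blochepg:::occ_cols(st)] %*% w)
  expect_equal(prof, manual, tolerance = 1e-12)
})

test_that("a local field gradient enters as a shift of the spoiling moment", {
  fx <- mini_fixture(n_pulses = 8L)
  rf <- effective_rf_train(fx$pulse, fx$seq, fx$grads, fx$grid)
  run <- run_sr_epg(fx$seq, fx$tissue, rf)
  sp <- weighting_spec(TR = fx$seq$TR, T2 = fx$tissue$T2)
  g0 <- 0.07 * 2 * pi / fx$pulse$delta   # local gradient, rad/m per TR
  # hybrid: same engine run, spoiling moment shifted analytically;
  # oracle: Bloch simulation with the gradient folded into its per-TR phase
  seq2 <- fx$seq; seq2$k_sp <- fx$seq$k_sp + g0
  bl <- bloch_run(seq2, fx$tissue, fx$pulse, fx$grads, fx$grid)
  s_h <- epg_signal(run$states, fx$seq$k_sp + g0, 0L, sp)
  s_b <- bl$signal[length(fx$seq$flip_train)]
  expect_lt(Mod(s_h - s_b) / Mod(s_b), 1e-3)
})

test_that("minimal spoiling moment follows the excitation k-space bound", {
  expect_equal(min_spoiling_moment(10, 5e-3), pi * 10 / 5e-3)
  p <- design_sinc_pulse(30 * pi / 180, kappa = 10, delta = 5e-3,
                         n_samples = 64)
  expect_equal(min_spoiling_moment(p$kappa, p$delta),
               gamma_1h * p$G * p$T_ex / 2, tolerance = 1e-12)
})
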