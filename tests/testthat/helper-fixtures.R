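# Miniature simulation setups shared across tests. Sizes are deliberately
# small (N <= 301 bins, <= 24 repetitions, <= 100 hard-pulse steps) so the
# unit suite stays fast; the acceptance tests use the full study sizes.

mini_fixture <- function(n_pulses = 16L, n_samples = 64L, n_bins = 301L,
                         round_moments = TRUE, ...) {
  build_fixture_sequence(n_pulses = n_pulses, n_samples = n_samples,
                         n_bins = n_bins, round_moments = round_moments, ...)
}

mini_grid <- function(n_bins = 101L, fov = 15e-3) spatial_grid(n_bins, fov)

trivial_spec <- function(TR = 15e-3, ...) {
  weighting_spec(TR = TR, TE = 0, T2 = Inf, ...)
}

# Independent Cartesian rotation oracle: Rodrigues rotation about an axis in
# the transverse plane at azimuth phi, then map (Mx, My, Mz) to the +/- basis.
cartesian_pulse_oracle <- function(alpha, phi, m) {
  mx <- Re(m[1] + m[2]) / 2
  my <- Re((m[1] - m[2]) / 2i)
  mz <- Re(m[3])
  axis <- c(cos(phi), sin(phi), 0)
  v <- c(mx, my, mz)
  ca <- cos(alpha); sa <- sin(alpha)
  rot <- v * ca + pracma_cross(axis, v) * sa + axis * sum(axis * v) * (1 - ca)
  c(complex(real = rot[1], imaginary = rot[2]),
    complex(real = rot[1], imaginary = -rot[2]),
    rot[3] + 0i, m[4])
}

pracma_cross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# Hermiticity residual of a configuration-state object:
# F-_k = Conj(F+_{-k}), Z_{-k} = Conj(Z_k).
hermiticity_residual <- function(states) {
  rev_cols <- rev(seq_len(ncol(states$f_plus)))
  max(Mod(states$f_minus - Conj(states$f_plus[, rev_cols])),
      Mod(states$z_comp - Conj(states$z_comp[, rev_cols])))
}

random_hermitian_states <- function(grid, K = 4L, kmax = 2L, seed = 42L) {
  set.seed(seed)
  st <- init_states(grid, K)
  n <- grid$n_bins
  for (k in 0:kmax) {
    fp <- complex(real = rnorm(n), imaginary = rnorm(n))
    fm <- complex(real = rnorm(n), imaginary = rnorm(n))
    zc <- complex(real = rnorm(n), imaginary = rnorm(n))
    st$f_plus[, st$k0 + k] <- fp
    st$f_minus[, st$k0 - k] <- Conj(fp)
    st$f_plus[, st$k0 - k] <- Conj(fm)
    st$f_minus[, st$k0 + k] <- fm
    st$z_comp[, st$k0 + k] <- zc
    st$z_comp[, st$k0 - k] <- Conj(zc)
  }
  st$z_comp[, st$k0] <- complex(real = rnorm(n))  # order 0 must be real
  st$kmax <- kmax
  st$n_index <- kmax
  st
}
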