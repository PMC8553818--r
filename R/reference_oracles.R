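build_alpha_matrix <- function(pulse, seq) {
  base <- signed_flips(pulse)
  if (pulse$nominal_flip == 0) stop("base pulse has zero flip", call. = FALSE)
  outer(base, seq$flip_train / pulse$nominal_flip)
}

#' Direct Bloch (isochromat) reference simulation
#'
#' Independent spatial-domain solution via the rotation-operator algorithm in
#' Cartesian coordinates: per repetition, phase accrual `omega*TR + k_sp*z`,
#' relaxation over TR, then the slice-selective pulse as a hard-pulse train
#' (prewinder, Rodrigues rotations alternating with gradient precession,
#' refocuser). Off-resonance and spoiling enter numerically here, unlike in
#' the hybrid engine. Microscopic dephasing (R2') is not simulated.
#'
#' @param seq an `mrf_sequence` (its `k_sp`, `TE`, `q` are used).
#' @param tissue a `tissue_params`.
#' @param pulse base `pulse_waveform`; per-TR pulses are amplitude-scaled to
#'   `seq$flip_train`.
#' @param grads a `gradient_scheme`.
#' @param grid a `spatial_grid` of isochromat positions (caller should check
#'   [aliasing_kmax()] against the number of repetitions).
#' @param coil per-isochromat coil sensitivity (default 1).
#' @return list with `profiles` (N x nTR complex matrix of M+ directly after
#'   each RF pulse), `profiles_echo` (at TE with the echo-q phase), and
#'   `signal` (complex vector per repetition, `dz * sum(coil * M+_echo)`).
#' @export
bloch_run <- function(seq, tissue, pulse, grads, grid, coil = 1) {
  stopifnot(inherits(seq, "mrf_sequence"), inherits(tissue, "tissue_params"),
            inherits(grid, "spatial_grid"))
  alphas <- build_alpha_matrix(pulse, seq)
  z <- grid$centers
  profiles <- cpp_bloch_train(
    alphas, seq$phase_train,
    gamma_1h * pulse$G * pulse$dt * z,
    grads$k_pre * z, grads$k_post * z,
    tissue$omega * seq$TR + seq$k_sp * z,
    exp(-seq$TR / tissue$T1), exp(-seq$TR / tissue$T2),
    isTRUE(seq$invert_first))
  omega <- tissue$omega
  echo_phase <- exp(-1i * seq$q * seq$k_sp * z + 1i * omega * seq$TE)
  e2te <- exp(-seq$TE / tissue$T2)
  profiles_echo <- profiles * (e2te * echo_phase)
  signal <- grid$dz * as.vector(crossprod(rep_len(coil + 0i, grid$n_bins),
                                          profiles_echo))
  list(profiles = profiles, profiles_echo = profiles_echo, signal = signal,
       grid = grid)
}

#' Slice-selective EPG reference simulation
#'
#' Independent Fourier-domain solution: the hard-pulse approximation is
#' carried out on a fine k-space lattice with state increment
#' `dk = gamma * G * dt`. Spoiling, prewinder and refocusing moments are
#' rounded to integer multiples of `dk` (residuals are reported); the pulse
#' itself shifts the lattice by exactly one increment per hard pulse. States
#' are truncated only on lattice overflow, never by magnitude.
#'
#' @inheritParams bloch_run
#' @param q_orders integer vector of echo orders to record per repetition
#'   (default: the sequence's own `q`).
#' @return list with `dk`, `period` (2*pi/dk), `kprime` (lattice frequencies),
#'   `f_plus`/`f_minus`/`z_comp` (final state over the lattice), `signals`
#'   (complex matrix, one row per requested echo order, coefficient scale),
#'   `signal` (first echo order at TE, integral scale: coefficient * period),
#'   `rounding_residuals`, and the integer moments used.
#' @export
ssepg_run <- function(seq, tissue, pulse, grads, q_orders = NULL) {
  stopifnot(inherits(seq, "mrf_sequence"), inherits(tissue, "tissue_params"))
  if (pulse$G == 0 || pulse$dt == 0) {
    stop("degenerate lattice: zero gradient or time step", call. = FALSE)
  }
  if (is.null(q_orders)) q_orders <- seq$q
  dk <- gamma_1h * pulse$G * pulse$dt
  moments <- c(k_sp = seq$k_sp, k_pre = grads$k_pre, k_post = grads$k_post)
  steps <- round(moments / dk)
  residuals <- moments - steps * dk
  alphas <- build_alpha_matrix(pulse, seq)
  n_steps <- nrow(alphas)
  nTR <- ncol(alphas)
  m_max <- nTR * (abs(steps[["k_sp"]]) + abs(steps[["k_pre"]]) +
                    abs(steps[["k_post"]]) + n_steps) + n_steps + 8L
  out <- cpp_ssepg_train(alphas, seq$phase_train,
                         as.integer(steps[["k_pre"]]),
                         as.integer(steps[["k_post"]]),
                         as.integer(steps[["k_sp"]]),
                         tissue$omega * seq$TR,
                         exp(-seq$TR / tissue$T1), exp(-seq$TR / tissue$T2),
                         isTRUE(seq$invert_first), as.integer(q_orders),
                         as.integer(m_max))
  period <- 2 * pi / dk
  te_fac <- exp(-seq$TE / tissue$T2 + 1i * tissue$omega * seq$TE)
  kprime <- (seq_along(out$f_plus) - out$m0_index) * dk
  signals <- out$signals * te_fac
  list(dk = dk, period = period, kprime = kprime,
       f_plus = out$f_plus, f_minus = out$f_minus, z_comp = out$z_comp,
       m0_index = out$m0_index, signals = signals,
       signal = signals[match(seq$q, q_orders), ] * period,
       rounding_residuals = residuals, moment_steps = steps)
}

#' Normalized RMSE between slice profiles
#'
#' RMS of the complex difference over z, normalized by the magnitude of the
#' spatial mean of the reference (Bloch) profile.
#'
#' @param reference,test complex vectors of equal length.
#' @return non-negative fraction.
#' @export
nrmse_bloch <- function(reference, test) {
  if (length(reference) != length(test)) stop("profile length mismatch", call. = FALSE)
  norm <- Mod(mean(reference))
  if (norm < .Machine$double.eps) {
    stop("degenerate normalization: reference profile has zero mean", call. = FALSE)
  }
  sqrt(mean(Mod(reference - test)^2)) / norm
}

#' Normalized RMSE between k-space representations
#'
#' RMS over k of the complex difference, normalized by the magnitude of the
#' spatial mean of the Bloch reference profile (so profile- and k-space-level
#' errors share one scale).
#'
#' @param kspace_a,kspace_b complex vectors of equal length.
#' @param bloch_profile complex slice profile providing the normalization.
#' @return non-negative fraction.
#' @export
nrmse_ssepg <- function(kspace_a, kspace_b, bloch_profile) {
  if (length(kspace_a) != length(kspace_b)) stop("k-space length mismatch", call. = FALSE)
  norm <- Mod(mean(bloch_profile))
  if (norm < .Machine$double.eps) {
    stop("degenerate normalization: reference profile has zero mean", call. = FALSE)
  }
  sqrt(mean(Mod(kspace_a - kspace_b)^2)) / norm
}
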