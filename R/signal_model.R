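#' Unnormalized sinc
#'
#' `sin(x)/x` with `sinc(0) = 1`; the damping factor of the piecewise-constant
#' discretization kernel uses this convention.
#'
#' @param x numeric.
#' @return numeric.
#' @export
sinc <- function(x) ifelse(x == 0, 1, sin(x) / x)

#' Configuration-state weighting specification
#'
#' Collects the analytic axes entering the weighting function W_k: global
#' off-resonance, microscopic dephasing, echo time, and the line-shape model
#' for the off-resonance distribution.
#'
#' @param TR repetition time (s).
#' @param TE echo time (s), `0 <= TE <= TR`.
#' @param T2 transverse relaxation time (s).
#' @param omega global off-resonance (rad/s).
#' @param kind one of `"lorentzian"` (exponential R2' decay),
#'   `"gaussian"` / `"spherical"` (width `sigma`), `"multipeak"` (sum of
#'   Lorentzian peaks), or `"custom"` (user characteristic function).
#' @param r2prime Lorentzian line width R2' (1/s).
#' @param sigma Gaussian / spherical width (rad/s).
#' @param peaks for `"multipeak"`: data.frame with columns `w` (weights,
#'   summing to 1), `omega` (rad/s), `r2prime` (1/s).
#' @param p_tilde for `"custom"`: a function of time t returning the
#'   characteristic function (time-domain Fourier transform) of the
#'   off-resonance distribution.
#' @return list of class `weighting_spec`.
#' @export
weighting_spec <- function(TR, TE = 0, T2 = Inf, omega = 0,
                           kind = c("lorentzian", "gaussian", "spherical",
                                    "multipeak", "custom"),
                           r2prime = 0, sigma = 0, peaks = NULL,
                           p_tilde = NULL) {
  kind <- match.arg(kind)
  if (TE < 0 || TE > TR) stop("TE must lie in [0, TR]", call. = FALSE)
  if (T2 <= 0) stop("T2 must be positive", call. = FALSE)
  if (kind == "multipeak") {
    stopifnot(is.data.frame(peaks), all(c("w", "omega", "r2prime") %in% names(peaks)))
    if (abs(sum(peaks$w) - 1) > 1e-8) {
      stop("multipeak weights must sum to 1", call. = FALSE)
    }
  }
  if (kind == "custom" && !is.function(p_tilde)) {
    stop("custom weighting needs a `p_tilde` function", call. = FALSE)
  }
  structure(list(TR = TR, TE = TE, T2 = T2, omega = omega, kind = kind,
                 r2prime = r2prime, sigma = sigma, peaks = peaks,
                 p_tilde = p_tilde), class = "weighting_spec")
}

#' Analytic configuration-state weighting W_k
#'
#' For order k the weighting acts on the echo formed at time `t = k*TR + TE`:
#' Lorentzian gives `exp(i omega t - R2'*|t| - TE/T2)`; Gaussian replaces the
#' R2' term by `exp(-sigma^2 t^2 / 2)`; the spherical line shape uses the
#' Bessel ratio `J1(2 sigma t) / (sigma t)` (limit 1 at t = 0); multipeak is
#' the weighted sum of Lorentzian weights at shifted frequencies; custom uses
#' the supplied characteristic function.
#'
#' @param k integer order(s).
#' @param spec a [weighting_spec()].
#' @return complex vector of weights, one per order.
#' @export
weight <- function(k, spec) {
  stopifnot(inherits(spec, "weighting_spec"))
  t <- k * spec$TR + spec$TE
  te_decay <- if (is.finite(spec$T2)) exp(-spec$TE / spec$T2) else 1
  base <- exp(1i * spec$omega * t) * te_decay
  switch(spec$kind,
    lorentzian = base * exp(-spec$r2prime * abs(t)),
    gaussian = base * exp(-spec$sigma^2 * t^2 / 2),
    spherical = base * bessel_ratio(spec$sigma, t),
    multipeak = {
      acc <- 0 + 0i
      for (j in seq_len(nrow(spec$peaks))) {
        acc <- acc + spec$peaks$w[j] *
          exp(1i * spec$peaks$omega[j] * t - spec$peaks$r2prime[j] * abs(t))
      }
      base * acc
    },
    custom = base * spec$p_tilde(t)
  )
}

bessel_ratio <- function(sigma, t) {
  x <- sigma * t
  out <- rep(1, length(x))
  nz <- abs(x) > 1e-12
  out[nz] <- besselJ(2 * abs(x[nz]), 1) / abs(x[nz])
  out
}

#' Fourier transform of the discretization kernel
#'
#' For the piecewise-constant bin kernel:
#' `F_{k,i}(k_sp) = dz * sinc(k * k_sp * dz / 2) * exp(i k k_sp z_i)`. The
#' sinc term is the damping factor accounting for intra-bin dephasing of
#' order-k states; it vanishes when `k * k_sp * dz = 2*pi` (aliasing onset).
#'
#' @param k integer order (scalar).
#' @param k_sp spoiling moment (rad/m).
#' @param grid a `spatial_grid`.
#' @return complex vector, one value per bin.
#' @export
kernel_fourier <- function(k, k_sp, grid) {
  stopifnot(inherits(grid, "spatial_grid"))
  grid$dz * sinc(k * k_sp * grid$dz / 2) * exp(1i * k * k_sp * grid$centers)
}

#' Hybrid Bloch-EPG signal
#'
#' Assembles the complex signal of echo order `q` from spatially-resolved
#' configuration states:
#' `s = sum_k W_k sum_i coil_i m0_i F_{k-q,i}(k_sp) F+_{k,i}`.
#' All analytic axes (TE, omega, R2', k_sp, q) are evaluated here without
#' re-running the engine.
#'
#' @param states a `config_states`.
#' @param k_sp spoiling moment (rad/m).
#' @param q refocused echo order (integer; 0 = FID/GRE, -1 = PSIF-type echo).
#' @param spec a [weighting_spec()]; its TR must match the sequence TR.
#' @param coil,m0 per-bin coil sensitivity and equilibrium magnetization
#'   (scalars or vectors; default spatially constant 1).
#' @param damping apply the intra-bin sinc damping factor (TRUE; FALSE
#'   reproduces the aliasing behavior of an equally discretized Bloch
#'   simulation).
#' @return complex scalar.
#' @export
epg_signal <- function(states, k_sp, q = 0L, spec, coil = 1, m0 = 1,
                       damping = TRUE) {
  stopifnot(inherits(states, "config_states"))
  ks <- state_orders(states)
  if (abs(q) > states$K) stop("echo order exceeds configuration range", call. = FALSE)
  grid <- states$grid
  z <- grid$centers
  w <- occ_cols(states)
  phase <- exp(1i * outer(z, (ks - q) * k_sp))
  damp <- if (damping) sinc((ks - q) * k_sp * grid$dz / 2) else rep(1, length(ks))
  weights <- weight(ks, spec)
  inner <- colSums((coil * m0) * phase * states$f_plus[, w, drop = FALSE])
  grid$dz * sum(weights * damp * inner)
}

#' Balanced SSFP signal (k_sp = 0 special case)
#'
#' With vanishing spoiling moment the kernel reduces to `dz` for every order,
#' the echo order becomes degenerate, and the signal is the plain weighted
#' sum of slice-integrated configurations.
#'
#' @inheritParams epg_signal
#' @return complex scalar.
#' @export
signal_bssfp <- function(states, spec, coil = 1, m0 = 1) {
  epg_signal(states, k_sp = 0, q = 0L, spec = spec, coil = coil, m0 = m0)
}

#' Partitioned-EPG signal (k_sp -> infinity limit)
#'
#' In the infinite-spoiling limit only the refocused order q contributes:
#' `s = dz * W_q * sum_i coil_i m0_i F+_{q,i}`. Its magnitude carries no
#' off-resonance dependency beyond the trivial phase accrual.
#'
#' @inheritParams epg_signal
#' @return complex scalar.
#' @export
signal_pepg <- function(states, q = 0L, spec, coil = 1, m0 = 1) {
  stopifnot(inherits(states, "config_states"))
  if (abs(q) > states$K) stop("echo order exceeds configuration range", call. = FALSE)
  if (abs(q) > states$kmax) return(0 + 0i)
  wq <- weight(q, spec)
  states$grid$dz * wq * sum(coil * m0 * states$f_plus[, states$k0 + q])
}

#' Recover the Bloch slice profile from configuration states
#'
#' Per-bin transverse magnetization of echo order q at echo time TE:
#' `M+(z_i) = m0_i sum_k W_k e^{i (k-q) k_sp z_i} F+_{k,i}` — the
#' superposition of weighted configurations that a direct Bloch simulation
#' would produce at the bin centers.
#'
#' @inheritParams epg_signal
#' @return complex vector, one value per bin.
#' @export
recover_bloch_profile <- function(states, k_sp, q = 0L, spec, m0 = 1) {
  stopifnot(inherits(states, "config_states"))
  ks <- state_orders(states)
  grid <- states$grid
  w <- occ_cols(states)
  phase <- exp(1i * outer(grid$centers, (ks - q) * k_sp))
  weights <- weight(ks, spec)
  m0 * as.vector((phase * states$f_plus[, w, drop = FALSE]) %*% weights)
}

#' Recover the slice-selective EPG k-space view
#'
#' Spatial Fourier transform of the weighted configuration superposition:
#' `F+(k') = m0 dz sum_k W_k sinc((k-q) k_sp dz/2)
#'           sum_i e^{i ((k-q) k_sp - k') z_i} F+_{k,i}`.
#' The MR signal is the DC component `F+(k' = 0)`.
#'
#' @inheritParams epg_signal
#' @param kprime numeric vector of spatial frequencies (rad/m).
#' @return complex vector, one value per `kprime`.
#' @export
recover_kspace <- function(states, k_sp, q = 0L, spec, kprime, m0 = 1) {
  stopifnot(inherits(states, "config_states"))
  ks <- state_orders(states)
  grid <- states$grid
  z <- grid$centers
  w <- occ_cols(states)
  damp <- sinc((ks - q) * k_sp * grid$dz / 2)
  weights <- weight(ks, spec)
  # collapse the order sum per bin first; the k' dependence then factorizes
  # into a single non-uniform DFT of the collapsed profile
  g <- as.vector((exp(1i * outer(z, (ks - q) * k_sp)) *
                    states$f_plus[, w, drop = FALSE]) %*% (weights * damp))
  m0 * grid$dz * as.vector(exp(-1i * outer(kprime, z)) %*% g)
}

#' Minimal spoiling moment for a slice-selective pulse
#'
#' Half the slice-gradient moment, `k_sp >= gamma G T_ex / 2 = pi*kappa/delta`:
#' the smallest spoiling moment that fully dephases the transverse
#' magnetization excited by a single pulse in the small-tip regime.
#'
#' @param kappa time-bandwidth product.
#' @param delta slice thickness (m).
#' @return moment in rad/m.
#' @export
min_spoiling_moment <- function(kappa, delta) pi * kappa / delta
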