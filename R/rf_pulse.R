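#' Spatial discretization grid along the slice direction
#'
#' `n_bins` equidistant bins of width `dz = fov / n_bins`, centered at
#' positions symmetric about z = 0.
#'
#' @param n_bins number of bins N.
#' @param fov spatial extent in meters.
#' @return list with `n_bins`, `fov`, `dz`, `centers`; class `spatial_grid`.
#' @export
spatial_grid <- function(n_bins, fov) {
  stopifnot(n_bins >= 1, fov > 0)
  dz <- fov / n_bins
  centers <- (seq_len(n_bins) - (n_bins + 1) / 2) * dz
  structure(list(n_bins = as.integer(n_bins), fov = fov, dz = dz,
                 centers = centers), class = "spatial_grid")
}

#' Gradient moments surrounding a slice-selective pulse
#'
#' @param k_pre pre-winder zeroth moment (rad/m), played before the pulse.
#' @param k_post refocusing zeroth moment (rad/m), played after the pulse.
#' @return list of class `gradient_scheme`.
#' @export
gradient_scheme <- function(k_pre, k_post) {
  .check_finite(k_pre, "k_pre"); .check_finite(k_post, "k_post")
  structure(list(k_pre = k_pre, k_post = k_post), class = "gradient_scheme")
}

#' Default moment-balanced gradient scheme
#'
#' Given the refocusing moment, the pre-winder is chosen so that the total
#' zeroth moment across pre-winder, slice gradient and refocuser vanishes:
#' `k_pre = -(gamma * G * T_ex + k_post)`. With `k_post = -gamma * G * t_f`
#' and the focus point near the pulse center, pre-winder and refocuser carry
#' (almost) equal negative areas.
#'
#' @param pulse a `pulse_waveform`.
#' @param k_post refocusing moment (rad/m); default from [focus_point()] run
#'   on a coarse internal grid.
#' @param grid optional `spatial_grid` used for the focus-point search.
#' @return `gradient_scheme`.
#' @export
default_gradient_scheme <- function(pulse, k_post = NULL, grid = NULL) {
  if (is.null(k_post)) {
    if (is.null(grid)) grid <- spatial_grid(301L, 3 * pulse$delta)
    tf <- focus_point(pulse, grid)
    k_post <- -gamma_1h * pulse$G * tf
  }
  gradient_scheme(k_pre = -(gamma_1h * pulse$G * pulse$T_ex + k_post),
                  k_post = k_post)
}

#' Design a Hann-apodized sinc excitation pulse
#'
#' Real-valued sinc envelope with time-bandwidth product `kappa` (i.e.
#' `kappa` zero-crossing intervals across the pulse duration) under a Hann
#' window, sampled at interval midpoints. The slice-select gradient follows
#' from `2*pi*kappa = gamma * G * T_ex * delta`; samples are scaled so that
#' `gamma * sum(B1) * dt` equals the nominal flip angle exactly.
#'
#' @param nominal_flip target on-resonance flip angle in radians.
#' @param kappa time-bandwidth product (dimensionless, > 0).
#' @param delta nominal slice thickness in meters.
#' @param T_ex pulse duration in seconds.
#' @param n_samples number of hard-pulse samples (>= 16).
#' @param apodization `"hann"` or `"none"`.
#' @return list of class `pulse_waveform` with fields `b1` (complex, tesla),
#'   `dt`, `T_ex`, `G`, `kappa`, `delta`, `nominal_flip`.
#' @export
design_sinc_pulse <- function(nominal_flip, kappa = 10, delta = 5e-3,
                              T_ex = 1e-3, n_samples = 1000L,
                              apodization = c("hann", "none")) {
  apodization <- match.arg(apodization)
  stopifnot(kappa > 0, delta > 0, T_ex > 0, n_samples >= 16)
  .check_finite(nominal_flip, "nominal_flip")
  dt <- T_ex / n_samples
  t <- (seq_len(n_samples) - 0.5) * dt
  x <- (t - T_ex / 2) / (T_ex / kappa)   # zero crossings at integer x
  env <- ifelse(abs(x) < 1e-12, 1, sin(pi * x) / (pi * x))
  if (apodization == "hann") env <- env * (0.5 - 0.5 * cos(2 * pi * t / T_ex))
  area <- sum(env) * dt
  b1 <- if (abs(nominal_flip) == 0) env * 0 else env * nominal_flip / (gamma_1h * area)
  G <- 2 * pi * kappa / (gamma_1h * T_ex * delta)
  structure(list(b1 = as.complex(b1), dt = dt, T_ex = T_ex, G = G,
                 kappa = kappa, delta = delta, nominal_flip = nominal_flip),
            class = "pulse_waveform")
}

#' Hard-pulse discretization of a shaped pulse
#'
#' Flip angles `alpha_i = gamma * |B1(t_i)| * dt` and phases
#' `phi_i = Arg(B1(t_i))` of the instantaneous hard pulses approximating the
#' waveform (negative real lobes appear as `phi = pi`).
#'
#' @param pulse a `pulse_waveform`.
#' @return list with numeric vectors `alpha` and `phi`.
#' @export
hard_pulse_flips <- function(pulse) {
  stopifnot(inherits(pulse, "pulse_waveform"), length(pulse$b1) > 0)
  alpha <- gamma_1h * Mod(pulse$b1) * pulse$dt
  phi <- ifelse(alpha > 0, Arg(pulse$b1), 0)
  list(alpha = alpha, phi = phi)
}

# Signed small-tip flip train: alpha_i * cos(phi_i) reproduces the signed
# envelope integral for real pulses.
signed_flips <- function(pulse) {
  hp <- hard_pulse_flips(pulse)
  hp$alpha * cos(hp$phi)
}

#' Effective RF operator of a slice-selective pulse
#'
#' Composes, for every bin of `grid`, the ordered operator product
#' `S(k_post z) * prod_i ( S(gamma G z dt) T_{phi_i}(alpha_i) ) * S(k_pre z)`
#' (earliest factors rightmost). Relaxation during the pulse is neglected, so
#' each per-bin operator is a rotation (unit determinant).
#'
#' @param pulse a `pulse_waveform`.
#' @param grads a `gradient_scheme`.
#' @param grid a `spatial_grid`.
#' @param rf_phase additional constant RF phase added to every hard pulse
#'   (radians); used for phase-alternated trains.
#' @return list of class `effective_rf`: `ops` (N x 9 complex matrix of
#'   column-major 3x3 entries acting on (F+, F-, Z)), plus `grid`, `grads`,
#'   `pulse` metadata.
#' @export
effective_rf <- function(pulse, grads, grid, rf_phase = 0) {
  stopifnot(inherits(pulse, "pulse_waveform"), inherits(grads, "gradient_scheme"),
            inherits(grid, "spatial_grid"))
  hp <- hard_pulse_flips(pulse)
  z <- grid$centers
  ops <- cpp_effective_rf(hp$alpha, hp$phi + rf_phase,
                          gamma_1h * pulse$G * pulse$dt * z,
                          grads$k_pre * z, grads$k_post * z)
  structure(list(ops = ops, grid = grid, grads = grads,
                 nominal_flip = pulse$nominal_flip),
            class = "effective_rf")
}

#' Spatially uniform (ideal hard pulse) effective operator
#'
#' Convenience constructor for an ideal, non-selective rotation applied
#' identically at every bin; useful for tests and idealized sequences.
#'
#' @param grid a `spatial_grid`.
#' @param alpha,phi flip angle and phase in radians.
#' @return `effective_rf`.
#' @export
ideal_pulse_rf <- function(grid, alpha, phi = 0) {
  m <- rotation_operator(alpha, phi)[1:3, 1:3]
  ops <- matrix(rep(as.vector(m), each = grid$n_bins), nrow = grid$n_bins)
  structure(list(ops = ops, grid = grid,
                 grads = gradient_scheme(0, 0), nominal_flip = alpha),
            class = "effective_rf")
}

op_determinant <- function(ops) {
  a11 <- ops[, 1]; a21 <- ops[, 2]; a31 <- ops[, 3]
  a12 <- ops[, 4]; a22 <- ops[, 5]; a32 <- ops[, 6]
  a13 <- ops[, 7]; a23 <- ops[, 8]; a33 <- ops[, 9]
  a11 * (a22 * a33 - a32 * a23) - a12 * (a21 * a33 - a31 * a23) +
    a13 * (a21 * a32 - a31 * a22)
}

#' Euler decomposition of an effective RF operator
#'
#' Decomposes each per-bin rotation into `T_phi(alpha) * S(phi_pre)`: an
#' effective flip-angle profile `alpha(z)` in `[0, pi]`, an effective pulse
#' phase `phi(z)` and a pre-phase `phi_pre(z)`, both wrapped to `(-pi, pi]`.
#' When `sin(alpha) < 1e-12` the pulse phase is gauge-fixed to zero and all
#' phase is folded into `phi_pre`.
#'
#' @param eff an `effective_rf` (or an N x 9 complex operator matrix).
#' @return list with `alpha_profile`, `phase_profile`, `prephase_profile`.
#' @export
euler_decompose <- function(eff) {
  ops <- if (inherits(eff, "effective_rf")) eff$ops else eff
  det <- op_determinant(ops)
  if (any(Mod(det - 1) > 1e-6)) {
    stop("operator is not a rotation (|det - 1| > 1e-6)", call. = FALSE)
  }
  a11 <- ops[, 1]; a12 <- ops[, 4]; a13 <- ops[, 7]; a33 <- ops[, 9]
  alpha <- acos(pmin(1, pmax(-1, Re(a33))))
  sa <- sin(alpha)
  phi <- ifelse(sa >= 1e-12, Arg(1i * a13), 0)
  # phi_pre from the better-conditioned of A11 = cos^2(a/2) e^{i psi} and
  # A12 = e^{2i phi} sin^2(a/2) e^{-i psi}
  use12 <- cos(alpha / 2)^2 < 0.5
  psi <- ifelse(use12, wrap_pi(2 * phi - Arg(a12)), Arg(a11))
  list(alpha_profile = alpha, phase_profile = wrap_pi(phi),
       prephase_profile = wrap_pi(psi))
}

wrap_pi <- function(x) {
  y <- (x + pi) %% (2 * pi) - pi
  ifelse(y == -pi, pi, y)
}

#' Recompose an effective operator from its Euler profiles
#'
#' Inverse of [euler_decompose()]: builds the N x 9 operator matrix
#' `T_phi(alpha) * S(phi_pre)` per bin.
#'
#' @param alpha,phi,phi_pre numeric vectors (radians), recycled to a common
#'   length.
#' @return N x 9 complex matrix.
#' @export
recompose_rf <- function(alpha, phi, phi_pre) {
  n <- max(length(alpha), length(phi), length(phi_pre))
  alpha <- rep_len(alpha, n); phi <- rep_len(phi, n); phi_pre <- rep_len(phi_pre, n)
  ca2 <- cos(alpha / 2)^2; sa2 <- sin(alpha / 2)^2; sa <- sin(alpha)
  ep <- exp(1i * phi); epre <- exp(1i * phi_pre)
  cbind(a11 = ca2 * epre,
        a21 = Conj(ep)^2 * sa2 * epre,
        a31 = -0.5i * Conj(ep) * sa * epre,
        a12 = ep^2 * sa2 * Conj(epre),
        a22 = ca2 * Conj(epre),
        a32 = 0.5i * ep * sa * Conj(epre),
        a13 = -1i * ep * sa,
        a23 = 1i * Conj(ep) * sa,
        a33 = cos(alpha) + 0i)
}

#' Focus point of a shaped pulse
#'
#' The effective instant `t_f` at which the pulse acts, found by maximizing
#' the free-induction decay `|integral M+(z) dz|` over candidate rewinder
#' moments `-gamma * G * t_f` applied after the pulse (golden-section search
#' on `[0, T_ex]`, tolerance `dt / 10`). The refocusing moment follows as
#' `k_post = -gamma * G * t_f` (refocusing lobe opposite in polarity to the
#' slice-selection gradient).
#'
#' @param pulse a `pulse_waveform` with non-zero envelope.
#' @param grid a `spatial_grid` for evaluating the FID integral.
#' @return focus time `t_f` in seconds.
#' @export
focus_point <- function(pulse, grid) {
  if (all(Mod(pulse$b1) == 0)) {
    stop("degenerate input: all-zero pulse has no focus point", call. = FALSE)
  }
  eff <- effective_rf(pulse, gradient_scheme(0, 0), grid)
  mplus <- eff$ops[, 7]  # column a13: response of equilibrium Mz = 1
  z <- grid$centers
  obj <- function(tf) Mod(sum(exp(-1i * gamma_1h * pulse$G * tf * z) * mplus))
  opt <- stats::optimize(obj, interval = c(0, pulse$T_ex), maximum = TRUE,
                         tol = pulse$dt / 10)
  opt$maximum
}
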