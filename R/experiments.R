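#' MR fingerprinting sequence description
#'
#' A constant-TR SSFP-type sequence with an arbitrary flip-angle train.
#' Constant TR (and spoiling moment) is a formalism requirement: only then do
#' the off-resonance and spoiling phase graphs coincide and grow linearly.
#'
#' @param flip_train flip angles in radians, one per repetition.
#' @param TR repetition time (s); constant across the train.
#' @param TE echo time (s), `0 <= TE <= TR`.
#' @param k_sp spoiling moment along the slice direction (rad/m).
#' @param q refocused echo order (0 = FID/GRE, -1 = PSIF-type).
#' @param phase_train RF phase per repetition (radians; scalar recycled).
#'   0/pi alternation can be requested with `phase_alternation = TRUE`.
#' @param invert_first apply an ideal inversion (Mz -> -Mz) before the train.
#' @param phase_alternation convenience flag overriding `phase_train` with
#'   a 0/pi alternating pattern.
#' @return list of class `mrf_sequence`.
#' @export
mrf_sequence <- function(flip_train, TR, TE = 0, k_sp = 0, q = 0L,
                         phase_train = 0, invert_first = FALSE,
                         phase_alternation = FALSE) {
  .check_finite(flip_train, "flip_train")
  stopifnot(TR > 0)
  if (any(TE < 0) || any(TE > TR)) stop("TE must lie in [0, TR]", call. = FALSE)
  n <- length(flip_train)
  if (isTRUE(phase_alternation)) {
    phase_train <- rep(c(0, pi), length.out = n)
  } else {
    phase_train <- rep_len(phase_train, n)
  }
  structure(list(flip_train = flip_train, TR = TR, TE = TE, k_sp = k_sp,
                 q = as.integer(q), phase_train = phase_train,
                 invert_first = isTRUE(invert_first)),
            class = "mrf_sequence")
}

#' Tissue parameter set
#'
#' @param T1,T2 relaxation times (s); a warning is issued when T2 > T1.
#' @param r2prime microscopic dephasing rate R2' (1/s).
#' @param omega off-resonance (rad/s).
#' @param m0 equilibrium magnetization (dimensionless).
#' @return list of class `tissue_params`.
#' @export
tissue_params <- function(T1, T2, r2prime = 0, omega = 0, m0 = 1) {
  stopifnot(T1 > 0, T2 > 0, r2prime >= 0, m0 > 0)
  if (T2 > T1) warning("T2 > T1 is unphysical for most tissues")
  structure(list(T1 = T1, T2 = T2, r2prime = r2prime, omega = omega, m0 = m0),
            class = "tissue_params")
}

#' Reference MRF flip-angle train
#'
#' Deterministic 100-entry train: 15 deg for indices 1-14, a linear ramp
#' from 15 to 50 deg over indices 15-50, then a half-sine bump
#' `50 + 20 sin(pi (n - 50) / 50)` peaking at 70 deg at index 75. An ideal
#' inversion precedes the train.
#'
#' @param n_pulses train length (default 100).
#' @return numeric vector of flip angles in radians.
#' @export
fixture_flip_train <- function(n_pulses = 100L) {
  stopifnot(n_pulses >= 1)
  deg <- numeric(n_pulses)
  idx <- seq_len(n_pulses)
  deg[idx <= 14] <- 15
  ramp <- idx >= 15 & idx <= 50
  deg[ramp] <- 15 + (50 - 15) * (idx[ramp] - 15) / (50 - 15)
  tail <- idx >= 51
  deg[tail] <- 50 + 20 * sin(pi * (idx[tail] - 50) / 50)
  deg * pi / 180
}

#' Build the reference MRF test configuration
#'
#' Inversion-prepared 100-pulse spoiled SSFP train with TR = 15 ms,
#' Hann-apodized sinc pulses (kappa = 10, slice thickness 5 mm), spoiling
#' moment `4 * 2*pi/delta`, grid of `n_bins` bins over three slice
#' thicknesses. The refocusing moment is computed once from the maximum-flip
#' (70 deg) pulse and reused for all amplitude-scaled pulses; optionally all
#' moments are rounded to the ssEPG state increment `gamma*G*dt` so that the
#' three simulation methods are exactly comparable.
#'
#' @param n_pulses number of repetitions.
#' @param n_samples hard-pulse steps per excitation (145 reproduces the
#'   three-way comparison setting; 1000 is the accuracy default).
#' @param n_bins spatial bins across the field of view.
#' @param kappa,delta,T_ex,TR,TE sequence and pulse parameters (SI units).
#' @param k_sp_factor spoiling moment in units of `2*pi/delta`.
#' @param q refocused echo order.
#' @param round_moments round k_sp, k_pre, k_post to multiples of the ssEPG
#'   state increment.
#' @param fov_factor field of view in units of `delta`.
#' @return list with `seq`, `pulse` (70 deg base pulse), `grads`, `grid`,
#'   `tissue` (T1 = 800 ms, T2 = 50 ms), and `t_f` (focus point).
#' @export
build_fixture_sequence <- function(n_pulses = 100L, n_samples = 1000L,
                                   n_bins = 3001L, kappa = 10, delta = 5e-3,
                                   T_ex = 1e-3, TR = 15e-3, TE = 0,
                                   k_sp_factor = 4, q = 0L,
                                   round_moments = FALSE, fov_factor = 3) {
  max_flip <- 70 * pi / 180
  pulse <- design_sinc_pulse(max_flip, kappa = kappa, delta = delta,
                             T_ex = T_ex, n_samples = n_samples)
  grid <- spatial_grid(n_bins, fov_factor * delta)
  t_f <- focus_point(pulse, grid)
  k_post <- -gamma_1h * pulse$G * t_f
  k_sp <- k_sp_factor * 2 * pi / delta
  if (round_moments) {
    dk <- gamma_1h * pulse$G * pulse$dt
    k_post <- round(k_post / dk) * dk
    k_sp <- round(k_sp / dk) * dk
  }
  grads <- gradient_scheme(k_pre = -(gamma_1h * pulse$G * pulse$T_ex + k_post),
                           k_post = k_post)
  flips <- fixture_flip_train(n_pulses)
  seqn <- mrf_sequence(flips, TR = TR, TE = TE, k_sp = k_sp, q = q,
                       invert_first = TRUE)
  tissue <- tissue_params(T1 = 0.8, T2 = 0.05)
  list(seq = seqn, pulse = pulse, grads = grads, grid = grid,
       tissue = tissue, t_f = t_f)
}

#' Per-repetition effective RF operators for a flip-angle train
#'
#' Scales the base pulse to each nominal flip (pure amplitude scaling) and
#' composes the effective operator per repetition.
#'
#' @param pulse base `pulse_waveform`.
#' @param seq an `mrf_sequence` (flip and phase trains are used).
#' @param grads a `gradient_scheme`.
#' @param grid a `spatial_grid`.
#' @return list of `effective_rf`, one per repetition (shared objects for
#'   repeated flip/phase combinations).
#' @export
effective_rf_train <- function(pulse, seq, grads, grid) {
  hp <- hard_pulse_flips(pulse)
  scale <- seq$flip_train / pulse$nominal_flip
  z <- grid$centers
  psi_step <- gamma_1h * pulse$G * pulse$dt * z
  psi_pre <- grads$k_pre * z
  psi_post <- grads$k_post * z
  key <- paste(signif(scale, 15), signif(seq$phase_train, 15))
  cache <- new.env(parent = emptyenv())
  lapply(seq_along(scale), function(n) {
    k <- key[n]
    if (!is.null(cache[[k]])) return(cache[[k]])
    ops <- cpp_effective_rf(hp$alpha * scale[n], hp$phi + seq$phase_train[n],
                            psi_step, psi_pre, psi_post)
    eff <- structure(list(ops = ops, grid = grid, grads = grads,
                          nominal_flip = pulse$nominal_flip * scale[n]),
                     class = "effective_rf")
    cache[[k]] <- eff
    eff
  })
}

#' Off-resonance variation of a signal ensemble
#'
#' Standard deviation of the signal magnitude with respect to off-resonance,
#' normalized to the grand-mean magnitude over all off-resonance values and
#' time points.
#'
#' @param mag numeric matrix of |signal|, off-resonance values x time points
#'   (complex input is modulus-ed).
#' @return numeric vector, one variation fraction per time point.
#' @export
offres_variation <- function(mag) {
  if (is.complex(mag)) mag <- Mod(mag)
  if (!is.matrix(mag) || nrow(mag) < 2) {
    stop("need a matrix with >= 2 off-resonance samples", call. = FALSE)
  }
  grand <- mean(mag)
  if (grand <= .Machine$double.eps) {
    stop("degenerate normalization: zero mean signal", call. = FALSE)
  }
  sds <- sqrt(colMeans(mag^2) - colMeans(mag)^2)
  pmax(sds, 0) / grand
}

#' Aliasing-onset configuration order
#'
#' The configuration order at which the damping factor first vanishes,
#' `k_max = 2*pi / (dz * k_sp)`: orders beyond it cannot be resolved by the
#' spatial discretization alone and alias in an equally discretized Bloch
#' simulation.
#'
#' @param dz bin width (m) or a `spatial_grid`.
#' @param k_sp spoiling moment (rad/m).
#' @return real-valued order (caller floors for a count).
#' @export
aliasing_kmax <- function(dz, k_sp) {
  if (inherits(dz, "spatial_grid")) dz <- dz$dz
  if (dz <= 0 || k_sp <= 0) stop("dz and k_sp must be positive", call. = FALSE)
  2 * pi / (dz * k_sp)
}

#' Off-resonance variation map over spoiling moments
#'
#' One SR-EPG engine run serves the whole map: the spoiling moment and
#' off-resonance are swept analytically over the supplied grids, and the
#' off-resonance variation is evaluated per time point and spoiling
#' moment. Also reports, per requested echo order, the minimal spoiling
#' moment whose variation stays below `threshold` for all time points.
#'
#' @param seq,tissue,rf_train as for [run_sr_epg()].
#' @param ksp_grid spoiling moments (rad/m).
#' @param omega_grid off-resonance values (rad/s); the reference analysis
#'   uses 101 values in `[-pi/TR, pi/TR]`.
#' @param q echo orders (integer vector).
#' @param threshold variation threshold (fraction, default 0.01).
#' @return list with `variation` (array n x n_ksp x n_q), `ksp_grid`,
#'   `omega_grid`, `q`, and `min_ksp` (per echo order; NA when no grid point
#'   suppresses the variation everywhere).
#' @export
spoiling_sweep <- function(seq, tissue, rf_train, ksp_grid, omega_grid,
                           q = 0L, threshold = 0.01) {
  nTR <- length(seq$flip_train)
  variation <- array(NA_real_, c(nTR, length(ksp_grid), length(q)))
  min_ksp <- rep(NA_real_, length(q))
  for (iq in seq_along(q)) {
    run <- run_sr_epg(seq, tissue, rf_train,
                      ksp_projection = list(ksp = ksp_grid, q = q[iq]))
    ks <- seq(-run$states$K, run$states$K)
    # W[omega, k] at TE = 0: pure off-resonance phase of each order
    W <- exp(1i * outer(omega_grid, ks) * seq$TR)
    for (j in seq_along(ksp_grid)) {
      s <- W %*% run$projection[, j, ]    # omega x n
      variation[, j, iq] <- offres_variation(Mod(s))
    }
    ok <- apply(variation[, , iq, drop = FALSE] < threshold, 2, all)
    if (any(ok)) min_ksp[iq] <- ksp_grid[min(which(ok))]
  }
  list(variation = variation, ksp_grid = ksp_grid, omega_grid = omega_grid,
       q = q, min_ksp = min_ksp, threshold = threshold)
}

#' Generate an MRF signal dictionary
#'
#' One SR-EPG run per (T1, T2) pair; echo time, off-resonance, microscopic
#' dephasing, spoiling moment and echo order are evaluated analytically from
#' that run. Fully deterministic given the configuration.
#'
#' @param tissues data.frame with columns `T1`, `T2` (seconds).
#' @param seq an `mrf_sequence` template.
#' @param pulse,grads,grid pulse and geometry (as in
#'   [effective_rf_train()]).
#' @param axes named list of analytic axes: `TE` (s), `omega` (rad/s),
#'   `r2prime` (1/s), `k_sp` (rad/m), `q` (integer); missing axes default to
#'   the sequence/tissue values.
#' @param max_entries guard on the number of dictionary rows.
#' @return data.frame with columns T1, T2, n, TE, omega, r2prime, k_sp, q,
#'   re, im.
#' @export
dictionary_generate <- function(tissues, seq, pulse, grads, grid,
                                axes = list(), max_entries = 2e6) {
  stopifnot(is.data.frame(tissues), all(c("T1", "T2") %in% names(tissues)))
  TE <- axes$TE %||% seq$TE
  omega <- axes$omega %||% 0
  r2prime <- axes$r2prime %||% 0
  k_sp <- axes$k_sp %||% seq$k_sp
  qs <- axes$q %||% seq$q
  nTR <- length(seq$flip_train)
  n_rows <- nrow(tissues) * nTR * length(TE) * length(omega) *
    length(r2prime) * length(k_sp) * length(qs)
  if (n_rows > max_entries) {
    stop("dictionary would hold ", n_rows, " rows (limit ", max_entries, ")",
         call. = FALSE)
  }
  rf_train <- effective_rf_train(pulse, seq, grads, grid)
  out <- vector("list", nrow(tissues))
  for (it in seq_len(nrow(tissues))) {
    tissue <- tissue_params(T1 = tissues$T1[it], T2 = tissues$T2[it])
    run <- run_sr_epg(seq, tissue, rf_train, keep = "fplus")
    rows <- expand.grid(n = seq_len(nTR), TE = TE, omega = omega,
                        r2prime = r2prime, k_sp = k_sp, q = qs,
                        KEEP.OUT.ATTRS = FALSE)
    vals <- complex(length(rows$n))
    for (r in seq_len(nrow(rows))) {
      st <- states_at(run, rows$n[r])
      spec <- weighting_spec(TR = seq$TR, TE = rows$TE[r], T2 = tissue$T2,
                             omega = rows$omega[r], r2prime = rows$r2prime[r])
      vals[r] <- epg_signal(st, k_sp = rows$k_sp[r], q = rows$q[r], spec = spec)
    }
    rows$T1 <- tissues$T1[it]; rows$T2 <- tissues$T2[it]
    rows$re <- Re(vals); rows$im <- Im(vals)
    out[[it]] <- rows
  }
  do.call(rbind, out)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Reconstruct the configuration states at one time point of a run
#'
#' Uses the retained F+ history plus hermiticity
#' (`F-_k = Conj(F+_{-k})`) to rebuild a `config_states` view sufficient for
#' all transverse signal evaluations.
#'
#' @param run result of [run_sr_epg()] with `keep = "fplus"`.
#' @param n repetition index (1-based, state directly after the n-th pulse).
#' @return `config_states` (longitudinal components zeroed; transverse exact).
#' @export
states_at <- function(run, n) {
  st <- run$states
  if (is.null(run$history)) stop("run has no retained history", call. = FALSE)
  fp <- run$history[, , n]
  st$f_plus <- fp
  st$f_minus <- Conj(fp[, rev(seq_len(ncol(fp)))])
  st$z_comp <- matrix(0 + 0i, nrow(fp), ncol(fp))
  st$kmax <- min(n, st$K)
  st$n_index <- n
  st
}
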