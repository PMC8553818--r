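#' Initialize spatially-resolved configuration states
#'
#' Allocates configuration-state arrays F+_{k,i}, F-_{k,i}, Z_{k,i} over
#' orders k = -K..K and the bins of `grid`, in thermal equilibrium:
#' Z_{0,i} = 1, everything else zero. The equilibrium (fourth) component
#' delta_{k,0} is implicit; [epg_relax()] adds recovery to Z_0 directly.
#'
#' @param grid a `spatial_grid`.
#' @param max_order K, at least the number of repetitions to simulate.
#' @return object of class `config_states` with matrices `f_plus`, `f_minus`,
#'   `z_comp` of dimension bins x (2K+1), the column index `k0` of order 0,
#'   the highest occupied order `kmax`, and the TR counter `n_index`.
#' @export
init_states <- function(grid, max_order) {
  stopifnot(inherits(grid, "spatial_grid"))
  if (max_order < 1) stop("`max_order` must be >= 1", call. = FALSE)
  K <- as.integer(max_order)
  n <- grid$n_bins
  zero <- matrix(0 + 0i, n, 2L * K + 1L)
  zc <- zero
  zc[, K + 1L] <- 1 + 0i
  structure(list(f_plus = zero, f_minus = zero, z_comp = zc,
                 K = K, k0 = K + 1L, kmax = 0L, grid = grid, n_index = 0L),
            class = "config_states")
}

#' Orders of a configuration-state object
#' @param states a `config_states`.
#' @param occupied if TRUE, restrict to the occupied window.
#' @return integer vector of configuration orders.
#' @export
state_orders <- function(states, occupied = TRUE) {
  if (occupied) seq(-states$kmax, states$kmax) else seq(-states$K, states$K)
}

occ_cols <- function(states) {
  (states$k0 - states$kmax):(states$k0 + states$kmax)
}

#' Configuration-state shift (gradient dephasing)
#'
#' Moves F+ configurations up one order and F- configurations down one order;
#' Z is untouched. Raises an error instead of silently truncating when a
#' transverse state occupies the boundary order.
#'
#' @param states a `config_states`.
#' @return shifted `config_states`.
#' @export
epg_shift <- function(states) {
  k0 <- states$k0; km <- states$kmax
  w <- occ_cols(states)
  if (!any(states$f_plus[, w] != 0) && !any(states$f_minus[, w] != 0)) {
    return(states)   # no transverse content: shifting is a no-op
  }
  if (km == states$K) {
    hi <- k0 + km; lo <- k0 - km
    if (any(states$f_plus[, hi] != 0) || any(states$f_minus[, lo] != 0)) {
      stop("configuration-state overflow: highest order reached max_order",
           call. = FALSE)
    }
    cols_new <- (lo + 1L):hi
    cols_old <- lo:(hi - 1L)
  } else {
    states$kmax <- km + 1L
    cols_new <- (k0 - km):(k0 + km + 1L)
    cols_old <- (k0 - km - 1L):(k0 + km)
  }
  fp <- states$f_plus; fm <- states$f_minus
  fp[, cols_new] <- fp[, cols_new - 1L]
  fp[, cols_new[1L] - 1L] <- 0 + 0i
  fm[, cols_new - 1L] <- fm[, cols_new]
  fm[, cols_new[length(cols_new)]] <- 0 + 0i
  states$f_plus <- fp
  states$f_minus <- fm
  states
}

#' Relaxation and recovery of configuration states
#'
#' Transverse orders decay with E2 = exp(-t/T2), longitudinal with
#' E1 = exp(-t/T1); recovery (1 - E1) feeds only Z at order zero, driven by
#' the implicit delta_{k,0} equilibrium component.
#'
#' @param states a `config_states`.
#' @param t duration in seconds.
#' @param T1,T2 relaxation times in seconds.
#' @return relaxed `config_states`.
#' @export
epg_relax <- function(states, t, T1, T2) {
  if (t < 0) stop("`t` must be non-negative", call. = FALSE)
  if (T1 <= 0 || T2 <= 0) stop("relaxation times must be positive", call. = FALSE)
  e1 <- exp(-t / T1); e2 <- exp(-t / T2)
  w <- occ_cols(states)
  states$f_plus[, w] <- states$f_plus[, w] * e2
  states$f_minus[, w] <- states$f_minus[, w] * e2
  states$z_comp[, w] <- states$z_comp[, w] * e1
  states$z_comp[, states$k0] <- states$z_comp[, states$k0] + (1 - e1)
  states
}

#' Apply an effective RF operator to all configuration orders
#'
#' Multiplies, per bin, every order's (F+, F-, Z) vector by the bin's 3x3
#' rotation; the RF pulse acts identically on all configuration orders.
#'
#' @param states a `config_states`.
#' @param eff an `effective_rf` on the same grid.
#' @return mixed `config_states`.
#' @export
epg_apply_rf <- function(states, eff) {
  stopifnot(inherits(eff, "effective_rf"))
  if (!isTRUE(all.equal(eff$grid$centers, states$grid$centers))) {
    stop("grid mismatch between states and effective RF", call. = FALSE)
  }
  o <- eff$ops
  w <- occ_cols(states)
  fp <- states$f_plus[, w, drop = FALSE]
  fm <- states$f_minus[, w, drop = FALSE]
  zc <- states$z_comp[, w, drop = FALSE]
  states$f_plus[, w] <- o[, 1] * fp + o[, 4] * fm + o[, 7] * zc
  states$f_minus[, w] <- o[, 2] * fp + o[, 5] * fm + o[, 8] * zc
  states$z_comp[, w] <- o[, 3] * fp + o[, 6] * fm + o[, 9] * zc
  states
}

#' Invert longitudinal configuration states
#'
#' Ideal adiabatic inversion: Z -> -Z at every order and bin, transverse
#' states untouched.
#'
#' @param states a `config_states`.
#' @return inverted `config_states`.
#' @export
epg_invert <- function(states) {
  w <- occ_cols(states)
  states$z_comp[, w] <- -states$z_comp[, w]
  states
}

#' Run the spatially-resolved EPG recursion
#'
#' Evolves configuration states through `shift -> relax -> RF` per
#' repetition. Off-resonance and the spoiling moment never enter the
#' recursion: they are recovered analytically downstream, so one run serves
#' all (omega, k_sp, TE, R2', q) combinations.
#'
#' @param seq an `mrf_sequence`.
#' @param tissue a `tissue_params`.
#' @param rf_train an `effective_rf`, or a list of them (one per repetition).
#'   RF phase alternation in `seq$phase_train` is applied by phase-shifting
#'   the operators.
#' @param keep `"none"` (final state only) or `"fplus"` (retain the F+
#'   history as a bins x orders x n array — the memory-hungry option that
#'   enables arbitrary post-hoc analysis).
#' @param signal_specs optional list of signal recipes evaluated after every
#'   repetition without retaining history; each entry is a list with elements
#'   `k_sp`, `q`, `spec` (a [weighting_spec()]), and optional `damping`
#'   (default TRUE). Results are returned as a complex matrix n x length(specs).
#' @param ksp_projection optional list(`ksp` = numeric grid, `q` = integer)
#'   accumulating the slice-integrated kernel projection
#'   `P[k, j, n] = sum_i kernel_{k-q,i}(ksp_j) F+_{k,i}^{(n)}` during the run.
#' @return list with `states` (final `config_states`), and depending on the
#'   options `history`, `signals`, `projection`.
#' @export
run_sr_epg <- function(seq, tissue, rf_train, keep = c("none", "fplus"),
                       signal_specs = NULL, ksp_projection = NULL) {
  keep <- match.arg(keep)
  stopifnot(inherits(seq, "mrf_sequence"), inherits(tissue, "tissue_params"))
  if (inherits(rf_train, "effective_rf")) {
    rf_train <- rep(list(rf_train), length(seq$flip_train))
  }
  nTR <- length(seq$flip_train)
  if (length(rf_train) != nTR) stop("`rf_train` length must match the flip train")
  grid <- rf_train[[1L]]$grid
  states <- init_states(grid, max_order = nTR + 1L)
  if (isTRUE(seq$invert_first)) states <- epg_invert(states)

  history <- if (keep == "fplus") {
    array(0 + 0i, dim = c(grid$n_bins, 2L * states$K + 1L, nTR))
  }
  signals <- if (!is.null(signal_specs)) {
    matrix(0 + 0i, nTR, length(signal_specs))
  }
  proj <- NULL
  if (!is.null(ksp_projection)) {
    proj <- array(0 + 0i,
                  dim = c(2L * states$K + 1L, length(ksp_projection$ksp), nTR))
  }

  for (n in seq_len(nTR)) {
    states <- epg_shift(states)
    states <- epg_relax(states, seq$TR, tissue$T1, tissue$T2)
    states <- epg_apply_rf(states, rf_train[[n]])
    states$n_index <- n
    if (!is.null(history)) history[, , n] <- states$f_plus
    if (!is.null(signal_specs)) {
      for (j in seq_along(signal_specs)) {
        sp <- signal_specs[[j]]
        damping <- if (is.null(sp$damping)) TRUE else sp$damping
        signals[n, j] <- epg_signal(states, k_sp = sp$k_sp,
                                    q = if (is.null(sp$q)) 0L else sp$q,
                                    spec = sp$spec, damping = damping)
      }
    }
    if (!is.null(proj)) {
      proj[, , n] <- project_states(states, ksp_projection$ksp,
                                    q = if (is.null(ksp_projection$q)) 0L
                                        else ksp_projection$q)
    }
  }

  out <- list(states = states)
  if (!is.null(history)) {
    out$history <- history
    out$orders <- seq(-states$K, states$K)
  }
  if (!is.null(signals)) out$signals <- signals
  if (!is.null(proj)) {
    out$projection <- proj
    out$projection_ksp <- ksp_projection$ksp
  }
  out
}

# Slice-integrated kernel projection over a spoiling-moment grid:
# P[k, j] = sum_i dz * sinc((k-q) ksp_j dz / 2) e^{i (k-q) ksp_j z_i} F+_{k,i}.
# Evaluated with an order recurrence to avoid re-exponentiation per order.
project_states <- function(states, ksp, q = 0L) {
  grid <- states$grid
  z <- grid$centers
  dz <- grid$dz
  nk_all <- 2L * states$K + 1L
  P <- matrix(0 + 0i, nk_all, length(ksp))
  ks <- state_orders(states)
  E <- exp(1i * outer(z, ksp))          # one step in order
  V <- exp(1i * (ks[1L] - q) * outer(z, ksp))
  w <- occ_cols(states)
  for (idx in seq_along(ks)) {
    k <- ks[idx]
    fk <- states$f_plus[, w[idx]]
    damp <- sinc((k - q) * ksp * dz / 2)
    P[states$k0 + k, ] <- dz * damp * colSums(V * fk)
    if (idx < length(ks)) V <- V * E
  }
  P
}

#' Write a configuration-state history container
#'
#' Plain-text container: a directory holding JSON metadata plus one TSV per
#' component with the complex states flattened over (n, k, i). Written
#' atomically (temp directory, then rename).
#'
#' @param run result of [run_sr_epg()] with `keep = "fplus"`.
#' @param path destination directory.
#' @return `path`, invisibly.
#' @export
write_state_history <- function(run, path) {
  if (is.null(run$history)) stop("run has no retained history", call. = FALSE)
  tmp <- paste0(path, ".tmp")
  unlink(tmp, recursive = TRUE)
  dir.create(tmp, recursive = TRUE)
  d <- dim(run$history)
  meta <- list(n_bins = d[1L], n_orders = d[2L], n_reps = d[3L],
               orders = run$orders, fov = run$states$grid$fov,
               centers_first = run$states$grid$centers[1L],
               dz = run$states$grid$dz)
  jsonlite::write_json(meta, file.path(tmp, "meta.json"),
                       auto_unbox = TRUE, digits = NA)
  h <- run$history
  df <- data.frame(re = sprintf("%.17g", as.vector(Re(h))),
                   im = sprintf("%.17g", as.vector(Im(h))))
  utils::write.table(df, file.path(tmp, "f_plus.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  unlink(path, recursive = TRUE)
  file.rename(tmp, path)
  invisible(path)
}

#' Read a configuration-state history container
#' @param path directory written by [write_state_history()].
#' @return list with `history` array and `meta`.
#' @export
read_state_history <- function(path) {
  meta <- jsonlite::read_json(file.path(path, "meta.json"), simplifyVector = TRUE)
  df <- utils::read.table(file.path(path, "f_plus.tsv"), header = TRUE, sep = "\t")
  h <- array(complex(real = df$re, imaginary = df$im),
             dim = c(meta$n_bins, meta$n_orders, meta$n_reps))
  list(history = h, meta = meta)
}
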