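#' Simulate a configured sequence
#'
#' Runs the SR-EPG engine for the configured sequence and evaluates the
#' hybrid Bloch-EPG signal per repetition; optionally writes the signal table
#' and a state-history container. Logs a one-line summary (highest occupied
#' order, aliasing order, minimal-spoiling check).
#'
#' @param config path to a YAML run configuration, or a config list.
#' @param out optional output file for the signal table.
#' @param states_out optional directory for the state-history container.
#' @param quiet suppress the summary message.
#' @return data.frame signal table (invisibly returns written path info as
#'   attributes).
#' @export
run_simulate <- function(config, out = NULL, states_out = NULL, quiet = FALSE) {
  cfg <- read_run_config(config)
  obj <- config_objects(cfg)
  spec <- weighting_spec(TR = obj$seq$TR, TE = obj$seq$TE, T2 = obj$tissue$T2,
                         omega = obj$tissue$omega,
                         r2prime = obj$tissue$r2prime)
  rf_train <- effective_rf_train(obj$pulse, obj$seq, obj$grads, obj$grid)
  run <- run_sr_epg(obj$seq, obj$tissue, rf_train,
                    keep = if (is.null(states_out)) "none" else "fplus",
                    signal_specs = list(list(k_sp = obj$seq$k_sp,
                                             q = obj$seq$q, spec = spec)))
  s <- run$signals[, 1]
  df <- data.frame(n = seq_along(s), TE = obj$seq$TE,
                   omega = obj$tissue$omega, r2prime = obj$tissue$r2prime,
                   k_sp = obj$seq$k_sp, q = obj$seq$q,
                   re = Re(s), im = Im(s))
  if (!quiet) {
    kmax_alias <- aliasing_kmax(obj$grid, max(obj$seq$k_sp, .Machine$double.xmin))
    msg <- sprintf(
      "highest occupied order %d; aliasing onset order %.1f; k_sp %s minimal spoiling pi*kappa/delta",
      run$states$kmax, kmax_alias,
      if (obj$seq$k_sp >= min_spoiling_moment(obj$pulse$kappa, obj$pulse$delta))
        ">=" else "< (warning:)")
    message(msg)
  }
  if (!is.null(out)) write_signal_table(df, out)
  if (!is.null(states_out)) write_state_history(run, states_out)
  df
}

#' Three-way method comparison on one configuration
#'
#' Runs the hybrid Bloch-EPG, the direct Bloch simulation and the
#' slice-selective EPG on the same configured sequence and reports the
#' profile nRMSE (hybrid vs Bloch), the k-space nRMSE (hybrid vs ssEPG, on
#' coefficient scale over a lattice window covering the occupied orders plus
#' the pulse bandwidth), and relative signal deviations at the last simulated
#' repetition.
#'
#' @param config path to YAML config or config list; `options.round_moments`
#'   should be TRUE for exact three-way comparability.
#' @param out optional output file for the (metric, value) report table.
#' @return data.frame with columns `metric`, `value`.
#' @export
run_compare <- function(config, out = NULL) {
  cfg <- read_run_config(config)
  obj <- config_objects(cfg)
  seqn <- obj$seq; tissue <- obj$tissue
  spec <- weighting_spec(TR = seqn$TR, TE = seqn$TE, T2 = tissue$T2,
                         omega = tissue$omega, r2prime = tissue$r2prime)

  rf_train <- effective_rf_train(obj$pulse, seqn, obj$grads, obj$grid)
  run <- run_sr_epg(seqn, tissue, rf_train)
  hybrid_profile <- recover_bloch_profile(run$states, seqn$k_sp, seqn$q, spec)
  hybrid_signal <- epg_signal(run$states, seqn$k_sp, seqn$q, spec)

  bl <- bloch_run(seqn, tissue, obj$pulse, obj$grads, obj$grid)
  n_last <- length(seqn$flip_train)
  bloch_profile <- bl$profiles_echo[, n_last]
  bloch_signal <- bl$signal[n_last]

  ss <- ssepg_run(seqn, tissue, obj$pulse, obj$grads)
  # lattice window: occupied configuration orders + pulse bandwidth
  bw_steps <- ceiling(min_spoiling_moment(obj$pulse$kappa, obj$pulse$delta) / ss$dk)
  half <- min(abs(ss$moment_steps[["k_sp"]]) * (run$states$kmax + 2L) + 2L * bw_steps,
              ss$m0_index - 1L)
  idx <- (ss$m0_index - half):(ss$m0_index + half)
  kwin <- ss$kprime[idx]
  hybrid_k <- recover_kspace(run$states, seqn$k_sp, seqn$q, spec, kwin) / ss$period
  ssepg_k <- ss$f_plus[idx] * exp(-seqn$TE / tissue$T2 + 1i * tissue$omega * seqn$TE)
  ssepg_signal <- ss$signal[n_last]

  df <- data.frame(
    metric = c("nrmse_bloch_profile", "nrmse_ssepg_kspace",
               "rel_dev_hybrid_bloch", "rel_dev_ssepg_bloch"),
    value = c(nrmse_bloch(bloch_profile, hybrid_profile),
              nrmse_ssepg(ssepg_k, hybrid_k, bloch_profile),
              Mod(hybrid_signal - bloch_signal) / Mod(bloch_signal),
              Mod(ssepg_signal - bloch_signal) / Mod(bloch_signal)))
  if (!is.null(out)) {
    tmp <- paste0(out, ".tmp")
    utils::write.table(data.frame(metric = df$metric, value = fmt17(df$value)),
                       tmp, sep = "\t", row.names = FALSE, quote = FALSE)
    file.rename(tmp, out)
  }
  df
}

#' Generate a dictionary from a configuration
#'
#' @param config path to YAML config or config list.
#' @param tissues data.frame of (T1, T2) pairs in seconds; default is the
#'   configured tissue only.
#' @param axes analytic axes passed to [dictionary_generate()].
#' @param out optional output directory (JSON metadata + TSV table, written
#'   atomically).
#' @param max_entries row guard.
#' @return dictionary data.frame.
#' @export
run_dictionary <- function(config, tissues = NULL, axes = list(), out = NULL,
                           max_entries = 2e6) {
  cfg <- read_run_config(config)
  obj <- config_objects(cfg)
  if (is.null(tissues)) {
    tissues <- data.frame(T1 = obj$tissue$T1, T2 = obj$tissue$T2)
  }
  dict <- dictionary_generate(tissues, obj$seq, obj$pulse, obj$grads,
                              obj$grid, axes = axes,
                              max_entries = max_entries)
  if (!is.null(out)) {
    tmp <- paste0(out, ".tmp")
    unlink(tmp, recursive = TRUE)
    dir.create(tmp, recursive = TRUE)
    jsonlite::write_json(list(n_rows = nrow(dict),
                              tissues = tissues,
                              axes = axes),
                         file.path(tmp, "meta.json"),
                         auto_unbox = TRUE, digits = NA)
    tab <- dict
    for (nm in names(tab)) tab[[nm]] <- fmt17(tab[[nm]])
    utils::write.table(tab, file.path(tmp, "dictionary.tsv"), sep = "\t",
                       row.names = FALSE, quote = FALSE)
    unlink(out, recursive = TRUE)
    file.rename(tmp, out)
  }
  dict
}

#' Spoiling-moment sweep from a configuration
#'
#' @param config path to YAML config or config list.
#' @param ksp_factors spoiling moments in units of `2*pi/delta`.
#' @param n_omega number of off-resonance samples in `[-pi/TR, pi/TR]`.
#' @param q echo orders.
#' @param threshold variation threshold.
#' @param out optional TSV output of the variation map.
#' @return result of [spoiling_sweep()].
#' @export
run_sweep <- function(config, ksp_factors = seq(0, 12, by = 0.25),
                      n_omega = 101L, q = 0L, threshold = 0.01, out = NULL) {
  cfg <- read_run_config(config)
  obj <- config_objects(cfg)
  delta <- obj$pulse$delta
  ksp_grid <- ksp_factors * 2 * pi / delta
  omega_grid <- seq(-pi / obj$seq$TR, pi / obj$seq$TR, length.out = n_omega)
  rf_train <- effective_rf_train(obj$pulse, obj$seq, obj$grads, obj$grid)
  sw <- spoiling_sweep(obj$seq, obj$tissue, rf_train, ksp_grid, omega_grid,
                       q = q, threshold = threshold)
  if (!is.null(out)) {
    long <- expand.grid(n = seq_len(dim(sw$variation)[1]),
                        ksp_factor = ksp_factors, q = q,
                        KEEP.OUT.ATTRS = FALSE)
    long$variation <- as.vector(sw$variation)
    tmp <- paste0(out, ".tmp")
    utils::write.table(long, tmp, sep = "\t", row.names = FALSE, quote = FALSE)
    file.rename(tmp, out)
  }
  sw
}
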