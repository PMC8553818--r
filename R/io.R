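fmt17 <- function(x) sprintf("%.17g", x)

#' Write a signal table
#'
#' Delimited text with columns (n, TE, omega, r2prime, k_sp, q, re, im),
#' 17 significant digits, written atomically (temp file then rename).
#'
#' @param df data.frame holding at least the listed columns.
#' @param path destination file.
#' @return `path`, invisibly.
#' @export
write_signal_table <- function(df, path) {
  cols <- c("n", "TE", "omega", "r2prime", "k_sp", "q", "re", "im")
  missing <- setdiff(cols, names(df))
  if (length(missing)) stop("missing columns: ", paste(missing, collapse = ", "))
  out <- df[, cols]
  for (nm in cols) out[[nm]] <- fmt17(out[[nm]])
  tmp <- paste0(path, ".tmp")
  utils::write.table(out, tmp, sep = "\t", row.names = FALSE, quote = FALSE)
  file.rename(tmp, path)
  invisible(path)
}

#' Read a signal table written by [write_signal_table()]
#' @param path file path.
#' @return data.frame.
#' @export
read_signal_table <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t")
}

#' Write a pulse waveform file
#'
#' Two-column delimited text (time_s, complex B1 in tesla as "re+imj") after
#' a header block of `# key value` lines carrying G, kappa, delta, T_ex and
#' the nominal flip; round-trips bit-identically at 17 significant digits.
#'
#' @param pulse a `pulse_waveform`.
#' @param path destination file.
#' @return `path`, invisibly.
#' @export
write_pulse_waveform <- function(pulse, path) {
  stopifnot(inherits(pulse, "pulse_waveform"))
  t <- (seq_along(pulse$b1) - 0.5) * pulse$dt
  hdr <- c(paste("# G_T_per_m", fmt17(pulse$G)),
           paste("# kappa", fmt17(pulse$kappa)),
           paste("# delta_m", fmt17(pulse$delta)),
           paste("# T_ex_s", fmt17(pulse$T_ex)),
           paste("# nominal_flip_rad", fmt17(pulse$nominal_flip)))
  im <- Im(pulse$b1)
  b1 <- paste0(fmt17(Re(pulse$b1)), ifelse(im < 0, "", "+"), fmt17(im), "j")
  lines <- c(hdr, "time_s\tb1_T", paste(fmt17(t), b1, sep = "\t"))
  tmp <- paste0(path, ".tmp")
  writeLines(lines, tmp)
  file.rename(tmp, path)
  invisible(path)
}

#' Read a pulse waveform file
#' @param path file written by [write_pulse_waveform()].
#' @return `pulse_waveform`.
#' @export
read_pulse_waveform <- function(path) {
  lines <- readLines(path)
  hdr <- lines[startsWith(lines, "# ")]
  kv <- do.call(rbind, strsplit(sub("^# ", "", hdr), " "))
  meta <- as.numeric(kv[, 2])
  names(meta) <- kv[, 1]
  body <- lines[!startsWith(lines, "# ")][-1]
  parts <- do.call(rbind, strsplit(body, "\t"))
  t <- as.numeric(parts[, 1])
  m <- regmatches(parts[, 2],
                  regexec("^(.*[0-9.])([+-][0-9.eE+-]*)j$", parts[, 2]))
  re <- as.numeric(vapply(m, `[`, "", 2))
  im <- as.numeric(vapply(m, `[`, "", 3))
  dt <- if (length(t) > 1) t[2] - t[1] else meta[["T_ex_s"]]
  structure(list(b1 = complex(real = re, imaginary = im), dt = dt,
                 T_ex = meta[["T_ex_s"]], G = meta[["G_T_per_m"]],
                 kappa = meta[["kappa"]], delta = meta[["delta_m"]],
                 nominal_flip = meta[["nominal_flip_rad"]]),
            class = "pulse_waveform")
}

default_run_config <- function() {
  list(
    sequence = list(n_pulses = 100L, TR_ms = 15, TE_ms = 0,
                    flip_deg = "fixture", k_sp_per_delta = 4, q = 0L,
                    phase_alternation = FALSE, invert_first = TRUE),
    pulse = list(kappa = 10, delta_mm = 5, T_ex_ms = 1, n_samples = 1000L,
                 apodization = "hann"),
    tissue = list(T1_ms = 800, T2_ms = 50, R2p_per_s = 0, off_res_hz = 0),
    grid = list(n_bins = 3001L, fov_factor = 3),
    options = list(round_moments = FALSE)
  )
}

#' Read a run configuration
#'
#' Structured YAML with explicit units in the key names (TR_ms, delta_mm,
#' off_res_hz, ...); values are converted to SI internally. Missing keys take
#' the reference defaults. Re-loading a written configuration reproduces
#' byte-identical outputs.
#'
#' @param path YAML file, or a list already in config form.
#' @return validated configuration list of class `run_config`.
#' @export
read_run_config <- function(path) {
  raw <- if (is.list(path)) path else yaml::read_yaml(path)
  cfg <- default_run_config()
  for (sec in names(raw)) {
    if (!sec %in% names(cfg)) stop("unknown config section `", sec, "`", call. = FALSE)
    for (key in names(raw[[sec]])) {
      if (!key %in% names(cfg[[sec]])) {
        stop("unknown config key `", sec, ".", key, "`", call. = FALSE)
      }
      cfg[[sec]][[key]] <- raw[[sec]][[key]]
    }
  }
  if (cfg$sequence$TR_ms <= 0) stop("sequence.TR_ms must be positive", call. = FALSE)
  if (cfg$pulse$delta_mm <= 0) stop("pulse.delta_mm must be positive", call. = FALSE)
  structure(cfg, class = c("run_config", "list"))
}

#' Write a run configuration
#' @param cfg configuration list.
#' @param path destination YAML file.
#' @return `path`, invisibly.
#' @export
write_run_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

# Materialize configuration into simulation objects (SI units).
config_objects <- function(cfg) {
  delta <- cfg$pulse$delta_mm * 1e-3
  pulse <- design_sinc_pulse(70 * pi / 180, kappa = cfg$pulse$kappa,
                             delta = delta, T_ex = cfg$pulse$T_ex_ms * 1e-3,
                             n_samples = cfg$pulse$n_samples,
                             apodization = cfg$pulse$apodization)
  grid <- spatial_grid(cfg$grid$n_bins, cfg$grid$fov_factor * delta)
  t_f <- focus_point(pulse, grid)
  k_post <- -gamma_1h * pulse$G * t_f
  k_sp <- cfg$sequence$k_sp_per_delta * 2 * pi / delta
  if (isTRUE(cfg$options$round_moments)) {
    dk <- gamma_1h * pulse$G * pulse$dt
    k_post <- round(k_post / dk) * dk
    k_sp <- round(k_sp / dk) * dk
  }
  grads <- gradient_scheme(-(gamma_1h * pulse$G * pulse$T_ex + k_post), k_post)
  flips <- cfg$sequence$flip_deg
  flips <- if (identical(flips, "fixture")) {
    fixture_flip_train(cfg$sequence$n_pulses)
  } else {
    as.numeric(flips) * pi / 180
  }
  seqn <- mrf_sequence(flips, TR = cfg$sequence$TR_ms * 1e-3,
                       TE = cfg$sequence$TE_ms * 1e-3, k_sp = k_sp,
                       q = cfg$sequence$q,
                       invert_first = cfg$sequence$invert_first,
                       phase_alternation = cfg$sequence$phase_alternation)
  tissue <- tissue_params(T1 = cfg$tissue$T1_ms * 1e-3,
                          T2 = cfg$tissue$T2_ms * 1e-3,
                          r2prime = cfg$tissue$R2p_per_s,
                          omega = 2 * pi * cfg$tissue$off_res_hz)
  list(pulse = pulse, grid = grid, grads = grads, seq = seqn, tissue = tissue,
       t_f = t_f)
}
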