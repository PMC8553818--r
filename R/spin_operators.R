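#' @useDynLib blochepg, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats optimize sd
#' @importFrom utils read.table write.table modifyList
NULL

#' Gyromagnetic ratio of the proton
#'
#' `2 * pi * 42.577e6` rad/s/T, the angular gyromagnetic ratio of 1H used to
#' convert B1 amplitudes and gradient moments to flip angles and phases.
#'
#' @export
gamma_1h <- 2 * pi * 42.577e6

.check_finite <- function(x, name) {
  if (!is.numeric(x) || length(x) == 0L || any(!is.finite(x))) {
    stop("`", name, "` must be finite and numeric", call. = FALSE)
  }
  invisible(x)
}

new_operator4 <- function(entries, kind) {
  stopifnot(is.matrix(entries), dim(entries) == c(4L, 4L))
  structure(entries, kind = kind, class = c("epg_operator", class(entries)))
}

#' Magnetization state vector
#'
#' Builds the 4-component magnetization vector (M+, M-, Mz, Meq) on which the
#' rotation, relaxation and precession operators act. M+- = Mx +- i*My; the
#' fourth (equilibrium) component is 1 for physical states normalized to M0
#' and drives T1 recovery.
#'
#' @param m_plus,m_minus,m_z complex components; `m_minus` defaults to
#'   `Conj(m_plus)` as required for physical magnetization.
#' @param m_eq equilibrium component (default 1).
#' @return complex vector of length 4 with class `spin_state`.
#' @export
spin_state <- function(m_plus = 0, m_minus = Conj(m_plus), m_z = 1, m_eq = 1) {
  out <- as.complex(c(m_plus, m_minus, m_z, m_eq))
  class(out) <- "spin_state"
  out
}

#' RF rotation operator (hard pulse)
#'
#' The standard EPG mixing matrix T_phi(alpha) for an instantaneous RF pulse
#' with flip angle `alpha` and phase `phi`, embedded in 4D with identity on
#' the equilibrium row. Acting on (F+, F-, Z):
#' F+' = cos^2(a/2) F+ + e^{2i phi} sin^2(a/2) F- - i e^{i phi} sin(a) Z,
#' F-' = e^{-2i phi} sin^2(a/2) F+ + cos^2(a/2) F- + i e^{-i phi} sin(a) Z,
#' Z'  = -i/2 e^{-i phi} sin(a) F+ + i/2 e^{i phi} sin(a) F- + cos(a) Z.
#'
#' @param alpha flip angle in radians.
#' @param phi pulse phase in radians.
#' @return 4x4 complex matrix of class `epg_operator`, `kind = "rotation"`.
#' @export
rotation_operator <- function(alpha, phi = 0) {
  .check_finite(alpha, "alpha")
  .check_finite(phi, "phi")
  ca2 <- cos(alpha / 2)^2
  sa2 <- sin(alpha / 2)^2
  sa <- sin(alpha)
  ep <- exp(1i * phi)
  m <- matrix(0 + 0i, 4, 4)
  m[1, 1] <- ca2
  m[1, 2] <- ep^2 * sa2
  m[1, 3] <- -1i * ep * sa
  m[2, 1] <- Conj(m[1, 2])
  m[2, 2] <- ca2
  m[2, 3] <- Conj(m[1, 3])
  m[3, 1] <- -0.5i * Conj(ep) * sa
  m[3, 2] <- Conj(m[3, 1])
  m[3, 3] <- cos(alpha)
  m[4, 4] <- 1
  new_operator4(m, "rotation")
}

#' Relaxation and recovery operator
#'
#' R(t) = diag(E2, E2, E1, 1) with the single off-diagonal element (1 - E1)
#' coupling the equilibrium component into Mz, where E1 = exp(-t/T1) and
#' E2 = exp(-t/T2). Because configuration vectors carry the equilibrium
#' component delta_{k,0}, recovery feeds only the k = 0 longitudinal state.
#'
#' @param t duration in seconds (>= 0).
#' @param T1,T2 longitudinal / transverse relaxation times in seconds (> 0).
#' @return 4x4 complex matrix of class `epg_operator`, `kind = "relaxation"`.
#' @export
relaxation_operator <- function(t, T1, T2) {
  .check_finite(t, "t"); .check_finite(T1, "T1"); .check_finite(T2, "T2")
  if (t < 0) stop("`t` must be non-negative", call. = FALSE)
  if (T1 <= 0 || T2 <= 0) stop("relaxation times must be positive", call. = FALSE)
  e1 <- exp(-t / T1)
  e2 <- exp(-t / T2)
  m <- diag(c(e2, e2, e1, 1)) + 0i
  m[3, 4] <- 1 - e1
  new_operator4(m, "relaxation")
}

#' Precession / phase-accrual operator
#'
#' S(phi) = diag(e^{i phi}, e^{-i phi}, 1, 1); used for off-resonance and
#' gradient phase accrual. Satisfies S(a) S(b) = S(a + b).
#'
#' @param phi accrued phase in radians.
#' @return 4x4 complex matrix of class `epg_operator`, `kind = "precession"`.
#' @export
precession_operator <- function(phi) {
  .check_finite(phi, "phi")
  m <- diag(c(exp(1i * phi), exp(-1i * phi), 1 + 0i, 1 + 0i))
  new_operator4(m, "precession")
}
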