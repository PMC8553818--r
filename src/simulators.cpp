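#include <Rcpp.h>
#include <complex>
#include <vector>

using namespace Rcpp;
typedef std::complex<double> cd;

// 3x3 EPG mixing matrix for a hard pulse, column-major in a flat array.
static void hard_pulse_matrix(double alpha, double phi, cd T[9]) {
  const double ca2 = std::cos(alpha / 2.0) * std::cos(alpha / 2.0);
  const double sa2 = std::sin(alpha / 2.0) * std::sin(alpha / 2.0);
  const double sa = std::sin(alpha);
  const cd ep(std::cos(phi), std::sin(phi));
  const cd i1(0.0, 1.0);
  T[0] = ca2;                     // a11
  T[1] = std::conj(ep * ep) * sa2; // a21
  T[2] = -0.5 * i1 * std::conj(ep) * sa; // a31
  T[3] = ep * ep * sa2;           // a12
  T[4] = ca2;                     // a22
  T[5] = 0.5 * i1 * ep * sa;      // a32
  T[6] = -i1 * ep * sa;           // a13
  T[7] = i1 * std::conj(ep) * sa; // a23
  T[8] = std::cos(alpha);         // a33
}

// Effective slice-selective RF operator per spatial bin:
// A(z) = S(psi_post) * prod_i [ S(psi_step) T(alpha_i, phi_i) ] * S(psi_pre)
// with earlier factors applied first (rightmost). psi_* are per-bin phases.
// Returns an N x 9 complex matrix, columns = column-major 3x3 entries
// (a11, a21, a31, a12, a22, a32, a13, a23, a33).
// [[Rcpp::export]]
ComplexMatrix cpp_effective_rf(NumericVector alpha, NumericVector phi,
                               NumericVector psi_step, NumericVector psi_pre,
                               NumericVector psi_post) {
  const int ns = alpha.size();
  const int N = psi_step.size();
  if (phi.size() != ns) stop("alpha/phi length mismatch");
  if (psi_pre.size() != N || psi_post.size() != N) stop("phase vector length mismatch");

  std::vector<cd> T(9 * ns);
  for (int i = 0; i < ns; ++i) hard_pulse_matrix(alpha[i], phi[i], &T[9 * i]);

  ComplexMatrix out(N, 9);
  for (int j = 0; j < N; ++j) {
    cd A[9] = {cd(1, 0), 0, 0, 0, cd(1, 0), 0, 0, 0, cd(1, 0)};
    const cd epre(std::cos(psi_pre[j]), std::sin(psi_pre[j]));
    const cd estep(std::cos(psi_step[j]), std::sin(psi_step[j]));
    const cd epost(std::cos(psi_post[j]), std::sin(psi_post[j]));
    // A = S(psi_pre): scale rows 1,2 of identity
    A[0] = epre; A[4] = std::conj(epre);
    for (int i = 0; i < ns; ++i) {
      const cd* Ti = &T[9 * i];
      cd B[9];
      // B = Ti * A
      for (int c = 0; c < 3; ++c) {
        const cd a0 = A[3 * c], a1 = A[3 * c + 1], a2 = A[3 * c + 2];
        B[3 * c]     = Ti[0] * a0 + Ti[3] * a1 + Ti[6] * a2;
        B[3 * c + 1] = Ti[1] * a0 + Ti[4] * a1 + Ti[7] * a2;
        B[3 * c + 2] = Ti[2] * a0 + Ti[5] * a1 + Ti[8] * a2;
      }
      // A = S(psi_step) * B: scale rows 1 and 2
      for (int c = 0; c < 3; ++c) {
        A[3 * c] = estep * B[3 * c];
        A[3 * c + 1] = std::conj(estep) * B[3 * c + 1];
        A[3 * c + 2] = B[3 * c + 2];
      }
    }
    for (int c = 0; c < 3; ++c) {
      A[3 * c] *= epost;
      A[3 * c + 1] *= std::conj(epost);
    }
    for (int e = 0; e < 9; ++e) out(j, e) = Rcomplex{A[e].real(), A[e].imag()};
  }
  return out;
}

// Direct Bloch (isochromat) simulation in real Cartesian coordinates using
// the rotation-operator algorithm. Per TR: precession by phase_tr (omega*TR +
// k_sp*z), relaxation over TR, then the slice-selective pulse as a hard-pulse
// train (prewinder, alternating Rodrigues rotations and gradient precession,
// refocuser). Records M+(z) directly after each RF pulse.
// alphas: ns x nTR matrix of hard-pulse flips; phis: per-TR RF phase.
// [[Rcpp::export]]
ComplexMatrix cpp_bloch_train(NumericMatrix alphas, NumericVector phis,
                              NumericVector psi_step, NumericVector psi_pre,
                              NumericVector psi_post, NumericVector phase_tr,
                              double E1, double E2, bool invert_first) {
  const int ns = alphas.nrow();
  const int nTR = alphas.ncol();
  const int N = psi_step.size();
  if ((int)phis.size() != nTR) stop("phis length mismatch");

  std::vector<double> Mx(N, 0.0), My(N, 0.0), Mz(N, 1.0);
  if (invert_first) for (int j = 0; j < N; ++j) Mz[j] = -Mz[j];

  // per-isochromat rotation cos/sin for the fixed phases
  std::vector<double> cst(N), sst(N), cpr(N), spr(N), cpo(N), spo(N), ctr(N), str(N);
  for (int j = 0; j < N; ++j) {
    cst[j] = std::cos(psi_step[j]); sst[j] = std::sin(psi_step[j]);
    cpr[j] = std::cos(psi_pre[j]);  spr[j] = std::sin(psi_pre[j]);
    cpo[j] = std::cos(psi_post[j]); spo[j] = std::sin(psi_post[j]);
    ctr[j] = std::cos(phase_tr[j]); str[j] = std::sin(phase_tr[j]);
  }

  ComplexMatrix out(N, nTR);
  std::vector<double> R(9 * ns);

  for (int n = 0; n < nTR; ++n) {
    // Rodrigues rotation matrices about axis (cos phi, sin phi, 0), angle a
    const double cphi = std::cos(phis[n]), sphi = std::sin(phis[n]);
    for (int i = 0; i < ns; ++i) {
      const double a = alphas(i, n);
      const double ca = std::cos(a), sa = std::sin(a);
      double* Ri = &R[9 * i];
      // R = Rz(phi) * Rx(a) * Rz(-phi), row-major
      Ri[0] = cphi * cphi + sphi * sphi * ca;
      Ri[1] = cphi * sphi * (1.0 - ca);
      Ri[2] = sphi * sa;
      Ri[3] = Ri[1];
      Ri[4] = sphi * sphi + cphi * cphi * ca;
      Ri[5] = -cphi * sa;
      Ri[6] = -Ri[2];
      Ri[7] = -Ri[5];
      Ri[8] = ca;
    }
    for (int j = 0; j < N; ++j) {
      double x = Mx[j], y = My[j], z = Mz[j];
      // S(omega*TR + k_sp*z): rotate transverse by +phase (M+ *= e^{i phase})
      double xr = ctr[j] * x - str[j] * y;
      double yr = str[j] * x + ctr[j] * y;
      x = xr; y = yr;
      // relaxation over TR
      x *= E2; y *= E2; z = E1 * z + (1.0 - E1);
      // prewinder
      xr = cpr[j] * x - spr[j] * y; yr = spr[j] * x + cpr[j] * y; x = xr; y = yr;
      // hard-pulse train
      for (int i = 0; i < ns; ++i) {
        const double* Ri = &R[9 * i];
        const double nx = Ri[0] * x + Ri[1] * y + Ri[2] * z;
        const double ny = Ri[3] * x + Ri[4] * y + Ri[5] * z;
        const double nz = Ri[6] * x + Ri[7] * y + Ri[8] * z;
        // gradient precession over dt
        x = cst[j] * nx - sst[j] * ny;
        y = sst[j] * nx + cst[j] * ny;
        z = nz;
      }
      // refocuser
      xr = cpo[j] * x - spo[j] * y; yr = spo[j] * x + cpo[j] * y; x = xr; y = yr;
      Mx[j] = x; My[j] = y; Mz[j] = z;
      out(j, n) = Rcomplex{x, y};
    }
  }
  return out;
}

struct SsepgState {
  std::vector<cd> fp, fm, zc;
  int m0;     // index of lattice point k' = 0
  int lo, hi; // occupied index window
};

static void ssepg_shift(SsepgState& s, int sh) {
  if (sh == 0) return;
  const int size = (int)s.fp.size();
  if (s.lo - std::abs(sh) < 0 || s.hi + std::abs(sh) >= size)
    stop("ssEPG lattice overflow: increase m_max");
  if (sh > 0) {
    for (int m = s.hi; m >= s.lo; --m) s.fp[m + sh] = s.fp[m];
    for (int m = s.lo; m <= s.lo + sh - 1; ++m) s.fp[m] = cd(0, 0);
    for (int m = s.lo; m <= s.hi; ++m) s.fm[m - sh] = s.fm[m];
    for (int m = s.hi; m >= s.hi - sh + 1; --m) s.fm[m] = cd(0, 0);
  } else {
    const int a = -sh;
    for (int m = s.lo; m <= s.hi; ++m) s.fp[m - a] = s.fp[m];
    for (int m = s.hi; m >= s.hi - a + 1; --m) s.fp[m] = cd(0, 0);
    for (int m = s.hi; m >= s.lo; --m) s.fm[m + a] = s.fm[m];
    for (int m = s.lo; m <= s.lo + a - 1; ++m) s.fm[m] = cd(0, 0);
  }
  s.lo -= std::abs(sh);
  s.hi += std::abs(sh);
}

// Slice-selective EPG: hard-pulse approximation carried out on a fine
// k-space lattice with state increment dk = gamma*G*dt. Hard pulses mix
// (F+, F-, Z) at each lattice point; every precession interval shifts F+
// up / F- down by one lattice step; gradient moments enter as integer
// multiples of dk (s_pre, s_post, s_sp). Off-resonance advances a uniform
// phase omega*TR per repetition. Signal of echo order q is the state at
// lattice index q * s_sp after each pulse.
// [[Rcpp::export]]
List cpp_ssepg_train(NumericMatrix alphas, NumericVector phis,
                     int s_pre, int s_post, int s_sp, double phase_tr,
                     double E1, double E2, bool invert_first,
                     IntegerVector q_orders, int m_max) {
  const int ns = alphas.nrow();
  const int nTR = alphas.ncol();
  const int size = 2 * m_max + 1;
  SsepgState st;
  st.fp.assign(size, cd(0, 0));
  st.fm.assign(size, cd(0, 0));
  st.zc.assign(size, cd(0, 0));
  st.m0 = m_max;
  st.lo = st.hi = m_max;
  st.zc[st.m0] = invert_first ? cd(-1, 0) : cd(1, 0);

  const cd etr(std::cos(phase_tr), std::sin(phase_tr));
  ComplexMatrix signals(q_orders.size(), nTR);
  cd T[9];

  for (int n = 0; n < nTR; ++n) {
    // S(omega*TR + k_sp*z): uniform phase + lattice shift by s_sp
    ssepg_shift(st, s_sp);
    if (phase_tr != 0.0) {
      for (int m = st.lo; m <= st.hi; ++m) {
        st.fp[m] *= etr;
        st.fm[m] *= std::conj(etr);
      }
    }
    // relaxation + recovery
    for (int m = st.lo; m <= st.hi; ++m) {
      st.fp[m] *= E2; st.fm[m] *= E2; st.zc[m] *= E1;
    }
    st.zc[st.m0] += (1.0 - E1);
    // RF pulse: prewinder, [mix, step]*, refocuser
    ssepg_shift(st, s_pre);
    for (int i = 0; i < ns; ++i) {
      hard_pulse_matrix(alphas(i, n), phis[n], T);
      for (int m = st.lo; m <= st.hi; ++m) {
        const cd fp = st.fp[m], fm = st.fm[m], z = st.zc[m];
        st.fp[m] = T[0] * fp + T[3] * fm + T[6] * z;
        st.fm[m] = T[1] * fp + T[4] * fm + T[7] * z;
        st.zc[m] = T[2] * fp + T[5] * fm + T[8] * z;
      }
      ssepg_shift(st, 1);
    }
    ssepg_shift(st, s_post);
    for (int iq = 0; iq < q_orders.size(); ++iq) {
      const int idx = st.m0 + q_orders[iq] * s_sp;
      cd v = (idx >= 0 && idx < size) ? st.fp[idx] : cd(0, 0);
      signals(iq, n) = Rcomplex{v.real(), v.imag()};
    }
  }

  ComplexVector fp_out(size), fm_out(size), zc_out(size);
  for (int m = 0; m < size; ++m) {
    fp_out[m] = Rcomplex{st.fp[m].real(), st.fp[m].imag()};
    fm_out[m] = Rcomplex{st.fm[m].real(), st.fm[m].imag()};
    zc_out[m] = Rcomplex{st.zc[m].real(), st.zc[m].imag()};
  }
  return List::create(_["f_plus"] = fp_out, _["f_minus"] = fm_out,
                      _["z_comp"] = zc_out, _["m0_index"] = st.m0 + 1,
                      _["lo"] = st.lo + 1, _["hi"] = st.hi + 1,
                      _["signals"] = signals);
}
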