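---
title: "Hybrid Bloch-EPG simulation of slice-selective SSFP sequences"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hybrid Bloch-EPG simulation of slice-selective SSFP sequences}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem

Quantitative MRI methods such as MR fingerprinting (MRF) match measured
signal time courses against simulated dictionaries, so the forward model must
be exact. One stubborn confounder is the slice-selective RF pulse: the flip
angle (and phase) vary across the slice, and in gradient-spoiled SSFP
sequences the interplay of this slice profile with the spoiling gradient
re-introduces an off-resonance dependency that idealized extended-phase-graph
(EPG) simulations miss. Direct Bloch (isochromat) simulations capture the
effect but must be re-run for every off-resonance, echo time, dephasing rate
and spoiling moment of interest, and they alias unless the isochromat density
matches the highest dephasing moment simulated.

`blochepg` implements a hybrid formalism that keeps the EPG's configuration
states for spoiling while representing the slice profile in its natural
spatial basis. One engine run then yields the signal's dependency on echo
time `TE`, off-resonance `omega`, microscopic dephasing `R2'`, spoiling
moment `k_sp` and refocused echo order `q` *analytically*.

## The model

Magnetization is handled as the 4-vector `(M+, M-, Mz, M0)` with
`M± = Mx ± i My`; hard pulses `T_phi(alpha)`, relaxation `R(t)` and phase
accrual `S(phi)` act as 4x4 operators (`rotation_operator()`,
`relaxation_operator()`, `precession_operator()`). A shaped pulse played
under a constant slice gradient `G` is discretized into hard pulses
alternating with free precession; together with the pre-winder and
refocusing moments this composes an effective per-position rotation `RF(z)`
(`effective_rf()`), which decomposes per position into an effective flip
angle `alpha(z)`, pulse phase `phi(z)` and pre-phase `phi_pre(z)`
(`euler_decompose()`).

For a constant-TR sequence the per-repetition phase accrual
`phi = omega*TR + k_sp*z` can be expanded as a Fourier series. The Fourier
coefficients are spatially-resolved configuration states
`F+_k(z), F-_k(z), Z_k(z)`; each repetition acts on them as
`shift -> relax -> RF` (`run_sr_epg()`). Crucially, neither `omega` nor
`k_sp` enters the recursion: the signal of echo order `q` is assembled
afterwards as

```
s = sum_k W_k(omega, R2', TE) * sum_i dz * sinc((k-q) k_sp dz / 2)
      * exp(i (k-q) k_sp z_i) * F+_{k,i}
```

(`epg_signal()`). The weighting `W_k` acts on the echo formed at
`t = k*TR + TE`; the Lorentzian form `exp(i omega t - R2'|t| - TE/T2)` is the
default, with Gaussian, spherical (Bessel-ratio), multi-peak (e.g. fat
spectrum) and user-supplied characteristic-function variants
(`weighting_spec()`). The `sinc` term — the damping factor — is the Fourier
transform of the piecewise-constant bin kernel and accounts for intra-bin
dephasing of order-`k` states.

Two classical sequences are exact special cases: `k_sp = 0` is balanced SSFP
(`signal_bssfp()`, degenerate in the echo order), and `k_sp -> infinity`
collapses the sum onto the single refocused order — the partitioned EPG
(`signal_pepg()`), whose magnitude is off-resonance independent.

## Reference simulators

Two independent implementations form the cross-validation surface:

* `bloch_run()` — a rotation-operator isochromat simulation written in real
  Cartesian coordinates (Rodrigues rotations), with off-resonance and
  spoiling applied numerically per repetition. It shares no operator code
  with the engine.
* `ssepg_run()` — a slice-selective EPG that performs the hard-pulse
  approximation entirely in k-space on a fine lattice with state increment
  `dk = gamma*G*dt`. Spoiling, pre-winder and refocusing moments are rounded
  to integer multiples of `dk` (residuals are reported); states are truncated
  only on lattice overflow, never by magnitude, so the oracle stays exact.

`recover_bloch_profile()` and `recover_kspace()` map the hybrid states onto
both views; `nrmse_bloch()` / `nrmse_ssepg()` quantify the agreement, both
normalized by the magnitude of the spatial mean of the Bloch profile so that
profile- and k-space-level errors share one scale. The ssEPG states are
Fourier-series coefficients on the period `2*pi/dk`, whereas the hybrid
k-space is integral-scaled; comparisons divide the hybrid values by the
period and use a symmetric lattice window covering the occupied
configuration orders plus one pulse bandwidth on each side (beyond that
window both representations are numerically zero, and padding the window
would only dilute the RMS).

## Parameters and defaults

The bundled test configuration (`build_fixture_sequence()`) follows the
reference study conditions:

| parameter | default | meaning |
|---|---|---|
| `kappa` | 10 | time-bandwidth product of the Hann-apodized sinc pulse |
| `delta` | 5 mm | nominal slice thickness; `2*pi*kappa = gamma*G*T_ex*delta` |
| `T_ex` | 1 ms | pulse duration (cancels out of all signal-level results, since only `gamma*G*T_ex = 2*pi*kappa/delta` enters the operators) |
| `TR` | 15 ms | repetition time (constant — a formalism requirement) |
| `k_sp` | `4*2*pi/delta` | spoiling moment along the slice direction |
| grid | 3001 bins over `3*delta` | slice discretization |
| `T1`, `T2` | 800 ms, 50 ms | tissue relaxation |
| flip train | 100 pulses, inversion-prepared | 15 deg (1–14), linear ramp 15–50 deg (15–50), half-sine bump peaking at 70 deg at index 75 (51–100) |

The flip train is a deterministic approximation of the reference MRF train
(only its anchors — ramp range, maximum flip, high-flip region — are
published); an arbitrary measured train can be supplied via
`mrf_sequence()`. The refocusing moment is computed once from the
maximum-flip (70 deg) pulse via the focus point `t_f` (FID maximization,
golden-section search with tolerance `dt/10`) and reused for all
amplitude-scaled pulses, as on clinical systems; consequently the effective
pulse phase is not perfectly flat at low flips. The refocusing lobe has
polarity opposite to the slice gradient, `k_post = -gamma*G*t_f`, so that
`k_pre = -(gamma*G*T_ex + k_post)` leaves the block moment-balanced; this is
the only sign convention under which the pre- and post-lobes carry the equal
areas required for refocusing.

Hard pulses are sampled at interval midpoints, `t_i = (i - 1/2) dt`, making
the discrete flip sum a midpoint quadrature of the envelope integral; the
default is 1000 steps per pulse. The method-comparison mode uses 145 steps
per excitation and rounds all moments to the ssEPG state increment so that
the three simulators are exactly comparable. ("145 temporal steps" is read
as steps per excitation pulse; any other step count is one argument away.)

## Numerical choices

* **Euler gauge.** When `sin(alpha) < 1e-12` the pulse phase is undefined;
  it is gauged to zero and all phase folded into `phi_pre`. The pre-phase is
  extracted from `cos^2(alpha/2) e^{i phi_pre}` or, when that entry is
  ill-conditioned (`alpha` near `pi`), from the conjugate off-diagonal entry.
* **Aliasing.** An equally discretized Bloch simulation (equivalently, the
  hybrid signal without the damping factor) is exact until the first order
  with `k * k_sp * dz > 2*pi` is populated (`aliasing_kmax()`), then aliases
  abruptly; with the damping factor the discretization can follow accuracy
  needs instead of the spoiling moment. `run_simulate()` logs the check.
* **Order bookkeeping.** `K = n_TR + 1` orders are preallocated; the engine
  touches only the occupied window (linear phase-graph growth). A shift that
  would push occupied transverse states past `K` raises an error rather than
  truncating silently. Shifting a state with no transverse content is a
  no-op, so idle repetitions do not inflate the occupied window.
* **Memory.** `run_sr_epg()` keeps only the final state by default;
  `keep = "fplus"` retains the full `F+` history (bins x orders x n — about
  1 GB at the full study size), while `signal_specs` / `ksp_projection`
  stream signals or spoiling-moment projections per repetition without
  retaining history. The spoiling-moment sweep uses the streaming projection.
* **Equilibrium component.** The fourth component `delta_{k,0}` is stored
  implicitly; relaxation adds `(1 - E1)` to `Z_0` directly, which is exact.
* **Infinite-spoiling tests.** On a grid where `k_sp * dz` is a multiple of
  `2*pi` the damping factor vanishes identically for all `k != q`, so the
  partitioned-EPG identity holds to machine precision; tests use such a
  commensurate grid (N = 300 over `3*delta` with `k_sp = 1e6 * 2*pi/delta`)
  because for generic grids the sinc tails decay only like `1/k_sp`.

## What the tests do and do not show

The test suite cross-validates the hybrid signal against the Cartesian Bloch
oracle over all analytic axes (TE, omega, k_sp, q) and against the ssEPG in
k-space, reproduces the aliasing-onset orders (250 / 25 / 12.6 for N = 3001 /
301 / 151), and verifies that suppressing the off-resonance variation of the
F0 signal below 1% on the bundled train requires a spoiling moment of at
least `8 * 2*pi/delta` (measured: 8.25). Unit and property tests run on
miniature grids (up to 301 bins, 24 repetitions); the acceptance tests use
the full study sizes (3001 bins, 100 repetitions, sweeps over 49 spoiling
moments x 101 off-resonance values).

The synthetic inputs emulate amplitude-scaled Hann-sinc excitation under
ideal gradients with instantaneous acquisition. They do not emulate:
relaxation during the RF pulse (the effective operator would cease to be a
rotation; deliberately out of scope), variable TR (the phase graph would
branch exponentially), B1+ transmit inhomogeneity or spatially varying
T1/T2/M0 across the slice (the engine accepts per-bin operators, but no
convenience plumbing is provided), diffusion, magnetization transfer, or any
acquisition-trajectory/readout effects. Agreement of the three simulators
therefore validates the formalism and its implementation, not the fidelity
of any particular scanner protocol. The Bloch oracle also does not simulate
Lorentzian microscopic dephasing (that would require an isochromat ensemble
over frequency); the `R2'` weighting is validated against its closed form
and its Gaussian/spherical limits instead.

## Known limitations

* Constant TR and constant spoiling moment are structural assumptions.
* The printed reference agreement figures for the method comparison depend
  on the exact (unpublished) flip train; with the bundled approximation the
  comparison bounds are met with large margin but the literal values differ.
* The full-history mode is memory-hungry by design; use the streaming
  options for dictionary-scale work.
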