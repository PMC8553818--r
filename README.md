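# blochepg

Hybrid Bloch-EPG simulation of balanced and gradient-spoiled SSFP signal
time courses with realistic slice-selective RF pulses — the forward model
behind MR-fingerprinting (MRF) dictionaries — plus two independently
implemented reference simulators (direct Bloch and slice-selective EPG) for
cross-validation.

## Who this is for

Researchers in quantitative MRI who need exact transient-state signal
models: slice profiles re-introduce an off-resonance dependency in spoiled
SSFP/MRF that idealized EPG simulations miss, while direct Bloch simulations
must be re-run per parameter set and alias when the isochromat density is
too low for the spoiling moment.

## The model

Magnetization is evolved as spatially-resolved configuration states
`F+_k(z_i), F-_k(z_i), Z_k(z_i)` — the Fourier coefficients of the
magnetization with respect to the per-TR phase accrual
`phi = omega*TR + k_sp*z`. Each repetition applies `shift -> relax -> RF(z)`,
where `RF(z)` is the hard-pulse composition of the shaped pulse
(Hann-apodized sinc with time-bandwidth product `kappa`, slice thickness
`delta`, `2*pi*kappa = gamma*G*T_ex*delta`) with its pre-winder and
refocusing moments. Off-resonance and spoiling never enter the recursion;
the signal of echo order `q` is assembled analytically,

    s^(n) = sum_k W_k(omega, R2', TE) sum_i dz sinc((k-q) k_sp dz/2)
            e^{i (k-q) k_sp z_i} F+_{k,i}^(n),

with `W_k = exp(i omega (k TR + TE) - R2'|k TR + TE| - TE/T2)` (Gaussian,
spherical, multi-peak and custom line shapes available). One engine run
therefore serves every `(TE, omega, R2', k_sp, q)` combination: `k_sp = 0`
recovers balanced SSFP, `k_sp -> infinity` the partitioned EPG, dropping the
sinc damping factor reproduces an equally discretized Bloch simulation
(including its aliasing at order `k_max = 2*pi/(dz*k_sp)`), and a spatial
Fourier transform recovers the slice-selective EPG view.

## Worked example

Sixteen pulses of the bundled inversion-prepared MRF train on a reduced grid
(301 bins, 64 hard-pulse steps), with the three-way method comparison:

```r
library(blochepg)
cfg <- list(sequence = list(n_pulses = 16L),
            pulse    = list(n_samples = 64L),
            grid     = list(n_bins = 301L),
            options  = list(round_moments = TRUE))
df <- run_simulate(cfg)
head(df[, c("n", "k_sp", "re", "im")], 5)
#>   n k_sp         re        im
#> 1 1 5105 -3.775e-21 0.0012334
#> 2 2 5105 -9.489e-21 0.0011520
#> 3 3 5105 -8.693e-21 0.0010659
#> 4 4 5105 -7.472e-21 0.0009761
#> 5 5 5105 -1.506e-20 0.0008881
run_compare(cfg)
#>                 metric    value
#> 1  nrmse_bloch_profile 1.93e-14
#> 2   nrmse_ssepg_kspace 8.21e-03
#> 3 rel_dev_hybrid_bloch 1.64e-04
#> 4  rel_dev_ssepg_bloch 1.88e-06
```

The signal is purely imaginary (a real pulse tips equilibrium onto `-i`),
recovering through the inversion null; `k_sp` is the spoiling moment in
rad/m (`4*2*pi/delta`, rounded to the ssEPG lattice). The comparison report
shows the hybrid slice profile agreeing with the Cartesian Bloch simulation
at machine precision on a shared discretization, and signal deviations of
`1.6e-4` (hybrid vs Bloch — the intra-bin damping factor, which shrinks with
bin count) and `1.9e-6` (ssEPG vs Bloch). At the full study size (3001 bins,
145 steps) the k-space nRMSE drops to `3e-6`.

The same objects are scriptable:

```sh
Rscript inst/cli/blochepg simulate --config cfg.yaml --out signals.tsv
Rscript inst/cli/blochepg compare  --config cfg.yaml --out report.tsv
```

See `vignettes/hybrid-bloch-epg.Rmd` for the full model description,
parameter meanings and numerical choices.

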