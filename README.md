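# thtmito

Mechanistic modelling and single-cell trace analysis of thioflavin T
(ThT) as a mitochondrial membrane potential dye.

ThT, the standard amyloid marker, is a membrane-permeant cation: like
TMRM it accumulates in the mitochondrial matrix according to the Nernst
relation $c_{in}/c_{out} = e^{-zF\Delta\Psi/RT}$ and so reports the
mitochondrial membrane potential ΔΨm. But bound ThT is photosensitized
by blue light, produces reactive oxygen species, and can itself collapse
ΔΨm — an effect that needs *both* micromolar dye and light. This package
implements:

- **model core** — a six-variable ODE model of both dyes in a
  two-compartment cell: Goldman–Hodgkin–Katz fluxes
  $J = PZx\,(c_{in}-c_{out}e^{-x})/(1-e^{-x})$, $x = ZF\Delta\Psi/RT$,
  across plasma and inner mitochondrial membranes; a cooperative Hill
  step $k_{on}c^n/(K^n+c^n)$ for combined ThT binding +
  photosensitization; and a linear depolarization coupling
  $\Delta\Psi_m = \delta\,[ThT_{mphoto}] + \Delta\Psi_{m,0}$.
- **experiments** — scripted reproductions: light-step trajectories,
  an 8×8 dose × light phase grid of normalized steady-state TMRM,
  sensitivity sweeps of the Hill parameters, FCCP (protonophore) and
  dye-equilibration emulations.
- **trace analysis** — per-cell mean-intensity extraction from label
  masks, baseline and min–max normalization, final/initial response
  ratios, a Mann–Whitney U test (exact enumeration for small samples,
  Edgeworth-corrected normal beyond), population mean ± SD, pixel-wise
  colocalization regression, and the dose × time response matrix.
- **synthetic data** — a seeded generator of per-cell traces and
  two-channel 16-bit time-lapse stacks (cell masks, filamentous
  mitochondrial templates, lognormal cell gains, Poisson-like + read
  noise) with exact ground truth and an analytic colocalization
  expectation.

For whom: anyone choosing imaging conditions for ThT in live cells
(which doses and light levels leave ΔΨm intact), or needing a tested
reference implementation of the accompanying trace statistics.

## Worked example

Equilibrate both dyes (5 µM ThT, 25 nM TMRM) in the dark, then raise the
photosensitization rates 10-fold at t = 2 min:

```r
library(thtmito)
res <- run_photo_step(dose = 5, kon_multiplier = 10, horizon = 1800)
tr  <- res$trajectory
```

```
pre-step steady state: tmrm_m = 30.573 uM, dpsi_m = -150.0 mV
final (t = 1800 s):    tmrm_m = 17.809 uM, dpsi_m = -81.9 mV
photosensitized mito ThT plateau: 4.54 uM (monotone rise: TRUE)
```

The photosensitized pool rises monotonically to ~4.5 µM, which through
δ = 15 mV/µM depolarizes the inner membrane from −150 to −82 mV; at the
new steady state mitochondrial TMRM sits 92% below its dark value. The
same sweep over doses and light levels (`run_phase_grid()`) gives the
fraction of baseline TMRM retained:

```
dose   0.0   0.5   1.0   2.0   3.5   5.0   7.5  10.0   (light multiplier)
0.00     1 1.000 1.000 1.000 1.000 1.000 1.000 1.000
0.20     1 0.986 0.973 0.951 0.924 0.902 0.873 0.850
1.00     1 0.771 0.623 0.480 0.397 0.357 0.319 0.296
5.00     1 0.755 0.571 0.327 0.159 0.112 0.088 0.078
```

No light or no dye leaves TMRM at baseline (first row/column exactly 1);
0.2 µM barely registers, 1–5 µM depolarize strongly — the additive
dose-and-light requirement. On the analysis side, synthetic FCCP vs mock
populations (20 cells each) separate cleanly:

```
TMRM final/initial ratios: mock 0.968 vs FCCP 0.213
Mann-Whitney U = 400, p = 6.8e-08 (normal branch)
colocalization: R^2 = 0.9981 (analytic expectation 0.9981)
```

The numbered scripts under `analysis/` run these end to end and write
their tables beneath `results/`:

```sh
Rscript analysis/01_photo_step.R          # light-step trajectory
Rscript analysis/02_phase_grid.R          # dose x light phase grid
Rscript analysis/03_sensitivity.R         # Hill-parameter sensitivity
Rscript analysis/04_fccp_equilibration.R  # FCCP vs mock, dye loading
Rscript analysis/05_synthetic_pipeline.R  # synthetic traces + statistics
Rscript analysis/06_parameter_recovery.R  # (delta, Konm) identifiability
```

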