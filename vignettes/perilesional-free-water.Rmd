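---
title: "Perilesional free-water imaging: model, shells, and longitudinal statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Perilesional free-water imaging: model, shells, and longitudinal statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fwshells)
```

# The scientific problem

After a small subcortical ischemic stroke, the tissue around the visible
lesion changes for months: vasogenic edema enlarges the extracellular space
early on, Wallerian degeneration damages axons and myelin at a distance, and
atrophy and gliosis reshape the chronic lesion. Conventional diffusion tensor
imaging conflates these processes, because extracellular water and cellular
microstructure both move fractional anisotropy (FA).

Free-water imaging separates them with a two-compartment signal model. In
every voxel the diffusion-weighted attenuation is

$$A_i = f_T\, e^{-b_i\, g_i^\top D_T\, g_i} + (1 - f_T)\, e^{-b_i d_w},$$

where $f_T$ is the tissue volume fraction, $D_T$ the tissue diffusion
tensor, $d_w = 3.0\times10^{-3}\,\mathrm{mm^2/s}$ the diffusivity of free
water at body temperature, and $b_i$, $g_i$ the diffusion weighting and
direction of volume $i$. The *free-water fraction* $FW = 1 - f_T$ tracks the
extracellular compartment; the FA of $D_T$ (written FA~T~) tracks the
cellular compartment with the free water eliminated.

This package implements the full analysis around that model for a
longitudinal lesion study, and — because the motivating patient data are not
public — a synthetic-data layer that generates everything the analysis
consumes: mirror-symmetric digital phantoms with one subcortical lesion,
single-shell diffusion acquisitions (64 directions at
$b = 1500\,\mathrm{s/mm^2}$ plus one $b=0$, 2 mm isotropic voxels), Rician
noise, and four-timepoint cohorts with realistic retention.

# Pipeline stages

1. **simulate** — phantom anatomy, ground-truth $FW$/FA~T~ maps, forward
   signals, Rician noise (`phantom_spec()`, `make_truth_maps()`,
   `simulate_dwi()`, `simulate_cohort()`).
2. **fit** — the bi-tensor model by constrained nonlinear least squares
   (`fit_bitensor()`).
3. **shells** — lesion and perilesional region construction with
   contralateral mirroring (`build_shellset()`).
4. **extract** — region means and contralateral normalization
   (`extract_measures()`).
5. **stats** — per-region t-tests, longitudinal and cross-sectional mixed
   models, correlations, power (`fit_longitudinal_lmm()` and friends).

`run_pipeline()` ties the stages together from one nested configuration and
writes every intermediate artifact (NIfTI volumes, FSL-style gradient files,
TSV tables, a JSON run report).

# Fitting the bi-tensor model on single-shell data

The fit minimizes the attenuation sum of squares per voxel with the tissue
fraction box-constrained to $[\varepsilon, 1-\varepsilon]$
($\varepsilon = 0.01$) and $D_T$ kept positive semidefinite through a
lower-triangular (Cholesky) factorization, using a Levenberg–Marquardt solver
batched across voxels. Iteration stops when the largest parameter step falls
below `tol` ($10^{-6}$) or the relative cost decrease falls below `ftol`
($10^{-10}$), with a 200-iteration cap; non-converged voxels keep their best
iterate and are flagged in `n_iter_map`/`converged_map`, never aborting a
volume.

## Why the fit needs priors at a single b-value

With a single shell the model is not identifiable voxelwise: the intercept of
a log-linear fit is exactly collinear with the tensor trace, so a larger
free-water fraction can be traded against a smaller tissue mean diffusivity
with almost no change in the predicted signal. Two soft penalties make the
problem well-posed, both exposed in `fw_fit_config()`:

- `lambda_md` (default 0.1) anchors $\mathrm{tr}(D_T)/3$ to a reference
  healthy-tissue diffusivity (`md_tissue_ref`,
  $0.7\times10^{-3}\,\mathrm{mm^2/s}$). This is the assumption that carries
  the identifiability; on real data it biases $FW$ in proportion to how far
  true tissue MD departs from the reference.
- `lambda_reg` (default 0.1) pulls each voxel's $f_T$ toward the 6-neighbour
  mean of the previous outer iterate (three outer cycles), an
  iterated-Tikhonov smoothness term that plays the role of the original
  gradient-flow regularization of the method this model derives from. We do
  not claim equivalence with that implementation, whose exact functional is
  not published.

Initialization follows the same logic: a log-linear tensor fit, rescaled to
the reference MD, gives the tissue attenuation scale, and the mixture
equation is solved for $f_T$. The textbook MD-interpolation initializer
(`init_freewater()`) is kept available but is biased on single-shell data
(it maps the apparent MD, which already absorbs the free-water offset).

With both penalties at their defaults, on a noiseless phantom the
default-initialized fit recovers $FW$ to well below $10^{-6}$ (median); at
SNR 30 the white-matter RMSE is about 0.017, and at SNR 10 the unpenalized
fit visibly falls into the $FW$/MD valley (error correlation beyond 0.95)
while the penalties reduce the RMSE several-fold. The test suite asserts all
of these properties rather than quoting them.

# Shell construction choices

Shells are built by iterative morphological dilation and subtraction,
6-connected, so one iteration is exactly one voxel of city-block distance
(2 mm); shell $k$ is provably the set of voxels at L1 distance $k$ from the
lesion, which the tests verify against an independent brute-force distance
transform. 26-connectivity would advance 2 mm per iteration only along axes,
not diagonals, and was rejected for that reason. Shell labels (2 mm … 16 mm)
name the outer boundary of each ring.

The analysis order is: flip the lesion across the midline, subtract
ventricles from the flipped lesion (the contralateral reference must not
contain CSF), build 8 shells around both lesions separately, remove the
intersection of corresponding ipsi/contra shells *from both sides*
(the symmetric reading; the alternative one-sided subtraction is not used),
and filter the shells — not the lesion — with the white matter mask eroded
twice (4 mm). Region means are normalized as
$(\mathrm{ipsi} - \mathrm{contra})/\mathrm{contra}$; empty reference regions
yield `NA`, never infinities.

The synthetic midline is a voxel plane (odd left–right dimension), so the
flip is an exact axis reflection. Real data must arrive on a
midline-symmetric grid with pre-aligned masks; nonlinear registration is out
of scope.

# The cohort generator

`cohort_design()` encodes the study conditions: 27 enrolled subjects with
26/21/19/19 scans at 3–5 days, ~1, ~3 and ~12 months; monotone-by-subject
dropout; 72% of evaluable lesions shrinking by the third timepoint;
log-normal baseline lesion volumes; ages near 67 ± 12 with 41% female.

The ground-truth effect (`effect_profile()`) sets the lesion free-water
elevation to +41% of the contralateral value at baseline, scaled per
timepoint by (1, 2.707, 5.073, 6.122) — i.e., +41/+111/+208/+251% — and the
lesion FA~T~ change to −34.3% scaled by (1, 1.087, 0.755, 0.534), deepest at
one month. Each 2-mm ring attenuates the delta geometrically; the decay is
*timepoint-specific* (FW: 0.665, 0.34, 0.34, 0.52; FA~T~: 0.29, 0.55, 0.62,
0.645) because the perilesional field recedes at one month while the lesional
effect keeps growing — a scalar decay cannot express that and would force
every timepoint contrast to scale with the lesion trajectory.

Measure-level noise has a between-subject component (SD 0.15 for FW, 0.02
for FA~T~), a per-region residual (0.38 and 0.066), an optional scan-level
component (default 0 — switching it on induces within-session correlation
that the subject+location random-intercept model does not capture), and a
location random intercept (0.05/0.01) representing residual spatial structure
of the effect profile; a null cohort carries none of the latter. These SDs
were calibrated once to the reported cohort uncertainties (a lesion-level
spread near 0.4 and timepoint-contrast standard errors near 0.05 for FW and
0.007 for FA~T~) and are not adjusted thereafter.

What the generator does *not* emulate: heteroscedasticity over timepoints
(observed lesion spreads grow with the effect), realistic fiber architecture
(the truth tensor field is cylindrically symmetric with a smooth axis rule),
susceptibility/eddy artifacts, multi-shell acquisitions, and spatial
correlation of noise. Passing tests therefore demonstrate correctness of the
algorithms under the stated model, not performance on real scanners.

Two simulation granularities exist by design: the image path materializes
full DWI volumes per scan (used by the pipeline and the imaging tests), while
`simulate_cohort_measures()` draws normalized region measures directly from
the mixed-effects structure — replicate-level statistical calibration
(hundreds of model fits) would be unaffordable through the image path and
adds nothing to what it checks.

# Statistics layer

Per region and timepoint, one-sample t-tests on the normalized measures
(reported in percent with 95% CI and Cohen's d = mean/SD; no multiplicity
correction across the grid, matching the source design). The longitudinal
model is

`normalized ~ lesion_volume_ml + age + sex + days_z + timepoint +
(1|subject) + (1|location)`

fitted by REML, with the first timepoint as dummy reference and
days-since-event z-scored *within* each timepoint (so scan-interval deviations
are controlled without absorbing the timepoint effect; degenerate groups map
to 0). The omnibus timepoint test is a Wald chi-square on the dummy block
(LRT available); pairwise contrasts are Tukey-adjusted estimated marginal
means with Satterthwaite degrees of freedom (the source does not state its
df method; this choice is flagged, not asserted as equivalent). R² follows
the Nakagawa variance-partition definition. Sex is coded with male as the
indicator level. Missing rows are dropped with a message — never imputed.
Cross-sectional models per timepoint use a subject random intercept with
location dummy-coded against the lesion.

Spearman correlations use midranks and a t-approximation, with exact
permutation enumeration available for n ≤ 9; adjusted robustness regressions
are OLS with a hard error on rank deficiency naming the collinear columns;
power for the one-sample t-test is the noncentral-t tail probability with
ncp $= d\sqrt{n}$.

Perilesional summaries average the 8 shell means unweighted (voxel-weighted
averaging would let large outer shells dominate; the source wording is
ambiguous and the unweighted reading was adopted).

# Numerical choices and degenerate inputs

- Attenuations, not raw signals, are fitted; `s0` is the geometric mean of
  the $b=0$ volumes; nonpositive attenuations are clamped to a floor and
  counted on the fit object.
- FA eigenvalue computation clamps negative eigenvalues to zero (message);
  the all-zero tensor has FA 0; eigenvalue order is irrelevant to FA.
- Ground-truth tensors invert the FA formula in closed form for a prolate
  axially symmetric tensor at fixed MD (quadratic root with $a \ge b \ge 0$).
- The gradient table is a spherical-Fibonacci lattice under a seeded random
  rotation: deterministic, near-uniform, and guaranteed pairwise
  non-collinear for the direction counts used here.
- Empty regions, empty erosions, and all-shell-empty WM filters warn and
  produce `NA`/empty masks; they never abort a run.

# Problem sizes

The shipped defaults are reduced problem sizes chosen for interactive use on
one CPU: a 31-voxel grid and 8 subjects in `default_config()`, 21–33-voxel
grids in the test fixtures, 60–200 replicates in the calibration and recovery
studies, and the 31³ phantom for the noiseless round trip. The cohort-level
statistical defaults (27 subjects, 26/21/19/19 retention) are the study
conditions themselves and are independent of these sizes.

# Known limitations

- Single-shell identifiability rests on the tissue-MD prior; absolute $FW$
  levels on real data inherit its bias. Contralateral normalization cancels
  much of it, which is one reason the normalized measures are the analysis
  currency.
- The regularizer approximates, but is not, the original gradient-flow
  scheme of the free-water method's reference implementation.
- The mirror-flip path requires a symmetric grid; real brains are not
  symmetric, and the registration-based flip used on patient data is out of
  scope.
- Clinical scores in the generator are plausible but schematic; correlation
  analyses against them demonstrate plumbing, not clinical claims.
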