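# fwshells

Longitudinal free-water imaging analysis of the tissue around subcortical
brain lesions, with a fully synthetic data path.

## What it does, and for whom

After a small subcortical ischemic stroke, white matter beyond the visible
lesion keeps changing for months: early vasogenic edema, Wallerian
degeneration of crossing axons, later atrophy and gliosis. Free-water imaging
separates these processes on ordinary single-shell diffusion MRI with a
two-compartment model per voxel,

    A_i = f_T exp(-b_i g_i' D_T g_i) + (1 - f_T) exp(-b_i d_w),

where `f_T` is the tissue volume fraction (free-water fraction
`FW = 1 - f_T`), `D_T` the free-water-corrected tissue tensor (its FA is
written FA_T), and `d_w = 3.0e-3 mm^2/s` the diffusivity of free water at
body temperature. `FW` tracks the extracellular compartment, FA_T the
cellular one.

The package is for neuroimaging researchers who want that analysis as tested,
scriptable R: it simulates single-shell acquisitions (64 directions,
b = 1500 s/mm^2, 2 mm voxels, Rician noise) over mirror-symmetric lesion
phantoms, fits the bi-tensor model by constrained, spatially regularized
nonlinear least squares, builds eight concentric 2-mm perilesional shells
with contralateral mirroring, ventricle subtraction and white-matter
filtering, normalizes region means as `(ipsilateral - contralateral) /
contralateral`, and runs the longitudinal statistics: per-region one-sample
t-tests, linear mixed-effects models with crossed subject and location random
intercepts and Tukey-adjusted timepoint contrasts, Spearman correlations,
covariate-adjusted regressions, and noncentral-t power estimates. A
four-timepoint cohort generator encodes the study conditions (27 subjects,
26/21/19/19 retention, 72% shrinking lesions, rising lesional free-water of
+41% to +251% with the FA_T reduction deepest at one month).

## Worked example

```r
library(fwshells)

spec    <- phantom_spec(grid_shape = c(27L, 26L, 26L), seed = 42)
phantom <- build_phantom(spec)
gtab    <- make_gradient_table(64, 1500, n_b0 = 1, seed = 42)
truth   <- make_truth_maps(phantom, effect_profile(), timepoint = 1)
dwi     <- simulate_dwi(truth, gtab, s0 = 1000, snr = 30, seed = 42)

fit     <- fit_bitensor(dwi, gtab, phantom$wm)
shells  <- build_shellset(phantom$lesion, phantom$ventricles, phantom$wm)
measures <- extract_measures(fit, shells, subject = "S01", timepoint = "TP1")
subset(measures, measure == "fw", select = c(location, ipsi_n, normalized))
```

which prints

```
   location ipsi_n normalized
1    lesion    123 0.45071300
3       2mm     57 0.32821742
5       4mm     66 0.22278706
7       6mm     76 0.13665519
9       8mm     84 0.09673185
11     10mm     83 0.04126722
13     12mm     89 0.04411672
15     14mm    119 0.02714475
17     16mm    138 0.02305423
```

The lesion row says the fitted free-water fraction inside the lesion is about
45% above its mirrored contralateral reference at this noise realization (the
configured ground truth at the first timepoint is +41%), and the elevation
decays with each 2-mm shell — the spatial gradient the analysis is built to
measure. `ipsi_n` counts the voxels of each region after white-matter
filtering and bilateral overlap removal.

For a full cohort run (simulate -> fit -> shells -> extract -> stats, with
every intermediate written to disk plus a JSON run report):

```r
run_pipeline(default_config(seed = 1), "out/")
```

A command-line wrapper with `simulate`, `fit`, `shells`, `extract`, `stats`
and `run-all` subcommands is installed at `inst/cli/fwshells`.

## Methods

The model, regularization, shell morphology, cohort design and statistical
choices are documented in `vignettes/perilesional-free-water.Rmd`.
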