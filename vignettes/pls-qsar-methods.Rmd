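---
title: "PLS-QSAR with ordered predictors selection: models, validation and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{PLS-QSAR with ordered predictors selection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(opsqsar)
```

## The model

`opsqsar` models a single activity (pIC50, the negative decadic
logarithm of the molar IC50) as a linear function of molecular
descriptors, estimated by partial least squares with one response
(PLS1). Descriptors are autoscaled — column-wise mean-centered and
scaled to unit sample variance (n−1 denominator, the convention of
mainstream chemometrics software) — and the activity is mean-centered.
Centering alone suffices for y: predictions are invariant to whether y
is additionally scaled, and `fit_pls(scale_y =)` exposes both choices.

Each latent variable (LV) is the direction in descriptor space whose
projection has maximal covariance with the activity. For a single
response NIPALS requires no iteration: the weight vector at each step
is the normalized covariance X′y of the deflated matrix, which makes
the fit fully deterministic — there is no initialization to choose and
no convergence tolerance. Deflation proceeds on both X and y; after
`A = rank(X)` components the residual descriptor block is numerically
zero, and the fitted values coincide with ordinary least squares.

Coefficients are reported on the original descriptor units (with
intercept) and in standardized form, `b_std_j = b_raw_j sd(x_j)/sd(y)`.
Standardized coefficients feed Wold's significance rule: a descriptor
is flagged as significant when its absolute standardized coefficient
reaches half the largest one. The rule is a heuristic; descriptors just
below the threshold may still be retained when removing them degrades
cross-validated quality.

The number of latent variables is the key complexity parameter. The
packaged pipeline defaults to choosing it by Q²_LOO inside the OPS
scan over `lv_range = 1..min(8, n−2)`; analyses that mirror the worked
MMP-2 study pin `ncomp = 3`.

## Ordered predictors selection

OPS ranks descriptors by the absolute value of an *informative vector*
and then scans nested subsets of the ranked matrix, fitting a PLS model
and scoring it by leave-one-out cross validation at each candidate
subset size and LV count. Three informative vectors are available:

* **correlation** — Pearson r of each descriptor with the activity;
  robust, but blind to descriptors whose value is conditional on others;
* **regression** — the standardized regression vector of a pilot PLS
  fit with `max(lv_range)` components; sees conditional importance but
  is noisier at small n;
* **product** — their elementwise product, a compromise that rewards
  agreement between the two views.

All three are run by `ops_run_all()`, and the winner is the trial with
the best criterion (maximal Q² or, equivalently at fixed n, minimal
SEV — SEV is a monotone transform of PRESS, so the two orderings are
identical and both are offered only for reporting convenience). Ties
are broken toward the smaller subset, then fewer latent variables, then
lexicographic descriptor names, so a seeded run is fully reproducible.

Cross validation inside the search re-autoscales within every fold by
default (`refit_scaling = TRUE`), so no information from the held-out
compound leaks into the scaling; a fixed-scaling mode mimicking tools
that scale once is available and clearly flagged, because the behaviour
of historical QSAR software differs on this point. The same applies to
the |r| ≥ 0.3 activity pre-filter: following the published workflow it
is applied once on the full data set before splitting, and this
leakage-prone but faithful default is recorded in the filter report.
At the threshold boundary, descriptors with |r| exactly equal to the
threshold are retained ("lower than" is removed), with a 1e−12 guard
so floating-point representation cannot flip the decision.

## The validation battery

Internal quality: R² = 1 − RSS/SSy, SEC = √(RSS/(n−p−1)) with p the
LV count, and the F ratio (R²/p)/((1−R²)/(n−p−1)) compared to the
upper-0.05 quantile of F(p, n−p−1). An exact fit reports R² = 1,
SEC = 0 and an overflow flag instead of a fabricated F value.

Cross validation: Q² = 1 − PRESS/SSy and SEV = √(PRESS/n), where PRESS
sums squared leave-one-out prediction errors. Q² may be negative — the
model then predicts worse than the training mean — and the conventional
acceptance limits are R² > 0.6 and Q² > 0.5 with PRESS < SSy.

Leave-N-out robustness: for each N, rows are jointly permuted and
partitioned into consecutive blocks of N (last block possibly smaller),
each block left out once; Q²_LNO uses the SSy of the full unpermuted
activity vector, keeping the Q² = 1 − PRESS/SSy convention uniform.
With N = 1 any permutation gives exactly the LOO result, which the
tests assert. The default of six replicates per N follows the
hexaplicate protocol of the worked study's robustness figure (its text
elsewhere says three; both are honoured via `lno_replicates`). A robust
model keeps mean Q²_LNO close to Q²_LOO with small spread.

y-randomization: the activity is scrambled (default 10 times, identity
permutations allowed so the null is exact), the model refit on the
*fixed* descriptor subset and LV count, and straight lines are fitted
to the (|r(y_perm, y)|, R²) and (|r|, Q²) points, anchored by the
original model at |r| = 1, following Eriksson. Intercepts below 0.3
(R²) and 0.05 (Q²) indicate the original fit is not chance. The
refits deliberately do not re-run variable selection: scrambling
y and re-selecting would measure selection bias, not the chance
correlation of the model under scrutiny; a pipeline negative control
in the test suite shows that re-selection on scrambled activities can
indeed fabricate Q² > 0.5 at n = 31 with 81 candidate descriptors,
which is precisely why the fixed-subset protocol is the default.

External validation: `R²pred = 1 − PRESS_test/Σ(obs − ȳ_train)²` uses
the **training-set mean** in the denominator. The literature is
genuinely ambiguous here; the training-mean convention is the one
consistent with the packaged study's printed value (0.641), which the
test-set-mean variant does not reproduce. The Golbraikh–Tropsha
orientation is fixed the same way: k and R²₀ from regressing observed
on predicted through the origin, k′ and R′²₀ from predicted on
observed; this orientation reproduces the printed |R²₀ − R′²₀|.

Train/test splitting: the packaged study chose its five test compounds
manually, aided by a hierarchical-clustering dendrogram; that exact
split ships as a fixed-list fixture. `hca_split()` offers a
reproducible heuristic in the same spirit: complete-linkage clustering
(configurable) on Euclidean distances of the autoscaled descriptors,
one test compound per activity-quantile stratum, each from a distinct
cluster where possible, and never the global activity minimum or
maximum, so the training set spans the full range.

Outlier diagnostics: leverages `h_i = 1/n + t_i′(T′T)⁻¹t_i` (summing
to A + 1), studentized residuals scaled by SEC, the 2.5σ residual
threshold, and the Williams-plot leverage cutoff `h* = 3(A+1)/n` — the
cutoff convention chosen because the study draws such a line without
printing its formula; the multiplier is configurable. Flags never
remove compounds automatically; deletion is an explicit user decision.

## The synthetic generator

The study's descriptor matrix itself (439 descriptors from quantum
chemical, topological and E-state software, reduced to 81 by the
activity pre-filter) is not redistributable, so the package generates
matrices with the same *statistical* shape: 31 compounds, 81
descriptors, 6 informative ones arranged in 3 correlated pairs (a
latent factor per pair, intra-pair correlation 0.8), so exactly three
latent variables carry the planted signal, matching the worked model's
structure. Decoy descriptors each shadow one informative column with a
correlation drawn uniformly from [0, 0.15] — emulating the correlated
descriptor families real descriptor software produces — and the
activity is the planted linear combination plus Gaussian noise.

Two calibration choices matter:

* Each draw is *exactly* calibrated: the planted signal is rescaled to
  its design variance and the noise to its design standard deviation
  in-sample, so every seed realizes the same signal-to-noise regime
  rather than scattering around it. This is standard simulation
  practice when the quantity under study (here cross-validated
  predictivity) is itself a noisy functional of the draw.
* The default noise level (0.84 log units against a planted signal of
  variance ≈ 2.27) puts a least-squares fit on the six informative
  columns at R² ≈ 0.80 for n = 31 — the explained-variance regime of
  the worked model — and puts the OPS-selected model's Q²_LOO
  predominantly in the 0.5–0.8 window that separates predictive from
  suspiciously good small-n QSAR models.

What the generator does *not* emulate: non-Gaussian descriptor
distributions, discrete/count descriptors, activity measurement error
correlated with structure, and activity cliffs. Passing tests on this
generator therefore demonstrate the correctness and statistical
behaviour of the machinery, not performance on any particular real
descriptor set.

## Problem sizes and numerical tolerances

The test suite exercises: LOO against a brute-force refit oracle on
15×5 problems (agreement to 1e−10); PLS against ordinary least squares
at full rank (1e−6) and against an independent Krylov-subspace PLS1
implementation on 20×8 problems (1e−8); recovery experiments with 50
seeded replicates at the study's 31-compound scale (a 31×40 matrix
with a planted 3-descriptor model, and the full 31×81 preset); and
negative controls with 40 scrambled-activity replicates. These sizes
keep each experiment's sampling error around or below 5 percentage
points while the whole suite completes in under a minute on one core.

Degenerate inputs are rejected with named errors rather than silently
repaired: zero-variance columns at autoscaling (the offending column is
named), zero-variance activities, infeasible LV counts, leverages at 1,
zero HOMO–LUMO gaps, and external-validation denominators of zero.

## Known limitations

* Q² after variable selection is optimistically biased; the honest
  estimate of predictive power is the external R²pred on compounds
  never used for selection or fitting. The package reports both and the
  vignette's selection-bias negative control quantifies the hazard.
* With n = 31, single-split external validation on 5 compounds has
  large variance; the Golbraikh–Tropsha battery guards against gross
  pathologies, not against split-to-split fluctuation.
* The HCA split heuristic is one reasonable formalization of a manual
  practice; it is not claimed to reproduce any particular published
  manual split.
* pIC50 display follows the 3-decimal, round-half-away-from-zero
  convention of the source tables; internal computation never rounds.
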