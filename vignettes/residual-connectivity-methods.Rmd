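---
title: "Methods: seed-based residual functional connectivity under cognitive fatigue"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: seed-based residual functional connectivity under cognitive fatigue}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(resifc)
```

## The scientific question and the method's logic

State cognitive fatigue — the moment-to-moment sense of mental exhaustion
that builds during sustained effort, and that people with multiple
sclerosis (MS) report far more strongly than healthy controls (HC) — is a
*state*, not a trait. A task-based fMRI analysis that models the task
response throws the state away: whatever fluctuates with fatigue ends up
in the model's error term. This package implements the analysis built on
exactly that observation. A working-memory (n-back) experiment is modeled
with a deliberately rigid first-level GLM — one task regressor of **unit
amplitude for every trial**, so only the stable, time-invariant task
response is absorbed — and the saved residual time series becomes the
substrate for *task-independent (residual) functional connectivity*:
Pearson correlation between a seed region's mean residual percent signal
change and every voxel, Fisher-transformed (`z = atanh(r)`), then related
to in-scanner fatigue ratings (VAS-F, 0–100) with voxelwise linear
mixed-effects models and cluster-extent correction.

No real MRI data ship with the package; instead a synthetic-data module
generates the full study at
protocol fidelity — 26 MS and 14 HC subjects, two conditions (0-back,
2-back), 4 runs per condition, 140 volumes per run at TR 2 s, 65 trials
per 260-s run, five VAS-F ratings per subject and condition — with a known
planted coupling that the pipeline must recover. Every stage is therefore
testable end to end: the generator's ground truth is the oracle.

## The synthetic study

**Task schedules.** Each run packs 65 trials (1.5 s letter + 0.5 s base
inter-trial interval; a 2-s trial slot) and six null events into exactly
260 s. Null-event durations must be positive multiples of the 2-s trial
length; since the trials occupy 130 s, the remaining 130 s (65 two-second
units) are partitioned uniformly at random into six parts, which are
inserted at six random gaps between successive trials. We do not target
any particular inter-trial-interval moments: schedule optimizers used for
such designs have many free settings, so only the hard protocol
constraints (65 trials, six nulls, multiples of 2 s, 260 s total) are
honored. A letter stream over the 17-letter stimulus set
defines targets (letter "K" for 0-back; a two-back repeat for 2-back),
but targets never enter the analysis — the design models all trials at
unit amplitude, which the tests verify by relabeling targets and checking
the regressor is unchanged.

**Ratings and behavior.** VAS-F ratings are additive on a latent scale
(baseline 18, MS offset +22, −2 in 2-back, +3.5 per successive rating,
between-subject spread via the cohort's latent intercepts, noise SD 7)
and clipped to [0, 100] — clipping, not resampling, is the simplest
monotone way to respect the response scale. The defaults produce realistic
descriptives: a large MS–HC gap, and slightly higher MS fatigue in
0-back than 2-back. Accuracy carries the pattern the behavioral arm is designed
to detect: no fatigue–accuracy relation in 0-back, opposite-signed 2-back
slopes for HC (+0.021) and MS (−0.016) per standardized fatigue unit;
response time has a large 2-back cost and no fatigue coupling.

**BOLD runs.** Per voxel and volume the signal is
baseline (1000) + stable task response (trial boxcars convolved with the
canonical double-gamma HRF, constant amplitude 2 in a task region) +
per-run polynomial drift + motion-coupled components (per-voxel random
weights on the six simulated rigid-body parameters, which follow a random
walk with occasional spikes so the FD/DVARS outlier machinery is
exercised) + shared global/CSF/WM fluctuations + the planted coupling +
independent Gaussian noise, spatially smoothed (6 mm FWHM by default) and
rescaled so the marginal noise SD is exact even at the grid edge.

**The planted coupling — the ground truth.** A latent AR(1) fluctuation
`u(t)` is added to the seed region; the target region receives
`r u(t) + sqrt(1 - r^2) u'(t)` with an independent `u'`, so the latent
seed–target correlation in a run is exactly `r`. We set
`r = tanh(zeta)`, `zeta = intercept + slope(condition) * fatigue`, with
the run's fatigue covariate on a standardized scale. Two consequences:
the planted correlation can never leave (−1, 1) for any attainable
fatigue value, and — because the analysis works on the Fisher-z scale,
`atanh(tanh(zeta)) = zeta` — the planted `slope` is the *estimand* of the
voxelwise interaction model. The generative model is our choice (real
data dictate none); this link is the
one that makes "recovered slope equals planted slope" a well-posed
statement.

**Geometry.** The canonical grid is 30 × 36 × 30 voxels of 3 mm — the
group-analysis voxel size — with the affine placed so all five seed
centres (DLPFC 44 32 36; vmPFC −6 46 −6; dACC −4 20 46; insula 34 22 0;
striatum 18 12 0, all MNI mm) fall inside. Desk-scale grids re-centre the
box on the seeds' bounding box and refuse dimensions that cannot contain
them. Tissue masks are schematic corner blocks: they exist so tissue
regressors are exercised, not to emulate anatomy.

## Confound metrics

Framewise displacement is the Power sum — absolute frame-to-frame
translation changes plus rotations converted to arc length on a 50-mm
sphere (the standard convention; the radius is configurable). DVARS is
the spatial RMS of the temporally differenced signal; "standardized"
DVARS divides by the within-run median (the exact standardization varies
between tools; median is robust, and mean is available as an option).
First-row derivatives are 0 rather than dropped, keeping row counts
aligned. The expanded table carries the six motion parameters, their
derivatives, and quadratics of both (24 columns), the three tissue mean
signals with derivatives, FD, standardized DVARS, and motion-outlier
flags at FD > 0.5 mm or standardized DVARS > 1.5. The flags are carried
but not used as spike regressors — the deconvolution regresses out FD
itself rather than scrubbing frames. CompCor is deliberately out of
scope: it is not part of the deconvolution's nuisance set.

## The first-level model

The four runs of a condition are deconvolved in one model over 560
concatenated volumes: one unit-amplitude task regressor spanning all
runs; per-run Legendre drift polynomials up to order 3 (the drift basis is a
free choice; Legendre is the default, with a DCT option); per-run nuisance blocks (motion + derivatives,
FD, CSF/WM/global signals + derivatives), all zero outside their run.
Estimation is voxelwise OLS without prewhitening: the residuals are
consumed by correlation, which is invariant to the common scale, so an
AR noise model would buy nothing here.
Collinearity is detected by SVD (singular values below 1e-10 of the
largest) and reported with the offending column names. Residual
orthogonality to every design column is asserted in the tests at
`|X'e|/n < 1e-8`, and the generator's invariant-task plant yields
numerically zero residuals when noise, coupling and drift are switched
off — the property the whole method rests on.

Percent signal change is `100 (x - m)/m` with `m` the run's raw voxel
mean; residual series are deviations already, so their PSC is
`100 e_t / m`. The reference is per run and per voxel (a documented convention).

## Seed connectivity

Seeds are 4-mm spheres; a voxel belongs to a seed when its *centre* is
within the radius (the common seed-tooling rule; any-overlap would more
than double the voxel count at this radius/voxel-size ratio). The seed
series is the voxel-mean residual PSC per volume; correlation against
every voxel's residual series is computed **per run**, giving 4 maps per
condition per subject: run-wise rather than concatenated correlation is
what makes run estimable as a factor in the group model. `r` is clamped to ±(1 − 1e−7)
before `atanh`; zero-variance voxels get z = 0 with a warning rather than
NaN; a zero-variance seed series is an error.

## Behavioral analysis

Run-level fatigue is the mean of the ratings before and after the run;
runs with *both* ratings exactly 0 are excluded (no fatigue, so the
signal cannot reflect it — and exclusion guarantees positivity for the
power transform). The Box-Cox exponent is estimated once on the pooled
retained run means (per-group estimation is defensible too; pooled keeps
one scale for the group-difference estimates) by profile likelihood over
[−2, 2]. Mixed models are REML fits with `lme4`, Satterthwaite degrees of
freedom via `lmerTest`, random subject intercepts, and fixed
group × condition × (run or fatigue) structures. Post hoc pairwise
comparisons use `emmeans` with Tukey adjustment; slope comparisons
(`emtrends`) support the group-by-condition fatigue-slope follow-up.
Satterthwaite is used throughout, including the post hocs
(Kenward–Roger being the common alternative there): one df method keeps
the pipeline coherent and the two are materially identical at these
sample sizes.

## Voxelwise mixed-effects maps

For each seed and each group separately (the groups are never pooled),
every voxel's Fisher-z values are modeled as

```
z ~ condition + fatigue_c + condition:fatigue_c + run,  (1 | subject)
```

with `fatigue_c` the Box-Cox-transformed run fatigue, mean-centered
within group, and run a 4-level factor (the safer default; a numeric
option is provided). The reported map is the `condition:fatigue_c`
interaction — the 2-back minus 0-back fatigue slope, positive when
fatigue tightens connectivity more under load — converted to a signed
standard-normal Z for thresholding and tables. A condition-stratified
parameterization is available and yields the identical slope-difference
map.

Fitting ~30,000 independent mixed models per map with a generic fitter is
not affordable, so the package includes a dedicated mass-univariate
random-intercept REML engine (`lmm_mass_ranint`): the REML criterion is
profiled over the variance ratio `gamma = sigma_b^2/sigma_e^2` on a dense
grid (0 plus 240 log-spaced points in [1e−4, 1e3]) shared by all voxels,
so every quantity reduces to dense matrix algebra over all voxels at
once. For a fixed design, both the contrast's variance factor and its
Satterthwaite degrees of freedom (expected REML information of
(sigma_e^2, sigma_b^2)) are functions of `gamma` alone and are
precomputed on the grid. `gamma = 0` is a grid point, so singular fits
degrade to OLS gracefully and are counted and reported, never silent.
The engine is validated voxel-by-voxel against `lmerTest` in the test
suite (estimates and SEs to well under 1%, df to ~3%, the residual being
grid resolution and the expected- vs observed-information choice), and
its null behavior is checked by simulation: the fraction of null voxels
with p < 0.001 stays below 0.002 over 50 replicate datasets.

## Cluster-extent correction

Smoothness is estimated from standardized residual maps by the
first-difference Gaussian-field estimator,
`FWHM = voxel * sqrt(4 log 2 * var / var_diff)` per axis, averaged over
maps; under spatially independent noise its value is
`voxel * sqrt(2 log 2)` (≈1.18 voxels), which the tests pin to ±10%, and
a known 6-mm smoothing is recovered within 15% (the small positive bias
of difference-based estimators at 2 voxels FWHM is expected and
harmless here, since the calibration consumes the same estimator's
output). Null fields for the Monte-Carlo calibration are white noise
smoothed with the same separable Gaussian kernel and standardized by the
*exact* per-voxel SD of the smoothed field, so edge voxels are correctly
unit-variance. Thresholding is two-sided at voxel p < 0.001 (the tables
report both signs); positive and negative suprathreshold sets are
labeled separately with faces-only (NN1) connectivity by default — the
most conservative rule, configurable to the NN2/NN3 variants. The extent
threshold `k` is the smallest integer whose exceedance probability by
the per-simulation maximum extent is at most alpha = 0.05, and the
familywise error of the full procedure is verified on independent null
simulations (≤ alpha plus two Monte-Carlo standard errors). Any
specific extent threshold is a property of one dataset's residual
smoothness and grid; the calibration property — familywise error at or
below alpha — is the invariant this package tests. Cluster tables report peak mm coordinates via the affine, voxel
counts, and signed peak Z, positive clusters first — anatomical labeling
of peaks is out of scope.

## Parameter recovery and problem sizes

The recovery experiment plants a 2-back-only fatigue slope of 0.3
(Fisher-z per standardized fatigue unit) and runs 20 replicate studies of
20 subjects on a compact 12³ grid with one seed/target pair, each through
simulation, deconvolution, connectivity and the voxelwise mixed model.
Two checks per replicate: the interaction map's peak |t| lies inside the
planted target region, and the 95% CI at the *target-centre voxel* covers
the planted slope — the centre voxel, not the selected peak, so the
coverage check is free of winner's-curse bias. The experiment fixes
`noise_sd = 0.15` against unit latent amplitude: voxel noise attenuates a
sample correlation toward zero (a property of correlation, not of the
estimator), and at this noise level the attenuation of the z-scale slope
(~1%) is far below its standard error, making the planted slope the
estimand. At higher noise the same pipeline still finds
the peak but recovers a correspondingly attenuated slope — worth
remembering when interpreting real-data effect sizes, where measurement
noise is not tunable.

Scales used by the shipped tests and drivers, chosen as the package's
desk-scale defaults: FWE calibration on a 24³ grid at 6 mm FWHM with
1000 + 1000 simulations; recovery as above; behavioral recovery at 200
subjects per group with 120 null replicates for the Tukey error-rate
check; the demonstration pipeline at a 24 × 16 × 22 seed-covering grid
with the full 26/14 cohort. The full 30 × 36 × 30 grid runs in the same
code paths, only longer.

## Pipeline orchestration

`run_pipeline()` runs the stages (simulate, first-level, connectivity,
behavior, group, clusters) in dependency order against one artifact
directory. Volumes are a pure function of the configuration and the
master seed, so the heavy stages regenerate BOLD runs deterministically
instead of storing hundreds of them; the simulate stage materializes the
behavioral tables (plus one audit confounds table), the first-level
stage writes one audit residual volume and design matrix, and the
connectivity stage — which performs the deconvolution inline while
streaming subjects — writes the per-seed z-map stacks that the group
stage consumes. Every artifact set carries an FNV-1a hash of its
configuration; stages refuse inputs produced under a different
configuration, and a missing upstream artifact is an error naming the
stage to run. Determinism is exact: identical configurations reproduce
stat maps bit for bit (single-threaded reference mode).

## Known limitations

The generator makes no attempt at anatomy, k-space physics, or
preprocessing artifacts: it emulates *already-preprocessed* data, so
passing tests say nothing about registration, distortion or slice-timing
errors in real pipelines. Fatigue enters the plant linearly on the
z-scale through a single latent channel; real fatigue-related coupling is
surely distributed and nonlinear. The zero-fatigue exclusion rule rarely
fires at the default rating parameters (healthy controls occasionally
produce exact zeros; the rule is exercised directly in the tests). OLS
without prewhitening slightly misstates first-level standard errors
under temporal autocorrelation — immaterial here because only residuals,
not first-level inference, are consumed. The voxelwise engine supports
exactly one random intercept; crossed or nested random effects would
need the generic fitter.
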