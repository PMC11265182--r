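---
title: "Glymphatic ALPS indices from diffusion and kurtosis tensors: models, phantom and statistics"
author: "dkialps"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Glymphatic ALPS indices from diffusion and kurtosis tensors}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dkialps)
```

## The measurement

At the level of the lateral-ventricle body, three roughly orthogonal tissue
systems coexist: projection fibres running inferior–superior (z),
association fibres running anterior–posterior (y), and the perivascular
spaces of the medullary veins running right–left (x). Water moving along
the perivascular channel raises the x-axis diffusivity in *both* fibre
regions without a corresponding rise along the fibre axes, so the ratio

$$\mathrm{DTI\text{-}ALPS} \;=\;
\frac{\operatorname{mean}(D_{xx}^{\,proj},\, D_{xx}^{\,assoc})}
     {\operatorname{mean}(D_{yy}^{\,proj},\, D_{zz}^{\,assoc})}$$

serves as a proxy for glymphatic transport: values near 1 mean no
preferential perivascular diffusion, larger values mean more. The same
construction applied to the axis components of the fourth-order kurtosis
tensor,

$$\mathrm{DKI\text{-}ALPS} \;=\;
\frac{\operatorname{mean}(K_{xxxx}^{\,proj},\, K_{xxxx}^{\,assoc})}
     {\operatorname{mean}(K_{yyyy}^{\,proj},\, K_{zzzz}^{\,assoc})},$$

is motivated by the fact that most white matter contains crossing fibres,
where the single-tensor diffusivities are biased; the kurtosis tensor
captures exactly the non-Gaussian signature that crossing compartments
produce. Both indices are computed per hemisphere (each from one
projection-fibre and one association-fibre ROI) and for the whole brain.

## Signal model and estimator

Per voxel the package fits the standard two-term cumulant representation of
the diffusion-weighted signal,

$$\ln S(b, \mathbf{n}) \;=\; \ln S_0 \;-\; b\, \mathbf{n}^\top D\, \mathbf{n}
\;+\; \tfrac{b^2}{6}\, \overline{D}^2 \sum_{ijkl} n_i n_j n_k n_l\, W_{ijkl},$$

with $D$ the diffusion tensor (6 unique components, mm²/s), $W$ the fully
symmetric dimensionless kurtosis tensor (15 unique components) and
$\overline{D} = \operatorname{tr}(D)/3$ the mean diffusivity. All 22
unknowns are linear once the kurtosis block is parameterized as
$U = \overline{D}^2 W$; $W$ is recovered afterwards as $U/\overline{D}^2$.
This requires at least two non-zero shells and a design of rank 22; the
constructor refuses underdetermined schemes explicitly.

Two solvers are provided. Ordinary least squares solves the log-linear
system directly; the default weighted pass re-solves with weights equal to
the squared OLS-predicted signals, the usual correction for the
heteroscedasticity that the log transform induces (low signals have noisy
logs). On noiseless data both are exact: the package's round-trip tests
recover all 22 parameters of random valid models to better than 1e-8
relative error, which is the designed behaviour of a linear model evaluated
on its own forward signal, not a numerical accident.

Numerical and QC choices, all deliberately simple and visible:

* signals ≤ 0 invalidate the voxel rather than being floored — flooring
  biases kurtosis upward;
* `b0_threshold` = 50 s/mm² separates b0 from shells, and shells are the
  b-values rounded to the nearest 50 s/mm² (vendor jitter tolerance);
* kurtosis is declared undefined when $\overline{D}^2 < 10^{-12}$ mm⁴/s²;
* apparent axis kurtosis outside $[-3, 10]$ flags the voxel (physical
  plausibility window) but the value is kept — no projection or clipping;
* no positivity constraints in the fit; QC counts are reported instead.

### The two readings of "axis kurtosis"

The phrase "diffusivities of the kurtosis tensor along x, y, z" admits two
readings and the package implements both: `convention = "tensor"` returns
the raw fitted diagonal components $W_{xxxx}, W_{yyyy}, W_{zzzz}$ — what
per-component kurtosis-tensor output files of the common estimators
contain — while `convention = "apparent"` returns the directional kurtosis
$K_{app}(\mathbf{e}_i) = (\overline{D}^2/D_{ii}^2)\, W_{iiii}$. The default
is `tensor`; because the ALPS ratio is scale-free the two conventions give
genuinely different indices whenever the axis diffusivities differ, so
results should state which was used (the map sidecar records it).

## ROI geometry

ROIs are 5 mm diameter spheres, one projection-fibre and one
association-fibre ROI per hemisphere; a voxel belongs to a sphere iff its
center lies within the radius (voxel-center membership — partial-volume
weighting was rejected for transparency, and on a 2 mm grid a 5 mm sphere
is exactly the center voxel plus its six face neighbours). Published ALPS
work places these spheres manually on the JHU-ICBM FA template and reports
no coordinates, so this package never guesses centers: they are explicit
configuration (JSON, template-space mm), and the phantom supplies its own
ground-truth-aligned set. Within a hemisphere the two spheres must not
share voxels. NaN voxels (flagged fits, mask boundary) are excluded from
ROI means; an ROI must keep at least one valid voxel, and dropping below
50% validity flags the subject. Because the construction reads x/y/z tensor
components, inputs must live in an axis-aligned (template-like) space; the
affine's rotation is checked against 5° and a hard warning is raised
beyond that.

The study defines no "whole brain" index; the default here is the
arithmetic mean of the left and right indices, with pooling of the four ROI
means before the ratio available as `global = "pooled"`. The two coincide
exactly when the hemispheres have equal denominators and differ otherwise,
which the tests exercise.

## The phantom

The phantom exists so that every step of the pipeline can be checked
against numbers known in closed form. It emulates the acquisition the
index literature uses — one b0 plus 56 directions at b = 1000 and the same
56 at b = 2000 s/mm², 2 mm isotropic voxels — and the tissue geometry the
index assumes: four disjoint boxes, two per hemisphere, with projection
regions (principal diffusivity along z) and association regions (along y).
Default grid 16 × 16 × 10 voxels: the full simulate–fit–extract–index
pipeline runs in well under a second, which is what makes the seeded
repetition tests cheap.

Direction sets: the study's actual gradient table is unpublished. The 56
directions are a spherical-Fibonacci hemisphere layout — deterministic,
antipodally distinct, well spread (design rank 22) — shipped as a
plain-text fixture and regenerable from code with no RNG at all. A
repulsion-optimized set would differ imperceptibly for these purposes and
would drag in a seed for no benefit.

Default tissue parameters (per region, diagonal tensors):

| region | $D$ diag (10⁻³ mm²/s) | $W$ diag |
|---|---|---|
| projection | 1.0, 0.6, 1.6 | 1.30, 0.80, 0.60 |
| association | 1.1, 1.6, 0.55 | 1.35, 0.60, 0.80 |

The diffusivities realize the assumed fibre geometry with a free
perivascular x axis; by direct substitution they give DTI-ALPS
= 1.05/0.575 ≈ 1.826. The kurtosis diagonals were chosen once so that the
analytic DKI-ALPS (≈ 1.66) sits at the magnitude reported in vivo, with
along-fibre kurtosis below cross-fibre kurtosis as in white matter; they
are phantom parameters, not claims about migraine tissue.

### Crossing fibres and the cumulant formula

A mixture of Gaussian compartments with volume fractions $f_c$ and tensors
$D_c$ has, along direction $\mathbf{n}$ with compartment diffusivities
$d_c = \mathbf{n}^\top D_c \mathbf{n}$, effective diffusivity
$\mathbb{E}_f[d_c]$ and apparent excess kurtosis

$$K_{app}(\mathbf{n}) \;=\; 3\,\frac{\operatorname{Var}_f(d_c)}{\mathbb{E}_f[d_c]^2},$$

the second-order cumulant of the compound signal. For the canonical 50/50
crossing of a z-fibre and a y-fibre
($D$ = diag(0.3, 0.3, 1.7) and diag(0.3, 1.7, 0.3) × 10⁻³), this gives
$K_{app}(z) = 3 \cdot 0.49 / 1^2 = 1.47$ and exactly 0 along x.

An honest caveat that the tests quantify rather than hide: the cumulant
formula is the *small-b limit*. The two-point diffusivity distribution of
this crossing is symmetric, so its third cumulant vanishes and its fourth
is large and negative ($\kappa_4 = -0.48$ against $\mu_2 = 0.49$ in
(10⁻³)² units); at the clinical shells the fit sees attenuations up to
$bD \approx 3.4$, where that neglected quartic term matters. The
consequence, measured by the acceptance battery: the two-shell fit
recovers $K_{app}(z) \approx 1.20$ rather than 1.47, and the global
least-squares compromise leaks a small positive kurtosis
($\approx 0.2$) onto the x axis even though the x-signal itself is purely
mono-exponential. Scale all b-values down tenfold and the fitted values
land on the cumulant formula to within 2% (a property test). So: the
mixture oracle is exact as a limit statement and as a generator of ground
truth for *signals*; fitted kurtosis at b = 2000 is a truncated-model
estimate of it, for crossing geometries as for real brains. This is a
property of two-shell DKI, not of any particular implementation.

### Noise

Magnitude-MR noise is Rician: $\sqrt{(S+\epsilon_1)^2 + \epsilon_2^2}$
with $\epsilon \sim N(0, \sigma^2)$ and $\sigma = S_0/\mathrm{SNR}$;
Gaussian noise is available for comparison. At SNR 30 the voxel-level
estimates are nearly unbiased for the diffusivity diagonal (the ensemble
mean over hundreds of voxels is within ~1%), but a single voxel's $D_{xx}$
carries a median relative error of roughly 5% — 113 measurements at SNR 30
simply do not determine 22 parameters more tightly — and the 7-voxel ROI
means inherit seed-to-seed variability of a few percent in the indices.
Aggregated over 20 seeded phantoms the mean pipeline indices sit within 2%
of the analytic truth, which is the level at which the acceptance battery
pins them. Strongly attenuated measurements (the b = 2000 fibre-axis
signals) operate at local SNR near 1, where the Rician floor biases
kurtosis components; the default WLS fit limits but does not remove this.

## The cohort generator

`simulate_cohort()` draws each subject's region parameters log-normally
around the group means (log-normal for positivity; between-subject CV
default 8%, a mid-range figure for ALPS-index variability given the
published group SDs of 8–16% of the mean), applies named multiplicative
group effects (e.g. `c(right_kxxxx = 1.07)` for a +7% right-hemisphere
x-axis kurtosis shift in the patient group), builds a small phantom per
subject and runs the full pipeline. Covariates are drawn from
distributions shaped like a published migraine cohort (ages ~34 vs ~26,
male fraction ~0.29 vs ~0.59, clinical scores for patients only, truncated
at zero); they are plain columns, present so the correlation and report
machinery has realistic input, and carry no signal unless injected.

Two routes produce the indices: `pipeline = "imaging"` (default; signal
synthesis, tensor fit, ROI extraction) and `pipeline = "analytic"` (direct
substitution of the drawn diagonals into the index equations). A test
proves they agree to ~1e-13 on noiseless data — the fit is exact there —
which is what licenses using the analytic route for large calibration
loops. Statistical-power properties are identical by construction; the
imaging route is kept as the default because it exercises the whole
artifact. Cohort phantoms default to a 12 × 12 × 8 grid with 3-voxel
region boxes, the smallest geometry that still holds the four 5 mm
spheres; a 37 + 29 cohort simulates in a couple of seconds.

What the phantom and cohort deliberately do **not** model: anatomy beyond
four boxes, registration error, eddy/motion artifacts, CSF partial volume,
spatially varying SNR, and any real relationship between indices and
clinical covariates. Passing tests therefore demonstrate correctness of
the estimator, the geometry and the statistics under the stated generative
model — not clinical validity of the index.

## The statistical battery

The battery mirrors what ALPS group studies report, with the conventional
test per variable class:

* **Lilliefors** normality test for the indices: KS distance against a
  normal with estimated mean/SD; the p-value is Monte-Carlo (default 5000
  standard-normal samples of the same size, seeded) rather than
  table-based — transparent and testable. Null distributions are cached
  per (n, reps, seed), which is what makes 2000-replicate calibration runs
  cheap. Empirical type-I error at α = 0.05 lands in [0.03, 0.07].
  Its power is real but modest against platykurtic alternatives
  (≈ 0.5 against Uniform(0,1) at n = 100, matching the independent
  `nortest` implementation).
* **Two-sample t-test** for the indices, pooled-variance ("student") by
  default — the plain reading of "two-sample t-test" — with Welch as a
  flag; the group report records both p-values. A summary-statistic
  variant recomputes the identical test from printed mean ± SD ± n rows,
  which is how the published right-hemisphere DKI-ALPS comparison
  (1.6858 ± 0.20 (n 37) vs 1.5729 ± 0.21 (n 29), p ≈ 0.03) is reproduced;
  the conclusion is insensitive to the pooled/Welch choice and to the
  37-vs-39 enrolment ambiguity, so both are always checked.
* **Mann-Whitney U** for demographics: midrank U; exact mode enumerates
  all group assignments (n₁+n₂ ≤ 20, two-sided p = 2·min(tail, 0.5));
  normal mode uses the tie-corrected variance with continuity correction
  (identical to `wilcox.test`'s approximation). For tie-free 8+8 samples
  the two agree within 0.011 over every attainable U; under heavy ties the
  normal approximation can deviate by ~0.09 near p ≈ 1, which is a known
  property of the approximation, not a defect of either mode.
* **2×2 chi-square** for sex, uncorrected by default (Yates as a flag):
  the uncorrected statistic is what reproduces the classical
  (χ² = 2, p = 0.1573) pairing.
* **Correlations** (Pearson/Spearman) between indices and clinical
  variables, listwise deletion, t-transform p-values.
* **No multiple-testing correction** anywhere, α = 0.05 throughout —
  matching the practice of the literature this models, and stated so the
  reader can disagree.

Problem sizes used by the test and acceptance runs — 2000 null replicates
for calibration, 20 seeded phantoms for the noisy pipeline, 100 seeded
cohorts at the study's 37/29 enrolment for the laterality power run — were
chosen as the package's own balance of Monte-Carlo error against desk-scale
runtime.

## Known limitations

* Two-shell DKI truncation biases fitted kurtosis for strongly non-Gaussian
  voxels (quantified above); the cumulant ground truth is exact only as
  b → 0.
* Rician bias at low local SNR is not corrected; flagged, not fixed.
* ROI placement is the user's responsibility; the package checks geometry,
  not anatomy.
* The index itself measures diffusion anisotropy patterns, not flow; the
  package computes it faithfully and stays silent on physiology.
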