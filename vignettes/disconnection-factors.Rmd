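---
title: "Latent disconnection factors from lesion masks: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Latent disconnection factors from lesion masks: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(disconnectr)
```

# The problem

After a minor ischemic stroke, roughly a third to a half of patients show
post-stroke cognitive impairment (PSCI), but neither infarct volume nor
infarct location predicts it well: minor-stroke infarcts are small and
scattered, so voxel-based lesion-symptom mapping has little overlapping
signal to work with. A *hodological* alternative asks which white-matter
pathways a lesion interrupts. Given a normative streamline tractography
atlas, the percent disconnection of a tract is

$$
\mathrm{pct}(\text{tract}) \;=\; 100 \times
\frac{\#\{\text{streamlines intersecting the lesion mask}\}}
     {\#\{\text{streamlines in the tract}\}},
$$

computed independently for acute infarct masks and for chronic white
matter hyperintensity (WMH) masks. Because many tracts are affected
jointly and patients differ in which combination is hit, the per-tract
profiles are summarized by a mixed-membership model: latent Dirichlet
allocation (LDA), with participants as documents, tracts as words, and
disconnection severity as counts. Each latent *disconnection factor* k
has a tract signature $\Pr(\text{Tract}\mid\text{Factor}=k)$ and each
participant a loading vector $\Pr(\text{Factor}\mid\text{Participant})$
on the simplex. Loadings then enter ordinary association models for
cognitive outcomes.

This package implements that full chain — disconnection scoring, factor
discovery with stability-based selection of the number of factors, and
the outcome statistics — together with a synthetic cohort generator that
plants known factors and effects, so that every stage is testable without
patient data.

# Synthetic data: what it emulates and what it does not

`make_template()` builds an abstract brain-like geometry: nested
ellipsoids (brain, cortical shell, central elongated ventricle), nine
azimuthal lobar sectors over the white matter, and ten vascular-territory
codes (six supratentorial, four infratentorial) partitioning the brain.
It is *not* a registered standard-space brain: spatial normalization is
out of scope here, and everything downstream needs only internal
consistency (disjoint masks, complete labels, correct distances). The
grid defaults to $40^3$ voxels at 4 mm — small enough that exact
brute-force oracles (per-voxel tallies, per-sample point-in-mask loops)
can verify every geometric computation in the test suite.

`sample_lesions()` reproduces the two qualitative lesion regimes of a
minor-stroke cohort: infarcts are compact ellipsoidal blobs centered in a
random vascular territory and kept off the ventricle, which makes
across-subject overlap low (mean pairwise Dice well under 0.1); WMH are
periventricular shells — all white-matter voxels within a per-subject rim
distance (default 4–11 mm) of the ventricular surface — plus optional
satellites, which makes overlap high (Dice above 0.4). The generator does
not attempt realistic vascular anatomy or FLAIR/DWI signal, only the
overlap contrast that drives the methodological story.

Two corpus routes are provided deliberately:

* `sample_disconnection_corpus()` draws directly from the LDA generative
  process (loadings from a Dirichlet, signatures from sparse Dirichlets
  with near-disjoint supports, counts from a multinomial). Recovery tests
  against its ground truth are *exact-model* tests: a failure is
  attributable to the estimator, not to model misfit.
* The geometric route (lesions → `disconnection_profile()` →
  `encode_pseudocounts()`) exercises the full chain and is what
  `run_pipeline()` uses for the profile stages.

`sample_cognition()` links outcomes to one *causal* factor loading
$\theta_c$: each domain z-score (memory, attention/executive,
visuospatial, language) is
`baseline − effect_beta · w_domain · theta_c + confounds + noise`, with
age and education confounds (±0.25 z per SD), residual SD 0.6 split 35%
subject-shared / 65% timepoint-specific, and PSCI defined by the
threshold rule below. MoCA is generated correlated with mean month-6
cognition, and infarct/WMH volume surrogates are lognormal with moments
matched to a minor-stroke cohort (10.28 ± 17.10 and 9.01 ± 15.83 cm³).

## Default operating point

The defaults were fixed once, by a design study, to reproduce the study
conditions the package is exercised under: PSCI prevalence ≈ 0.5 at month
6 and ≈ 0.35 at month 36 with ≈ 30% of subjects changing status; a
fitted causal odds ratio per unit loading of order 10; and Dirichlet
loadings `alpha = (0.2, 0.055, 0.2)` — sparse memberships in which most
participants predominantly express a single factor and about 11% carry
the causal one.

One consequence deserves honesty. Factor loadings live on the simplex, so
they are negatively correlated by construction; for a Dirichlet with
causal-mass fraction $p$ and the rest split evenly,
$\mathrm{corr}(\theta_c,\theta_j) = -\sqrt{p/(1+p)}$ *independently of
the total concentration*. A real causal effect on $\theta_c$ therefore
projects onto every other loading with slope proportional to that
correlation (omitted-variable bias), and with enough power to detect the
causal factor in 105 subjects (z ≈ 3), the induced z on a non-causal
factor is ≈ 0.3 × 3 ≈ 0.9, which yields a 10–15% rejection rate at FDR
q = 0.05 — not the nominal 5%. No choice of Dirichlet escapes this while
keeping the causal effect detectable at this sample size; the same
phenomenon appears in real factor-outcome analyses as a significant
*negative* association of a factor strongly anti-correlated with the
causal one. The defaults sit on the best available ridge (causal
detection ≈ 0.75–0.8, non-causal ≈ 0.1), and the end-to-end test asserts
both sides as specified.

# Disconnection scoring

`rasterize_streamline()` samples each polyline segment at a spacing no
larger than `step_mm` (endpoints included), maps samples through the
inverse affine, and takes the nearest voxel (voxel-center convention;
indices are 1-based in R, with the affine defined on 0-based indices).
The default step is half the smallest voxel dimension, which guarantees
no voxel along a segment is skipped. A streamline counts as disconnected
when at least one of its voxels lies in the mask — the standard
disconnectome convention for "passing through"; no minimum-overlap rule
is applied, and this choice is documented rather than hidden because
single-voxel grazing contact is a genuine ambiguity of the approach.
Percent disconnection is monotone under mask growth and subadditive over
disjoint masks; the test suite verifies both, plus exact agreement with a
brute-force per-sample oracle on toy atlases.

`canonical_registry()` carries the 70-name tract schema used for
real atlases of this kind: 65 bundle names plus the corpus callosum
split into five segments (anterior frontal, posterior frontal, parietal,
temporal, occipital). It is a naming convention only — synthetic atlases
borrow its names, and the callosal labels are configurable because the
exact anatomical boundaries of the split are conventions, not
computations.

# Lesion volumetrics

Volumes are voxel count × |det of the affine's 3×3 block| / 1000, in cm³
throughout. ICV normalization multiplies by cohort mean intracranial
volume and divides by subject ICV. The bullseye parcellation crosses the
nine lobar sectors with four concentric layers of relative depth
$d = d_v/(d_v + d_c)$, where $d_v, d_c$ are Euclidean distances (mm) to
the ventricular and cortical surfaces; layer edges are the quartiles
{0.25, 0.5, 0.75} with half-open bins $[lo, hi)$ and $d = 1$ assigned to
layer 4. The source bullseye construction uses four equidistant
relative-distance layers; no alternative edge set is claimed here, and
the edges are a documented argument. Layer 1 is the most periventricular,
layer 4 juxtacortical, codes `(lobe − 1) × 4 + layer` ∈ 1..36. Distance
maps are exact Euclidean distance transforms computed against mask
boundary voxels; on the package's grid sizes this brute-force approach is
both exact and fast enough, and it is verified against per-voxel oracles.

# Factor model and inference

`fit_lda()` implements mean-field variational EM for smoothed LDA with
symmetric priors: Dirichlet(α) on loadings (default α = 1/K, so
document-level sparsity grows with K) and Dirichlet(η) on signatures
(default η = 0.01, favoring sparse tract signatures). The E-step iterates
the responsibilities
$\phi_{dtk} \propto e^{E[\log\theta_{dk}]} e^{E[\log\beta_{kt}]}$
together with $\gamma_{dk} = \alpha + \sum_t n_{dt}\phi_{dtk}$; the
M-step sets $\lambda_{kt} = \eta + \sum_d n_{dt}\phi_{dtk}$. Both
$\theta$ and $\beta$ are reported as normalized variational means. Every
update is coordinate ascent on the evidence lower bound, so the ELBO is
non-decreasing (asserted within 1e-6 relative tolerance on every test
corpus); fitting stops when its relative change drops below `tol`
(default 1e-6) or at `max_iter`. Initialization perturbs the empirical
tract frequencies with seeded Gamma noise, so runs are exactly
reproducible given a seed. All-zero subjects carry no information and are
excluded by `encode_pseudocounts()` with a warning.

Percentages are encoded as counts via `round(scale × pct)` with
`scale = 10` (0.1% resolution). The count scale is not part of the
scientific claim: the suite checks that loadings correlate above 0.95
across scales 1 and 10 and that signatures move less than 0.01 in total
variation when counts are multiplied by 5.

## Choosing K by stability

`lda_stability()` refits the model from `n_runs` seeded restarts, matches
factors across each run pair by the assignment maximizing the summed
Pearson correlation of tract signatures (solved exactly by dynamic
programming over subsets), and averages the matched correlations;
`select_k()` picks the K with the highest stability, breaking ties toward
the smaller K. The specific reproducibility statistic used by published
analyses of this design is not always stated; pairwise optimal-assignment
correlation over restarts is a standard choice and is recorded in the
model metadata so the selection rule is auditable. On planted
three-factor corpora (N = 300) the suite requires K = 3 to win in at
least 80% of replicates, mean matched signature cosine ≥ 0.9 and mean
absolute loading error ≤ 0.1; in practice recovery is near-exact.

# Outcome statistics

*PSCI rule.* A participant is impaired when any cognitive domain summary
z-score (the mean of that domain's test z-scores) is ≤ −1.5. Published
descriptions of this rule sometimes print the threshold without the
sign; +1.5 would classify nearly everyone as impaired, and the normative
convention is 1.5 SD *below* the mean, so −1.5 is used and the threshold
is a configurable argument.

*Cross-sectional models.* `fit_logistic()` is maximum-likelihood IRLS
with Wald standard errors from the observed information; odds ratios and
Wald 95% intervals $e^{\hat\beta \pm 1.96\,\mathrm{SE}}$ are reported.
Wald intervals are chosen for determinism; published intervals of this
kind are often profile-likelihood and will not match Wald exactly, while
the OR point estimates do. Separation is detected (divergent
coefficients or all fitted probabilities degenerate) and flagged rather
than silently reported. `lr_test()` is the nested likelihood-ratio test
$\chi^2 = 2\Delta\ell$ with df equal to the number of added parameters.
`bh_fdr()` applies Benjamini–Hochberg within each analysis family
(per-table), not globally. `cca_first()` computes the first canonical
pair from the SVD of the whitened cross-covariance and a permutation
p-value $(1 + \#\{r^\ast \ge r\})/(B + 1)$ under row permutation of the
feature block (default B = 9999, seeded; the p-value is floored at
$1/(B+1)$).

*Longitudinal model.* `fit_logistic_mixed()` fits
$\mathrm{logit}\,P(y_{it}=1) = x_{it}'\beta + b_i$, $b_i \sim N(0,
\sigma^2)$, by maximizing the marginal likelihood with adaptive
Gauss–Hermite quadrature: per subject, the integrand's mode and
curvature are found by Newton steps and the 15-node grid (configurable)
is centered and scaled there. Time is coded 0 (month 6) / 1 (month 36),
the loading is a time-invariant [0, 1] covariate, and a loading × time
interaction tests whether the factor's effect changes over follow-up.
Fixed effects agree with an independent adaptive-quadrature
implementation to ~1e-3 and are insensitive to doubling the node count;
with the random-intercept variance forced to zero the fit collapses to
plain logistic regression within 2%. Missing timepoints are dropped
case-wise in cross-sectional fits and handled by the available rows in
the longitudinal likelihood.

*Calibration.* The suite checks, under the null: Wald logistic and
mixed-model interaction type-I error within 5% ± 2% over 500 replicates
each; BH empirical FDR ≤ 0.05 plus twice its Monte-Carlo SE over 5000
replicates; and uniform CCA permutation p-values (KS test) over 500
replicates.

# The pipeline

`run_pipeline()` executes simulate → map-lesions → disconnect →
factorize → associate into one output directory, with per-stage seeds
derived deterministically from the master seed (so any stage can be
rerun in isolation with identical randomness), per-stage output
checksums in `manifest.json` (so silent input drift is detectable), and
skip-if-unchanged semantics. Masks and templates travel as NIfTI-1,
tables as CSV, model and association summaries as JSON, configuration as
one YAML file validated against the schema before any stage runs.
`pipeline_report()` renders per-factor top-tract tables with cumulative
load shares and the association summaries. The factorize stage defaults
to the planted corpus (`source = "planted"`), keeping estimator behavior
attributable; `source = "geometric"` switches to the WMH profile route.

Problem sizes used by the tests and the acceptance script — grids
$20^3$–$40^3$, 105–300 subjects, 10–50 replicates per property, 199–999
permutations — were chosen as the smallest sizes at which the planted
effects and calibration bounds are comfortably resolved.

# Known limitations

* The template is schematic; lobar sectors are geometric, not
  anatomical, so bullseye parcels are internally consistent but not
  comparable to atlas-based lobar labels.
* Tract-level disconnection inherits the usual atlas assumptions: a
  single normative white-matter anatomy, axonal interruption wherever a
  mask touches a streamline, and no weighting by the extent of overlap.
* Passing the synthetic suites shows the estimators work under the
  generative model they assume (plus the full geometric chain); it does
  not show that three factors, or these effect sizes, describe any real
  cohort.
* The compositional coupling of loadings described above means
  factor-wise outcome tests are not independent; interpreting a
  significant *negative* factor association requires checking its
  correlation with the dominant positive factor.
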