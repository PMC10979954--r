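---
title: "Methods: connectivity contrasts, graph metrics and cytokine signatures"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: connectivity contrasts, graph metrics and cytokine signatures}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cytonet)
```

# Scope and study design

`cytonet` implements an analysis pipeline for a two-genotype mouse study of
Alzheimer's-disease progression: 5xFAD mice and wild-type (WT) littermates
are imaged awake with resting-state fMRI at four cross-sectional ages (1.5,
2, 4, 6 months), and a 23-analyte cytokine panel is measured in dissected
brain regions of the same animals. The pipeline covers five stages —
preprocessing of ROI time series to connectivity matrices, Fisher-z group
contrasts, weighted graph metrics, cytokine panel cleaning, and
orthogonalized PLS modelling of cytokine signatures — plus a synthetic-data
generator that emulates the study design so that every stage is testable
without the raw scans.

# The synthetic-data generator

`synth_config()` fixes the simulated study conditions. The defaults encode
the design the pipeline targets:

* **16 subjects per genotype x age cell**, 4 EPI scans per imaging session,
  TR = 1.5 s, 300 volumes per scan. These match a study of roughly 130
  single-timepoint animals with "4 or 5" scans per session.
* **28 ROIs in 7 anatomical systems** (Sensorimotor Cortex, Heteromodal
  Cortex, Olfactory Cortex, Hippocampus, Striatum-Pallidum, Thalamus,
  Hypothalamus). The real parcellation is finer; 28 ROIs keeps the
  block-community structure while staying tractable for repeated
  simulation.
* **Block correlation structure**: within-system ROI pairs target r = 0.6,
  between-system pairs r = 0.2 — values typical of awake rodent rsFC after
  nuisance regression.
* **Genotype effect** of -0.3 Fisher-z units applied to the
  intra-hippocampus block at months 4 and 6, emulating late-stage
  suppression of intra-hippocampal connectivity; subject-level random
  intercept of SD 0.1 z applied to all edges.
* **Cytokines**: lognormal concentrations (noise SD 0.5 on the log scale)
  with 3 of 23 analytes planted to rise with age at 0.5 noise-SD per month
  in the 5xFAD group, and detection limits of 2 and 20 000 pg/mL.
* **Motion**: uniform jitter well below the scrub threshold plus Bernoulli
  spikes (0.2 mm translation) at rate 0.01 per volume, giving ~3%
  censored volumes and occasional whole-scan loss — a realistic retention
  profile for awake imaging.

Genotype and subject effects are applied *in z-space* and back-transformed,
so every target matrix is a valid correlation matrix; mildly indefinite
block targets (possible at extreme parameter combinations) are repaired by
eigenvalue clipping at 1e-8 followed by rescaling to unit diagonal, while a
configuration whose noise-free target is severely indefinite (a negative
eigenvalue beyond 5% of the leading one) is rejected with a diagnostic.
What the generator deliberately does **not** emulate: scanner physics,
hemodynamic autocorrelation, spatially structured noise, plate effects and
standard-curve estimation for the cytokine assay. Passing tests therefore
demonstrate correctness of the statistical machinery under the assumed
generative model, not robustness to every artifact of real data.

# Preprocessing

**Motion parameter.** Per-volume displacement is computed from rigid-body
affines as `|Tx|+|Ty|+|Tz| + |θx|·rz + |θy|·rz + |θz|·rx`, with Euler
angles extracted in the intrinsic Z-Y-X convention (validated only through
round-trip identities, so the convention cannot affect contracts). Two
choices deserve flagging. First, the radii are not standardized anywhere;
we default to rx = ry = rz = 5 mm, an effective mouse-brain radius, and
expose them as arguments. Second, the term pairing is asymmetric — both
in-plane rotations are scaled by `rz` — which we retain as published
rather than "correcting" to `θy·ry`; with isotropic default radii the two
readings coincide. Absolute values are summed because a displacement must
be non-negative.

**Scrubbing.** Volumes with displacement above 0.125 mm (half an in-plane
voxel) are censored together with one neighbour on each side; a scan is
kept only if at least 90% of volumes survive. Already-censored volumes are
not re-detected as offenders, which makes the rule idempotent.

**Nuisance regression** is an ordinary least-squares projection of each ROI
signal on an intercept, the WM-CSF mean signal (when supplied) and the six
rigid motion parameters, computed over retained volumes only. A
rank-deficient design is an error naming the collinear columns rather than
a silent drop.

**Band-pass.** A zero-phase 4th-order Butterworth band-pass at
0.01–0.1 Hz. Censored volumes are linearly interpolated before filtering
and re-excluded afterwards: interpolation avoids ringing across gaps while
the discard rule still governs which volumes reach the correlation step.
The series is demeaned and reflection-padded (three high-pass time
constants) before filtering to suppress start/end transients. Spatial
smoothing uses a normalized 3x3 Gaussian kernel with σ = 0.7 px (only the
kernel size is standardized; σ is our choice) and renormalizes by in-mask
kernel mass so constants are preserved at borders.

**Correlation.** Pearson correlation over retained volumes (at least 30
required). Zero-variance ROIs become NA rows/columns with a warning and
propagate pairwise instead of failing the scan; the graph stage later
treats them as absent edges and counts them.

# Connectivity contrasts

Edgewise and system-level analysis work in Fisher-z space (`atanh`),
where correlations average properly; correlations of exactly ±1 (possible
with duplicated ROIs in tests) are clipped to ±(1 − 1e-10). System
aggregation averages all between-system ROI pairs, or all distinct
within-system pairs for diagonal blocks; singleton systems have no
intra-system value and yield NA with a warning.

Group contrasts use a linear mixed model per edge, `z ~ genotype +
(1 | subject)` by REML, so repeated scans enter as repeated rows under a
subject random intercept; longitudinal analyses add age and the
genotype x age interaction. The genotype coefficient is tested with a
two-tailed Wald t-statistic. For the degrees of freedom we use the
*subject-stratum* residual count (number of subjects minus fixed-effect
count) rather than the scan-row residual count: genotype (and, in this
cross-sectional design, age) vary between subjects, so scan rows are not
independent replicates for this contrast. In balanced designs this
reproduces the exact subject-means t-test, and simulation under the null
generator shows the 5% level is held (empirical rate ≈ 0.05), whereas
row-based degrees of freedom are anticonservative. Singular fits fall back
to OLS with a recorded flag. The FDR family is all edges (or system pairs)
within one timepoint's comparison, corrected by Benjamini–Hochberg; both
the 0.05 and stricter 0.005 style thresholds seen in per-edge reporting
are exposed as the `alpha` parameter rather than hard-coded.

The two-way genotype x age ANOVA on global graph metrics is a
fixed-effects `aov` on subject means (scans averaged within subject
first), matching the scan → subject → group averaging order used
throughout.

# Weighted graph metrics

Connectivity matrices become weighted graphs with `w = |r|` and zero
diagonal. Strength, Onnela clustering, characteristic path length, global
efficiency and weighted assortativity are computed from their printed
definitions; Dijkstra distances and betweenness centrality, which are
standard algorithms rather than study-specific definitions, are delegated
to igraph. Choices worth recording:

* **Weight-to-length map**: `1/w`, the standard choice for correlation
  graphs. Nothing in the source material fixes it; it is exposed
  prominently here because every distance-based metric depends on it.
* **Clustering normalization**: weights are divided by the maximum weight
  before the geometric-mean triangle term (Onnela convention), keeping
  `C_i ≤ 1`; exposed as a flag defaulting to on.
* **Assortativity normalization**: the weighted degree-degree correlation
  is normalized by total edge weight `H = Σ w_ij` (the Leung–Chau
  estimator). A literal edge-count normalization of the same sums is not
  invariant under uniform weight rescaling and assigns a hub-and-leaves
  star a positive coefficient; the `H`-normalized form restores both the
  expected scale-invariance and the star's r = −1. Zero denominators
  (regular graphs) return NA flagged as undefined.
* **Disconnected graphs**: efficiency uses 1/∞ = 0; characteristic path
  length is reported as infinite with a finite-pairs fallback alongside.
* **Hub scores** (computed on group-mean graphs) award one point each for
  the 20% highest strength, 20% highest betweenness, 20% lowest mean
  distance and 20% lowest clustering coefficient. The "lowest clustering"
  criterion is unusual but retained as specified. Per-node path length
  means nodal mean distance (not eccentricity). Cutoffs are empirical
  80th/20th percentiles with linear interpolation; ties at the threshold
  all qualify, so fully regular graphs score 4 everywhere.

All metrics are validated against exhaustive-enumeration oracles
(all-simple-path search, explicit triple sums, term-by-term formula
evaluation) on hundreds of random graphs with up to 6 nodes.

# Cytokine cleaning

Concentrations below an analyte's standard-curve minimum are set to
0 pg/mL and values above the maximum to the curve maximum (idempotent).
An analyte is retained within a region stratum when nonzero in at least
half of the subjects, or — the group-bias exception — when its nonzero
values concentrate in one genotype. The exception is quantified as a
one-sided Fisher exact test on the genotype x nonzero table at p < 0.10
(threshold configurable): the qualitative published rule needs a numeric
operationalization, and the worked case of 3 nonzeros all in one genotype
of a 5v5 design (hypergeometric p = 0.0833) is retained under this
threshold. The stratum includes both genotypes — the bias test is
undefined otherwise — and every decision is logged in a machine-readable
audit table (rule fired: `half`, `bias`, or `dropped`).

# Partial least squares

The PLS engine is written from scratch. For a univariate response the
NIPALS inner loop converges in one step, so each component has the closed
form `w = X'y/||X'y||`, `t = Xw`, `p = X't/t't`, `q = y't/t't`, followed
by deflation of X and y. Predictors are z-scored with training statistics
(constant columns are an error naming the analyte); the response is age in
months for PLSR, or a two-level class coded −1/+1 for PLS-DA with class
assignment by sign — the study designs are two-group throughout, so no
multi-class coding is needed.

**Orthogonalization** re-expresses an A-component model as one predictive
latent variable plus A−1 response-orthogonal components (Trygg–Wold
orthogonal signal correction). Predictions are invariant to within 1e-8 —
a property asserted on every fitted model in the test suite — and the
orthogonal-component scores are uncorrelated with the response by
construction. The VIP vector of the parent fit is retained on the
orthogonalized model so that the mean-square-1 identity and the
"greater-than-average contribution" reading of VIP > 1 refer to the
predictive components that explain the response.

**Model selection** uses repeated random k-fold cross-validation: k = 3
when more than 30 samples, else k = 5 (the boundary n = 30 is not covered
by the stated rule; we assign k = 5, keeping more data per training fold),
100 repeats by default, candidates of 1–3 latent variables, RMSECV
(pooled out-of-fold root-mean-square error) for regression or accuracy for
PLS-DA, ties broken toward fewer components. Z-scoring is refit inside
each training fold by default — the leakage-safe reading — with a
`global_scaling` compatibility flag for the alternative. PLS-DA fold
draws that leave a training fold single-class are redrawn and counted.

**Significance** comes from a permutation test: the response is shuffled
and the same cross-validated statistic recomputed (`n_perm` = 1000 by
default), the observed statistic standardized as
`Z = (x_model − μ_null)/σ_null`, and the p-value taken from the
standard-normal tail in the favorable direction (lower RMSECV, higher
accuracy). A degenerate null (σ = 0) is flagged undefined rather than
returning an arbitrary value. Under a null generator the resulting
p-values are approximately uniform (Kolmogorov–Smirnov D ≈ 0.03–0.07 over
100 datasets at n_perm = 200 in the acceptance runs).

Numerical conventions: NIPALS tolerance is moot for the closed-form PLS1
path; components with no remaining covariance terminate extraction; the
score-orthogonality and mean(VIP²) = 1 identities are asserted at 1e-8 on
every fit. Models are fitted separately per region x genotype with age as
the response, mirroring the per-region signature analysis; the pipeline's
`signature_report()` lists analytes with VIP above 1 together with their
signed first-latent-variable loading (up- or down-regulated with age).

# Problem sizes used in validation

The test suite and acceptance script size their simulations to what the
statistical property needs rather than to the full study scale: oracle
equivalence uses 200 random graphs of up to 6 nodes; null calibration of
the edgewise contrast uses 100 synthetic datasets of 6 ROIs, 6 subjects
per genotype and 2 scans each; permutation calibration uses 100 datasets
of 24 samples x 10 analytes at 200 permutations; VIP recovery uses 50
replicates of a 26-subject, 23-analyte panel; and the end-to-end
determinism checks run the complete pipeline on the default 512-scan
synthetic study (with reduced cross-validation and permutation counts)
and on a smaller 7-system configuration, comparing artifacts
byte-for-byte.

# Known limitations

* Published summary statistics of the original cohort (per-region RMSECV
  values, per-edge p-values, VIP counts) are not reproducible targets: the
  underlying animal data are not deposited. The pipeline is validated by
  construction — exact oracles, closed forms, calibration and recovery on
  synthetic data — rather than by matching those numbers.
* The LME stage assumes a subject random intercept only; random slopes or
  scan-level covariates are out of scope.
* Spatial smoothing operates on image planes and is provided for
  completeness of the preprocessing contract; the ROI-series path used by
  the pipeline does not need it.
* PLS-DA supports exactly two classes.
* The co-registration/atlas-normalization steps of real imaging pipelines
  are not modelled; the generator emits ROI-labelled series directly.
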