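---
title: "Methods: representational similarity analysis of observed social touch"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: representational similarity analysis of observed social touch}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(touchrsa)
```

## The scientific problem

When people watch one person touch another — a hug, a slap, holding hands —
they read off the affective meaning of the interaction with little effort.
Two neural systems are candidate substrates: the theory-of-mind network
(notably the temporoparietal junction, TPJ), supporting explicit inference
about others' states, and the somatosensory cortex (Brodmann areas 3, 1, 2),
supporting an embodied re-enactment of the observed touch. A central
question in autism research is whether autistic adults, who often report
aversion to social touch, differ in either system when observing touch.

`touchrsa` implements the multivariate analysis used to ask that question:
representational similarity analysis (RSA) over region-of-interest (ROI)
voxel patterns evoked by a set of touch videos, combined with behavioural
affect ratings, questionnaire measures, and case-control statistics. The
package also ships a synthetic cohort generator with a known ground truth,
so the entire pipeline can be validated end to end — parameter recovery,
null calibration, power — without access to any scanner data.

## The design and the data

The target design has 75 short video stimuli: 39 social touch scenes
(positive, e.g. hugging; negative, e.g. slapping) and 36 non-social object
manipulations matched for the physical action (hugging a person vs. holding
a large box). Each participant rates every video twice on two 1–9 Likert
scales — valence (1 extremely unpleasant, 5 neutral, 9 extremely pleasant)
and arousal (1 extremely calm, 9 extremely exciting) — and later views the
same videos in the scanner while performing an orthogonal shirt-colour
task. The case-control sample is 21 autistic (ASD) and 21 neurotypical
(NT) adults. The pipeline consumes already-extracted stimulus × voxel
pattern matrices per subject and ROI; image preprocessing, GLM fitting and
ROI definition are upstream of this package and out of its scope.

## The model

### Dissimilarity matrices

Every analysis currency is a representational dissimilarity matrix (RDM):
a labelled, symmetric, zero-diagonal matrix of pairwise dissimilarities
between stimuli.

* **Neural RDMs** (`neural_rdm()`): entry $(i,j)$ is $1 - r_{ij}$, the
  Pearson correlation distance between the voxel patterns of stimuli $i$
  and $j$. The raw pairwise correlations define pattern similarity; the
  $1-r$ transform (range $[0,2]$) is the standard RSA convention and is
  configurable (`dissim = "neg_r"` gives $-r$; both are monotone
  relabelings, so permutation inference is unaffected). A *general touch*
  RDM spans all 75 stimuli ($75\times75$); the *social touch* RDM is its
  restriction to the 39 social stimuli ($39\times39$,
  `subset_rdm()`).
* **Model RDMs**: the binary social/non-social model (0 within class, 1
  across), binary motor-response and action-type models, absolute-difference
  models for the three physical covariates (pixel-wise intensity, pixel-wise
  motion energy, total motion energy), and the **affect RDM**
  (`affect_dissimilarity()`): for each subject the Euclidean distance
  $\sqrt{(v_i-v_j)^2 + (a_i-a_j)^2}$ between stimuli in the
  (valence, arousal) plane, computed from session-averaged ratings and then
  averaged across subjects. Each group's own affect RDM is used for that
  group's neural models.

### Regression RSA

For a dependent RDM $D$ and candidate model RDMs $M_1,\dots,M_k$, each
matrix is vectorised by its row-major upper triangle (diagonal excluded;
$n(n-1)/2$ entries — 2775 for the general model, 741 for the social model)
and z-scored (sample SD, $n-1$). The fit is ordinary least squares,

$$ z(D) = \beta_0 + \sum_k \beta_k\, z(M_k) + \varepsilon, $$

and each $\beta_k$ indexes model $k$'s independent contribution to the
neural dissimilarity structure. The general-touch model uses the social
binary model plus motor, physical and action-type regressors; the
social-touch model replaces the binary model by the group's affect RDM.
An intercept is included; with z-scored variables it is numerically ~0 and
the slopes are unchanged, so this choice is immaterial for the group model
but kept for generality at the subject level. The row-major triangle order
is fixed package-wide so that permutation indices and regressor rows always
align; any consistent z-scoring convention only rescales all betas by a
common factor, so the $n-1$ convention is fixed once and documented rather
than exposed.

### Permutation inference and FDR

Statistical inference on the group-level coefficients uses a permutation
test (default 1000 iterations, `rsa_regression()`): the entries of the
*neural* vector are randomly shuffled, the full regression is refit, and
for each regressor the empirical $p$ is the fraction of iterations whose
coefficient is **greater than or equal to** the observed one. This is a
one-sided test of $\beta > 0$, matching the count rule of the original
procedure; shuffling the dependent vector destroys the pair structure
identically for all regressors, which is exactly the intended null. The
same shuffled vector serves all regressors within an iteration, preserving
their correlation structure under the null.

Two details deserve note:

* The count rule can produce $p = 0$. The object reports it as counted
  (printed as `<1/n_perm`), and additionally stores the add-one smoothed
  value $(\text{count}+1)/(n_\text{perm}+1)$, which is never exactly zero
  and is the better-behaved quantity for downstream manipulation.
* FDR correction is Benjamini–Hochberg (`fdr_correct()`). The correction
  family is configurable (`pipeline_config(fdr_family=)`): `"joint"`
  (default) corrects across all regressors × ROIs within one (group,
  model) family; `"roi"` corrects within each fit; `"regressor"` across
  ROIs within a regressor. The family choice is genuinely open in this
  kind of design and is therefore surfaced as a parameter rather than
  hard-coded.

### Noise ceilings and subject-level analysis

Reliability of the neural data is quantified by leave-one-subject-out
correlations (`noise_ceiling()`): each subject's RDM vector is correlated
(Pearson) with the mean RDM vector of the remaining group members; the
held-out subject never enters its own reference. Group comparison of the
per-subject values uses the gated test below.

For direct group comparisons of representational strength, the regression
is fit per subject (`subject_level_analysis()`), and the per-subject
coefficients are compared between groups regressor by regressor.

### The statistical toolbox

All group statistics route through a normality gate: Shapiro–Wilk on each
sample at $\alpha = 0.05$; if any sample rejects (or is constant, where
the test is undefined), the non-parametric branch is taken. Parametric
branch: pooled-variance two-sample t; non-parametric: Mann–Whitney U with
tie-corrected normal approximation reported as a signed z (positive when
the first group ranks higher — the direction convention is documented, not
inferred). When every observation is tied the tie-corrected variance is
zero and the comparison is defined as $z = 0$, $p = 1$. Cohen's d uses the
pooled-SD formula and is attached whenever the null is rejected.
Correlations are Pearson or Spearman by the same gate; brain–behaviour
analyses additionally use a Spearman **rank partial correlation**
(rank-transform everything, residualise on covariate ranks, correlate
residuals; t-approximate $p$ on $n-2-k$ df) with age and mean framewise
displacement as covariates, and an ANCOVA-style adjusted group test
(`covariate_adjusted_group_test()`).

## The synthetic cohort generator

`simulate_cohort()` generates design, ratings, voxel patterns and
questionnaires from an explicit [ground truth](#) (`ground_truth()`), and
the truth is always serialized next to the data.

* **Ratings** are truncated Gaussians around per-(group, category,
  dimension) anchors, rounded to the integer 1–9 scale. The anchors are
  the group category medians the behavioural stage is expected to recover
  (NT valence 7.4 / 2.9 / 4.8 for positive / negative / non-social, ASD
  6.8 / 3.0 / 4.8; NT arousal 5.7 social vs 2.4 non-social, ASD 6.2 /
  2.5). Three noise scales on the 9-point scale — stimulus 0.8 (shared by
  all raters, driving high between-subject agreement), subject 0.4,
  session 0.5 — are the package's own choice of a realistic rater; they
  produce within-subject session correlations around 0.8–0.9 and high
  leave-one-out agreement, and are deliberately not exposed as tuning
  knobs of any test.
* **Patterns** for subject $s$, ROI $r$ are
  $P = \sum_m g(\text{group},r,m)\, F_m Q_{r,m}^\top + \varepsilon$,
  with $F_m$ the column-standardised feature matrix of model channel $m$
  (social indicator: 1 bit; affect: the group-mean (valence, arousal)
  stimulus coordinates from the ratings stage, so the planted geometry is
  exactly the affect RDM the regression fits; motor/action: one-hot;
  physical features: scalars), $Q_{r,m}$ a random orthonormal voxel
  projection drawn once per (ROI, channel) — orthonormalisation avoids
  accidental collinearity between planted channels — and
  $\varepsilon \sim N(0, 1)$ i.i.d. voxel noise. Default 200 voxels.
* **The planted hypothesis** (defaults): the social distinction and the
  nuisance channels everywhere in both groups; the affect geometry in TPJ
  for both groups (gain 0.5) but in the somatosensory ROIs only for the
  NT group. The NT somatosensory affect gain (0.65) was fixed by a power
  sweep at the study size so that the subject-level group difference is
  detected with ~0.95 power — i.e. the generator's default encodes a
  clearly detectable dissociation, as a ground-truth benchmark should.
  In somatosensory ROIs each subject's affect gain is scaled by
  $\exp(0.3 z_s)$ with $z_s \sim N(0,1)$: this per-subject embedding
  strength is the latent variable that the questionnaire generator
  couples to.
* **Questionnaires**: each scale is drawn around its group mean and SD
  (STQ 69.2 ± 9.6 NT vs 56.8 ± 13.2 ASD; SRS-A total 51.9 ± 8.9 vs
  63.8 ± 11.6, with analogous subscale parameters), with coupling ±0.5
  to $z_s$ — positive for social-touch preference, negative for
  autistic-trait scores. STQ totals are rounded and clipped to the
  attainable 20–100 range. Age and mean framewise displacement are drawn
  uncoupled for use as covariates.

Everything is a pure function of (config, seed); stage seeds are derived
deterministically from the master seed.

### What the generator does and does not emulate

It reproduces the study's *statistical* structure: category median
structure and rating reliability, correlated model geometries embedded in
voxel patterns, group-specific embedding gains, questionnaire coupling.
It does **not** simulate haemodynamics, spatial voxel correlation,
session/run structure, head motion artefacts, or ROI-size variability —
so a passing recovery suite demonstrates the pipeline's correctness and
power under idealised noise, not the signal-to-noise ratio of real fMRI.
Single-subject neural RDMs under the default noise are noisier than real
group data in reliable ROIs (leave-one-subject-out correlations around
0.05), which is why group-average fits carry the primary inference, as
they do in the target analysis.

## Numerical and design choices

* Medians/MADs for ratings are reported with the **unscaled** MAD (median
  absolute deviation without the 1.4826 consistency factor), matching the
  scale on which such ratings are conventionally summarised.
* Group comparisons of category ratings reduce each subject to the *mean*
  over the category's stimuli before testing (configurable to median);
  the reduction is a documented choice, not a claim about the original
  analysis.
* Rating reliability correlations default to Spearman (ordinal scales);
  within-subject reliability requires exactly two sessions, and constant
  rating vectors yield a flagged `NA` rather than silent omission.
* `fit_rdm_regression()` refuses rank-deficient designs naming the
  collinear columns; `vectorize_z()` refuses constant RDMs; degenerate
  (constant) voxel patterns error naming the stimulus.
* Permutation streams, projections and noise are all seeded; identical
  seeds give bit-identical results, and the permutation test solves all
  shuffled fits through one QR decomposition for speed.

## Validation problem sizes

The test suite validates against independent oracles (normal equations,
brute-force Benjamini–Hochberg, double-loop affect distances, pairwise-win
Mann–Whitney counts, replayed permutation streams) and runs
calibration/recovery studies at deliberately chosen sizes: null
calibration with 500 single-subject replicates at 200 permutations
(empirical type-I error within the binomial 95% band of 0.05), a 5-point
gain grid with 50 replicates per point at the full 21-subject, 200-voxel
study size (mean recovered affect beta strictly increasing), and 50 full
21 + 21 cohort replicates for the somatosensory dissociation (NT affect
coefficient significant, ASD not, groups different — recovered in well
over 80% of replicates). These sizes give stable Monte-Carlo estimates
while keeping the default suite quick to run.

## Known limitations

* ROIs are opaque labels over supplied pattern matrices; no voxel
  selection, searchlight, or anatomical logic is included.
* Only plain correlation distances are implemented — no cross-validated
  (crossnobis) distances, which would be preferred for noisy
  single-subject inference but are not part of the target analysis.
* The permutation test is exchangeability-based on RDM entries; entries
  sharing a stimulus are not independent, which is exactly why inference
  relies on the permutation null rather than parametric OLS standard
  errors.
* The Mann–Whitney z sign convention and the FDR family are conventions
  of this package (documented above), since neither is uniquely
  determined by the analysis description it follows.
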