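---
title: "Methods: linking connectomes, ongoing thought, and well-being"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: linking connectomes, ongoing thought, and well-being}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

thoughtnet implements a complete inference chain for resting-state
neurocognitive studies in which participants rate their ongoing thoughts on
a short Likert questionnaire after a rest scan, functional connectomes are
built from ROI time series, and self-reported well-being is measured
separately. The chain has five statistical stages — thought-pattern
decomposition, the network-based statistic (NBS), signed graph metrics,
test-retest reliability, and bootstrap mediation — plus a synthetic cohort
generator that plants known structure so every stage can be validated
end-to-end without human data. This vignette is the package's account of the
models, the tunable parameters, and the design decisions taken where the
methodology left real choices open.

## Thought-pattern decomposition

Items of the experience-sampling questionnaire (Likert 1–4, no missing
cells) are treated as observations with subjects as features, and
hierarchically clustered with Ward linkage on squared Euclidean distances
(`stats::hclust(method = "ward.D")` on squared distances — the classic
SPSS-style Ward). The tree is cut into exactly two clusters, which
partitions the questionnaire before decomposition. Each cluster is then
standardized item-wise and decomposed by PCA on the item correlation matrix;
the leading three components per cluster (six in total, the pipeline
default; a strict eigenvalue-greater-than-1 rule is available via
`select_n_components()`) are varimax-rotated with Kaiser row normalization
(tolerance 1e-8). Because an orthogonal rotation is used, item communalities
and the loading Frobenius norm are conserved — the test suite asserts both
to 1e-8.

Three conventions remove the indeterminacies that otherwise make factor
output irreproducible:

* **Sign**: within each rotated component, the loading largest in absolute
  value is made positive.
* **Scores**: the regression method (`W = R^{-1} L`), the common default in
  commercial PCA implementations; in-sample score columns have mean zero by
  construction.
* **Projection**: session-2 ratings are standardized with the *session-1*
  means and standard deviations and multiplied by the *session-1* weights
  (`project_session()`); nothing is refit, so test-retest comparisons see
  the identical measurement model in both sessions.

## Connectome construction

`build_connectome()` computes all pairwise Pearson correlations between ROI
time series and zeroes the diagonal; matrices stay fully connected, signed,
and weighted. No Fisher z-transform is applied by default — the analyses
operate on raw `r` — but `fisher_z = TRUE` enables it for sensitivity runs.
Mean connectivity, a subject-level nuisance regressor in the NBS, is the
mean over the strict upper triangle of the *signed* weights (the mean of
absolute weights would conflate overall coupling with sign balance).
Edge bookkeeping everywhere uses the strict upper triangle with 0-based
node pairs `(i, j)`, `i < j`.

## Network-based statistic

For one contrast the NBS proceeds in three steps:

1. **Edgewise GLM.** At every edge, ordinary least squares of edge weight on
   the full design: the six thought scores (block of interest) plus
   intercept, mean connectivity, age, gender, and motion fraction
   (nuisance). The per-edge t statistic for the contrast column is computed
   vectorized across all edges. Edges fit perfectly by the design (zero
   residual variance) would have infinite t; they are capped at 1e6 with a
   log note.
2. **Component extraction.** Edges with `|t| >= T` (two-sided default,
   `T = 3.2`) are assembled into a graph and its connected components are
   the candidate effects. Component *size* is the **edge count** (NBS
   "extent"); the intensity variant is deliberately not implemented.
   One-sided modes (`positive`, `negative`) are available; two-sided is the
   default so a single component can carry both positively and negatively
   associated edges.
3. **Permutation FWE.** Under the default `permute_interest` scheme the rows
   of the interest block are shuffled jointly — all six scores move
   together, preserving their inter-correlation — while the
   nuisance-connectome pairing stays fixed. Each permutation records the
   maximal component size; the FWE-corrected p-value of an observed
   component of size `s` is `(#{null >= s} + 1) / (n_perm + 1)`. The +1
   smoothing avoids p = 0 and is standard practice; `p_smoothing = FALSE`
   reproduces the plain `k/n` proportion, and `exhaustive = TRUE` (up to 8
   subjects) replaces sampling by the full permutation group, where the
   plain proportion over all `n!` shuffles is exact. Freedman–Lane residual
   permutation is available behind `scheme = "freedman_lane"`.

Each of the six contrasts is tested in its own NBS run at alpha = 0.05 with
no correction across contrasts. This mirrors the analysis the pipeline
reproduces and is a deliberately liberal choice; users scanning many
questionnaires should correct accordingly.

## Signed graph metrics

Significant components become mask graphs: `mask_connectome()` retains a
subject's own weights on the component edges and zeroes everything else.
On the masked graph:

* **Strength triplet** per node: positive strength `sum(max(w, 0))`,
  negative strength as a **magnitude** `sum(|min(w, 0)|)`, total strength
  their sum. Reporting negative strength as a magnitude means "total =
  positive + negative" reads as intended on ring plots and in robustness
  checks.
* **Fractional strength**: the ratio of summed positive to summed negative
  weights, at node or graph level, analyzed downstream on the natural-log
  scale. When the negative (or positive) sum is zero the log ratio is
  undefined; such subjects are flagged and propagate as missing — never as
  zero — and are dropped from regressions with a logged count.
* **Betweenness centrality**: weighted shortest paths on lengths `1/|w|`
  (signed shortest-path semantics are ill-defined, so the absolute weight is
  the connection strength; the sign carries no meaning here), ties split
  fractionally, normalized by `(n-1)(n-2)` over ordered pairs so the middle
  node of a three-node path scores exactly 1. Components with fewer than 3
  nodes score 0.

Group-level characterizations are metrics computed per subject and then
averaged — not metrics of the averaged graph.

## Test-retest reliability

`icc()` implements the two-way random-effects, absolute-agreement,
single-measure coefficient ICC(2,1) from the ANOVA mean squares, with a
percentile bootstrap CI over subjects (5,000 resamples by default) and a
one-sided F-test of ICC > 0. ICC(2,1) is the strict choice when sessions
are interchangeable random "raters"; ICC(3,1) (consistency) is available via
`form = "ICC3_1"` for sensitivity — it ignores a systematic session offset
that ICC(2,1) penalizes. Brain-side reliability is computed on the natural
log of graph fractional strength. `change_correlation()` is the Pearson
correlation of session-to-session changes with its t-based p-value: the
state/trait dissociation rests on a measure being *unstable but coupled*
(state-like) versus *stable and decoupled* (trait-like).

## Mediation

`mediate()` estimates the indirect effect of brain connectivity `x` (log
fractional strength) on a well-being domain `y` through a thought score `m`,
adjusting every path for age, gender, and motion fraction (mean connectivity
is an NBS-stage nuisance only). Continuous variables are z-scored once on
the full analysis sample, so paths are standardized betas; the same
complete-case subsample is used for all paths, which makes the OLS
decomposition `c = c' + a*b` hold to machine precision (asserted at 1e-8 in
the tests). The indirect effect `a*b` gets a percentile-bootstrap CI (5,000
resamples by default, subjects resampled with replacement); significance is
the CI excluding zero. Regression p-values for the brain predictor are
Bonferroni-corrected across the two well-being domains (`k = 2`).

## The synthetic cohort generator

`simulate_cohort()` is first-class, tested code, not a fixture. From a
single seed it generates everything downstream stages consume. Defaults
emulate the study conditions the pipeline targets: 211 subjects, a 264-node
parcellation in 13 networks, 25 Likert items, a 40-subject retest arm, and
gender drawn Bernoulli(0.61) to match a 129/82 split;
`desk_cohort_config()` scales to 200 subjects and 60 nodes for interactive
and simulation work.

**Ratings.** Six latent unit-variance factors, three per item cluster, with
within-cluster factor correlation 0.2 (clusters independent); each item
loads 0.95 on its factor and is discretized at the standard-normal quartiles
into 1–4. The high loading is an idealization: the 4-level discretization
alone costs roughly 0.03–0.05 in score-factor correlation, and with
realistic questionnaire loadings (~0.7) the regression scores would recover
the planted factors at |r| ≈ 0.8, too weak a ground truth for sharp
recovery tests. With these defaults the two clusters are recovered exactly
by Ward clustering and the six scores correlate |r| >= 0.9 with the planted
factors at n = 200.

**Connectomes.** A shared population matrix (correlation matrix of a
low-rank factor model, shrunk by 0.6) plus a subject-level mean shift
(sd 0.06) on all edges — this makes the mean-connectivity nuisance
non-degenerate — plus planted component effects plus i.i.d. edge noise
(sd 0.16), clipped to [-1, 1] with saturation monitored (a warning fires
when more than 5% of planted-edge values clip). A planted component is a
connected edge set whose weights shift by `score * effect_per_edge * sign`;
with the default effect 0.1 the per-edge edge–score correlation is
`0.1 / sqrt(0.1^2 + 0.16^2 + 0.06^2) ≈ 0.5`, and the variance of a planted
edge decomposes into effect² + noise² + shift², which the tests verify to
5% at n = 2000. Planted edges overwrite the population baseline with a
designed pattern (~60% at +0.35, ~40% at −0.35, one association sign
flipped): mixed baselines keep both strength sums bounded away from zero so
the component's log fractional strength is defined for every subject, and
score effects then raise the positive sum while shrinking the negative one,
giving the brain summary a strong monotone coupling with the score
(realized standardized a-path ≈ 0.7). A symmetric construction (effects
aligned with baseline signs) would leave the pos/neg ratio constant in the
score — the balance metric would carry no signal.

**Well-being.** Psychological well-being follows the configured mediation
model: `c' * z(brain) + b * score + covariate effects + noise`, where
`brain` is the log fractional strength of the mediated (state-like)
component, so the a-path is realized through the planted edge effect
(`a_path` multiplies that effect; `a_path = 0` severs the first path).
Social well-being loads only directly on the trait-like component's
connectivity — its indirect effect is null by construction, which is what
the end-to-end test asserts.

**Retest.** Session-2 factor scores are `rho * s1 + sqrt(1 - rho^2) * e`
with `rho = trait_icc` for the trait-like factor and `state_icc` elsewhere,
giving population ICC(2,1) equal to `rho` (equal variances, no mean shift).
Session-2 connectomes reuse each subject's baseline and mean shift with
fresh edge noise; the state-like component's edges follow the session-2
score, while trait-like components express the stable session-1 score, so
their session-to-session changes are decoupled from score changes — the
trait side of the dissociation. The correlation between change in the
state-like score and change in its mean planted-edge weight is pinned to
`change_coupling` by adding a shared session-2-only perturbation to those
edges whose variance is solved in closed form from the generative variances
(`beta^2 Var(Δs) (cc^{-2} - 1) - 2 sigma^2/E`; clamped at zero with a
warning when the requested coupling exceeds what the effect admits). Because
the perturbation is session-2-only, it also lowers the state component's
brain-side ICC below the trait component's — a known asymmetry of this
construction.

**What the generator does not emulate.** BOLD autocorrelation and
finite-scan sampling noise in the correlations (connectomes are drawn
directly, not from simulated time series), spatial smoothness and
distance-dependent structure of real connectomes, heavy-tailed motion
artifacts correlated with connectivity, item-level response styles, and
missing data. Passing tests therefore certify the statistical machinery —
error control, recovery, calibration — under a clean generative model, not
robustness to fMRI preprocessing pathologies, which are upstream and out of
scope.

## Numerical choices and degenerate inputs

* Varimax: Kaiser row normalization, tolerance 1e-8.
* Singular item correlation matrices abort with the most collinear item
  named; constant items abort standardization.
* Edgewise GLM: rank-deficient designs abort naming the dependent columns;
  perfect fits cap at |t| = 1e6 with a note.
* Component ordering: by decreasing edge count, ties broken by smallest
  node id, so output is deterministic.
* Connectome I/O: full-precision TSV (17 significant digits), symmetry
  validated on read at 1e-10, weights validated against [-1, 1].
* ICC with zero between-subject variance returns 0 with a warning; p-values
  are floored at the smallest positive double.
* All randomness flows from named integer seeds; internal stages derive
  per-stage streams from the one top-level seed, and identical config plus
  seed reproduces every number bit-for-bit.

## Validation problem sizes

The test suite validates the chain at desk scale: type-I error of the NBS
from 200 null cohorts (n = 100, 40 nodes, 200 permutations each),
planted-component recovery over 20 cohorts (n = 200, 60 nodes, 1,000
permutations), exact agreement with an exhaustive 720-permutation
enumeration at n = 6, mediation recovery and CI coverage over 300 runs at
n = 500 (1,000 bootstrap resamples), and one full end-to-end run at the
desk defaults (1,000 permutations, 1,000 bootstrap resamples). Full-scale
settings (264 nodes, 5,000 permutations, 5,000 resamples) are the package
defaults for real analyses.

## Known limitations

* The NBS reports component-level inference only; no edge-level localization
  claim is made within a significant component.
* Six contrasts are tested at alpha = 0.05 each, uncorrected across
  contrasts (faithful to the reproduced analysis, but liberal).
* Betweenness on `1/|w|` treats strong negative edges as short — defensible
  for centrality-of-information-flow readings, but one of several
  conventions for signed graphs.
* ICC form and the meaning of bootstrap CIs are configurable because the
  methodology is genuinely underdetermined; defaults are documented above.
* The generator's item loadings are idealized (see above); real
  questionnaires will show weaker score recovery than the synthetic
  benchmarks.
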