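---
title: "Discovering and scoring morphological signatures of drug resistance"
author: "morphosig authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Discovering and scoring morphological signatures of drug resistance}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(morphosig)
```

# The problem

High-content assays such as Cell Painting measure thousands of
quantitative morphology features per cell. When clonal cell lines of known
drug sensitivity are profiled untreated, any systematic morphological
difference between resistant and sensitive clones is a candidate
*intrinsic* signature of resistance — a way to anticipate treatment
response without exposing cells to the drug. The difficulty is that such
differences are subtle and easily dominated by technical variation: the
imaging batch (day), how long cells sat in vehicle before fixation, how
dense each well grew, and generic clone-to-clone idiosyncrasies that have
nothing to do with resistance. morphosig implements a discovery procedure
built around explicitly modelling and excluding those nuisance sources,
and a rank-based scoring method that applies the resulting signature to
single profiles.

# Processing model and assumptions

Single-cell feature tables are median-aggregated per well: the median is
robust to segmentation errors and the heavy tails typical of single-cell
morphology distributions, and the per-well cell count is retained as a
covariate rather than discarded. Profiles are z-scored **per plate**
(population standard deviation, i.e. divide by $n$; `sd_type = "sample"`
is available), which puts features on a common scale and absorbs
plate-level offsets. A consequence worth knowing: any effect that is
constant within a plate — including a batch effect when each batch is one
plate — is removed by per-plate centering, and the largest attainable
|z| on a plate of $n$ wells is $\sqrt{n-1}$, so the 15-SD outlier rule
cannot fire on single-plate extremes of a standardized feature; it guards
pre-normalized inputs and pooled multi-plate extremes. No batch-effect
*correction* is applied beyond this; batch-varying features are instead
excluded at discovery time.

Feature selection applies five rules in a fixed order (blocklist, missing,
low variance, outlier, correlation) so that attribution is unambiguous and
the procedure is idempotent. Choices the field leaves loose are pinned
down as follows:

* **Low variance** means the most frequent value occupies more than 95% of
  wells, or the variance is below $10^{-12}$ — the unique-value-ratio
  heuristic common in profiling pipelines.
* **Correlation** (threshold 0.9) repeatedly finds the most correlated
  remaining pair and drops the member with the larger mean absolute
  correlation to everything else (ties by feature name): deterministic,
  and keeps the less redundant feature. After selection no surviving pair
  exceeds the threshold.
* The **blocklist** is a set of name patterns supplied by the user; the
  shipped default is empty.

# Discovery: two linear models, Tukey families, and exclusions

For every feature $Y_j$ an OLS fit of

$$Y_j = \beta_0 + \beta_{status}X_{status} + \beta_{batch}X_{batch} +
\beta_{time}X_{time} + \beta_{clone}X_{clone} + \varepsilon$$

quantifies covariate contributions ($R^2$ and coefficients are recorded).
Clones nest inside resistance status, so clone dummies aliased with status
are dropped to restore full rank; any other aliasing is an error. Because
the nesting makes individual coefficients awkward to interpret, inference
per covariate uses Tukey's HSD on the feature values grouped by that
covariate's levels: the Tukey–Kramer statistic
$q = |\bar y_i - \bar y_j| / \sqrt{(\mathrm{MSE}/2)(1/n_i + 1/n_j)}$
against the studentized-range distribution, which controls the family-wise
error rate within each covariate family at unequal group sizes. For a
two-level family this reduces exactly to the pooled two-sample t-test
($q = |t|\sqrt2$), which the test suite verifies to $10^{-6}$, and the
general case is cross-checked against `stats::TukeyHSD`. Grouped raw
values (not covariate-residualized values) are used — the families are
descriptive screens, and grouping keeps them well defined under the
nesting. Degenerate cells are pinned: zero difference with zero residual
variance gives $p = 1$; a nonzero difference with zero residual variance
gives $p = 0$.

Cell count is continuous and has no Tukey family, so a second model
$Y_j = \beta_0 + \beta_{status}X_{status} + \beta_{count}X_{count} +
\varepsilon$ supplies a two-sided coefficient p-value; a constant feature
gets coefficient 0 and $p = 1$.

A feature joins the signature when its status comparison passes
$\alpha^* = \alpha_{base}/n$ (Bonferroni across all $n$ tested features;
$\alpha_{base} = 0.05$ by default and configurable) and none of the
exclusions fire: any significant batch pair, any significant
incubation-time pair, cell-count $p < \alpha^*$, or **two or more**
significant wild-type–wild-type clone pairs (one aberrant pair could be a
single odd clone; two independent pairs mark a feature that tracks clone
identity generically). Incubation time has two levels here, so Tukey and
the model coefficient coincide up to pooling; Tukey is used for symmetry
with the other categorical covariates. Survivors are signed by the
resistant − sensitive mean difference. Note what a Bonferroni screen does
and does not promise: the *expected* number of false admits is
$\alpha_{base}$ per run regardless of $n$, so an occasional single chance
admit among hundreds of null features is expected behaviour, not a defect.

# Scoring

The signature is applied with a single-sample rank-based score. Within a
profile of $N$ features (the full post-selection feature set — the rank
universe deliberately includes non-signature features, and $N$ is recorded
with the output), ranks are ascending with ties averaged. The up component
is the mean rank of the up set, rescaled by its attainable extremes
$\frac{n_u+1}{2}$ and $\frac{2N-n_u+1}{2}$ to $[-0.5, 0.5]$; the down
component does the same on reversed ranks $N+1-r$; their sum lies in
$[-1, 1]$, reaching the bounds exactly at full concordance/discordance.
Rank-based construction makes the score invariant to any strictly
monotone transform of the profile, hence comparable across differently
normalized datasets. The permutation null shuffles the profile's rank
vector uniformly (equivalently, permutes feature identities) with the
signature fixed — 1,000 permutations by default — and reports the
empirical 2.5/97.5 percentiles per well, plus a dataset-pooled interval;
no smoothing is applied.

# Evaluation

Score > 0 calls a well resistant (a score of exactly 0 is called
sensitive: zero concordance is no evidence of resistance). Accuracy is
meaningful because the designs are near-balanced. Average precision uses
step interpolation over thresholds at distinct scores — the
sample-averaged PR-area convention — and AUROC uses the Mann–Whitney rank
form with half-credit for ties, which equals trapezoidal integration of
the tie-grouped ROC (asserted to $10^{-9}$ in the tests). Chance level is
estimated by feature-identity shuffling: same-sized up/down sets redrawn
from the surviving pool, scores and metrics recomputed (1,000 repeats by
default); label shuffling is the obvious alternative but identity
shuffling is what the per-well permutation null already mirrors, so it is
the default throughout. Splits (training / validation / test / holdout /
transfer) are defined by clone, plate, or explicit well lists and are
enforced disjoint.

# What the synthetic generator does and does not emulate

`syntheticConfig()` defaults define the study design: 5 sensitive + 5
resistant clones × 20 replicate wells across 3 batches (one 96-well plate
per batch, wells laid out in a repeating serpentine pattern so each clone
is dispersed across rows), incubation alternating 4 h / 13 h within each
clone on a cycle independent of batch, and 40–120 cells per well. Feature
structure: 500 raw features, of which 10 shift up and 10 shift down with
resistance (Cohen's d = 1.5 at cell level), 5 each confounded with batch,
time, and cell count (shift 1.0), 5 with per-clone idiosyncratic shifts
drawn N(0, 1) — wild-type clones included, precisely to exercise the
within-wild-type exclusion — and a 20-feature block sharing a latent
factor at ρ = 0.95. The 500-feature scale is a deliberate desk-scale
choice: it preserves the qualitative shape of a real campaign (thousands
of raw features reduced to hundreds by selection, then to tens by
discovery) at a size where the whole pipeline runs in seconds per
replicate; effect sizes are tunable, not calibrated to any real dataset,
because per-feature effect sizes of resistance are not identifiable from
published summaries.

Two generator details matter for interpretation. First, every non-block
feature carries a per-well random effect (SD 0.5) on top of unit
cell-level noise — the well-to-well biological variability that does not
average away with cell number. Without it, well medians of same-direction
signature features would correlate near 1 through their shared status
shift and the correlation filter would destroy the planted signature; with
it, planted features survive selection, as a real signature spread across
weakly dependent features would. Second, the latent factor of the
correlated block has both cell- and well-level components, because the
median's nonlinearity would otherwise wash the cell-level correlation out
of the well profiles.

Artifact injection is per-feature: with probability 0.01 an inert feature
receives a whole-well displacement of 25 raw SDs (a staining failure), and
with probability 0.01 a 1% sprinkling of missing cell values (which
propagate to NA well medians and are caught by the missing rule). As noted
above, per-plate standardization compresses single-well artifacts below
the 15-SD outlier threshold, so that rule is exercised directly on
normalized-scale fixtures in the tests. The generator does not simulate
pixel-level images, segmentation error, illumination gradients, well
position effects, or batch effects richer than mean shifts — so passing
tests demonstrate correctness of the pipeline's logic and its planted-truth
recovery behaviour, not performance on real microscopy data.

# Numerical and reproducibility choices

All randomness flows from explicit seeds: the generator consumes its
config seed; scoring, permutation nulls and shuffled baselines take seed
arguments and restore the caller's RNG state; `runPipeline()` derives
documented substreams from one master seed and records them in the run
manifest together with per-stage row/feature counts, so a run is exactly
reproducible from its manifest (identical config + seed gives
byte-identical outputs). Ranking ties use average ranks; correlation-rule
ties break lexicographically; the classification boundary at 0 is pinned
to sensitive. Test-suite problem sizes (500 features × 200 wells × ~80
cells/well, 20 replicate seeds for the recovery and null studies) were
chosen to make planted-truth recovery statistically meaningful while
keeping the full suite fast enough for routine development.

# Known limitations

* The discovery screen is mass-univariate: features are tested one at a
  time, so a multivariate signature visible only jointly will be missed,
  and correlated survivors contribute redundant information to the score.
* Exclusion by significance is conservative in well-powered designs — a
  feature with a minuscule but significant batch difference is discarded
  even if its status effect is far larger.
* Per-plate z-scoring removes plate-constant biology along with technical
  offsets; with one plate per batch, batch-linked biology is
  unrecoverable by design.
* The empty-signature case refuses to score rather than returning 0,
  since a score over no features is undefined; callers must handle the
  refusal.
* Real-data performance depends on acquisition choices (staining quality,
  segmentation) entirely outside this package's scope.
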