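---
title: "Building and comparing RRBS methylation clocks"
author: "rrbsclock maintainers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Building and comparing RRBS methylation clocks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The model

A DNA-methylation clock is a linear predictor of chronological age from the
percent methylation of a fixed panel of CpG sites:

$$\widehat{\mathrm{age}} \;=\; T\!\left(\beta_0 + \sum_{i} w_i\, m_i\right),$$

where $m_i \in [0, 100]$ is percent methylation at clock site $i$, $w_i$ is
the site's weight in days per percentage point, $\beta_0$ is an intercept in
days, and $T$ is a monotone age transform — the identity for clocks trained
directly on age in days, $\exp(a\,s+b)$ for clocks trained on log age, or a
logistic calibration. `rrbsclock` treats a clock as a first-class object
(`ClockDefinition`) carried in a plain-text TSV: coordinates, weights,
intercept, transform, the training-set mean methylation of each site (used
for imputation), a minimum site-coverage fraction below which a prediction
is flagged invalid (default 0.9), and the strand policy of the methylation
values.

Weights are estimated by penalized linear regression on a cohort matrix of
untreated wild-type samples, with the quality filters standard for
multi-tissue RRBS clocks: drop samples with fewer than $2\times10^6$
covered CpGs, drop sites with $<5\times$ coverage in more than 90% of
samples, restrict to sites observed in every remaining sample, split 80/20
with tissue stratification, select the penalty by tissue-stratified 10-fold
cross-validation, refit on the full training split, and keep the
nonzero-weight sites as the clock. Both threshold rules use strict
inequalities, mirroring their usual statement ("fewer than", "more than"):
a sample with exactly $2\times10^6$ covered sites stays, and a site
under-covered in exactly 90% of samples stays.

## The penalized regression core

The solver minimizes the scikit-learn/glmnet objective

$$\frac{1}{2n}\lVert y - \beta_0 - X\beta\rVert^2
  + \lambda\left(\alpha\lVert\beta\rVert_1
  + \tfrac{1-\alpha}{2}\lVert\beta\rVert_2^2\right)$$

by cyclic coordinate descent with soft-thresholding, implemented in
compiled code with active-set cycling between full sweeps. Features are
standardized internally (population standard deviation, so
$x_j^\top x_j/n = 1$ and the update denominator is $1+\lambda(1-\alpha)$);
the response is centered; the reported model is back-transformed to the
original percent scale. The $\lambda$ grid is geometric over three decades
from $\lambda_{\max} = \max_j |x_j^\top y| / (n\alpha)$, at which the
solution is exactly zero (a $10^{-12}$ relative slack in the
soft-threshold comparison absorbs summation-order differences between the
grid construction and the solver). Convergence is declared when the largest
standardized coefficient update in a sweep falls below `tol` (default
1e-6); the per-sweep objective trace is retained so monotonicity is
testable. Cross-validation assigns folds round-robin within each tissue
after one seeded shuffle, warm-starts along the descending path, and
selects the MSE-minimizing $\lambda$ by default (a one-standard-error rule
is available).

### Why the clock-training default is pure L1

The generic elastic-net default mixes the penalties equally
($\alpha = 0.5$). For clock *training* this package deliberately defaults
to $\alpha = 1$ (pure lasso; `train_config(l1_ratio = )` exposes the
mixing). The reason is a scale effect that only shows up when the response
is age in days: with $\mathrm{sd}(y) \approx 300$ days, the penalties that
matter for site selection are of order $\lambda\alpha \approx 10$–$100$,
and at those $\lambda$ the ridge half divides every coefficient by
$1+\lambda(1-\alpha) \approx 5$–$80$. Sparse solutions are crushed toward
zero, so cross-validation finds the validation error monotone decreasing
all the way down the path and settles on a dense model in which most
selected sites are noise (on the bundled S1 preset: ~900 sites, 4% of them
truly age-informative). With $\alpha = 1$ the validation curve has an
interior minimum and the selected panel is small and overwhelmingly
informative (36 sites, 81% truly informative, on the same data). Nothing
else in the pipeline changes; users wanting the mixed penalty can set it
explicitly.

## Applying clocks

`predict_age()` makes the missing-site policy explicit rather than
implicit: impute uncovered clock sites with their stored training means
(default when available), with a flat 50%, or refuse to predict
(`strict`). Every prediction reports how many clock sites were observed
and is flagged invalid below the clock's coverage fraction; invalid
predictions are returned, not dropped, so downstream analyses choose their
own filter. ΔAge (epigenetic age acceleration) is predicted minus
chronological age; lifespan-extending interventions are expected to shift
it negative.

## The statistical battery

All p-values are two-tailed. Group comparisons of ages, absolute errors
and ΔAge use the Mann–Whitney U test: exact when both groups have at most
12 observations (the full permutation null of the rank sum is computed by
a subset-sum dynamic program over doubled midranks, so ties are exact
too), and a tie-corrected normal approximation with continuity correction
otherwise. The exact two-tailed p is
$\min(1,\, 2\min(P(W\le w), P(W\ge w)))$. Clock-versus-clock agreement is
quantified by Pearson correlation of DNAm ages and, separately, of ΔAges
(which removes the shared chronological trend — the two matrices answer
different questions). Systematic bias is tested by regressing residuals on
chronological age (slope zero for an unbiased clock; algebraically the
predicted-versus-age slope minus one). Sex-type group comparisons use a
combined OLS: the interaction term tests slope difference, the group term
of the additive model tests intercept difference. Site- and gene-level
clock overlaps use the Yates-corrected chi-square on the 2×2 membership
table over a configurable universe (the correction floors at zero).
Weight-distribution symmetry compares positive weights against absolute
negative weights with the exact/approximate MWU; variance homogeneity
across clocks uses Bartlett's statistic in closed form. No multiplicity
correction is applied by default (raw p-values are reported, matching
field practice); Benjamini–Hochberg columns are optional.

Genomic context follows the standard partition: island (inside a merged
island interval), shore (within 2 kb of an edge, inclusive), shelf (2–4
kb), open sea (beyond 4 kb, or on a contig without annotation, with a
warning). BED input is 0-based half-open and converted at the boundary;
all internal coordinates are 1-based inclusive, matching bismark coverage
output and genome-browser style clock coordinates. Strand-resolved input
can be merged onto forward-strand dinucleotide anchors (reverse-strand
counts at $p+1$ added to $p$), conserving read counts exactly.

## The synthetic cohort generator

`simulate_cohort()` produces the world the clock machinery assumes, so the
whole pipeline is testable without external downloads:

- **Ages** uniform over 7–1050 days (one week to 35 months — a whole mouse
  lifespan), default 200 samples across four tissues.
- **Baselines** $m_0 \sim 100\cdot\mathrm{Beta}(0.4, 0.4)$, the bimodal
  hypo/hyper-methylated landscape of real methylomes.
- **Informative sites** (default 40 of 2000) drift linearly at
  0.015–0.04 percentage points per day — a 15–40 point change across the
  lifespan — signed toward 50% methylation, emulating the drift toward
  intermediate methylation states reported for aging methylomes;
  trajectories are clipped to [0, 100].
- **Tissue offsets** (sd 4 points on a random 20% of sites) and **batch
  offsets** (2 batches, sd 2 points genome-wide) on the mean scale.
- **Reads**: depth negative-binomial (mean 30, size 5), methylated reads
  binomial(depth, $m/100$), so observed percent methylation carries
  realistic beta-binomial-style noise (~9 points sd at 50% methylation and
  30× depth).
- **Missingness**: cells with sampled depth 0 are unobserved, and a
  *site-structured* dropout removes further cells. The marginal dropout
  rate is the configured `dropout_prob` (default 5%), but it is
  concentrated on a "variably covered" 10% of sites. This is deliberate:
  independent per-cell dropout at 5% would leave essentially *no* site
  observed in all 200 samples ($0.95^{200}\approx 3\times10^{-5}$),
  contradicting the defining feature of real RRBS cohorts — a stable
  common core (hundreds of thousands of sites shared by hundreds of
  samples) plus sample-specific missingness. The structured form
  reproduces both phenomena with the same marginal rate.

What a green test on this generator establishes: that the filters,
splitter, solver, selection rule and statistics do what they claim on data
with the assumed structure (linear drift, binomial noise, modest tissue
and batch shifts). What it does not establish: performance on real RRBS
corpora, whose batch effects are larger and confounded with tissue and
study, whose informative sites are far more numerous and weaker, and whose
age distribution is strongly skewed. The published real-data error rates
are therefore not reproduced or asserted anywhere in the package.

## Numerical and design choices

- Counts are authoritative over the percent column when reading coverage
  files; discrepancies beyond 0.5 points warn (upstream emitters round).
- "Covered" for the sample filter means depth ≥ 1 by default (the depth is
  configurable; the originating analysis does not state one).
- The stratified splitter assigns `round(n · test_fraction)` samples per
  tissue to the test set; remainders train; a one-sample tissue trains
  with a warning. One seeded generator drives everything, and resample
  $i$ of the robustness study uses `base_seed + i` so any single resample
  is reproducible in isolation.
- "Wilcoxon test" for robustness enrichment is read as the unpaired
  two-sample rank-sum test (the groups — shared versus non-shared clock
  sites — are unpaired).
- The exact-MWU group-size threshold (12) keeps the exact null cheap
  (worst case a few hundred thousand DP cells); it is configurable.
- Zero-variance features receive coefficient zero with a warning rather
  than an error: fully methylated/unmethylated sites are real data, not
  user error.
- PCA-based outlier flagging (beyond $k$ MADs on the first two principal
  components) is provided but off by default, as an algorithmic stand-in
  for figure-based batch exclusions that cannot be reproduced exactly.
- The pipeline's config files use a flat `key: value` dialect (a YAML
  subset) parsed in-package, keeping the runtime dependency set to
  packages guaranteed present.

## Known limitations

- The solver stores dense matrices; it is comfortable to ~$10^5$ sites ×
  hundreds of samples on a laptop but is not engineered for $10^6$-site
  whole-genome panels.
- Exact MWU beyond group sizes ~150 becomes slow; the normal
  approximation takes over well before that by default.
- Normalization of new samples onto a clock's original training
  distribution (required by some published clocks) is out of scope; such
  clocks should be applied through their own pipelines.
- The generator does not emulate read-level artifacts (bisulfite
  conversion failure, PCR duplicates) or genuinely confounded
  batch/tissue structure.
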