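---
title: "Regulated KS enrichment: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Regulated KS enrichment: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

# Overview

`regks` implements a complete analysis chain for factorial microarray
time-course studies of the kind used to profile hypoxic-seizure
epileptogenesis in neonatal rat brain: a baseline (noHS) arm, a
hypoxic-seizure (HS) arm and an HS arm followed by NBQX treatment, each
sampled in hippocampus and cortex at 1, 6, 12, 48 and 168 h with 4–6
replicates per cell. The chain runs from probeset-level intensities with
present/absent calls through normalization, gene collapse, ANOVA response
sets, a sign-aware ("regulated") Kolmogorov–Smirnov gene-set enrichment
statistic, and nested post-processing. A synthetic-study generator with
planted ground truth makes every stage testable without any external data.

# The regulated KS statistic

A signed gene set names $k_u$ positive regulatees (genes a pathway
up-regulates) and $k_d$ negative regulatees, $k = k_u + k_d \ge 1$. Given
a profile of $n$ expression values (typically log2 ratios of treatment to
time-matched control), values are converted to ranks, rank 1 for the
largest value. For each regulatee group the empirical CDF of its ranks is
compared with the discrete-uniform population CDF, and the signed
deviation at the point of maximum absolute deviation is retained:
$d_u$ and $d_d$, signed analogues of the usual KS statistic $|d|$.
Deviations are evaluated at every member rank *and* at the grid point just
below it — both sides of every step — which is the conservative reading of
the KS convention and makes the statistic exactly reproducible by
brute-force enumeration over the rank grid.

The two groups combine into a single bounded statistic

$$
d_{UpDown} = \frac{k_u\, d_u - k_d\, d_d}{k_u + k_d},
$$

positive when regulation is coherent (up-regulatees ranked high,
down-regulatees low). This is the unique membership-proportional linear
combination with the three properties the statistic is designed around: a
fixed scale $-1 \le d_{UpDown} \le 1$, continuous behaviour as $k_u \to 0$
or $k_d \to 0$ (reducing to $-d_d$ and $d_u$ respectively), and weighting
of each group in proportion to its size, so a small noisy group cannot
overwhelm a larger coherent one. The test suite verifies all three by
exhaustive enumeration of regulatee placements on small universes.

**P-values** are one-sided Monte-Carlo permutation probabilities: $k_u$
and $k_d$ genes are redrawn without replacement from the universe and
$P = \Pr(d^{perm}_{UpDown} \ge d^{obs}_{UpDown})$. We permute set
membership rather than the profile, which matches the null hypothesis of
random incidence of regulatees in a fixed profile. A reported 0 means "below
the resolution floor $1/n_{perm}$", which is attached as an attribute. The
default for single-set calls is $n_{perm} = 10^5$, matching a reporting
floor of $10^{-5}$; collection screening defaults to $10^4$ per null shape
(null distributions depend only on $(k_u, k_d, n)$ and are cached per
shape). The permutation loop is in C++ and uses R's RNG, so `set.seed()`
governs it. An analytic P-value would require the exact null of the
combined statistic, which has no convenient closed form at finite $n$;
Monte-Carlo with a cached per-shape null is exact in the limit and
verifiable against full enumeration at small $n$, which the suite does.

**Enrichment scores.** `c_left` is the chord slope of the up-regulatee CDF
from the origin to its maximum-deviation point, $F_u(x^*)/x^*$; `c_right`
is the mirrored chord for down-regulatees, $(1-F_d(x^*))/(1-x^*)$. A
uniformly scattered group scores about 1, an empty group exactly 1 (the
neutral value), and "all $k$ members in the top $k$ ranks of $n$" scores
$n/k$. Chord slopes were chosen over local slopes because the chord is
well-defined at every step function and degrades gracefully; a degenerate
argmax at 0 or 1 falls back to the adjacent step with a flag.

**Leading edges** are the up-regulatees ranked at or above the up-group's
maximum-deviation point and the down-regulatees at or below the
down-group's — the genes actually driving the enrichment. They are always
subsets of the respective regulatee lists.

**Screening a collection** scores every set, adjusts P-values to FDRs with
Benjamini–Hochberg *within each source collection separately*, and selects
sets with `fdr < 0.25` and `max(c_left, c_right) >= 2`. Ranks break ties
deterministically by (value descending, gene name ascending): reproducibility
was preferred over midranks, which would break the integer-rank grid that
the enumeration oracle (and the step-side evaluation) relies on.

# Differential expression

**Response sets** come from per-tissue two-way ANOVA on log2 probeset
intensities, `value ~ treatment * time`, selecting on the treatment-effect
P-value and then mapping probesets to gene symbols. With jittered
replicate counts the design is unbalanced, so Type II sums of squares are
used (each main effect adjusted for the other; invariant to cell-size
imbalance under the no-interaction null). The implementation projects all
features through shared QR decompositions at once; it is checked against
`car::Anova(type = 2)` and a balanced textbook oracle. Thresholds are
config-driven: FDR 0.25 for the HS arm in both tissues; for the NBQX arm
the defaults are FDR 0.25 in hippocampus and raw P 0.01 in cortex,
mirroring the original per-tissue choices. The epileptogenic set is the
union over tissues of (HS selection ∩ NBQX selection), with provenance
kept per gene.

**Expression ratios** use a robust Bayesian point estimate: the observed
log2 ratio of condition means, with delta-method measurement noise
$\tau$, is combined with a zero-centred Gaussian prior (scale 1 log2
unit) on the true log2 ratio, giving the posterior median
$m\,\sigma_0^2/(\sigma_0^2+\tau^2)$. The estimate shrinks toward a ratio
of 1 as noise grows and never overshoots the plain ratio of means; it is
antisymmetric under swapping conditions. A strictly flat prior cannot
shrink (it returns the MLE), so a weak proper prior is the design choice
that realizes "variance-driven shrinkage toward 1"; the scale of 1 log2
unit says a priori that 2-fold changes are typical, which suits
moderate-effect microarray data. P-values are classical equal-variance
pooled t-tests — computed on log2 intensities inside `ratio_profile()`,
where replicate noise is close to Gaussian; the means-level fallback in
`estimate_ratio()` tests on the scale of its inputs. When a gene has
several probesets the (ratio, P) pair with the smallest P is reported for
the gene (the min-P rule); intensities collapse to genes by the
per-cell maximum instead.

**Overlap significance** between per-tissue selections uses the
hypergeometric null: mean $n_1 n_2/N$, the classical SD, and a stable
log-space upper tail. For the published set sizes (1,049 and 969 in a
14,405-gene universe) the expectation rounds to 71 ± 8, and an observed
overlap of 619 sits far below the $10^{-9}$ bound; the acceptance script
recomputes both.

# Preprocessing

QC summarises each chip by its number of present calls and the 75th
percentile of present-call intensities (marginal calls count as absent —
the conservative choice, since only present calls are trusted).
Percentiles interpolate linearly between order statistics (the type-7
convention; documented because percentile conventions differ).
Normalization rescales each chip so its present-call 75th percentile hits
a common target; the target is the *median* of the per-chip percentiles,
which is scale-stable, reduces to the identity for one chip, and makes
renormalization idempotent. Outlier screening uses robust z-scores
(median/MAD, threshold 6) on the two QC statistics, and a tissue-swap
check comparing each sample's correlation with its own tissue's
leave-one-out centroid against the other tissue's centroid.

Standardization is per-gene z-scoring of log2 intensities with the n−1
standard deviation; zero-variance genes standardize to zero with a warning
rather than erroring, which keeps degenerate synthetic fixtures usable.
The unsupervised variation filter is the plain sum of squared deviations
of log2 intensity about the gene mean, $S^2 = \sum_j (y_{gj}-\bar y_g)^2$
— the minimal reading of a "sum-of-squares statistic", large for genes
with many moderate or a few large deviations — with the top 1,000 genes
kept by default. Display clustering is seeded k-means with
average-linkage ordering inside and across clusters; only memberships and
the display order are contractual, not any particular self-organizing-map
internals, which the original platform used but which add nothing
testable to the ordering contract.

# The synthetic generator

`sim_config()` defaults describe the strong-signal study the package is
validated on: 2,000 genes measured by 1–3 probesets (probesets share the
gene signal plus independent probe noise and a fixed probe offset, so
both collapse rules are exercised), the full 2 × 3 × 5 factorial with 4–6
replicates per cell, log2-additive Gaussian noise (sd 0.5 gene-level,
0.25 probe-level) — the simplest model consistent with downstream
z-scoring and equal-variance t-tests. Planted structure: 15% + 15%
developmental genes drifting ±2 log2 units across the time course, 10%
HS-responsive genes (2:1 up:down) with effect 1.5 log2 units scaled by
temporal weights (0.6, 0.8, 1.0, 0.5, 0.3) peaking at 12 h, 30% of HS
genes NBQX-responsive (effect 1, 70% shifted further up), and 10%
tissue-specific genes (±2 log2 units) — the last added so the tissue-swap
QC check is observable, mirroring the tissue-specific clusters real
hippocampus/cortex data shows. Absent calls thin with decreasing log2
intensity through a logistic with midpoint 5; 1% of present calls become
marginal. Gene sets: 100 sets of 10–40 members, 20 truly enriched at
regulatee purity 0.9, null sets drawn uniformly (mostly up-only, as in
typical curated collections). Seizure phenotypes are exponential latency
(mean 114 s) and truncated-rounded Gaussian counts (mean 10.6, sd 2.9).
No effect-size scale for the HS response is prescribed by the biology
beyond "moderate fold changes"; 1.5 log2 units at the peak with sd 0.5
noise and 4–6 replicates is a realistic moderate-effect regime in which
a well-implemented pipeline should recover nearly all planted genes, and
the recovery criteria are stated against exactly this configuration.

What the generator does *not* emulate: probe-level (PM/MM) structure,
spatial chip artifacts, heavy-tailed or intensity-dependent noise,
correlated gene modules beyond the planted sets, and batch effects.
Passing tests therefore demonstrate correctness of the algorithms under
the stated statistical model, not robustness to every artifact of real
chips.

# Numerical choices and degenerate inputs

* Intensities are strictly positive and stored linear-scale; log2 happens
  inside computations, never at I/O.
* Permutation P comparisons use a $10^{-12}$ slack so float noise cannot
  flip a tie; ANOVA sums of squares are clamped at 0 and constant rows
  get P = 1 with a degeneracy flag.
* `combn()`-style enumeration always indexes positions, avoiding the
  length-1 scalar pitfall.
* Problem sizes in the shipped tests and acceptance script (2,000-gene
  studies, 100-set collections, $10^3$–$10^4$ permutations per shape,
  500-case oracle sweeps) were chosen so the whole suite completes in
  about a minute while keeping every Monte-Carlo tolerance at 3 standard
  errors or better.

# Known limitations

* The Monte-Carlo P floor (1/n_perm) limits FDR resolution for very small
  P; raise `n_perm` for publication-grade tables.
* Type II ANOVA is the right default for jittered replicate counts but
  not for structurally missing cells; `two_way_anova()` requires at least
  one replicated cell and errors without residual degrees of freedom.
* The shrinkage ratio estimator is a documented stand-alone contract
  (lognormal measurement model, weak Gaussian prior, posterior median);
  it is not numerically identical to any external fold-change estimator.
* `flag_outliers()` needs a genuine tissue contrast to detect swaps; on
  studies with no tissue-specific expression the check is powerless (it
  then simply flags nothing).
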