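---
title: "Methods: synthetic-lethal discovery from pooled CRISPR screens"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: synthetic-lethal discovery from pooled CRISPR screens}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crisprsl)
```

## The analysis problem

A pooled CRISPR knockout dropout screen infects a cell population with a
genome-scale sgRNA library and tracks each construct's relative abundance
by sequencing at successive timepoints. Constructs targeting genes the
cells need deplete over time. When the goal is a *genotype-specific*
synthetic-lethal gene — one required only in cells carrying a particular
oncogenic mutation, such as *GNAQ/GNA11*-mutant uveal melanoma — the raw
dropout list is mostly noise of the wrong kind: pan-essential genes
(ribosome, proteasome, replication) and lineage-essential genes deplete in
every screen of that lineage. The pipeline in this package reproduces the
integrative strategy of screening several mutant lines, intersecting their
hits, and then *excluding* everything that external dependency panels or a
lineage-matched expression comparison can explain without invoking the
genotype.

## Pipeline stages and their assumptions

### TMM normalization and fold-change scoring

Sequencing depth varies between samples and the sequenced pool is
compositional, so counts are normalized with trimmed-mean-of-M-values
(TMM) factors before fold changes are taken. The reference sample is the
one whose 75th-percentile count fraction is closest to the mean of those
percentiles. For sample $k$ against reference $r$, over sgRNAs nonzero in
both:

$$M_s = \log_2\frac{y_{sk}/N_k}{y_{sr}/N_r},\qquad
  A_s = \tfrac12 \log_2\!\Big(\frac{y_{sk}}{N_k}\cdot\frac{y_{sr}}{N_r}\Big),\qquad
  v_s = \frac{N_k-y_{sk}}{N_k\,y_{sk}} + \frac{N_r-y_{sr}}{N_r\,y_{sr}}$$

After dropping the top and bottom 30% by $M$-rank and 5% by $A$-rank, the
log2 factor is the precision-weighted mean $\sum (M_s/v_s)/\sum(1/v_s)$,
and factors are rescaled to geometric mean 1. The unit test suite checks
this against both a straight-line hand evaluation and the `edgeR`
implementation. One behavior is worth stating explicitly: the
inverse-variance weights depend on *absolute* depth, so rescaling one
sample's counts leaves the fold-change arithmetic exactly unchanged but
can move the factors marginally (the tests bound this at 0.02). The
minimum-survivor guard after trimming is `min(10, nominal post-trim
retention)`: ten constructs for real libraries, relaxed on toy-sized ones
where a 30% double trim cannot leave ten.

sgRNA fold change is `log2(cpm_t + q) − log2(cpm_0 + q)` with
`cpm = 1e6 · y / effective_size` and pseudocount `q = 0.5` CPM —
equivalent to half a count at a one-million effective size. Placing the
pseudocount on the CPM scale keeps zero-count sgRNAs finite *and* makes
fold changes exactly invariant to sample rescaling, which a count-scale
pseudocount cannot be. Replicates are averaged at the logFC level (each
later-day replicate against the mean baseline log2 CPM of its cell line),
keeping per-replicate normalization meaningful; pooling counts across
replicates would not. The baseline is the earliest sampled day (default
day 4, i.e. the first post-selection measurement, not the plasmid pool);
`baseline_day` is a config knob. The gene summary is the median over the
gene's constructs — robust to a single inefficient sgRNA — with the mean
available via `gene_summary = "mean"`.

### The RSA depletion statistic

Ranks are assigned ascending by logFC (rank 1 = most depleted), with tied
constructs all taking the *worst* rank of their block, so ties cannot
borrow significance. For a gene with sorted ranks $r_1 \le \dots \le r_n$
among $N$ constructs,

$$p = \min_{i \in 1..n} P(X \ge i), \qquad X \sim \mathrm{Hypergeom}(N, n, r_i),$$

the best tail over all prefixes of the gene's constructs. Binomial
coefficients are evaluated through `lgamma` differences so the tail is
stable for libraries beyond $10^5$ constructs; the kernel is verified
against exhaustive enumeration over all $\binom{N}{n}$ placements for
every configuration with $N \le 15$, $n \le 4$, and against `phyper`.
Scoring is one-sided for dropout only; enrichment is out of scope.

**Measured null calibration.** Each individual tail $P(X \ge i)$ is, under
a uniform permutation of ranks, exactly the CDF of the $i$-th order
statistic — marginally uniform. The minimum over $n$ such (positively
correlated) uniforms is therefore anticonservative: $P(p \le \alpha)$ lies
between $\alpha$ and $n\alpha$. The calibration test in this package
measures the exceedance fraction at $N = 1000$, 200 genes × 5 constructs,
2,000 permutations: about $3.9\alpha$ at $\alpha = 0.01$ and $3.3\alpha$
at $\alpha = 0.05$. This is a property of the statistic's standard
definition (no internal correction for the minimum), not of this
implementation — exact enumeration at small $N$ and an independent
`phyper`-based reimplementation reproduce it. Downstream, the adjusted
values are used as a ranking-and-threshold device on top of an
intersection-plus-exclusion design, as is standard practice for this
statistic; users needing calibrated gene-level p-values should apply a
permutation null.

### Cross-fitted covariate weighting ("IHW-lite")

Genes with higher baseline read abundance give better-powered depletion
tests, and baseline abundance is independent of the p-value under the
null, which makes it a valid weighting covariate. The default covariate is
the per-gene mean baseline log2 CPM of its constructs. Hypotheses are
split into `G = 5` covariate quantile bins and `K = 5` folds stratified by
bin; for each fold, per-bin weights are learned on the other folds as
$w_g \propto \max(1-\hat\pi_{0,g},\ 0.05)$, with $\hat\pi_{0,g}$ the
tail-census estimator $\min(1, \#\{p>\lambda\}/((1-\lambda)m))$ at
$\lambda = 0.5$, then normalized to mean 1 over the held-out fold.
Weighted BH applies plain BH to $p_i/w_i$ (zero weight ⇒ adjusted value
1). Because each hypothesis's weight is learned without its own p-value,
the usual BH FDR argument carries over; the test suite verifies empirical
FDR control on 500 pure-null simulations at $m = 5000$. The 0.05 weight
floor prevents empty-looking bins from extinguishing hypotheses outright.
This plug-in scheme deliberately replaces the published convex-optimization
weight learning: it is deterministic, dependency-free, and preserves the
cross-fitting argument. Fold assignment is keyed by sorted hypothesis
names, so results are invariant to input order when names are supplied;
below `10·G·K` hypotheses the procedure falls back to plain BH with a
warning.

### The exclusion cascade

Per screen and day, a gene is a hit iff gene-summary `logFC ≤ −0.5`
(boundary inclusive) **and** adjusted `P < 0.01` (strict). Candidates at a
day are hits in *all* screens minus the union of:

- **pan-essential**: median dependency score across all annotated cell
  lines `< −0.4` in *any* of the three dependency panels. The median (not
  "any line") is the aggregator — per-line "any" would exclude nearly
  every gene; `pan_aggregate` exposes mean and fraction-below
  alternatives. A missing value is dropped from the median, and a gene
  absent from a panel cannot be excluded by that panel (absence of
  evidence is not evidence), though it is flagged in the validation
  report.
- **published scalar scores**: priority score or cell-line dependency
  score `> 0.4` (strict); one missing field falls through to the other.
- **lineage**: median over cutaneous-melanoma panel lines `< −0.5`, or
  *any* wild-type UM control line `< −0.5`. The lineage step reads the
  first (CRISPR) dependency panel by default.

Exclusion tags are computed for every step regardless of order, so
`excluded_by` is complete provenance. Robust hits are candidates at both
day 14 and day 21; late hits at day 21 only. Relaxing any threshold can
only grow the final set (tested).

### Expression signature

Per gene, the 5th/95th percentiles (linear-interpolation quantiles, R type
7) of TPM over **all pooled non-target samples** bound the target-type
median: strictly above the 95th ⇒ high, strictly below the 5th ⇒ low. The
pooled-samples reading is the default; percentiles over per-tumor-type
medians are available via `pool = "type_medians"`. The lineage z rule then
computes per-lineage medians of `log2(TPM+1)` — the log scale prevents one
high-TPM lineage from dominating the standard deviation — z-scores them
across lineages, and keeps a high call only when
`z_target − z_comparator ≥ 0.5` (signed, direction-matched; the absolute
variant is a flag). Zero variance across lineage medians removes the call
with an explicit tag. Signature membership reorders the hit table: robust
before late, signature members first within class, then ascending best
adjusted p.

## What the synthetic study emulates — and what it does not

The generator plants four gene classes with known identity. Per sgRNA
`s` of gene `g`, latent abundance is
`a_s · 2^(−u_s · d_{g,l} · (day − day0))` with `a_s ~ logNormal(0,1)`
(library skew), efficacy `u_s ~ Beta(5,1)` fixed per construct, and class-
and line-specific depletion rate `d` in log2 units/day. Abundances are
renormalized each day (closed population: sequencing is compositional —
neutral genes drift slightly positive as essentials drop out, and tests
tolerate that), scaled to the target depth, and counts drawn
negative-binomially. Defaults, chosen once as the study conditions:

| parameter | default | rationale |
|---|---|---|
| genes × sgRNAs | 2,000 × 5 | desk-scale stand-in for a genome-scale library |
| planted classes | 60 pan / 40 lineage / 40 SL | a few percent of the library each |
| days | 4, 14, 21 | early baseline plus two scoring timepoints |
| depth | 500 reads/sgRNA | representation-scale coverage |
| NB dispersion | 0.05 | typical overdispersion of sequenced pools |
| d (pan / lineage / SL) | 0.15 / 0.12 / 0.12 log2/day | ≈2.5 and 2 log2 units of depletion by day 21 at full efficacy |
| dependency score | −k·d + N(0, 0.05), k = 1/d_pan | pan-essentials center at −1.0, neutral at 0 |
| scalar scores | N(0.6, 0.1) pan, N(0.05, 0.1) otherwise | pan-essentials sit above the 0.4 cutoff |
| expression | log2(TPM+1) ~ N(m_g, 0.5), shift ±3 | clearly separated planted signature genes |

Each artifact (truth, counts, panels, expression) draws from its own RNG
stream at a fixed offset from the master seed, so components are
reproducible independently.

Not modeled: sgRNA off-target effects, copy-number artifacts, clonal
outgrowth, infection bottlenecks, replicate-level batch effects (the
default is one replicate with NB noise only), gene-length or GC biases in
expression, and real DepMap/TCGA data idiosyncrasies (score
miscalibration between RNAi and CRISPR panels, missing-value structure).
Passing recovery tests therefore demonstrates that the cascade's logic and
thresholds do what they claim under controlled noise — not that the
thresholds are optimal for any particular real dataset, and not a
reproduction of any published screen's specific gene lists (those require
the original counts and versioned external downloads).

## Numerical choices and degenerate inputs

- Hypergeometric tails: log-gamma binomial coefficients; terms summed over
  the support with out-of-support terms exactly zero via `lchoose`;
  results clipped to [0, 1].
- TMM: trim ranks use `ties.method = "first"` for determinism; a sample
  identical to (or an exact scaling of) the reference gets factor 1
  through an `|M| < 1e-9` short-circuit before trimming.
- Quantile definition everywhere: R's default type 7 (linear
  interpolation), which is what the 5th/95th percentile calls and the TMM
  reference selection use.
- Gene symbols are matched case-sensitively after whitespace stripping; no
  alias resolution — the synthetic study controls its own namespace.
- Empty exclusion sets, empty signatures, absent expression input, and
  all-null simulations are all exercised by tests; the pipeline completes
  and reports zeros rather than erroring.
- Validation failures that would corrupt results (missing baseline-day
  sample, unannotated sample or cell line, negative or non-integer count,
  duplicate identifiers) are fatal and name the offending record.

## Problem sizes used by the shipped validation

The replicated recovery study runs 5 simulations of the default 2,000-gene
study; RSA enumeration covers all configurations with N ≤ 15, n ≤ 4; null
calibration uses 2,000 permutations of 1,000 construct ranks; FDR control
uses 500 pure-null simulations at m = 5,000. These sizes give Monte-Carlo
standard errors comfortably below the margins being tested while keeping
the full suite fast on a single CPU.

## Known limitations

- The RSA minimum-tail statistic is anticonservative under the null by
  roughly a factor of the construct count (measured above); it is treated
  as a ranking statistic feeding a threshold-and-exclusion design, not as
  a calibrated p-value.
- The IHW-lite weight learning is a plug-in scheme; it forgoes some power
  of the published convex formulation in exchange for determinism and
  simplicity.
- Dependency panels are assumed to share gene symbols with the screen
  library; no identifier mapping is attempted.
- The Score-project "cell line dependency score" is modeled as a per-gene
  scalar; a per-(gene, line) matrix variant would need a different input
  shape.
- Which panel the lineage medians should be computed from is not uniquely
  determined by the design; the first (CRISPR) panel is the default and
  the choice is configurable.
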