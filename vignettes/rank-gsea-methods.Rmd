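---
title: "Rank-based gene-set scoring and robust rank aggregation: models and choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Rank-based gene-set scoring and robust rank aggregation: models and choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rankgsea)
```

## The problem

Given a clustered single-cell expression matrix and a collection of gene
sets (signatures), we want one defensible significance call per gene set
and cluster: *is this biological program enriched in this cluster?* Any
single scoring method answers this with its own biases; a plain
intersection of several methods' calls is overly conservative and throws
away the information in how strongly each method ranks each set. This
package scores every cell with six methods that depend only on the
*within-cell ordering* of expression values, tests each set per cluster,
and aggregates the per-method rankings into a single order-statistic
p-value per set.

Because every score is a function of within-cell ranks alone, two
properties hold by construction and are enforced by tests:

* **monotone invariance** — any strictly increasing per-cell transform
  (log-normalisation, scaling) leaves all scores unchanged, so raw and
  normalised counts give identical results;
* **composition independence** — a cell's score does not change when other
  cells are added, removed or reordered (with one caveat for the
  JASMINE-style score, below).

## Within-cell ranking

All methods consume a shared per-cell ranking (`rank_cell()`). Ties are
resolved by mid-ranks (`average`) by default: it is deterministic and the
convention under which Mann–Whitney-type statistics are usually defined.
`min`, `dense` and seeded `random` tie-breaking are available; `random`
reproduces the behaviour of tools that permute tied genes, and derives its
permutation deterministically from the seed and the cell identifier, so
results are reproducible and independent of cell order. Zeros (dropouts)
are not dropped: they form one tie group at the least-expressed end. An
all-zero cell therefore gets all-tied ranks and well-defined, near-null
scores rather than an error.

## The six scores

With $n$ genes in the matrix, a set $S$ of size $n_s$, and per-cell
descending ranks $r_g$ (1 = most expressed):

* **AUCell-style** — recovery-curve area in the top
  $L = \lceil 0.05\,n \rceil$ ranks, normalised by its maximum attainable
  value: $\mathrm{score} = \sum_{x=1}^{L} H(x) \big/ \sum_{x=1}^{L}
  \min(x, n_s)$, where $H(x)$ counts set members with rank $\le x$. The
  normalisation pins the score to $[0,1]$ with 1 meaning the set packs the
  top of the cell's ranking — the classic description only fixes "area
  under the recovery curve", so the scale is a package choice.
* **UCell-style** — ranks capped at $r_{\max}+1$ ($r_{\max}=1500$ by
  default) to blunt the uninformative tail, then the Mann–Whitney U
  against the best packing: $U = \sum_{g \in S}\min(r_g, r_{\max}+1) -
  n_s(n_s+1)/2$, $\mathrm{score} = 1 - U/(n_s r_{\max})$, clamped at 0
  (the clamp can bind only when $n_s$ approaches $r_{\max}$).
* **singscore-style** — mean ascending rank of the set, rescaled between
  its theoretical minimum $(n_s+1)/2$ and maximum $(2n-n_s+1)/2$.
* **ssGSEA-style** — genes ordered by decreasing expression; position $i$
  carries weight $(n-i+1)^{\alpha}$ with $\alpha = 0.25$; the score is the
  *sum* over positions of the gap between the weighted in-set empirical
  CDF and the uniform out-of-set CDF (the integral form used for
  single-sample scoring). The usual final normalisation by the
  across-cells score range is deliberately omitted: that step is the one
  part of the classic definition that couples cells together, and dropping
  it restores composition independence.
* **JASMINE-style** — dropout-aware: among expressed (nonzero) genes, the
  mean descending rank of expressed set members divided by the number of
  expressed genes gives the mean component (0.5 when no member is
  expressed); a 2×2 table of set membership versus expression gives an
  odds-ratio enrichment component (Haldane +0.5 on all four cells whenever
  a zero appears, so it stays finite; a likelihood-ratio variant is
  available). $1-\mathrm{RM}$ and the enrichment component are min–max
  scaled across cells and averaged.
* **Viper-style** — ascending ranks mapped to interior quantiles
  $q = (\mathrm{rank} - 0.5)/n$ and through $\Phi^{-1}$; the reported
  score is $\mathrm{NES} = \sqrt{n_s}\,\overline{\Phi^{-1}(q)}$, which is
  approximately standard normal under within-cell noise. Ranks are taken
  *within* each cell. The phrase "across cells" appears in descriptions of
  the original regulon method, but cross-cell ranking would contradict the
  composition-independence property that motivates this family, so the
  within-cell reading is implemented. With unsigned gene sets (all modes
  +1, weight 1) the three-tailed regulon combination degenerates to this
  two-tail term; signed regulons are out of scope.

The JASMINE caveat: its min–max scaling makes the *final* score depend on
the cell cohort. The unscaled components are per-cell quantities, are
returned in `$components`, and are what the composition-independence tests
check for this method.

## Differential testing

For each method and cluster, each set's per-cell scores in the cluster are
compared against all other cells (one-vs-rest) with the two-sided Wilcoxon
rank-sum test; p-values are Bonferroni-multiplied by the number of sets
tested within each (method, cluster), mirroring per-cluster marker
testing, and called significant at adjusted $p \le 0.05$. No
minimum-effect-size prefilter is applied. `mode = "auto"` uses the exact
null when the pooled size is ≤ 25 and tie-free, else the tie- and
continuity-corrected normal approximation. A note on accuracy: the normal
approximation deviates from the exact p by up to ≈ 0.09 at the smallest
sizes (≈ 0.036 once the pooled size reaches 12) — figures obtained by
exhaustive enumeration — so the exact mode is preferred whenever
available. All-tied input carries no information and returns $p = 1$
exactly.

One-vs-rest has a visible consequence on synthetic data: a set planted
"up" in cluster A is genuinely *down* in clusters B and C (their "rest"
includes A), so mirror down-calls in non-target clusters are true
positives of the contrast, not artefacts.

## Robust rank aggregation

Per cluster and direction, each method contributes its significant sets
ordered by p-value (ties: larger $|$effect$|$ first, then name). For set
$i$ and method $j$ the normalised rank is $r_{ij} = R_{ij}/N$; the sorted
vector $r_{(1)} \le \dots \le r_{(k)}$ is compared with uniform order
statistics through the binomial upper tail
$\beta_{x,k} = \sum_{\ell=x}^{k} \binom{k}{\ell} r_{(x)}^{\ell}
(1-r_{(x)})^{k-\ell}$, the score is $\rho = \min_x \beta_x$, and the
reported p-value is $\min(1, k\rho)$ (Bonferroni over the $k$ order
statistics). Methods with no significant sets still count toward $k$;
sets a method does not list are imputed at the bottom ($r = 1$), the
conservative reading of "not significant for that method".

**Choice of the denominator $N$.** Two readings exist and both are
implemented (`dialect` argument; the choice is recorded in the output
header):

* `union` (default): $N$ is the number of sets *tested*. The order
  statistic's null is then "where does this set fall among everything the
  method could have ranked", which is what makes a set top-ranked by all
  methods highly significant. Normalising instead by the size of the union
  of *significant* sets degenerates: a set that is the only significant
  one would get $r = 1$ and $p = 1$ precisely when the evidence is
  unanimous, so that variant is not offered.
* `paper`: the literal per-set reading of the published equation —
  absences imputed as rank $N$, then each set's ranks divided by that
  set's largest rank across methods. Read this way, the worst-ranked
  method's $r$ is forced to 1 for every set, and a set ranked first by
  *every* method has denominator 1, $r \equiv 1$, $p = 1$: unanimously
  top-ranked sets can never be called. The dialect is kept for
  transparency, with this caveat; on data where methods disagree enough,
  its calls can coincide with the union dialect's, but on strong planted
  signal they provably do not.

The Bonferroni factor is $k$ (the number of methods), matching a
correction applied to the minimum of $k$ β-values; an additional
across-sets correction is deliberately not applied by default.

## Concordance between methods

Kendall's coefficient of concordance quantifies method agreement. The
construction here: for each pair of methods and each gene set, the two
per-cell score vectors are treated as two raters ranking the cells and
the tie-corrected two-rater $W \in [0,1]$ is computed; pairs are
summarised by the median over sets, and the report carries an overall
median. A between-method concordance can be built several ways (over
cells per set, over sets per cell, or on cluster summaries), so this is
one documented reading; for two raters without ties,
$W = (1+\rho_{\mathrm{Spearman}})/2$, giving 0.5 as the null reference.

## The synthetic generator

`simulate_sc()` emulates the demo use case every test runs against:
clustered PBMC-like counts scored against a hallmark-sized collection.
Defaults — 2000 genes, 3 clusters × 200 cells, 20 mutually disjoint
30-gene sets, 3 planted, fold change 4 — are the package's fixed study
conditions, chosen as a small but realistic cartoon of a few-thousand-cell
10x experiment: log-normal baseline means (meanlog 0.5, sdlog 1) give a
median expression around 1–2 counts with a long right tail, and
negative-binomial sampling with $\mathrm{var} = \mu + 0.3\mu^2$ produces
realistic overdispersion and a dropout fraction that rises as means fall,
without a separate zero-inflation layer. Planting multiplies the member
genes' means by the fold change in the target cluster only (round-robin
assignment, direction up; fold < 1 would plant down-regulation).

What the generator does *not* emulate — library-size variation, batch
effects, correlated gene modules, real marker structure, doublets —
bounds what passing tests show: they demonstrate correctness of the
statistics and recovery under idealised NB noise, not performance on real
tissue.

Problem sizes used by the test suite and the acceptance script (the
package's own choice of demonstration scale): the full default generator
for recovery and 20 null replicates for type-I control; a 50-cell,
500-gene cohort for bit-identity (composition/monotone-invariance)
checks; $10^5$ Monte-Carlo draws per $k$ for the β-score oracle; 1000
replicates of $k=6$ orderings of 50 sets for null calibration.

## Numerical and tolerance policy

* β-scores are evaluated as vectorised binomial upper tails
  (`pbinom(..., lower.tail = FALSE)`); no explicit summation of binomial
  terms, so no cancellation issues.
* Monte-Carlo agreement uses 3 standard errors as a *per-comparison*
  band. Across several hundred comparisons a correct implementation is
  expected to brush past a per-comparison band occasionally (nominal
  exceedance 0.27%), so the suite requires ≥ 99% of comparisons within
  3 SE and none beyond 6 SE — a wrong formula fails both by orders of
  magnitude.
* Min–max scaling of a constant JASMINE component returns 0.5 (the
  centre) rather than dividing by zero; Kendall's $W$ of two constant
  vectors is reported as missing.
* Ties in the ssGSEA-style ordering are kept in input (gene) order —
  deterministic, and unaffected by monotone transforms.
* All generator and tie-breaking randomness is seed-derived; no global
  RNG state leaks (`with_local_seed` restores `.Random.seed`).

## Known limitations

* Signed/weighted regulons (true three-tailed combination), bidirectional
  singscore, pseudobulk/imputation preprocessing and non-rank-based
  scoring families are out of scope.
* Gene identifiers are matched by exact string equality; no species or ID
  conversion.
* The JASMINE final score is cohort-dependent by construction; use the
  unscaled components when composition independence matters.
* The paper-literal RRA dialect is provided for transparency but, read
  literally, cannot flag unanimous top ranks (see above); the union
  dialect is the default for that reason.

## A worked run

```{r example, eval = FALSE}
sim <- simulate_sc(sim_config(seed = 1))
fit <- rank_gsea(sim$matrix, sim$sets, sim$labels)
print(fit)
summary(fit)
head(fit$rra[fit$rra$p_corrected <= 0.05, ])
plot(fit, kind = "stackbar", file = "stackbar.png")
```
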