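# rankgsea

Rank-based gene-set enrichment analysis for clustered single-cell
expression data, with robust rank aggregation (RRA) of multiple scoring
methods into one significance call per gene set and cluster.

## The problem

Single-cell gene-set scoring methods disagree: each has its own biases,
and a plain intersection of their per-cluster calls is conservative and
discards how *strongly* each method ranks each set. `rankgsea`

1. scores every cell against a gene-set collection with six methods that
   depend only on the within-cell ordering of expression values
   (AUCell-, UCell-, singscore-, ssGSEA-, JASMINE- and Viper-style
   scores) — so results are invariant to monotone normalisation and to
   cohort composition;
2. tests each set per cluster (one-vs-rest, two-sided Wilcoxon rank-sum,
   Bonferroni within method × cluster, significant at adjusted
   p ≤ 0.05);
3. aggregates the per-method significant rankings with RRA: for set *i*
   with normalised ranks r\_ij = R\_ij / N across k methods (N = number
   of sets tested; absent sets imputed at r = 1), the sorted ranks are
   compared with uniform order statistics through the binomial tail

   β\_{x,k}(r\_{(x)}) = Σ\_{ℓ=x..k} C(k,ℓ) r\_{(x)}^ℓ (1 − r\_{(x)})^{k−ℓ},

   the score is ρ = min\_x β\_x, and the reported p-value is
   min(1, k·ρ). Direction (up/down) is aggregated separately.

It also reports pairwise Kendall-W concordance between methods, ships a
negative-binomial synthetic-data generator with planted enriched sets (so
the whole pipeline is testable without downloads), readers/writers for
10x-style MTX, dense CSV/TSV, GMT and cluster-label TSV, plot-data tables
with basic renderings, and a command-line interface.

Intended users: computational biologists who want a defensible,
multi-method enrichment call per cluster, and method developers who need
a reproducible rank-aggregation reference with ground-truth simulation.

## Worked example

```r
library(rankgsea)

sim <- simulate_sc(sim_config(seed = 1))   # 2000 genes, 3x200 cells,
                                           # 20 sets, 3 planted at fold 4
fit <- rank_gsea(sim$matrix, sim$sets, sim$labels)
print(fit)
```

```
Rank-based gene-set enrichment analysis
  methods:    aucell, ucell, singscore, ssgsea, jasmine, viper
  gene sets: 20   cells: 600   clusters: 3
  RRA-significant (p_corrected <= 0.05): 9 set x cluster x direction call(s)
 cluster direction set_name p_corrected n_methods_detected
      C1        up    SET01   9.375e-08                  6
      C2      down    SET01   9.375e-08                  6
      C2        up    SET02   9.375e-08                  6
      C3        up    SET03   9.375e-08                  6
      C1      down    SET02   6.000e-06                  6
      ...
```

The three planted sets (SET01–SET03) are recovered as up in exactly their
target clusters with p\_corrected ≈ 9.4 × 10⁻⁸: each is ranked first by
all six methods among the 20 tested sets, so ρ = (1/20)⁶ and
p = 6ρ ≈ 9.4 × 10⁻⁸. The down calls are the mirror image of the
one-vs-rest contrast — a set up-regulated in C2 is genuinely down in C1
and C3 relative to "the rest" — not false positives. `summary(fit)` adds
per-method counts and the overall median pairwise Kendall W (0.94 here:
the methods rank cells very consistently on this strong planted signal).

Each stage is also exposed on its own (`score_all()`,
`differential_all()`, `rra_aggregate()`, `concordance_report()`,
`beta_score()`, `simulate_sc()`, readers/writers), and the same pipeline
runs from the shell:

```sh
CLI=$(Rscript -e 'cat(system.file("cli", "rankgsea", package = "rankgsea"))')
Rscript $CLI simulate --seed 1 --out demo/
Rscript $CLI score --matrix demo/ --gmt demo/sets.gmt --out demo/scores
Rscript $CLI diff --scores demo/scores --clusters demo/clusters.tsv --out demo/diff
Rscript $CLI integrate --diff demo/diff/differential.tsv --out demo/rra
```

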