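# CTEC — cross-tabulation ensemble clustering for single-cell RNA-seq

Single-cell clustering methods disagree: one tool over-splits a large cell
population, another merges rare cell types, and both scatter cells across
cluster boundaries. When the errors are complementary, the disagreement
itself carries signal. CTEC turns it into a consensus: given two (or more)
hard labelings `C1`, `C2` of the same cells plus a low-dimensional embedding
(PCA coordinates), it builds the contingency table between the labelings,
matches each cluster of one method to its dominant partner in the other, and
iteratively re-labels the *unmatched* cells of each cluster until the two
labelings correspond perfectly. The converged method-1 labeling is the
consensus `C_ens`.

Two correction rules are provided:

* **CTEC-DB (distribution-based)** — a column `m` of the cross-tabulation is
  corrected when the coefficient of variation of its count vector,
  `CV(m) = STD(m) / MEAN(m)`, reaches a threshold annealed from 2.0 down by
  0.2 per round: concentrated columns (strong correspondence) are trusted
  first, flat ones only as the threshold falls.
* **CTEC-OB (outlier-based)** — each cluster's cells are scored with COPOD
  (copula-based outlier detection, `-log` empirical tail probabilities summed
  over embedding dimensions); unmatched cells that are *not* outliers join
  the dominant partner, outliers keep their labels.

For more than two inputs, a progressive scheduler first discards the worst
labeling by Calinski–Harabasz score, then repeatedly merges the most
dissimilar remaining pair (lowest adjusted Rand index) with the pair
ensemble. From-scratch ARI, NMI and CH metrics, a synthetic benchmark
generator with controlled split/merge/noise errors, and CSV/MatrixMarket
readers round out the package. Audience: anyone with cluster assignments
from two or more scRNA-seq pipelines who wants a single defensible labeling
without re-running the clusterers.

## Worked example

```r
library(CTEC)

fx <- syntheticFixture("flagship", seed = 1)   # 2000 cells, 5 true clusters
ari(fx$method1, fx$truth)                      # 0.716  (over-split + noise)
ari(fx$method2, fx$truth)                      # 0.836  (rare merge + noise)

res <- ctecPair(fx$method1, fx$method2, fx$features, ensembleConfig("DB"))
res
#> CTECResult: 2000 cells, 4 clusters, 6 rounds, termination=converged
traceTable(res)
#>   round cv_th changed_col changed_row k1 k2
#> 1     1   2.0           0           0  6  4
#> 2     2   1.8          91           0  6  4
#> 3     3   1.6           0          37  6  4
#> 4     4   1.4           0          63  6  4
#> 5     5   1.2         510           0  4  4
#> 6     6   1.0           0           0  4  4
ari(consensus(res), fx$truth)                  # 0.855
nmi(consensus(res), fx$truth)                  # 0.813
```

Reading the trace: at threshold 1.8 the column pass re-labels 91 noisy cells
into their dominant clusters; the row passes at 1.6–1.4 clean the second
labeling; at 1.2 the two halves of the over-split dominant cluster fire
(510 cells) and the labelings reach perfect correspondence — the consensus
(ARI 0.855) beats both inputs. The cluster count drops to 4 because the
rare-cluster merge carried by method 2 is irreversible; with the outlier-based
strategy (`ensembleConfig("OB")`) the same fixture reaches ARI ≈ 0.92.

A command-line interface wraps the same functions:

```sh
ctec=$(Rscript -e 'cat(system.file("exec", "ctec", package = "CTEC"))')
Rscript $ctec simulate --scenario flagship --seed 1 --o fix
Rscript $ctec pair --labels1 fix/method1.csv --labels2 fix/method2.csv \
    --features fix/features.csv --strategy DB --o ens.csv
Rscript $ctec metrics --pred ens.csv --truth fix/truth.csv
```

Each run writes the ensemble labels (input schema plus a `ctec_label`
column), a JSON iteration trace and a JSON manifest (inputs, checksums,
configuration, termination).

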