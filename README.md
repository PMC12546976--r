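# biorankr

Network propagation for cancer therapeutic target-gene prioritization.
Given a protein–protein interaction (PPI) network, a set of seed genes
already linked to a disease, gene annotation sources (GO/KEGG/Reactome-style
GMT files) and a tumor/control expression matrix, `biorankr` ranks every
gene in the network by a **biologically informed personalized PageRank**:
both the teleport vector and the edge weights are built from the molecular
evidence instead of being uniform.

## The model

**Node evidence.** Annotation terms enriched in the seed set `S` are
selected per source `j` by a one-sided Fisher exact test against the
network universe with Benjamini–Hochberg FDR control (adjusted value
< 10⁻⁵ by default), giving per-source retained sets `F_j` and their union
`F`. Each gene `i` gets an annotation score

```
theta_i = ell                              if i in S
        = sum_j |A(i) ∩ F_j| / |F_j|       otherwise
```

where `A(i)` is the gene's annotation set and `ell` is a large constant
(default 1000) that pins seeds at the highest teleport priority. A second,
topological score rewards differentially expressed genes close to seeds:
expression is z-scored per gene, cells with `z > 2.5` are flagged, a gene
is DE when its flag rate strictly exceeds the matrix-wide mean rate, and
for DE genes

```
phi_i = |N(i) ∩ S| / |N(i)| + |N2(i) ∩ S| / |N2(i)|
```

over first- and second-order network neighborhoods. The teleport vector is
the convex mix `q = alpha * theta_hat + (1 - alpha) * phi_hat` of the two
normalized scores.

**Edge evidence.** Each interaction `(i, j)` is weighted by shared
significant annotations, `W1_ij = c + |A(i) ∩ A(j) ∩ F|` (floor `c > 0`),
and by tumor co-expression, `W2_ij = P⁺_ij / Σ_k P⁺_ik` (Pearson
coefficients clipped at zero, rows normalized). The transition kernel is
`W = beta * W1_hat + (1 - beta) * W2`, a convex mix of two row-stochastic
matrices.

**Propagation.** Scores are the fixed point of

```
PR(v) = (1 - d) q(v) + d * sum_{u -> v} PR(u) w(u, v) / sum_k w(u, k)
```

found by power iteration (damping `d = 0.85`, L1 tolerance 1e-10).
A classic PageRank baseline (uniform `q`, uniform `W`), ranking metrics
(Recall@K, nDCG@K, truncated top-K validation rate, top-K overlap counts)
and a synthetic planted-module fixture generator round out the toolkit.

## Worked example

```r
library(biorankr)

# synthetic study: 300 genes, a 25-gene disease module, 8 seeds,
# 40 tumor + 20 control samples, 2 annotation sources
bundle <- generate_fixture(fixture_config(seed = 5))
fit <- biorank_pipeline(bundle$network, bundle$catalog, bundle$seeds,
                        bundle$expr, truth = bundle$truth)
print(fit$sig)
print(fit$ranking, n = 5)
print(fit$evaluation)
```

```
Significant annotation terms: 8 retained of 100 tested (adjusted < 1e-05, per_source)
Gene ranking over 300 genes; top 5 :
 rank  gene      score
    1 G0128 0.04382433
    2 G0153 0.04251833
    3 G0220 0.04119777
    4 G0297 0.04118392
    5 G0207 0.03965162
   k match    recall      ndcg validation_rate n_truth
1 10     5 0.2941176 0.3578133            50.0      17
2 15     8 0.4705882 0.4137149            53.3      17
```

Eight of the hundred synthetic annotation terms survive the enrichment
filter (the planted disease terms). The ranking covers all 300 network
genes with scores summing to 1; the top ranks are dominated by seeds and
planted-module genes. Against the planted truth (the 17 module genes that
are not seeds), 8 are recovered in the top 15 — a 53.3 % validation rate,
Recall@15 of 0.47 and nDCG@15 of 0.41.

The same pipeline runs from the shell over files:

```sh
Rscript inst/cli/biorank.R simulate --out fx --seed 5
Rscript inst/cli/biorank.R run --ppi fx/ppi.tsv \
    --gmt fx/source1.gmt,fx/source2.gmt --expr fx/expression.tsv \
    --conditions fx/conditions.tsv --seeds fx/seeds.txt \
    --truth fx/truth.txt --out results/
Rscript inst/cli/biorank.R baseline --ppi fx/ppi.tsv --truth fx/truth.txt
Rscript inst/cli/biorank.R evaluate --ranking results/ranking.tsv \
    --truth fx/truth.txt --k 15
```

A YAML config file can mirror every flag (flags win). Real inputs use the
same formats: a HIPPIE-style tab-separated edge list with confidence
scores (interactions kept when confidence > 0.7), standard GMT gene sets,
a genes × samples expression TSV with a sample→condition map, and plain
gene lists for seeds and the evaluation truth set (e.g. an OncoKB-derived
list).

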