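# goannopt

Optimizing gene-set annotations by combining ontology structure with gene
expression data.

## The problem

Curated Gene Ontology annotations are simultaneously incomplete (true
gene-term links are missing, especially at specific terms) and overly
general (genes stay annotated to processes that are irrelevant to the
condition being studied). Both defects propagate straight into gene-set
enrichment analysis. `goannopt` is for computational biologists who want
condition-specific, probability-valued annotation matrices instead of a
static binary one.

## The method

Two stages operate on the term-by-gene annotation matrix
**A** (entries in [0, 1]):

**1. Extension by downward random walk with restart.** After closing the
curated annotations under the true-path rule, each parent→child edge of
the GO DAG is weighted by the Lin semantic similarity of its endpoints,
`lin(p,q) = 2·IC(MICA) / (IC(p) + IC(q))`, with information content
`IC(x) = −ln(n_x / n_root)` taken from the annotation corpus itself. Per
child, incoming weights are normalised over its ancestors to give the
transition matrix **T**, and the walk

&nbsp;&nbsp;&nbsp;&nbsp;`R ← β·R·T + (1−β)·I`

is iterated from **R** = **I** to its steady state
**R\*** = (1−β)(**I**−β**T**)⁻¹. An unannotated pair (term *i*, gene *j*)
then receives the walk mass arriving at *i* from the gene's annotated
terms, keeping only contributions above a per-row mean threshold; curated
entries stay exactly 1.

**2. Consensus filtering against expression clusters.** Genes are
clustered by k-means on z-scored expression profiles (one-hot category
matrix **C**); the row-normalised statistic matrix **S** = **A·C** gives
each term's annotation-mass share per cluster. Each term keeps only its
dominant cluster, scaled by that share (`a*_ij = a_ij · c_j,kmax ·
s_i,kmax`, random uniform tie-break). These per-k matrices are averaged
over a range of cluster counts (default k = 3..15) and again over
bootstrap resamples of the samples (default 50); consensus values below
τ = 0.1 are removed.

Evaluation helpers compute Kendall's coefficient of concordance over
bootstrap enrichment rankings, rank-based ROC/AUC, Benjamini–Hochberg
FDR, and a rank-sum competitive enrichment test.

## Worked example

A fully synthetic study with planted ground truth — 200 genes in 3
expression clusters, a 13-term ontology, 20% of leaf annotations planted
on genes of the *wrong* cluster:

```r
library(goannopt)

sim <- simulate_study("study", n_genes = 200, k_true = 3,
                      p_inconsistent = 0.2, n_samples = 40, effect = 2,
                      seed = 1)
cfg <- run_config(obo = sim$paths$obo,
                  annotations = sim$paths$annotations,
                  expression = sim$paths$expression,
                  gene_sets = sim$paths$gene_sets,
                  out_dir = "study/out",
                  k_min = 3, k_max = 8, n_boot = 20,
                  min_set_size = 5, max_set_size = 500, seed = 1)
res <- run_pipeline(cfg)
#> expression: 200 genes x 40 samples
#> ontology: 13 terms
#> random walk converged in 3 iterations
#> 9 gene set(s) pass the size filter

# do the consensus scores separate planted-inconsistent annotations
# from consistent ones?
lp <- sim$truth$leaf_pairs
sc <- res$final[cbind(match(lp$term, rownames(res$final)),
                      match(lp$gene, colnames(res$final)))]
roc_auc(sc, !lp$inconsistent)
#> [1] 1
round(c(consistent = mean(sc[!lp$inconsistent]),
        inconsistent = mean(sc[lp$inconsistent])), 3)
#>   consistent inconsistent
#>        0.334        0.016
```

Consistent annotations keep a consensus score around 0.33 (they survive
most clusterings, scaled by the dominant-cluster share), while planted
inconsistent ones collapse toward 0, so ranking by the final score
separates them perfectly (AUC = 1 at these study conditions). The run
writes the extended, final and thresholded matrices, per-gene filter
scores, a filtered GMT and a JSON manifest under `study/out/`; genes whose
every annotation was removed are dropped from the gene sets, e.g.

```r
head(sort(res$scores, decreasing = TRUE), 3)
#> g0034 g0095 g0114
#>     1     1     1
```

A thin CLI wraps the same functions:

```sh
Rscript inst/scripts/goannopt simulate --out study --seed 1
Rscript inst/scripts/goannopt run --config config.json
```

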