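# dwglasso

Sparse Gaussian graphical model inference with prior biological knowledge,
and network-based differential gene expression analysis.

## The problem

Conventional differential expression analysis tests each gene's mean shift
between two groups and ignores how genes interact. Gaussian graphical
models capture direct interactions: for expression data
`X ~ N(0, Sigma)`, a non-zero off-diagonal entry of the precision matrix
`Theta = Sigma^-1` is a conditional dependence between two genes given all
others. With far fewer samples than genes, `Theta` is estimated by the
graphical LASSO,

    argmin_{Theta > 0}  -log det(Theta) + tr(S Theta) + lambda * ||Theta||_1

This package implements the **weighted** variant (wgLASSO), which
penalizes each gene pair by how little support it has in an interaction
database (e.g. STRING scores rescaled to [0, 1] and arranged in a
symmetric matrix `W`):

    argmin_{Theta > 0}  -log det(Theta) + tr(S Theta)
                        + lambda * ||(1 - W) * Theta||_1

High-confidence pairs are penalized less, so prior evidence lowers the
barrier for an edge without ever forcing one. On top of the solver the
package provides **dwgLASSO**, a pipeline for two-group designs: filter
genes by significance (Welch *t* or concordance index with BH-FDR), fit
one wgLASSO network per group with its own cross-validated penalty
(one-standard-error rule), and rank genes by the **differential network
score** `dns_i = |sd_i^h - sd_i^l|` — the absolute change of the gene's
scaled node degree (degree / max degree) between the group networks. The
top of that ranking is the biomarker candidate list.

A simulation module generates scale-free ground truths (preferential
attachment trees, density exactly `2/p`), Gaussian data, and
accuracy-corrupted prior matrices, and benchmarks wgLASSO against plain
graphical LASSO and Meinshausen–Bühlmann neighbor selection ("or"/"and"
rules) at matched sparsity.

Intended users: computational biologists analyzing expression studies
with two phenotypic groups who want interaction-aware gene
prioritization, and methodologists benchmarking precision-matrix
estimators.

## Worked example

Simulate two groups of 60 samples over 100 genes sharing a scale-free
backbone, with three planted hubs that each gain strong extra interactions
in exactly one group, then run the pipeline:

```r
library(dwglasso)

tg <- generateTwoGroupData(p = 100, nPerGroup = 60,
                           nDifferentialHubs = 3, seed = 42)
cat("planted hubs:", paste0("g", tg$truth@differentialNodes), "\n")
#> planted hubs: g24 g29 g69

X <- rbind(tg$xA, tg$xB)
groups <- factor(rep(c("tumor", "normal"), each = 60),
                 levels = c("tumor", "normal"))
grid <- lambdaGrid(crossprod(scale(X) / sqrt(nrow(X) - 1)),
                   length = 15, ratio = 0.2)
res <- runDwglasso(X, groups, alpha = 1.0, cvFolds = 10, seed = 7,
                   grid = grid, topK = 5)
head(res$scores[, c("gene", "dH", "dL", "sdH", "sdL", "dns", "rank")], 5)
#>   gene dH dL    sdH    sdL   dns rank
#> 1  g29  1 13 0.0714 1.0000 0.929    1
#> 2  g24 14  1 1.0000 0.0769 0.923    2
#> 3  g69 14  2 1.0000 0.1538 0.846    3
#> 4  g39  1  6 0.0714 0.4615 0.390    4
#> 5  g13  5  0 0.3571 0.0000 0.357    5
```

All three planted hubs rank 1–3: each has a high degree in exactly one
group network (`dH` vs `dL`), so its scaled degree swings between about 0
and 1 and its `dns` dwarfs the background churn (0.39 for the best
non-hub). `alpha = 1` keeps every gene because the planted signal here is
rewiring, not mean shift; on real data the default `alpha = 0.05` first
restricts to differentially expressed or survival-associated genes. With
`weights = W` from `buildWeightMatrix(readPriorTable("string.tsv"),
colnames(X))` the network stage uses the prior-weighted penalty; without
it the fits reduce to plain graphical LASSO.

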