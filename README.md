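# sakura

Knowledge-guided dimensionality reduction for single-cell transcriptomics.

Unsupervised embeddings (PCA, plain autoencoders) represent cells by the
directions of largest overall variance, so signals carried by a handful of
genes — a rare islet endocrine subtype defined by one hormone gene, a small
senescent fraction with an elevated CDK-inhibitor program, the *CD8A*/*CD8B*
axis separating otherwise similar T cells — are routinely absorbed into
larger clusters. `sakura` trains a regularized autoencoder whose bottleneck
must, in addition to reconstructing the expression profile, predict
user-supplied **genes of interest** (GOI) through a regression head, so the
embedding provably retains that information.

## The model

For log-transformed expression profiles $x_i$, an encoder
$f_{enc}(x_i)=h_i$ (three hidden CELU layers, 50-dimensional bottleneck)
and decoder $f_{dec}(h_i)=x_i'$ are trained with

$$\mathcal{L} = \mathcal{L}_{rec} + \mathcal{L}_{reg} + \mathcal{L}_{goi}$$

* $\mathcal{L}_{rec} = \sum_i \lambda_1\lVert x_i - x_i'\rVert_1 +
  \lambda_2\lVert x_i - x_i'\rVert^2$ — L1/L2 reconstruction;
* $\mathcal{L}_{reg} = \lambda_3\,SW_2(f_{enc}(\mathcal{D}),\mathcal{P})$ —
  sliced 2-Wasserstein distance between the embedding distribution and a
  uniform prior $\mathcal{P}\sim U(-k,k)^{50}$, preventing representation
  collapse;
* $\mathcal{L}_{goi} = \sum_i \lambda_4 L_1 + \lambda_5 L_2^2 +
  \lambda_6(1-\cos)$ between observed and head-predicted GOI values, where
  targets may be single genes, sums (e.g. *CD8A* + *CD8B*), or minima of
  z-scored signature averages.

Training alternates reconstruction+regularization updates (batches of 200)
with GOI updates (batches of 100, decoder frozen) under RMSProp
(lr 0.001, smoothing 0.9) on a 50/50 train/test split, with $\lambda_3$
ramped from $10^{-4}$ by 0.01 per epoch and $\lambda_{4..6}$ ramped from 0
by 0.01 per epoch starting after 50 epochs, all capped at 1. The held-out
half is a canary for distorted training.

The package also ships the full downstream toolkit: SNN-Louvain
clustering; the gene-expression **distinctiveness score**
$G=\frac1m\sum_i\frac1k\sum_j q(t_{ij})\,q(F_i(e_{ij}))$ with
$q(t)=4t(t-1)+1$; Davies-Bouldin, average silhouette width and
Calinski-Harabasz internal validation; majority cluster labeling with
precision/recall/F1, adjusted Rand index and normalized mutual
information; marker-driven annotation refinement (doublet-vote and
QC-percentile gated subtype promotion, suspicious-annotation flagging);
gene-signature scoring; and a negative-binomial simulator so the whole
pipeline is testable offline.

## Worked example

```r
library(sakura)

fx  <- makeFixture("rare_subtype", seed = 7)   # 2000 cells x 1000 genes,
                                               # 5% subtype, 5 markers
sce <- preprocess(fx$sce, n_genes = 500, force_include = fx$markers)
x   <- t(SummarizedExperiment::assay(sce, "scaled"))
y   <- buildGoiTargets(sce, fx$goi)

model <- trainSakura(x, y, goi = fx$goi,
                     config = trainConfig(epochs = 300, seed = 1))
emb   <- embedCells(model, x)
cl    <- snnCluster(emb, seed = 1)
clp   <- snnCluster(SingleCellExperiment::reducedDim(sce, "PCA"), seed = 1)

adjustedRandIndex(clusterIds(cl),  fx$truth$population)   # 0.9596
adjustedRandIndex(clusterIds(clp), fx$truth$population)   # 0.9062
distinctiveness(sce, cl,  fx$markers)$G                   # 0.2043
distinctiveness(sce, clp, fx$markers)$G                   # 0.0148
```

The PCA-50 baseline finds only the three major types and merges the rare
subtype into its parent (ARI 0.906 against the true four populations); the
marker-guided embedding gives the subtype its own cluster (ARI 0.960) and
multiplies the markers' distinctiveness score fourteen-fold — the rare
population is now visible to ordinary clustering.

A thin CLI over the same functions lives in `inst/scripts/sakura-cli.R`
(subcommands `simulate`, `preprocess`, `run`, `cluster`, `evaluate`,
`annotate`).

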