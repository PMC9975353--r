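# resvae

Unsupervised identification of cluster-specific gene or peak sets in
single-cell data with ensembles of restricted-latent variational
autoencoders (resVAE) and Robust Rank Aggregation.

## Who this is for

Single-cell analysts who have a count matrix (scRNA-seq transcripts,
scATAC-seq peaks) and a clustering — hard labels from any tool, or soft
weights describing transitional/partial cell identities — and want, per
cluster, a ranked, truncated, confidence-scored set of characteristic
features *without* differential-expression testing against other
clusters.

## The method

A resVAE is a VAE whose latent space is partitioned into one block of
`u` units per cluster; the sampled latent code of each cell is gated by
its (label-smoothed) cluster assignment, so each label effectively owns
a label-specific latent subspace. The loss is

    L = α · Σ (x − x̂)²  +  β · ½ Σ (exp(logσ) + (s − μ)² − 1 − logσ)

— a β-VAE objective with reconstruction weight α, KL weight β and a
latent prior offset s (α = β = 1 recovers the standard VAE). Models use
the Mish activation with Glorot-uniform initialisation (He-uniform when
ReLU is selected) and are trained with Rectified Adam plus Lookahead.

After training, the relevance of feature g to cluster c is read off the
decoder as the absolute linear path weight from c's latent block:
`score(c, g) = Σ_i Σ_h |W1[i, h]| · |W2[h, g]|`. Per cluster, each
model's descending weight curve is truncated at a knee found by a
bin-and-rotate search (split the curve into N bins, rotate the first bin
so the chord from its first to its median data point is horizontal, take
the rotated-y maximum); the median knee across models is the shared
cut-off. The truncated lists of all models are reduced to one consensus
per cluster by Robust Rank Aggregation: each feature's normalised ranks
r₍k₎ are scored with beta order-statistic CDFs, ρ = min_k BetaCDF(r₍k₎;
k, m − k + 1), Bonferroni-corrected by the model count, and reported with
the display score −log10(corrected) and an ensemble confidence (fraction
of models ranking the feature above the cut-off).

Two synthetic study systems with full regulatory ground truth are
included — a bifurcating trajectory (7 populations, 35 transcription
factors in branch-specific modules regulating 500 targets, 20
housekeeping negative controls) and a myeloid-differentiation model (11
classical regulators, progenitor plus 4 fates) — so the whole pipeline is
testable offline, together with hypergeometric overlap diagnostics,
cluster-partition splitting, clustering-quality metrics and an
optimal-cluster-number scan.

## Worked example

```r
library(resvae)

sim  <- simulateBifurcation(simulationConfig(seed = 1L))   # 1400 x 555
ens  <- ensembleConfig(modelConfig(seed = 100L),           # α,β ∈ {1,2}
                       replicatesPerSetting = 2L)          # 8 models
maps <- runEnsemble(sim$counts, sim$hard, ens)
cons <- resvaeConsensus(maps)

head(consensusTable(cons$sEndC))
#>    feature          rho    corrected    score confidence nModels
#> 1 TF_B11_1 1.110852e-22 8.886815e-22 21.05125          1       8
#> 2  TF_B9_1 2.843781e-20 2.275025e-19 18.64301          1       8
#> 3  TF_B2_2 4.339265e-17 3.471412e-16 15.45949          1       8
#> 4  TF_B9_2 4.339265e-17 3.471412e-16 15.45949          1       8
#> 5  TF_B6_1 1.865805e-16 1.492644e-15 14.82604          1       8
#> 6 TF_B10_1 6.403840e-16 5.123072e-15 14.29047          1       8

recoveryScore(cons, sim$truth, clusters = c("sEndC", "sEndD"))$perCluster
#> sEndC sEndD
#>   1.0   0.9
```

The consensus for the terminal C-branch population is headed by the
C-branch module TFs (B11, B9, B2, B6, B10) with ensemble confidence 1 —
every one of the 8 models ranked them above the cluster's cut-off (55,
the median bin-and-rotate knee). ρ is the RRA score: the probability-
scale evidence that a feature sits this high in all lists by chance, so
8.9e-22 (corrected) for TF_B11_1 means essentially certain membership;
`score` is −log10 of that. The recovery line says 10/10 of sEndC's and
9/10 of sEndD's ground-truth module TFs were identified. All 20
housekeeping controls rank below every true TF's median position.

Reading your own data instead:

```r
counts <- readMatrix("matrix.mtx")                   # + features/barcodes.tsv
labels <- readAssignments("labels.csv", "hard", cellIds = rownames(counts))
maps   <- runEnsemble(counts, labels, ensembleConfig(modelConfig(seed = 1L)))
```

A thin command-line interface over the same functions is installed at
`inst/cli/resvae.R` (`simulate`, `train`, `ensemble`, `aggregate`
subcommands).

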