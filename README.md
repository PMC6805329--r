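# metamlann

Inference of microbial communities at unsampled urban locations,
formulated as multi-label classification. Given metagenomic samples
collected across a transit system (subway stations), `metamlann` predicts
the presence or absence of each microbial genus at locations that were
never sampled, from features of the urban environment: subway line
membership weighted by ridership, a transit-graph embedding of the station
network, and the surface material the sample was collected from.

The package is aimed at computational microbiologists and urban-genomics
practitioners working with MetaSUB-style survey data (MetaPhlAn
relative-abundance profiles plus station/turnstile metadata), and at
methodologists who want a fully testable desk-scale reimplementation of
the model.

## The model

Labels are the binary **microbial distribution matrix**
Y ∈ {0,1}^(n×m): Y_ij = 1 when sample i's relative abundance of genus j
meets a threshold γ (strictly positive when γ = 0). Features are the
concatenation F = [F_s | F_c | F_m] of ridership-weighted line indicators,
a node2vec-style embedding of the station network (edge weights = minimum
stop counts, express edges weight 1, walk affinity = 1/weight), and a
surface-material one-hot.

**MetaMLAnn** is a feed-forward network with m + 1 hidden blocks of p
units: individual blocks B_1..B_m wired each to its own output neuron and
a shared block B_share wired to all of them,

    o_i = σ( W2_i · B_i + W2_share · B_share + b2 ),
    B_i = f_B( W1_i · x + b1_i ),

trained by minibatch SGD on cross-entropy summed over labels and averaged
over samples, plus a phylogenetic graph-Laplacian penalty

    J = J_CE + λ · mean_i ( o_i' L o_i ),   L = D − P,

where P is the genus-level evolutionary similarity matrix (mean pairwise
alignment identity over species pairs, per kingdom, zero across kingdoms)
and D its row-sum degree matrix. The penalty equals
½ Σ P_jk (o_j − o_k)², pulling scores of phylogenetically similar genera
together. Shipped alongside: an inverse-distance-weighting (IDW) spatial
baseline, the convex ensemble **MetaMLAnn+** (o_h = α·o + (1−α)·o_m,
α = 0.7 by default), micro-averaged precision/recall/F1 and ranking-loss
evaluation with a 3-fold cross-validation harness, and a synthetic-data
generator that emulates all five input kinds with planted, recoverable
structure.

See `vignettes/metamlann-methods.Rmd` for the full model account, the
design decisions and the generator's assumptions.

## Worked example

```r
library(metamlann)

sc  <- generate_scenario(scenario_config(seed = 1))   # synthetic survey
tg  <- build_transit_graph(sc$transit$stations)
emb <- embed_stations(tg, d = 16, seed = 1)
fm  <- assemble_features(sc$samples, sc$transit$stations, embedding = emb,
                         turnstiles = sc$transit$turnstiles,
                         materials = sc$config$materials)
Y   <- sc$Y[fm$sample_ids, ]

cfg <- metamlann_config(k = ncol(fm$X), m = ncol(Y), lambda = 0.01,
                        seed = 1, epochs = 200)
cv  <- kfold_cv(fm$X, Y, k = 3, metamlann_trainer(cfg, sc$laplacian), seed = 1)
round(cv$mean, 4)
#>    precision       recall           f1 ranking_loss
#>       0.8146       0.7650       0.7885       0.0931
```

Mean over the three folds: about 81% of predicted presences are planted
presences (precision), about 77% of planted presences are found (recall),
for a micro-F1 of 0.79; 9% of (present, absent) genus pairs are ranked in
the wrong order (ranking loss). An IDW baseline and the α = 0.7 ensemble
plug into the same harness via `idw_trainer()` and `ensemble_trainer()`.

A thin command-line wrapper over the same functions lives at
`inst/cli/metamlann.R` (subcommands `simulate`, `features`, `similarity`,
`train`, `predict`, `evaluate`, `cv`, `ensemble`).

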