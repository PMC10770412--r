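# pathsurv

Multi-omics survival prognosis with pathway-masked variational
autoencoders, neural Cox models, and DeepSHAP interpretation.

## What problem this solves

Predicting patient survival from bulk gene and miRNA expression is a
small-n / large-p problem: cohorts of a few hundred patients against tens
of thousands of features. `pathsurv` implements a two-stage deep-learning
pipeline for this setting, aimed at computational biologists and
biostatisticians working with censored survival outcomes and paired omics
blocks:

1. **KL-PMVAE** — a variational autoencoder whose encoder routes genes
   through a sparse gene→pathway layer (connections only where a pathway
   membership mask allows), concatenates pathway activations with the miRNA
   layer, and learns a low-dimensional latent posterior $N(\mu, \sigma^2)$.
   It minimises
   $\mathrm{BCE}(x_{gene},\hat x_{gene}) + \mathrm{BCE}(x_{miRNA},\hat
   x_{miRNA}) + \beta D_{KL}(N(\mu,\sigma^2)\,\|\,N(0,I)) +
   \lambda_1\lVert\theta_1\rVert_2$, with $\beta$ following a cyclical
   KL-annealing schedule (0 → 1 within each cycle) that counteracts
   posterior collapse.
2. **LFSurv** — a one-hidden-layer Cox network (tanh, dropout, bias-free
   linear output) mapping $[\mu, \text{clinical}]$ to a prognostic index
   (PI) by minimising the average negative log partial likelihood
   $-\tfrac{1}{n_{E=1}}\sum_{i:E_i=1}(PI_i - \log\sum_{j\in R(T_i)}
   e^{PI_j}) + \lambda_2\lVert\theta_2\rVert_2$ (Breslow ties). Patients
   with PI above the tuning-cohort median form the predicted high-risk
   group.
3. **DeepSHAP** — DeepLIFT-rescale attributions against a low-risk
   reference population, propagated through LFSurv (feature → PI) and the
   encoder (gene/miRNA/pathway node → latent feature), with Key Input
   Factor (KIF) and Key Pathway Factor (KPF) reports for features recurring
   in the top-10 lists of several top latent features.

Supporting modules provide min-max normalisation, variance filtering,
pathway-mask construction from GMT gene sets, reproducible 20% / 64% / 16%
splits, a synthetic multi-omics survival cohort generator (shared latent
factors, pathway-structured loadings, Weibull proportional hazards,
calibrated censoring), evaluation statistics (pair-counting concordance
index, Kaplan–Meier, log-rank, exact Wilcoxon signed-rank, univariate Cox +
Benjamini–Hochberg, Schoenfeld detectable hazard ratios), and a
repeated-split experiment protocol with matched-split model comparison.

## Worked example

```r
library(pathsurv)

cohort <- generate_cohort(synthetic_config(n_samples = 300, seed = 42))
achieved_event_rate(cohort)
#> [1] 0.7033333
plan <- make_splits(cohort$survival$sample_id, seed = 1)

mask <- build_pathway_mask(cohort$pathways, colnames(cohort$gene),
                           min_genes = 5, max_genes = 50)
mask
#> <pathway_mask> 120 genes x 8 pathways, 120 connections

xg <- unclass(cohort$gene)[, rownames(mask)]
xm <- unclass(cohort$miRNA)
arch <- vae_architecture(mask, n_miRNA = ncol(xm), d_latent = 8, hidden_width = 32)
fit <- train_kl_pmvae(
  train = list(gene = xg[plan$train_ids, ], miRNA = xm[plan$train_ids, ]),
  valid = list(gene = xg[plan$valid_ids, ], miRNA = xm[plan$valid_ids, ]),
  arch = arch, schedule = beta_schedule(30, 2, 0.5), lr = 5e-3, seed = 1
)
glance(fit)
#> # A tibble: 1 × 5
#>   n_epochs best_epoch best_valid_recon integration d_latent
#>      <int>      <int>            <dbl> <chr>          <int>
#> 1       30         24             103. entangle           8

mu <- extract_latent(xg, xm, fit)
features <- cbind(mu, as.matrix(cohort$clinical[, -1]))
rownames(features) <- cohort$survival$sample_id
sfit <- train_lfsurv(
  train = list(features = features[plan$train_ids, ],
               surv = dplyr::filter(cohort$survival, sample_id %in% plan$train_ids)),
  valid = list(features = features[plan$valid_ids, ],
               surv = dplyr::filter(cohort$survival, sample_id %in% plan$valid_ids)),
  spec = survnet_spec(ncol(features), hidden_width = 8, dropout_rate = 0.2),
  n_epochs = 150, seed = 2
)
test_pi <- predict(sfit, features[plan$test_ids, ])
test_surv <- dplyr::filter(cohort$survival, sample_id %in% plan$test_ids)
concordance_index(test_pi, test_surv)$c_index
#> [1] 0.8409091
```

A testing-set concordance of 0.84 on this strong-signal cohort means 84% of
comparable patient pairs (the pair with shorter follow-up died, times
distinct) are ranked correctly by the PI. Risk groups split at the tuning
median PI separate sharply:

```r
groups <- assign_risk_groups(predict(sfit, features[plan$tuning_ids, ]), test_pi)
logrank_test(groups, test_surv)
#> # A tibble: 1 × 3
#>   statistic       p_value method
#>       <dbl>         <dbl> <chr>
#> 1      36.7 0.00000000134 log-rank
```

and DeepSHAP identifies which survival-network inputs drive the high- vs
low-risk PI difference (here, latent features rather than the weak clinical
covariates):

```r
sel <- sample_attribution_groups(
  assign_risk_groups(predict(sfit, features)), n_each = 50, seed = 3)
net <- build_lfsurv_network(sfit, colnames(features))
shap <- deepshap_scores(net, features[sel$explained_ids, ],
                        features[sel$reference_ids, ])
head(shap$overall, 5)
#> # A tibble: 5 × 2
#>   feature  overall
#>   <chr>      <dbl>
#> 1 latent_3   1.25
#> 2 latent_1   0.675
#> 3 latent_6   0.425
#> 4 latent_7   0.294
#> 5 latent_8   0.262
```

From here, `build_encoder_network()` + `deepshap_scores()` attribute each
top latent feature back to genes, miRNAs and pathway nodes, and
`identify_kif()` extracts the recurring key factors. `run_protocol()` wraps
the whole repeated-split training/tuning/testing design, and
`compare_models()` runs matched-split signed-rank comparisons between model
variants. See the methods vignette (`vignettes/pathsurv-methods.Rmd`) for
the modelling assumptions and design choices.

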