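# shared fixtures, all built in code

toy_omics <- function(values, ids = NULL, kind = "gene") {
  if (is.null(ids)) ids <- rownames(values) %||% paste0("s", seq_len(nrow(values)))
  omics_matrix(values,
    sample_ids = ids,
    feature_ids = colnames(values) %||% paste0("f", seq_len(ncol(values))),
    omics_kind = kind
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

toy_mask <- function() {
  structure(
    matrix(c(1, 1, 0, 0, 0, 0, 1, 1), 4, 2,
      dimnames = list(paste0("g", 1:4), c("P1", "P2"))
    ),
    class = c("pathway_mask", "matrix", "array")
  )
}

small_cohort <- function(n = 200, seed = 11, weights = c(rep(1, 4), 0.5, 0.5)) {
  generate_cohort(synthetic_config(
    n_samples = n, n_genes = 60, n_miRNAs = 15, n_pathways = 4, d_true = 4,
    effect_weights = weights, seed = seed
  ))
}

# train a small joint VAE + survival net on a cohort; used by attribution
# and evaluation tests
fit_small_pipeline <- function(cohort, d_latent = 4, vae_epochs = 15,
                               surv_epochs = 120, seed = 2) {
  mask <- build_pathway_mask(cohort$pathways, colnames(cohort$gene),
    min_genes = 5, max_genes = 50
  )
  xg <- unclass(cohort$gene)[, rownames(mask), drop = FALSE]
  xm <- unclass(cohort$miRNA)
  n <- nrow(xg)
  tr <- seq_len(floor(0.8 * n))
  va <- setdiff(seq_len(n), tr)
  arch <- vae_architecture(mask, ncol(xm), d_latent, hidden_width = 16)
  fit <- train_kl_pmvae(
    list(gene = xg[tr, ], miRNA = xm[tr, ]),
    list(gene = xg[va, ], miRNA = xm[va, ]),
    arch, beta_schedule(vae_epochs, 2, 0.5),
    lr = 5e-3, seed = seed
  )
  mu <- extract_latent(xg, xm, fit)
  clin <- as.matrix(cohort$clinical[, -1])
  feats <- cbind(mu, clin)
  rownames(feats) <- cohort$survival$sample_id
  spec <- survnet_spec(ncol(feats), 8, 0.2)
  sfit <- train_lfsurv(
    list(features = feats[tr, ], surv = cohort$survival[tr, ]),
    list(features = feats[va, ], surv = cohort$survival[va, ]),
    spec,
    n_epochs = surv_epochs, seed = seed + 1
  )
  list(
    vae = fit, surv = sfit, mask = mask, xg = xg, xm = xm,
    feats = feats, mu = mu, clin = clin, cohort = cohort
  )
}

# O(n^2) loop-based concordance oracle implementing the pair count directly
brute_force_cindex <- function(eta, time, event) {
  num <- 0
  den <- 0
  n <- length(eta)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (time[i] > time[j] && event[j] == 1) {
        den <- den + 1
        if (eta[i] < eta[j]) num <- num + 1
      }
    }
  }
  list(c_index = num / den, num = num, den = den)
}

# log-rank statistic from first principles: one 2x2 table per event time
brute_force_logrank <- function(time, event, group) {
  stopifnot(all(group %in% c(0, 1)))
  ev_times <- sort(unique(time[event == 1]))
  o1 <- e1 <- v <- 0
  for (t in ev_times) {
    at_risk <- time >= t
    n_tot <- sum(at_risk)
    n1 <- sum(at_risk & group == 1)
    d_tot <- sum(time == t & event == 1)
    d1 <- sum(time == t & event == 1 & group == 1)
    o1 <- o1 + d1
    e1 <- e1 + d_tot * n1 / n_tot
    if (n_tot > 1) {
      v <- v + d_tot * (n1 / n_tot) * (1 - n1 / n_tot) * (n_tot - d_tot) / (n_tot - 1)
    }
  }
  (o1 - e1)^2 / v
}
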