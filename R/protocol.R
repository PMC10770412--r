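#' Configuration for the repeated-split experiment protocol
#'
#' Defines the grids and bookkeeping for the two-stage protocol: hold out a
#' fixed testing set, then repeatedly (default 10 times) re-split the tuning
#' set 4:1 into training/validation, grid-search the autoencoder by
#' validation reconstruction loss and the survival network by validation
#' concordance, refit both on the whole tuning set with the winning
#' settings, and score the held-out test set. Grids default to single
#' values sized for desk-scale cohorts; every entry can be overridden.
#'
#' @param integration Autoencoder integration variant, or `"clinical_only"`
#'   to skip the omics stage entirely (the clinical-covariates-only
#'   baseline).
#' @param d_latent,vae_hidden,lambda1,vae_lr Autoencoder grids (vectors).
#' @param vae_epochs,n_cycles,cutting_ratio Annealing settings.
#' @param surv_hidden,dropout,lambda2,surv_lr,surv_epochs Survival-network
#'   grids and settings.
#' @param batch_size Autoencoder mini-batch size.
#' @param min_genes,max_genes Realised pathway size bounds for the mask.
#' @param n_repeats Number of tuning re-splits (default 10).
#' @param master_seed Integer; per-repeat seeds are `master_seed * 1000 + r`.
#' @return An `experiment_config` list.
#' @export
experiment_config <- function(integration = "entangle",
                              d_latent = 8, vae_hidden = 32, lambda1 = 0,
                              vae_lr = 5e-3, vae_epochs = 30, n_cycles = 2,
                              cutting_ratio = 0.5,
                              surv_hidden = 8, dropout = 0.2, lambda2 = 1e-4,
                              surv_lr = 0.01, surv_epochs = 150,
                              batch_size = 64,
                              min_genes = 15, max_genes = 300,
                              n_repeats = 10, master_seed = 1L) {
  stopifnot(n_repeats >= 1, length(d_latent) >= 1, length(surv_hidden) >= 1)
  structure(
    as.list(environment()),
    class = "experiment_config"
  )
}

# normalise + filter one omics block over the three splits; variance filter
# is computed on the tuning samples only, then applied everywhere
prepare_block <- function(block, plan, threshold = 0.02) {
  sub <- function(ids) {
    restore_omics(unclass(block)[ids, , drop = FALSE], block)
  }
  tune_norm <- suppressWarnings(minmax_normalize(sub(plan$tuning_ids)))
  filt <- variance_filter(tune_norm, threshold = threshold)
  test_norm <- suppressWarnings(minmax_normalize(sub(plan$test_ids)))
  test_filt <- variance_filter(test_norm, keep_ids = filt$kept)
  list(tuning = filt$matrix, test = test_filt$matrix, kept = filt$kept)
}

clinical_matrix <- function(clinical, ids) {
  m <- as.matrix(clinical[match(ids, clinical$sample_id), -1, drop = FALSE])
  rownames(m) <- ids
  m
}

#' Run the repeated-split experiment protocol
#'
#' @param data A list (e.g. a `synthetic_dataset`) with elements `gene`,
#'   `miRNA` ([omics_matrix()]), `clinical` (tibble, `sample_id` first),
#'   `survival` (tibble) and `pathways` ([pathway_collection()]).
#' @param config An [experiment_config()].
#' @param plan Optional [make_splits()] plan; built from `master_seed` when
#'   omitted, and required to be shared when two runs are to be compared.
#' @return An `experiment_report`: per-repeat tibble `repeats` (winning
#'   hyperparameters, validation metric, testing C-index), `summary`
#'   (median/mean/SD of the testing C-indices), the split `plan` and the
#'   `config`.
#' @export
run_protocol <- function(data, config, plan = NULL) {
  stopifnot(inherits(config, "experiment_config"))
  ids <- data$survival$sample_id
  if (is.null(plan)) plan <- make_splits(ids, seed = config$master_seed)
  clinical_only <- identical(config$integration, "clinical_only")

  if (!clinical_only) {
    gene <- prepare_block(data$gene, plan)
    mirna <- prepare_block(data$miRNA, plan)
    mask <- build_pathway_mask(data$pathways, gene$kept,
      min_genes = config$min_genes, max_genes = config$max_genes
    )
    # restrict the gene blocks to mask-covered genes, mask order
    gene$tuning <- restore_omics(
      unclass(gene$tuning)[, rownames(mask), drop = FALSE], gene$tuning
    )
    gene$test <- restore_omics(
      unclass(gene$test)[, rownames(mask), drop = FALSE], gene$test
    )
  }
  surv_by <- function(ids_) {
    data$survival[match(ids_, data$survival$sample_id), ]
  }

  rows <- vector("list", config$n_repeats)
  for (r in seq_len(config$n_repeats)) {
    seed_r <- config$master_seed * 1000L + r
    ts <- split_tuning(plan$tuning_ids, seed = seed_r)

    features_for <- NULL
    vae_best <- NULL
    if (!clinical_only) {
      vae_best <- grid_search_vae(gene, mirna, mask, ts, config, seed_r)
      latent_tuning <- extract_latent(
        if (vae_best$arch$n_gene > 0) unclass(gene$tuning) else NULL,
        if (vae_best$arch$n_miRNA > 0) unclass(mirna$tuning) else NULL,
        vae_best$refit
      )
      latent_test <- extract_latent(
        if (vae_best$arch$n_gene > 0) unclass(gene$test) else NULL,
        if (vae_best$arch$n_miRNA > 0) unclass(mirna$test) else NULL,
        vae_best$refit
      )
      feats_tuning <- cbind(latent_tuning, clinical_matrix(data$clinical, plan$tuning_ids))
      feats_test <- cbind(latent_test, clinical_matrix(data$clinical, plan$test_ids))
    } else {
      feats_tuning <- clinical_matrix(data$clinical, plan$tuning_ids)
      feats_test <- clinical_matrix(data$clinical, plan$test_ids)
    }

    surv_best <- grid_search_lfsurv(feats_tuning, surv_by, ts, config, seed_r)
    test_pi <- predict(surv_best$refit, feats_test)
    test_c <- concordance_index(test_pi, surv_by(plan$test_ids))$c_index

    rows[[r]] <- tibble::tibble(
      repeat_id = r, seed = seed_r,
      d_latent = if (clinical_only) NA_integer_ else vae_best$d_latent,
      lambda1 = if (clinical_only) NA_real_ else vae_best$lambda1,
      valid_recon = if (clinical_only) NA_real_ else vae_best$valid_recon,
      surv_hidden = surv_best$hidden, dropout = surv_best$dropout,
      lambda2 = surv_best$lambda2, valid_cindex = surv_best$valid_cindex,
      test_cindex = test_c
    )
  }
  repeats <- dplyr::bind_rows(rows)
  structure(
    list(
      repeats = repeats,
      summary = tibble::tibble(
        median = stats::median(repeats$test_cindex),
        mean = mean(repeats$test_cindex),
        sd = stats::sd(repeats$test_cindex)
      ),
      plan = plan, config = config
    ),
    class = "experiment_report"
  )
}

grid_search_vae <- function(gene, mirna, mask, ts, config, seed_r) {
  grid <- expand.grid(
    d_latent = config$d_latent, hidden = config$vae_hidden,
    lambda1 = config$lambda1, lr = config$vae_lr,
    cutting_ratio = config$cutting_ratio,
    KEEP.OUT.ATTRS = FALSE
  )
  best <- NULL
  for (gidx in seq_len(nrow(grid))) {
    gr <- grid[gidx, ]
    arch <- vae_architecture(
      mask = structure(unclass(mask), class = c("pathway_mask", "matrix", "array")),
      n_miRNA = ncol(mirna$tuning), d_latent = gr$d_latent,
      hidden_width = gr$hidden, integration = config$integration
    )
    sched <- beta_schedule(config$vae_epochs, config$n_cycles, gr$cutting_ratio)
    fit <- train_kl_pmvae(
      train = list(
        gene = unclass(gene$tuning)[ts$train_ids, , drop = FALSE],
        miRNA = unclass(mirna$tuning)[ts$train_ids, , drop = FALSE]
      ),
      valid = list(
        gene = unclass(gene$tuning)[ts$valid_ids, , drop = FALSE],
        miRNA = unclass(mirna$tuning)[ts$valid_ids, , drop = FALSE]
      ),
      arch = arch, schedule = sched, lambda1 = gr$lambda1, lr = gr$lr,
      batch_size = config$batch_size, seed = seed_r
    )
    val <- if (inherits(fit, "concat_vae_fit")) {
      fit$gene_fit$history$valid_recon[fit$gene_fit$best_epoch] +
        fit$mirna_fit$history$valid_recon[fit$mirna_fit$best_epoch]
    } else {
      min(fit$history$valid_recon, na.rm = TRUE)
    }
    if (is.null(best) || val < best$valid_recon) {
      best <- list(
        valid_recon = val, d_latent = gr$d_latent, lambda1 = gr$lambda1,
        arch = arch, sched = sched, gr = gr
      )
    }
  }
  # refit on the whole tuning set with the winning settings
  best$refit <- train_kl_pmvae(
    train = list(gene = unclass(gene$tuning), miRNA = unclass(mirna$tuning)),
    valid = NULL, arch = best$arch, schedule = best$sched,
    lambda1 = best$gr$lambda1, lr = best$gr$lr,
    batch_size = config$batch_size, seed = seed_r
  )
  best
}

grid_search_lfsurv <- function(feats_tuning, surv_by, ts, config, seed_r) {
  grid <- expand.grid(
    hidden = config$surv_hidden, dropout = config$dropout,
    lambda2 = config$lambda2, KEEP.OUT.ATTRS = FALSE
  )
  best <- NULL
  for (gidx in seq_len(nrow(grid))) {
    gr <- grid[gidx, ]
    spec <- survnet_spec(ncol(feats_tuning), gr$hidden, gr$dropout)
    fit <- train_lfsurv(
      train = list(
        features = feats_tuning[ts$train_ids, , drop = FALSE],
        surv = surv_by(ts$train_ids)
      ),
      valid = list(
        features = feats_tuning[ts$valid_ids, , drop = FALSE],
        surv = surv_by(ts$valid_ids)
      ),
      spec = spec, lambda2 = gr$lambda2, lr = config$surv_lr,
      n_epochs = config$surv_epochs, seed = seed_r
    )
    if (is.null(best) || fit$valid_cindex > best$valid_cindex) {
      best <- list(
        valid_cindex = fit$valid_cindex, hidden = gr$hidden,
        dropout = gr$dropout, lambda2 = gr$lambda2, spec = spec, gr = gr
      )
    }
  }
  rownames_all <- rownames(feats_tuning)
  best$refit <- train_lfsurv(
    train = list(features = feats_tuning, surv = surv_by(rownames_all)),
    valid = NULL, spec = best$spec, lambda2 = best$gr$lambda2,
    lr = config$surv_lr, n_epochs = config$surv_epochs, seed = seed_r
  )
  best
}

#' Compare matched experiment reports by Wilcoxon signed-rank
#'
#' Pairwise two-sided signed-rank tests on testing-set C-indices from runs
#' built on identical split plans (same testing set, same tuning
#' re-splits); mismatched plans are an error because the pairing would be
#' invalid.
#'
#' @param reports Named list of `experiment_report`s.
#' @return A tibble of pairwise rows: `model_a`, `model_b`,
#'   `median_a`, `median_b`, `statistic`, `p_value`.
#' @export
compare_models <- function(reports) {
  stopifnot(length(reports) >= 2)
  if (is.null(names(reports))) names(reports) <- paste0("model_", seq_along(reports))
  ref_plan <- reports[[1]]$plan
  for (rp in reports[-1]) {
    if (!identical(sort(rp$plan$test_ids), sort(ref_plan$test_ids)) ||
        !identical(rp$repeats$seed, reports[[1]]$repeats$seed)) {
      stop("reports were not built on identical split plans")
    }
  }
  pairs <- utils::combn(names(reports), 2, simplify = FALSE)
  purrr::map_dfr(pairs, function(pr) {
    a <- reports[[pr[1]]]$repeats$test_cindex
    b <- reports[[pr[2]]]$repeats$test_cindex
    wt <- wilcoxon_signed_rank(a, b)
    tibble::tibble(
      model_a = pr[1], model_b = pr[2],
      median_a = stats::median(a), median_b = stats::median(b),
      statistic = wt$statistic, p_value = wt$p_value
    )
  })
}
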