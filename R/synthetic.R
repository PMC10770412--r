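#' Configuration for a synthetic multi-omics survival cohort
#'
#' Defines a cohort with the statistical structure the modelling pipeline
#' assumes: a set of latent factors partially shared between the gene and
#' miRNA blocks, pathway-structured gene loadings (each pathway's genes load
#' on the same small factor subset), clinical covariates, and
#' proportional-hazards survival with independent right censoring.
#'
#' @param n_samples,n_genes,n_miRNAs,n_pathways Cohort dimensions.
#' @param d_true Number of true latent factors.
#' @param shared_fraction Fraction of factors loading on BOTH omics blocks;
#'   the remainder is split between gene-specific and miRNA-specific factors.
#' @param effect_weights Numeric vector of length `d_true + 2` (latent
#'   factors, then age and high-stage indicator) defining the true log-hazard.
#' @param baseline_shape,baseline_scale Weibull baseline hazard parameters.
#' @param censoring_rate_target Desired fraction of censored subjects.
#' @param noise_sd Gaussian noise added on the linear scale before the
#'   logistic squashing that keeps expression in (0, 1).
#' @param loading_scale Multiplier on the factor loadings (signal strength).
#' @param seed Integer seed; generation is fully deterministic given it.
#' @return A `synthetic_config` list.
#' @export
synthetic_config <- function(n_samples = 400, n_genes = 120, n_miRNAs = 30,
                             n_pathways = 8, d_true = 8, shared_fraction = 0.5,
                             effect_weights = c(rep(1, 8), 0.5, 0.5),
                             baseline_shape = 1.5, baseline_scale = 0.1,
                             censoring_rate_target = 0.3, noise_sd = 0.3,
                             loading_scale = 1, seed = 1L) {
  stopifnot(
    n_samples > 0, n_genes > 0, n_miRNAs > 0, n_pathways > 0, d_true > 0,
    shared_fraction >= 0, shared_fraction <= 1,
    length(effect_weights) == d_true + 2,
    baseline_shape > 0, baseline_scale > 0,
    censoring_rate_target > 0, censoring_rate_target < 1, noise_sd > 0
  )
  structure(
    list(
      n_samples = n_samples, n_genes = n_genes, n_miRNAs = n_miRNAs,
      n_pathways = n_pathways, d_true = d_true,
      shared_fraction = shared_fraction, effect_weights = effect_weights,
      baseline_shape = baseline_shape, baseline_scale = baseline_scale,
      censoring_rate_target = censoring_rate_target, noise_sd = noise_sd,
      loading_scale = loading_scale, seed = as.integer(seed)
    ),
    class = "synthetic_config"
  )
}

#' Generate a synthetic multi-omics survival cohort
#'
#' Draws standard-normal latent factors, builds pathway-blocked gene
#' loadings and miRNA loadings over the shared factor subset plus
#' miRNA-specific factors, squashes noisy linear combinations through a
#' logistic so expression lies in (0, 1), and simulates Weibull
#' proportional-hazards survival, `T = (-log U / (scale * exp(pi)))^(1/shape)`,
#' with the true prognostic index `pi = effect_weights . [z, age, stage_h]`.
#' Independent exponential censoring is calibrated by bisection so the
#' realised censoring rate approximates the target.
#'
#' @param config A [synthetic_config()].
#' @return A `synthetic_dataset` list: `gene` and `miRNA` blocks
#'   ([omics_matrix()]), `clinical` and `survival` tibbles, a
#'   [pathway_collection()] matching the gene blocks, the true latent matrix,
#'   the true prognostic index, and the factor-assignment bookkeeping
#'   (`pathway_factors`, `gene_loadings`, `mirna_loadings`).
#' @examples
#' cohort <- generate_cohort(synthetic_config(n_samples = 50, seed = 7))
#' achieved_event_rate(cohort$survival)
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  cfg <- config
  with_seed(cfg$seed, {
    n <- cfg$n_samples
    d <- cfg$d_true
    n_shared <- round(cfg$shared_fraction * d)
    shared <- seq_len(n_shared)
    specific <- setdiff(seq_len(d), shared)
    gene_specific <- specific[seq_len(ceiling(length(specific) / 2))]
    mirna_specific <- setdiff(specific, gene_specific)
    gene_factors <- c(shared, gene_specific)
    mirna_factors <- c(shared, mirna_specific)
    if (length(gene_factors) == 0) gene_factors <- seq_len(d)
    if (length(mirna_factors) == 0) mirna_factors <- seq_len(d)

    z <- matrix(stats::rnorm(n * d), n, d)
    sample_ids <- sprintf("s%04d", seq_len(n))
    rownames(z) <- sample_ids
    colnames(z) <- paste0("factor_", seq_len(d))

    # genes partitioned into pathway blocks; each pathway loads on 1-2 factors
    gene_ids <- sprintf("gene%04d", seq_len(cfg$n_genes))
    block <- rep(seq_len(cfg$n_pathways), length.out = cfg$n_genes)
    block <- sort(block)
    pathway_factors <- lapply(seq_len(cfg$n_pathways), function(p) {
      k <- 1 + (p %% 2)
      idx <- ((p - 1 + seq_len(k) - 1) %% length(gene_factors)) + 1
      unique(gene_factors[idx])
    })
    L_gene <- matrix(0, cfg$n_genes, d, dimnames = list(gene_ids, colnames(z)))
    for (g in seq_len(cfg$n_genes)) {
      f <- pathway_factors[[block[g]]]
      L_gene[g, f] <- stats::rnorm(length(f), mean = 1, sd = 0.25) *
        sample(c(-1, 1), length(f), replace = TRUE)
    }
    mirna_ids <- sprintf("mir%03d", seq_len(cfg$n_miRNAs))
    L_mirna <- matrix(0, cfg$n_miRNAs, d, dimnames = list(mirna_ids, colnames(z)))
    for (m in seq_len(cfg$n_miRNAs)) {
      f <- mirna_factors[((m - 1) %% length(mirna_factors)) + 1]
      L_mirna[m, f] <- stats::rnorm(1, mean = 1, sd = 0.25) * sample(c(-1, 1), 1)
    }

    squash <- function(lin) 1 / (1 + exp(-lin))
    gene_vals <- squash(
      cfg$loading_scale * (z %*% t(L_gene)) +
        matrix(stats::rnorm(n * cfg$n_genes, sd = cfg$noise_sd), n, cfg$n_genes)
    )
    mirna_vals <- squash(
      cfg$loading_scale * (z %*% t(L_mirna)) +
        matrix(stats::rnorm(n * cfg$n_miRNAs, sd = cfg$noise_sd), n, cfg$n_miRNAs)
    )
    dimnames(gene_vals) <- list(sample_ids, gene_ids)
    dimnames(mirna_vals) <- list(sample_ids, mirna_ids)

    age <- stats::runif(n)
    stage_h <- stats::rbinom(n, 1, 0.3)
    clinical <- tibble::tibble(sample_id = sample_ids, age = age, stage_h = stage_h)

    w <- cfg$effect_weights
    true_pi <- as.numeric(cbind(z, age, stage_h) %*% w)

    u <- stats::runif(n)
    t_event <- (-log(u) / (cfg$baseline_scale * exp(true_pi)))^(1 / cfg$baseline_shape)
    v <- stats::runif(n)
    cens <- calibrate_censoring(t_event, v, cfg$censoring_rate_target)
    time <- pmin(t_event, cens$times)
    event <- as.integer(t_event <= cens$times)

    pathways <- pathway_collection(
      stats::setNames(
        lapply(seq_len(cfg$n_pathways), function(p) gene_ids[block == p]),
        sprintf("PW%02d", seq_len(cfg$n_pathways))
      )
    )

    structure(
      list(
        gene = omics_matrix(gene_vals, omics_kind = "gene"),
        miRNA = omics_matrix(mirna_vals, omics_kind = "miRNA"),
        clinical = clinical,
        survival = survival_table(
          tibble::tibble(sample_id = sample_ids, time = time, event = event)
        ),
        pathways = pathways,
        true_latent = z,
        true_pi = true_pi,
        pathway_factors = pathway_factors,
        gene_loadings = L_gene,
        mirna_loadings = L_mirna,
        config = cfg
      ),
      class = "synthetic_dataset"
    )
  })
}

# bisection on the exponential censoring rate so that, with the drawn
# uniforms held fixed, the realised censored fraction matches the target
calibrate_censoring <- function(t_event, v, target, tol = 0.005) {
  cens_frac <- function(rate) {
    mean((-log(v) / rate) < t_event)
  }
  lo <- 1e-8
  hi <- 1
  while (cens_frac(hi) < target && hi < 1e8) hi <- hi * 2
  if (cens_frac(hi) < target) {
    warning(sprintf(
      "censoring target %.2f infeasible; achieved %.3f", target, cens_frac(hi)
    ))
    return(list(times = -log(v) / hi, rate = hi))
  }
  rate <- hi
  for (i in 1:200) {
    mid <- sqrt(lo * hi)
    if (cens_frac(mid) < target) lo <- mid else hi <- mid
    rate <- mid
    if (abs(cens_frac(mid) - target) <= tol) break
  }
  list(times = -log(v) / rate, rate = rate)
}

#' Realised event rate of a cohort
#'
#' @param survival A survival tibble (columns `sample_id`, `time`, `event`)
#'   or a `synthetic_dataset`.
#' @return The proportion of subjects with an observed event,
#'   `(#events) / (#samples)`.
#' @examples
#' achieved_event_rate(tibble::tibble(
#'   sample_id = as.character(1:4), time = 1:4, event = c(1, 0, 0, 1)
#' ))
#' @export
achieved_event_rate <- function(survival) {
  if (inherits(survival, "synthetic_dataset")) survival <- survival$survival
  stopifnot(nrow(survival) > 0)
  mean(survival$event)
}

#' Write a synthetic cohort to disk in the formats the readers accept
#'
#' Emits gene/miRNA expression TSVs, clinical and survival TSVs, a GMT file,
#' and a ground-truth TSV (true latent factors and true prognostic index)
#' for recovery experiments.
#'
#' @param dataset A `synthetic_dataset`.
#' @param dir Output directory (created if missing).
#' @return Invisibly, the named vector of written paths.
#' @export
write_cohort <- function(dataset, dir) {
  stopifnot(inherits(dataset, "synthetic_dataset"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    gene = file.path(dir, "gene_expression.tsv"),
    miRNA = file.path(dir, "mirna_expression.tsv"),
    clinical = file.path(dir, "clinical.tsv"),
    survival = file.path(dir, "survival.tsv"),
    pathways = file.path(dir, "pathways.gmt"),
    truth = file.path(dir, "ground_truth.tsv")
  )
  write_expression_tsv(dataset$gene, paths["gene"])
  write_expression_tsv(dataset$miRNA, paths["miRNA"])
  utils::write.table(dataset$clinical, paths["clinical"],
    sep = "\t", quote = FALSE, row.names = FALSE
  )
  utils::write.table(dataset$survival, paths["survival"],
    sep = "\t", quote = FALSE, row.names = FALSE
  )
  write_gmt(dataset$pathways, paths["pathways"])
  truth <- data.frame(
    sample_id = rownames(dataset$true_latent),
    dataset$true_latent,
    true_pi = dataset$true_pi,
    check.names = FALSE
  )
  utils::write.table(truth, paths["truth"],
    sep = "\t", quote = FALSE, row.names = FALSE
  )
  invisible(paths)
}
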