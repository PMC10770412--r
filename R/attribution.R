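# Attribution works on an explicit sequential representation of the trained
# networks: a list of layers, each either an affine transform ("linear":
# weights + bias), an elementwise activation ("act": one function name per
# unit), or an inference-mode batch norm ("bn": per-unit scale and shift).
# Inference-mode batch norm is affine, so folding it into the neighbouring
# linear layer is exact; the DeepLIFT linear and rescale rules then apply
# layer by layer.

seq_network <- function(layers, input_ids, output_ids) {
  structure(
    list(layers = layers, input_ids = input_ids, output_ids = output_ids),
    class = "seq_network"
  )
}

layer_linear <- function(W, b = NULL) {
  if (is.null(b)) b <- rep(0, ncol(W))
  list(type = "linear", W = W, b = b)
}

layer_act <- function(fun, width) {
  list(type = "act", fun = rep(fun, length.out = width))
}

# inference-mode batch norm as scale/shift
layer_bn <- function(bn_params, stats, eps = 1e-5) {
  if (any(stats$var + eps <= 0)) stop("zero running variance in batch norm")
  a <- bn_params$gamma / sqrt(stats$var + eps)
  list(type = "bn", a = a, c = bn_params$beta - a * stats$mean)
}

act_apply <- function(fun, x) {
  out <- x
  for (f in unique(fun)) {
    idx <- which(fun == f)
    out[, idx] <- switch(f,
      relu = pmax(x[, idx, drop = FALSE], 0),
      tanh = tanh(x[, idx, drop = FALSE]),
      sigmoid = 1 / (1 + exp(-x[, idx, drop = FALSE])),
      identity = x[, idx, drop = FALSE],
      stop("unknown activation: ", f)
    )
  }
  out
}

act_deriv <- function(fun, x) {
  out <- x
  for (f in unique(fun)) {
    idx <- which(fun == f)
    xi <- x[, idx, drop = FALSE]
    out[, idx] <- switch(f,
      relu = (xi > 0) * 1,
      tanh = 1 - tanh(xi)^2,
      sigmoid = {
        s <- 1 / (1 + exp(-xi))
        s * (1 - s)
      },
      identity = xi * 0 + 1
    )
  }
  out
}

#' Evaluate a sequential network
#'
#' @param network A `seq_network` (see [fold_inference_transforms()]).
#' @param x Input matrix (samples x inputs).
#' @return The output matrix.
#' @export
net_forward <- function(network, x) {
  for (ly in network$layers) {
    x <- switch(ly$type,
      linear = sweep(x %*% ly$W, 2, ly$b, "+"),
      act = act_apply(ly$fun, x),
      bn = sweep(sweep(x, 2, ly$a, "*"), 2, ly$c, "+")
    )
  }
  if (!all(is.finite(x))) stop("non-finite activations in network forward pass")
  x
}

#' Fold inference-mode batch norms into neighbouring affine layers
#'
#' A batch norm in inference mode is the elementwise affine map
#' `a * x + c`; it is absorbed exactly into the adjacent linear transform,
#' and consecutive linear layers are merged. Folding is idempotent and the
#' folded network reproduces the original outputs to machine precision,
#' which lets the layer-wise attribution rules treat every transform as
#' either linear or an elementwise nonlinearity.
#'
#' @param network A `seq_network`.
#' @return The folded `seq_network` containing only alternating linear and
#'   activation layers.
#' @export
fold_inference_transforms <- function(network) {
  layers <- lapply(network$layers, function(ly) {
    if (ly$type == "bn") {
      layer_linear(diag(ly$a, length(ly$a)), ly$c)
    } else {
      ly
    }
  })
  out <- list()
  for (ly in layers) {
    k <- length(out)
    if (ly$type == "linear" && k > 0 && out[[k]]$type == "linear") {
      prev <- out[[k]]
      out[[k]] <- layer_linear(prev$W %*% ly$W, as.numeric(prev$b %*% ly$W) + ly$b)
    } else {
      out[[k + 1]] <- ly
    }
  }
  seq_network(out, network$input_ids, network$output_ids)
}

# forward pass retaining pre-activation inputs of every layer
net_forward_trace <- function(network, x) {
  trace <- vector("list", length(network$layers))
  for (i in seq_along(network$layers)) {
    ly <- network$layers[[i]]
    trace[[i]] <- x
    x <- switch(ly$type,
      linear = sweep(x %*% ly$W, 2, ly$b, "+"),
      act = act_apply(ly$fun, x),
      bn = sweep(sweep(x, 2, ly$a, "*"), 2, ly$c, "+")
    )
  }
  list(out = x, inputs = trace)
}

#' DeepLIFT attributions for one sample against one or many references
#'
#' Propagates difference-from-reference multipliers backward through a
#' folded network: linear layers use the linear rule (the weight matrix),
#' elementwise nonlinearities the rescale rule (multiplier = difference in
#' output over difference in input, falling back to the analytic derivative
#' when the input difference is below 1e-7). The returned contributions
#' satisfy summation-to-delta: they sum to the difference between the
#' sample's output and the reference's output.
#'
#' @param network A folded `seq_network` (batch norms folded; see
#'   [fold_inference_transforms()]; unfolded batch norms are handled as
#'   affine layers).
#' @param x Numeric vector: the explained sample.
#' @param x_ref Numeric vector or matrix (one reference per row).
#' @param target Output neuron index or name.
#' @return A matrix (references x inputs) of contribution scores; one row
#'   per reference.
#' @export
deeplift_attributions <- function(network, x, x_ref, target = 1L) {
  x <- matrix(as.numeric(x), nrow = 1)
  if (is.null(dim(x_ref))) x_ref <- matrix(as.numeric(x_ref), nrow = 1)
  if (ncol(x) != ncol(x_ref)) stop("sample and reference shapes differ")
  if (is.character(target)) target <- match(target, network$output_ids)
  R <- nrow(x_ref)
  tr_x <- net_forward_trace(network, x)
  tr_r <- net_forward_trace(network, x_ref)
  if (!all(is.finite(tr_x$out)) || !all(is.finite(tr_r$out))) {
    stop("non-finite activations")
  }
  out_width <- ncol(tr_x$out)
  M <- matrix(0, R, out_width)
  M[, target] <- 1
  for (i in rev(seq_along(network$layers))) {
    ly <- network$layers[[i]]
    if (ly$type == "linear") {
      M <- M %*% t(ly$W)
    } else if (ly$type == "bn") {
      M <- sweep(M, 2, ly$a, "*")
    } else {
      pre_x <- tr_x$inputs[[i]][rep(1, R), , drop = FALSE]
      pre_r <- tr_r$inputs[[i]]
      d_in <- pre_x - pre_r
      d_out <- act_apply(ly$fun, pre_x) - act_apply(ly$fun, pre_r)
      r <- ifelse(abs(d_in) < 1e-7, act_deriv(ly$fun, pre_x), d_out / d_in)
      M <- M * r
    }
  }
  contrib <- M * (x[rep(1, R), , drop = FALSE] - x_ref)
  colnames(contrib) <- network$input_ids
  contrib
}

#' DeepSHAP contribution scores over a reference population
#'
#' For each explained sample the SHAP value of a feature is its DeepLIFT
#' contribution averaged over the reference samples (the low-risk group);
#' the per-feature overall contribution score is the mean absolute SHAP
#' value across the explained (high-risk) samples.
#'
#' @param network A `seq_network`; batch norms are folded automatically.
#' @param explained Matrix of explained samples (rows; typically high risk).
#' @param references Matrix of reference samples (rows; typically low risk).
#' @param target Output neuron index or name.
#' @param check_tol Relative tolerance for the summation-to-delta check
#'   (default 1e-4).
#' @return An `attribution_table`: `shap` (explained x features), `overall`
#'   tibble (`feature`, `overall` = mean |SHAP|, descending), sample ids and
#'   the target label.
#' @export
deepshap_scores <- function(network, explained, references, target = 1L,
                            check_tol = 1e-4) {
  stopifnot(nrow(explained) > 0, nrow(references) > 0)
  network <- fold_inference_transforms(network)
  if (is.character(target)) target <- match(target, network$output_ids)
  out_x <- net_forward(network, explained)[, target]
  out_r <- net_forward(network, references)[, target]
  shap <- matrix(0, nrow(explained), ncol(explained),
    dimnames = list(rownames(explained), network$input_ids)
  )
  for (i in seq_len(nrow(explained))) {
    contrib <- deeplift_attributions(
      network, explained[i, ], references, target
    )
    # summation-to-delta per (explained, reference) pair
    delta <- out_x[i] - out_r
    err <- abs(rowSums(contrib) - delta)
    if (any(err > check_tol * pmax(1, abs(delta)))) {
      stop("summation-to-delta violated beyond tolerance")
    }
    shap[i, ] <- colMeans(contrib)
  }
  overall <- tibble::tibble(
    feature = colnames(shap),
    overall = unname(colMeans(abs(shap)))
  )
  overall <- dplyr::arrange(overall, dplyr::desc(.data$overall), .data$feature)
  structure(
    list(
      shap = shap, overall = overall,
      explained_sample_ids = rownames(explained),
      reference_sample_ids = rownames(references),
      target = network$output_ids[target] %||% target
    ),
    class = "attribution_table"
  )
}

#' Rank the survival-network inputs by overall contribution
#'
#' @param table An `attribution_table` targeting the prognostic index.
#' @return Character vector of feature ids sorted by descending overall
#'   score (ties broken alphabetically for determinism).
#' @export
rank_latent_features <- function(table) {
  stopifnot(inherits(table, "attribution_table"))
  table$overall$feature
}

#' Identify key input factors across latent-feature attributions
#'
#' A gene or miRNA ranking in the top `top_k` contributors for more than
#' one of the supplied latent-feature targets is a Key Input Factor (KIF);
#' applying the same rule to pathway-node attributions yields Key Pathway
#' Factors (KPFs).
#'
#' @param per_latent_tables Named list of `attribution_table`s, one per
#'   latent target (at least two for a meaningful report).
#' @param top_k List length considered "high contribution" (default 10).
#' @return A `key_factor_report`: tibble `factors` (`feature`, `frequency`,
#'   `latents`), plus the per-latent top lists.
#' @export
identify_kif <- function(per_latent_tables, top_k = 10) {
  stopifnot(length(per_latent_tables) >= 1)
  if (is.null(names(per_latent_tables))) {
    names(per_latent_tables) <- paste0("latent_", seq_along(per_latent_tables))
  }
  if (length(per_latent_tables) < 2) {
    warning("fewer than two latent targets: no factor can repeat")
  }
  top_lists <- lapply(per_latent_tables, function(tb) {
    utils::head(tb$overall$feature, top_k)
  })
  counts <- table(unlist(top_lists))
  kif <- names(counts)[counts >= 2]
  factors <- tibble::tibble(
    feature = kif,
    frequency = as.integer(counts[kif]),
    latents = vapply(kif, function(f) {
      paste(names(top_lists)[vapply(top_lists, function(l) f %in% l, logical(1))],
            collapse = ",")
    }, character(1))
  )
  factors <- dplyr::arrange(factors, dplyr::desc(.data$frequency), .data$feature)
  structure(
    list(factors = factors, top_lists = top_lists, top_k = top_k),
    class = "key_factor_report"
  )
}

# ---- builders: trained models -> sequential networks ---------------------

block_diag_linear <- function(W, b, passthrough) {
  if (passthrough == 0) {
    return(layer_linear(W, b))
  }
  n_in <- nrow(W)
  n_out <- ncol(W)
  Wb <- matrix(0, n_in + passthrough, n_out + passthrough)
  Wb[seq_len(n_in), seq_len(n_out)] <- W
  Wb[n_in + seq_len(passthrough), n_out + seq_len(passthrough)] <-
    diag(passthrough)
  layer_linear(Wb, c(b, rep(0, passthrough)))
}

#' Sequential view of a trained survival network (inference mode)
#'
#' @param fit An `lfsurv_fit`.
#' @param input_ids Optional input feature names.
#' @return A `seq_network` mapping features to the prognostic index.
#' @export
build_lfsurv_network <- function(fit, input_ids = NULL) {
  p <- fit$params
  seq_network(
    list(
      layer_linear(p$W1, p$b1),
      layer_act("tanh", ncol(p$W1)),
      layer_linear(p$w2, 0)
    ),
    input_ids %||% paste0("input_", seq_len(nrow(p$W1))),
    "PI"
  )
}

# encoder layers shared by the latent-head and composed networks; clinical
# covariates (if any) ride along as identity passthrough columns
encoder_layers <- function(fit, passthrough = 0) {
  arch <- fit$arch
  p <- fit$model$params
  s <- fit$model$stats
  stopifnot(arch$integration %in% c("entangle", "gene_only", "miRNA_only"))
  layers <- list()
  P <- arch$n_pathway
  m <- arch$n_miRNA
  extra <- m + passthrough
  if (arch$n_gene > 0) {
    layers <- c(layers, list(
      block_diag_linear(p$W_gp * arch$mask, p$b_p, extra),
      list(type = "act", fun = c(rep("relu", P), rep("identity", extra)))
    ))
    if (arch$batchnorm) {
      bn <- layer_bn(p$bn_p, s$bn_p)
      layers <- c(layers, list(list(
        type = "bn",
        a = c(bn$a, rep(1, extra)), c = c(bn$c, rep(0, extra))
      )))
    }
  }
  layers <- c(layers, list(
    block_diag_linear(p$W_h, p$b_h, passthrough),
    list(type = "act",
         fun = c(rep("relu", arch$hidden_width), rep("identity", passthrough)))
  ))
  if (arch$batchnorm) {
    bn <- layer_bn(p$bn_h, s$bn_h)
    layers <- c(layers, list(list(
      type = "bn",
      a = c(bn$a, rep(1, passthrough)), c = c(bn$c, rep(0, passthrough))
    )))
  }
  layers <- c(layers, list(block_diag_linear(p$W_mu, p$b_mu, passthrough)))
  layers
}

encoder_input_ids <- function(fit, gene_ids = NULL, mirna_ids = NULL) {
  arch <- fit$arch
  c(
    if (arch$n_gene > 0) gene_ids %||% rownames(arch$mask),
    if (arch$n_miRNA > 0) mirna_ids %||% paste0("miRNA_", seq_len(arch$n_miRNA))
  )
}

#' Sequential view of the trained encoder up to the latent means
#'
#' @param fit A `kl_pmvae_fit` (entangle or single-omics variant).
#' @param gene_ids,mirna_ids Optional input names.
#' @return A `seq_network` from (gene, miRNA) inputs to all latent means.
#' @export
build_encoder_network <- function(fit, gene_ids = NULL, mirna_ids = NULL) {
  seq_network(
    encoder_layers(fit, passthrough = 0),
    encoder_input_ids(fit, gene_ids, mirna_ids),
    paste0("latent_", seq_len(fit$arch$d_latent))
  )
}

#' Sequential view of the gene-to-pathway-node encoder head
#'
#' Pathway node values are the post-activation (and post-batch-norm) values
#' forwarded to the joint hidden layer.
#'
#' @param fit A `kl_pmvae_fit` with a gene branch.
#' @param gene_ids Optional gene names.
#' @return A `seq_network` from genes to pathway node values.
#' @export
build_pathway_network <- function(fit, gene_ids = NULL) {
  arch <- fit$arch
  stopifnot(arch$n_gene > 0)
  p <- fit$model$params
  s <- fit$model$stats
  layers <- list(
    layer_linear(p$W_gp * arch$mask, p$b_p),
    layer_act("relu", arch$n_pathway)
  )
  if (arch$batchnorm) layers <- c(layers, list(layer_bn(p$bn_p, s$bn_p)))
  seq_network(
    layers,
    gene_ids %||% rownames(arch$mask),
    colnames(arch$mask) %||% paste0("pathway_", seq_len(arch$n_pathway))
  )
}

#' Sequential view from pathway-node values (and miRNA) to latent means
#'
#' The truncated encoder tail: pathway node values are treated as the input
#' layer, so attributions of latent features to pathway nodes follow the
#' same rules as any other layer pair.
#'
#' @param fit A `kl_pmvae_fit` with a gene branch.
#' @param mirna_ids Optional miRNA names.
#' @return A `seq_network` from (pathway nodes, miRNA) to latent means.
#' @export
build_latent_from_pathway_network <- function(fit, mirna_ids = NULL) {
  arch <- fit$arch
  p <- fit$model$params
  s <- fit$model$stats
  layers <- list(
    layer_linear(p$W_h, p$b_h),
    layer_act("relu", arch$hidden_width)
  )
  if (arch$batchnorm) layers <- c(layers, list(layer_bn(p$bn_h, s$bn_h)))
  layers <- c(layers, list(layer_linear(p$W_mu, p$b_mu)))
  seq_network(
    layers,
    c(
      colnames(arch$mask) %||% paste0("pathway_", seq_len(arch$n_pathway)),
      if (arch$n_miRNA > 0) {
        mirna_ids %||% paste0("miRNA_", seq_len(arch$n_miRNA))
      }
    ),
    paste0("latent_", seq_len(arch$d_latent))
  )
}

#' Composed network: raw omics plus clinical covariates to prognostic index
#'
#' Chains the trained encoder (posterior means) with the trained survival
#' network, with clinical covariates passed through untouched, so gene- and
#' miRNA-level contributions to the prognostic index can be attributed in
#' one backward pass.
#'
#' @param vae_fit A `kl_pmvae_fit` (entangle or single-omics).
#' @param surv_fit An `lfsurv_fit` trained on `[latent means, clinical]`.
#' @param clinical_ids Names of the clinical covariates (possibly empty).
#' @param gene_ids,mirna_ids Optional omics input names.
#' @return A `seq_network` from (gene, miRNA, clinical) to the PI.
#' @export
build_composed_network <- function(vae_fit, surv_fit, clinical_ids = character(),
                                   gene_ids = NULL, mirna_ids = NULL) {
  n_clin <- length(clinical_ids)
  layers <- c(
    encoder_layers(vae_fit, passthrough = n_clin),
    list(
      layer_linear(surv_fit$params$W1, surv_fit$params$b1),
      layer_act("tanh", ncol(surv_fit$params$W1)),
      layer_linear(surv_fit$params$w2, 0)
    )
  )
  seq_network(
    layers,
    c(encoder_input_ids(vae_fit, gene_ids, mirna_ids), clinical_ids),
    "PI"
  )
}

#' Draw the explained / reference samples for attribution
#'
#' Takes up to `n_each` high-risk samples (explained) and `n_each` low-risk
#' samples (reference) at random; when fewer are available all are used
#' with a warning.
#'
#' @param groups A `risk_groups` tibble.
#' @param n_each Target group size (default 100).
#' @param seed Integer seed.
#' @return A list with `explained_ids` (high risk) and `reference_ids`
#'   (low risk).
#' @export
sample_attribution_groups <- function(groups, n_each = 100, seed = 1L) {
  hi <- groups$sample_id[groups$risk_group == "high"]
  lo <- groups$sample_id[groups$risk_group == "low"]
  if (length(hi) < n_each || length(lo) < n_each) {
    warning(sprintf(
      "requested %d per group; using %d high-risk and %d low-risk samples",
      n_each, min(n_each, length(hi)), min(n_each, length(lo))
    ))
  }
  with_seed(seed, list(
    explained_ids = sample(hi, min(n_each, length(hi))),
    reference_ids = sample(lo, min(n_each, length(lo)))
  ))
}
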