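#' Architecture of the pathway-masked variational autoencoder
#'
#' The encoder routes gene expression through a sparse gene-to-pathway
#' transform (connections permitted only where the pathway mask is 1,
#' followed by ReLU and batch norm), concatenates the pathway activations
#' with the miRNA layer, passes one fully connected hidden layer (ReLU,
#' batch norm) and emits the latent means and log-variances through two
#' parallel linear heads (no batch norm at the bottleneck). The decoder
#' mirrors this: a shared hidden layer, a sigmoid miRNA branch, and a gene
#' branch through a pathway-level layer whose final transform reuses the
#' transposed mask's sparsity pattern before the sigmoid output.
#'
#' @param mask A `pathway_mask` from [build_pathway_mask()]; required unless
#'   `integration = "miRNA_only"`.
#' @param n_miRNA Number of miRNA features (0 for `"gene_only"`).
#' @param d_latent Latent dimension (default 16).
#' @param hidden_width Width of the fully connected hidden layers (default 128).
#' @param integration `"entangle"` (joint latent space, the default),
#'   `"concatenate"` (two single-omics autoencoders whose latents are joined
#'   afterwards), `"gene_only"` or `"miRNA_only"`.
#' @param batchnorm Apply batch normalisation (default TRUE; every layer
#'   except the latent bottleneck and the sigmoid outputs).
#' @return A `vae_architecture` list.
#' @export
vae_architecture <- function(mask = NULL, n_miRNA = 0, d_latent = 16,
                             hidden_width = 128,
                             integration = c("entangle", "concatenate",
                                             "gene_only", "miRNA_only"),
                             batchnorm = TRUE) {
  integration <- match.arg(integration)
  stopifnot(d_latent >= 1)
  has_gene <- integration != "miRNA_only"
  has_mirna <- integration != "gene_only"
  if (has_gene && is.null(mask)) stop("a pathway mask is required for gene input")
  if (has_mirna && n_miRNA < 1) stop("n_miRNA must be positive for miRNA input")
  structure(
    list(
      mask = if (has_gene) unclass(mask) else NULL,
      n_gene = if (has_gene) nrow(mask) else 0L,
      n_pathway = if (has_gene) ncol(mask) else 0L,
      n_miRNA = if (has_mirna) as.integer(n_miRNA) else 0L,
      d_latent = as.integer(d_latent),
      hidden_width = as.integer(hidden_width),
      integration = integration,
      batchnorm = batchnorm
    ),
    class = "vae_architecture"
  )
}

#' Initialise VAE parameters
#'
#' @param arch A [vae_architecture()].
#' @param seed Integer seed for the weight draws.
#' @param zero Logical; initialise all weights and biases to zero (useful
#'   for hand-checked forward passes).
#' @return A list with trainable `params` and batch-norm running `stats`.
#' @export
vae_init_params <- function(arch, seed = 1L, zero = FALSE) {
  stopifnot(arch$integration != "concatenate")
  has_gene <- arch$n_gene > 0
  has_mirna <- arch$n_miRNA > 0
  P <- arch$n_pathway
  h <- arch$hidden_width
  d <- arch$d_latent
  enc_in <- (if (has_gene) P else 0) + arch$n_miRNA
  init <- function(n_in, n_out) {
    if (zero) matrix(0, n_in, n_out) else nn_init_weight(n_in, n_out)
  }
  with_seed(seed, {
    params <- list()
    stats <- list()
    if (has_gene) {
      params$W_gp <- init(arch$n_gene, P) * arch$mask
      params$b_p <- rep(0, P)
      params$bn_p <- list(gamma = rep(1, P), beta = rep(0, P))
      stats$bn_p <- list(mean = rep(0, P), var = rep(1, P))
    }
    params$W_h <- init(enc_in, h)
    params$b_h <- rep(0, h)
    params$bn_h <- list(gamma = rep(1, h), beta = rep(0, h))
    stats$bn_h <- list(mean = rep(0, h), var = rep(1, h))
    params$W_mu <- init(h, d)
    params$b_mu <- rep(0, d)
    params$W_lv <- init(h, d)
    params$b_lv <- rep(0, d)
    params$W_zh <- init(d, h)
    params$b_zh <- rep(0, h)
    params$bn_zh <- list(gamma = rep(1, h), beta = rep(0, h))
    stats$bn_zh <- list(mean = rep(0, h), var = rep(1, h))
    if (has_mirna) {
      params$W_hm <- init(h, arch$n_miRNA)
      params$b_hm <- rep(0, arch$n_miRNA)
    }
    if (has_gene) {
      params$W_hp <- init(h, P)
      params$b_hp <- rep(0, P)
      params$bn_hp <- list(gamma = rep(1, P), beta = rep(0, P))
      stats$bn_hp <- list(mean = rep(0, P), var = rep(1, P))
      params$W_pg <- init(P, arch$n_gene) * t(arch$mask)
      params$b_pg <- rep(0, arch$n_gene)
    }
    list(params = params, stats = stats)
  })
}

bn_fwd <- function(x, bn_params, stats, training, momentum = 0.1) {
  bn <- list(
    gamma = bn_params$gamma, beta = bn_params$beta,
    running_mean = stats$mean, running_var = stats$var
  )
  res <- nn_bn_forward(x, bn, training = training, momentum = momentum)
  list(
    out = res$out,
    stats = list(mean = res$bn$running_mean, var = res$bn$running_var),
    cache = res$cache
  )
}

#' Encode expression into a latent posterior
#'
#' @param x_gene,x_miRNA Numeric matrices (samples x features) in [0, 1];
#'   either may be NULL for single-omics variants.
#' @param arch A [vae_architecture()].
#' @param model Parameter list from [vae_init_params()] or a trained fit's
#'   `model` element.
#' @param training Logical; batch statistics (TRUE) vs running statistics
#'   (FALSE, the inference default).
#' @return A `latent_posterior` list with matrices `mu` and `logvar`.
#' @export
encode <- function(x_gene, x_miRNA, arch, model, training = FALSE) {
  fw <- vae_encode_forward(x_gene, x_miRNA, arch, model$params, model$stats, training)
  structure(list(mu = fw$mu, logvar = fw$logvar), class = "latent_posterior")
}

vae_encode_forward <- function(x_gene, x_miRNA, arch, params, stats, training) {
  caches <- list()
  parts <- list()
  if (arch$n_gene > 0) {
    if (ncol(x_gene) != arch$n_gene) stop("gene input does not match the mask")
    lin_p <- nn_linear_forward(x_gene, params$W_gp * arch$mask, params$b_p)
    act_p <- nn_relu_forward(lin_p$out)
    a_p <- act_p$out
    if (arch$batchnorm) {
      bnp <- bn_fwd(a_p, params$bn_p, stats$bn_p, training)
      a_p <- bnp$out
      stats$bn_p <- bnp$stats
      caches$bn_p <- bnp$cache
    }
    caches$lin_p <- lin_p
    caches$act_p <- act_p
    parts$pathway <- a_p
  }
  if (arch$n_miRNA > 0) {
    if (ncol(x_miRNA) != arch$n_miRNA) stop("miRNA input width mismatch")
    parts$mirna <- x_miRNA
  }
  concat <- do.call(cbind, unname(parts))
  lin_h <- nn_linear_forward(concat, params$W_h, params$b_h)
  act_h <- nn_relu_forward(lin_h$out)
  a_h <- act_h$out
  if (arch$batchnorm) {
    bnh <- bn_fwd(a_h, params$bn_h, stats$bn_h, training)
    a_h <- bnh$out
    stats$bn_h <- bnh$stats
    caches$bn_h <- bnh$cache
  }
  caches$lin_h <- lin_h
  caches$act_h <- act_h
  mu <- nn_linear_forward(a_h, params$W_mu, params$b_mu)$out
  logvar <- nn_linear_forward(a_h, params$W_lv, params$b_lv)$out
  dimnames(mu) <- list(rownames(concat), paste0("latent_", seq_len(ncol(mu))))
  dimnames(logvar) <- dimnames(mu)
  list(
    mu = mu, logvar = logvar, caches = caches,
    concat = concat, a_h = a_h, stats = stats
  )
}

#' Sample latent variables by the reparameterization trick
#'
#' `zhat = mu + sigma * epsilon` with `sigma = exp(logvar / 2)`, so the
#' stochastic draw is external noise and gradients flow through the
#' posterior parameters.
#'
#' @param post A `latent_posterior` from [encode()].
#' @param epsilon Noise matrix of the same shape as `post$mu`; drawn
#'   standard normal when omitted.
#' @return The sampled latent matrix.
#' @examples
#' post <- structure(
#'   list(mu = matrix(1), logvar = matrix(log(4))),
#'   class = "latent_posterior"
#' )
#' reparameterize(post, epsilon = matrix(0.5)) # 1 + 2 * 0.5 = 2
#' @export
reparameterize <- function(post, epsilon = NULL) {
  if (is.null(epsilon)) {
    epsilon <- matrix(stats::rnorm(length(post$mu)), nrow(post$mu), ncol(post$mu))
  }
  stopifnot(all(dim(epsilon) == dim(post$mu)))
  post$mu + exp(post$logvar / 2) * epsilon
}

#' Decode latent variables into reconstructed expression
#'
#' @param zhat Latent matrix (samples x d_latent).
#' @param arch A [vae_architecture()].
#' @param model Parameter list (`params` + `stats`).
#' @param training Logical as in [encode()].
#' @return A list with `x_gene` and/or `x_miRNA` reconstructions, all values
#'   in (0, 1).
#' @export
decode <- function(zhat, arch, model, training = FALSE) {
  fw <- vae_decode_forward(zhat, arch, model$params, model$stats, training)
  list(x_gene = fw$x_gene, x_miRNA = fw$x_miRNA)
}

vae_decode_forward <- function(zhat, arch, params, stats, training) {
  if (ncol(zhat) != arch$d_latent) stop("latent width mismatch")
  caches <- list()
  lin_zh <- nn_linear_forward(zhat, params$W_zh, params$b_zh)
  act_zh <- nn_relu_forward(lin_zh$out)
  hd <- act_zh$out
  if (arch$batchnorm) {
    bnz <- bn_fwd(hd, params$bn_zh, stats$bn_zh, training)
    hd <- bnz$out
    stats$bn_zh <- bnz$stats
    caches$bn_zh <- bnz$cache
  }
  caches$lin_zh <- lin_zh
  caches$act_zh <- act_zh
  x_mirna <- NULL
  if (arch$n_miRNA > 0) {
    logits_m <- nn_linear_forward(hd, params$W_hm, params$b_hm)
    x_mirna <- nn_sigmoid_forward(logits_m$out)$out
    caches$logits_m <- logits_m
  }
  x_gene <- NULL
  if (arch$n_gene > 0) {
    lin_hp <- nn_linear_forward(hd, params$W_hp, params$b_hp)
    act_hp <- nn_relu_forward(lin_hp$out)
    pd <- act_hp$out
    if (arch$batchnorm) {
      bnhp <- bn_fwd(pd, params$bn_hp, stats$bn_hp, training)
      pd <- bnhp$out
      stats$bn_hp <- bnhp$stats
      caches$bn_hp <- bnhp$cache
    }
    logits_g <- nn_linear_forward(pd, params$W_pg * t(arch$mask), params$b_pg)
    x_gene <- nn_sigmoid_forward(logits_g$out)$out
    caches$lin_hp <- lin_hp
    caches$act_hp <- act_hp
    caches$logits_g <- logits_g
    caches$pd <- pd
  }
  list(
    x_gene = x_gene, x_miRNA = x_mirna, hd = hd,
    caches = caches, stats = stats
  )
}

bce_clamp <- 1e-7

bce_sum_mean <- function(x, xhat) {
  xh <- pmin(pmax(xhat, bce_clamp), 1 - bce_clamp)
  sum(-(x * log(xh) + (1 - x) * log(1 - xh))) / nrow(x)
}

#' Compound VAE loss
#'
#' Binary cross-entropy reconstruction terms for each omics block (summed
#' over features, averaged over samples), the closed-form Gaussian KL
#' divergence to the standard-normal prior weighted by the annealing
#' coefficient `beta`, and an L2-norm penalty on the trainable parameters:
#' `total = bce_gene + bce_miRNA + beta * kl + lambda1 * ||theta||_2`.
#'
#' @param x_gene,x_miRNA Inputs in [0, 1] (either may be NULL).
#' @param xhat_gene,xhat_miRNA Reconstructions in (0, 1); values are clamped
#'   inside `(1e-7, 1 - 1e-7)` before the log to avoid infinite loss.
#' @param post The `latent_posterior` used for the draw.
#' @param beta KL weight in [0, 1].
#' @param lambda1 L2 regularisation weight.
#' @param params Trainable parameter tree (only needed when `lambda1 > 0`).
#' @return A `vae_loss_terms` list: `bce_gene`, `bce_miRNA`, `kl`,
#'   `l2_penalty`, `total`.
#' @export
vae_loss <- function(x_gene, x_miRNA, xhat_gene, xhat_miRNA, post,
                     beta = 1, lambda1 = 0, params = NULL) {
  bce_g <- if (!is.null(x_gene)) bce_sum_mean(x_gene, xhat_gene) else 0
  bce_m <- if (!is.null(x_miRNA)) bce_sum_mean(x_miRNA, xhat_miRNA) else 0
  kl <- gaussian_kl(post)
  l2 <- if (!is.null(params)) ptree_l2norm(params) else 0
  structure(
    list(
      bce_gene = bce_g, bce_miRNA = bce_m, kl = kl, l2_penalty = l2,
      total = bce_g + bce_m + beta * kl + lambda1 * l2
    ),
    class = "vae_loss_terms"
  )
}

# 0.5 * sum(mu^2 + sigma^2 - log sigma^2 - 1) per sample, averaged
gaussian_kl <- function(post) {
  s2 <- exp(post$logvar)
  sum(0.5 * (post$mu^2 + s2 - post$logvar - 1)) / nrow(post$mu)
}

#' Cyclical KL-annealing schedule
#'
#' Divides `n_epochs` into `n_cycles` equal cycles (remainder absorbed by
#' the last). Within a cycle of length L the KL weight ramps linearly,
#' `beta(e) = min(1, e / (cutting_ratio * L))` for epoch index e starting at
#' 0, and stays at 1 for the rest of the cycle, so every cycle starts near 0
#' and ends at 1. `cutting_ratio = 0` gives the conventional VAE objective
#' (`beta` identically 1). When `cutting_ratio * L < 1` the ramp degenerates
#' to a single `beta = 0` epoch followed by 1.
#'
#' @param n_epochs,n_cycles Positive integers.
#' @param cutting_ratio Fraction of each cycle spent ramping, in [0, 1].
#' @return An `annealing_schedule` list with the per-epoch `beta_path`.
#' @examples
#' beta_schedule(5, 1, 0.5)$beta_path # 0 0.4 0.8 1 1
#' @export
beta_schedule <- function(n_epochs, n_cycles = 1, cutting_ratio = 0.5) {
  stopifnot(n_epochs >= 0, n_cycles >= 1, cutting_ratio >= 0, cutting_ratio <= 1)
  if (n_epochs == 0) {
    return(structure(
      list(n_epochs = 0L, n_cycles = n_cycles, cutting_ratio = cutting_ratio,
           beta_path = numeric(0)),
      class = "annealing_schedule"
    ))
  }
  base_len <- n_epochs %/% n_cycles
  lens <- rep(base_len, n_cycles)
  lens[n_cycles] <- lens[n_cycles] + n_epochs %% n_cycles
  beta_path <- unlist(lapply(lens, function(L) {
    e <- seq_len(L) - 1
    if (cutting_ratio == 0) rep(1, L) else pmin(1, e / (cutting_ratio * L))
  }))
  # a cycle always finishes at the full objective
  ends <- cumsum(lens)
  beta_path[ends] <- 1
  structure(
    list(n_epochs = as.integer(n_epochs), n_cycles = as.integer(n_cycles),
         cutting_ratio = cutting_ratio, beta_path = beta_path),
    class = "annealing_schedule"
  )
}

# full forward + backward pass for one batch; returns loss terms and the
# gradient tree matching the trainable parameters
vae_batch_grad <- function(x_gene, x_miRNA, arch, params, stats, beta, lambda1,
                           epsilon = NULL) {
  n <- if (!is.null(x_gene)) nrow(x_gene) else nrow(x_miRNA)
  enc <- vae_encode_forward(x_gene, x_miRNA, arch, params, stats, training = TRUE)
  post <- list(mu = enc$mu, logvar = enc$logvar)
  if (is.null(epsilon)) {
    epsilon <- matrix(stats::rnorm(length(post$mu)), n, arch$d_latent)
  }
  sigma <- exp(post$logvar / 2)
  zhat <- post$mu + sigma * epsilon
  dec <- vae_decode_forward(zhat, arch, params, stats, training = TRUE)
  stats <- dec$stats
  for (nm in names(enc$stats)) stats[[nm]] <- enc$stats[[nm]]

  loss <- vae_loss(x_gene, x_miRNA, dec$x_gene, dec$x_miRNA, post,
    beta = beta, lambda1 = lambda1, params = params
  )

  g <- ptree_map(params, function(p) p * 0)
  dhd <- matrix(0, n, arch$hidden_width)

  if (arch$n_gene > 0) {
    dlogits_g <- (dec$x_gene - x_gene) / n
    Wpg_m <- params$W_pg * t(arch$mask)
    bk <- nn_linear_backward(dlogits_g, dec$caches$logits_g, Wpg_m)
    g$W_pg <- bk$dW * t(arch$mask)
    g$b_pg <- bk$db
    dpd <- bk$dx
    if (arch$batchnorm) {
      bnb <- nn_bn_backward(dpd, dec$caches$bn_hp,
        list(gamma = params$bn_hp$gamma)
      )
      g$bn_hp <- list(gamma = bnb$dgamma, beta = bnb$dbeta)
      dpd <- bnb$dx
    }
    dpd <- nn_relu_backward(dpd, dec$caches$act_hp)
    bk <- nn_linear_backward(dpd, dec$caches$lin_hp, params$W_hp)
    g$W_hp <- bk$dW
    g$b_hp <- bk$db
    dhd <- dhd + bk$dx
  }
  if (arch$n_miRNA > 0) {
    dlogits_m <- (dec$x_miRNA - x_miRNA) / n
    bk <- nn_linear_backward(dlogits_m, dec$caches$logits_m, params$W_hm)
    g$W_hm <- bk$dW
    g$b_hm <- bk$db
    dhd <- dhd + bk$dx
  }
  if (arch$batchnorm) {
    bnb <- nn_bn_backward(dhd, dec$caches$bn_zh, list(gamma = params$bn_zh$gamma))
    g$bn_zh <- list(gamma = bnb$dgamma, beta = bnb$dbeta)
    dhd <- bnb$dx
  }
  dhd <- nn_relu_backward(dhd, dec$caches$act_zh)
  bk <- nn_linear_backward(dhd, dec$caches$lin_zh, params$W_zh)
  g$W_zh <- bk$dW
  g$b_zh <- bk$db
  dz <- bk$dx

  # KL gradients plus the reconstruction path through the sampled z
  dmu <- dz + beta * post$mu / n
  s2 <- sigma^2
  dlogvar <- dz * epsilon * sigma / 2 + beta * 0.5 * (s2 - 1) / n

  bk_mu <- nn_linear_backward(dmu, list(x = enc$a_h), params$W_mu)
  bk_lv <- nn_linear_backward(dlogvar, list(x = enc$a_h), params$W_lv)
  g$W_mu <- bk_mu$dW
  g$b_mu <- bk_mu$db
  g$W_lv <- bk_lv$dW
  g$b_lv <- bk_lv$db
  da_h <- bk_mu$dx + bk_lv$dx
  if (arch$batchnorm) {
    bnb <- nn_bn_backward(da_h, enc$caches$bn_h, list(gamma = params$bn_h$gamma))
    g$bn_h <- list(gamma = bnb$dgamma, beta = bnb$dbeta)
    da_h <- bnb$dx
  }
  da_h <- nn_relu_backward(da_h, enc$caches$act_h)
  bk <- nn_linear_backward(da_h, enc$caches$lin_h, params$W_h)
  g$W_h <- bk$dW
  g$b_h <- bk$db
  dconcat <- bk$dx

  if (arch$n_gene > 0) {
    dap <- dconcat[, seq_len(arch$n_pathway), drop = FALSE]
    if (arch$batchnorm) {
      bnb <- nn_bn_backward(dap, enc$caches$bn_p, list(gamma = params$bn_p$gamma))
      g$bn_p <- list(gamma = bnb$dgamma, beta = bnb$dbeta)
      dap <- bnb$dx
    }
    dap <- nn_relu_backward(dap, enc$caches$act_p)
    bk <- nn_linear_backward(dap, enc$caches$lin_p, params$W_gp * arch$mask)
    g$W_gp <- bk$dW * arch$mask
    g$b_p <- bk$db
  }

  if (lambda1 > 0) g <- ptree_add(g, ptree_l2norm_grad(params, lambda1))

  list(loss = loss, grads = g, stats = stats)
}

#' Train the pathway-masked VAE
#'
#' Minimises the compound loss by Adam over shuffled mini-batches, with the
#' KL weight following the cyclical annealing schedule and the mask's zero
#' pattern re-imposed after every update. Model selection keeps the
#' parameters of the epoch with the lowest validation reconstruction loss
#' (BCE only, inference mode). With `integration = "concatenate"` two
#' single-omics autoencoders are trained independently (the gene one keeps
#' the pathway mask, the miRNA one is fully connected) and their latents are
#' joined by [extract_latent()].
#'
#' @param train,valid Lists with elements `gene` and/or `miRNA`
#'   (samples x features matrices in [0, 1]); validation may be NULL, in
#'   which case the final epoch's parameters are kept.
#' @param arch A [vae_architecture()].
#' @param schedule An [beta_schedule()] result; its length sets the epochs.
#' @param lambda1 L2 penalty weight (default 0).
#' @param lr Adam learning rate (default 1e-3).
#' @param batch_size Mini-batch size (default 64; a trailing singleton batch
#'   is merged into its predecessor so batch statistics stay defined).
#' @param seed Integer seed controlling initialisation, shuffling and noise.
#' @return A `kl_pmvae_fit` with the selected `model` (params + batch-norm
#'   stats), the per-epoch loss `history` tibble, `best_epoch` and the
#'   architecture.
#' @export
train_kl_pmvae <- function(train, valid = NULL, arch, schedule,
                           lambda1 = 0, lr = 1e-3, batch_size = 64, seed = 1L) {
  if (arch$integration == "concatenate") {
    return(train_concatenate_vae(train, valid, arch, schedule, lambda1, lr,
      batch_size, seed))
  }
  init <- vae_init_params(arch, seed = seed)
  params <- init$params
  stats <- init$stats
  opt <- adam_init(params)
  n_epochs <- schedule$n_epochs
  history <- vector("list", n_epochs)
  best <- list(loss = Inf, model = list(params = params, stats = stats), epoch = 0L)
  xg <- train$gene
  xm <- train$miRNA
  n <- if (!is.null(xg)) nrow(xg) else nrow(xm)

  with_seed(seed + 1L, {
    for (epoch in seq_len(n_epochs)) {
      beta <- schedule$beta_path[epoch]
      idx <- sample.int(n)
      starts <- seq(1, n, by = batch_size)
      batches <- lapply(starts, function(s) idx[s:min(s + batch_size - 1, n)])
      nb <- length(batches)
      if (nb > 1 && length(batches[[nb]]) == 1) {
        batches[[nb - 1]] <- c(batches[[nb - 1]], batches[[nb]])
        batches[[nb]] <- NULL
      }
      terms <- c(bce_gene = 0, bce_miRNA = 0, kl = 0, total = 0)
      for (b in batches) {
        res <- vae_batch_grad(
          if (!is.null(xg)) xg[b, , drop = FALSE] else NULL,
          if (!is.null(xm)) xm[b, , drop = FALSE] else NULL,
          arch, params, stats, beta, lambda1
        )
        if (!is.finite(res$loss$total)) {
          stop(sprintf("VAE loss diverged (non-finite) at epoch %d", epoch))
        }
        stats <- res$stats
        upd <- adam_step(params, res$grads, opt, lr = lr)
        params <- upd$params
        opt <- upd$state
        if (arch$n_gene > 0) {
          params$W_gp <- params$W_gp * arch$mask
          params$W_pg <- params$W_pg * t(arch$mask)
        }
        w <- length(b) / n
        terms <- terms + w * c(res$loss$bce_gene, res$loss$bce_miRNA,
                               res$loss$kl, res$loss$total)
      }
      model <- list(params = params, stats = stats)
      val_recon <- NA_real_
      if (!is.null(valid)) {
        val_recon <- vae_recon_loss(valid$gene, valid$miRNA, arch, model)
        if (val_recon < best$loss) {
          best <- list(loss = val_recon, model = model, epoch = epoch)
        }
      }
      history[[epoch]] <- tibble::tibble(
        epoch = epoch, beta = beta,
        bce_gene = terms[["bce_gene"]], bce_miRNA = terms[["bce_miRNA"]],
        kl = terms[["kl"]], total = terms[["total"]],
        valid_recon = val_recon
      )
    }
  })
  if (is.null(valid) || best$epoch == 0L) {
    best <- list(
      loss = NA_real_, model = list(params = params, stats = stats),
      epoch = n_epochs
    )
  }
  structure(
    list(
      model = best$model, best_epoch = best$epoch, arch = arch,
      schedule = schedule,
      history = if (n_epochs > 0) dplyr::bind_rows(history) else tibble::tibble(),
      lambda1 = lambda1, seed = seed
    ),
    class = "kl_pmvae_fit"
  )
}

# validation reconstruction loss: BCE only, inference mode, z = mu
vae_recon_loss <- function(x_gene, x_miRNA, arch, model) {
  post <- encode(x_gene, x_miRNA, arch, model, training = FALSE)
  rec <- decode(post$mu, arch, model, training = FALSE)
  bce <- 0
  if (!is.null(x_gene)) bce <- bce + bce_sum_mean(x_gene, rec$x_gene)
  if (!is.null(x_miRNA)) bce <- bce + bce_sum_mean(x_miRNA, rec$x_miRNA)
  bce
}

train_concatenate_vae <- function(train, valid, arch, schedule, lambda1, lr,
                                  batch_size, seed) {
  mask <- structure(arch$mask, class = c("pathway_mask", "matrix", "array"))
  d_half <- max(1L, arch$d_latent %/% 2L)
  arch_g <- vae_architecture(mask, 0, d_half, arch$hidden_width,
    integration = "gene_only", batchnorm = arch$batchnorm
  )
  arch_m <- vae_architecture(NULL, arch$n_miRNA, arch$d_latent - d_half,
    arch$hidden_width,
    integration = "miRNA_only", batchnorm = arch$batchnorm
  )
  fit_g <- train_kl_pmvae(list(gene = train$gene),
    if (!is.null(valid)) list(gene = valid$gene) else NULL,
    arch_g, schedule, lambda1, lr, batch_size, seed
  )
  fit_m <- train_kl_pmvae(list(miRNA = train$miRNA),
    if (!is.null(valid)) list(miRNA = valid$miRNA) else NULL,
    arch_m, schedule, lambda1, lr, batch_size, seed + 1000L
  )
  structure(
    list(gene_fit = fit_g, mirna_fit = fit_m, arch = arch, seed = seed),
    class = c("concat_vae_fit", "kl_pmvae_fit")
  )
}

#' Extract latent features (posterior means) from a trained VAE
#'
#' Returns the posterior means, evaluated in inference mode (running
#' batch-norm statistics, no sampling); these are the features fed to the
#' survival network. For the concatenate variant the two single-omics latent
#' blocks are column-bound.
#'
#' @param x_gene,x_miRNA Expression matrices (either may be NULL for
#'   single-omics variants).
#' @param fit A `kl_pmvae_fit` from [train_kl_pmvae()].
#' @return A samples x d_latent matrix of posterior means.
#' @export
extract_latent <- function(x_gene, x_miRNA, fit) {
  if (inherits(fit, "concat_vae_fit")) {
    mu_g <- extract_latent(x_gene, NULL, fit$gene_fit)
    mu_m <- extract_latent(NULL, x_miRNA, fit$mirna_fit)
    colnames(mu_m) <- paste0("latent_", ncol(mu_g) + seq_len(ncol(mu_m)))
    return(cbind(mu_g, mu_m))
  }
  encode(x_gene, x_miRNA, fit$arch, fit$model, training = FALSE)$mu
}
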