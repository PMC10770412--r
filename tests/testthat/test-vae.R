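test_that("encoder respects the pathway mask and hand-set weights", {
  mask <- structure(
    matrix(c(1, 1), 2, 1, dimnames = list(c("g1", "g2"), "P1")),
    class = c("pathway_mask", "matrix", "array")
  )
  arch <- vae_architecture(mask, n_miRNA = 1, d_latent = 1, hidden_width = 1,
                           batchnorm = FALSE)
  model <- vae_init_params(arch, zero = TRUE)

  # zeroed parameters: mu = 0, logvar = 0
  xg <- matrix(c(0.2, 0.8, 0.4, 0.6), 2, 2)
  xm <- matrix(c(0.5, 0.1), 2, 1)
  post <- encode(xg, xm, arch, model)
  expect_equal(unname(post$mu), matrix(0, 2, 1))
  expect_equal(unname(post$logvar), matrix(0, 2, 1))

  # hand-set weights: pathway = relu(2*g1 + 1*g2), hidden = relu(p + 3*m),
  # mu = 0.5*h + 0.1
  model$params$W_gp <- matrix(c(2, 1), 2, 1)
  model$params$W_h <- matrix(c(1, 3), 2, 1)
  model$params$W_mu <- matrix(0.5, 1, 1)
  model$params$b_mu <- 0.1
  post2 <- encode(xg, xm, arch, model)
  p_manual <- pmax(2 * xg[, 1] + xg[, 2], 0)
  h_manual <- pmax(p_manual + 3 * xm[, 1], 0)
  expect_equal(as.numeric(post2$mu), 0.5 * h_manual + 0.1)
})

test_that("masked encoder weights carry exact zeros where the mask forbids", {
  mask <- toy_mask()
  arch <- vae_architecture(mask, n_miRNA = 3, d_latent = 2, hidden_width = 4)
  init <- vae_init_params(arch, seed = 5)
  expect_true(all(init$params$W_gp[unclass(mask) == 0] == 0))
  expect_true(all(init$params$W_pg[t(unclass(mask)) == 0] == 0))
})

test_that("reparameterization is mu + exp(logvar/2) * epsilon", {
  post <- structure(
    list(mu = matrix(c(1, -2), 2, 1), logvar = matrix(c(log(4), 0), 2, 1)),
    class = "latent_posterior"
  )
  expect_equal(reparameterize(post, matrix(0, 2, 1)), post$mu)
  expect_equal(
    reparameterize(post, matrix(c(0.5, 1), 2, 1)),
    matrix(c(1 + 2 * 0.5, -2 + 1), 2, 1)
  )
})

test_that("decoder outputs stay inside (0, 1) and honour the transposed mask", {
  mask <- toy_mask()
  arch <- vae_architecture(mask, n_miRNA = 3, d_latent = 2, hidden_width = 4)
  model <- vae_init_params(arch, seed = 6)
  z <- matrix(rnorm(10), 5, 2)
  rec <- decode(z, arch, model)
  expect_true(all(rec$x_gene > 0 & rec$x_gene < 1))
  expect_true(all(rec$x_miRNA > 0 & rec$x_miRNA < 1))
  expect_true(all(model$params$W_pg[t(unclass(mask)) == 0] == 0))
  expect_error(decode(matrix(0, 2, 3), arch, model), "latent")
})

test_that("the compound loss matches its closed-form pieces", {
  # exact reconstruction of binary targets with unit posterior: total ~ 0
  x <- matrix(c(0, 1, 1, 0), 2, 2)
  post <- list(mu = matrix(0, 2, 1), logvar = matrix(0, 2, 1))
  lt <- vae_loss(x, NULL, x, NULL, post, beta = 1, lambda1 = 0)
  expect_equal(lt$total, 0, tolerance = 1e-5)
  expect_equal(lt$kl, 0)

  # single latent mu = 1, sigma^2 = 1 -> KL = 0.5
  post1 <- list(mu = matrix(1, 1, 1), logvar = matrix(0, 1, 1))
  expect_equal(vae_loss(NULL, NULL, NULL, NULL, post1, beta = 1)$kl, 0.5)

  # beta weights the KL term; beta = 1 is the conventional objective
  xh <- matrix(0.7, 2, 2)
  l0 <- vae_loss(x, NULL, xh, NULL, post1_rep <- list(
    mu = matrix(1, 2, 1), logvar = matrix(0, 2, 1)
  ), beta = 0)
  l1 <- vae_loss(x, NULL, xh, NULL, post1_rep, beta = 1)
  expect_equal(l1$total - l0$total, l1$kl)

  # KL is non-negative and zero only at the prior
  set.seed(3)
  for (i in 1:20) {
    p <- list(mu = matrix(rnorm(4), 2, 2), logvar = matrix(rnorm(4), 2, 2))
    expect_gte(vae_loss(NULL, NULL, NULL, NULL, p)$kl, 0)
  }

  # the penalty is the L2 norm of the parameter tree
  params <- list(W = matrix(c(3, 4), 1, 2))
  lt2 <- vae_loss(x, NULL, xh, NULL, post, beta = 0, lambda1 = 2, params = params)
  expect_equal(lt2$l2_penalty, 5)
  expect_equal(lt2$total, lt2$bce_gene + 2 * 5)
})

test_that("cyclical annealing ramps beta from 0 to 1 within every cycle", {
  expect_equal(beta_schedule(7, 2, 0)$beta_path, rep(1, 7))
  expect_equal(beta_schedule(5, 1, 0.5)$beta_path, c(0, 0.4, 0.8, 1, 1))

  sched <- beta_schedule(20, 3, 0.5)
  expect_length(sched$beta_path, 20)
  expect_true(all(sched$beta_path >= 0 & sched$beta_path <= 1))
  # cycles are 6, 6, 8 epochs; each ends at 1 and restarts near 0
  ends <- cumsum(c(6, 6, 8))
  expect_equal(sched$beta_path[ends], rep(1, 3))
  starts <- c(1, 7, 13)
  expect_equal(sched$beta_path[starts], rep(0, 3))
  expect_equal(max(sched$beta_path), 1)

  # degenerate ramp: cutting_ratio * L < 1
  tiny <- beta_schedule(3, 3, 0.5)
  expect_equal(tiny$beta_path, c(1, 1, 1)) # L = 1 per cycle: end forced to 1
})

test_that("training reduces reconstruction loss, deterministically, and keeps the mask", {
  cohort <- small_cohort(n = 200)
  mask <- build_pathway_mask(cohort$pathways, colnames(cohort$gene),
    min_genes = 5, max_genes = 50
  )
  xg <- unclass(cohort$gene)[, rownames(mask)]
  xm <- unclass(cohort$miRNA)
  arch <- vae_architecture(mask, ncol(xm), d_latent = 4, hidden_width = 16)
  sched <- beta_schedule(12, 2, 0.5)
  fit <- train_kl_pmvae(
    list(gene = xg[1:160, ], miRNA = xm[1:160, ]),
    list(gene = xg[161:200, ], miRNA = xm[161:200, ]),
    arch, sched, lr = 5e-3, seed = 2
  )
  h <- tidy(fit)
  expect_lt(
    h$bce_gene[nrow(h)] + h$bce_miRNA[nrow(h)],
    h$bce_gene[1] + h$bce_miRNA[1]
  )
  expect_true(all(fit$model$params$W_gp[unclass(mask) == 0] == 0))
  expect_true(all(fit$model$params$W_pg[t(unclass(mask)) == 0] == 0))
  expect_gte(fit$best_epoch, 1)

  fit2 <- train_kl_pmvae(
    list(gene = xg[1:160, ], miRNA = xm[1:160, ]),
    list(gene = xg[161:200, ], miRNA = xm[161:200, ]),
    arch, sched, lr = 5e-3, seed = 2
  )
  expect_equal(tidy(fit2)$total, h$total)

  # zero epochs: initial parameters returned unchanged
  fit0 <- train_kl_pmvae(
    list(gene = xg[1:160, ], miRNA = xm[1:160, ]),
    NULL, arch, beta_schedule(0, 1, 0.5), seed = 2
  )
  expect_equal(fit0$model$params, vae_init_params(arch, seed = 2)$params)
})

test_that("latent extraction returns inference-mode posterior means", {
  pipe <- fit_small_pipeline(small_cohort(n = 150), vae_epochs = 10)
  mu <- extract_latent(pipe$xg, pipe$xm, pipe$vae)
  post <- encode(pipe$xg, pipe$xm, pipe$vae$arch, pipe$vae$model, training = FALSE)
  expect_equal(mu, post$mu)

  # identical input rows give identical latent rows
  xg2 <- pipe$xg[c(1, 1), ]
  xm2 <- pipe$xm[c(1, 1), ]
  mu2 <- extract_latent(xg2, xm2, pipe$vae)
  expect_equal(mu2[1, ], mu2[2, ])
})

test_that("trained latents recover the true factors on strong-signal data", {
  cohort <- generate_cohort(synthetic_config(
    n_samples = 300, n_genes = 60, n_miRNAs = 15, n_pathways = 4, d_true = 4,
    effect_weights = c(rep(1, 4), 0.5, 0.5), noise_sd = 0.2, seed = 77
  ))
  pipe <- fit_small_pipeline(cohort, d_latent = 4, vae_epochs = 25, seed = 5)
  cc <- stats::cancor(pipe$mu, cohort$true_latent)$cor
  expect_gte(max(cc), 0.5)
})

test_that("the concatenate variant joins two single-omics latent blocks", {
  cohort <- small_cohort(n = 120)
  mask <- build_pathway_mask(cohort$pathways, colnames(cohort$gene),
    min_genes = 5, max_genes = 50
  )
  xg <- unclass(cohort$gene)[, rownames(mask)]
  xm <- unclass(cohort$miRNA)
  arch <- vae_architecture(mask, ncol(xm), d_latent = 4, hidden_width = 8,
                           integration = "concatenate")
  fit <- train_kl_pmvae(
    list(gene = xg[1:96, ], miRNA = xm[1:96, ]),
    list(gene = xg[97:120, ], miRNA = xm[97:120, ]),
    arch, beta_schedule(6, 1, 0.5), seed = 3
  )
  mu <- extract_latent(xg, xm, fit)
  expect_equal(ncol(mu), 4)
  mu_g <- extract_latent(xg, NULL, fit$gene_fit)
  mu_m <- extract_latent(NULL, xm, fit$mirna_fit)
  expect_equal(unname(mu), unname(cbind(mu_g, mu_m)))
})

test_that("analytic VAE gradients match numerical differentiation", {
  mask <- toy_mask()
  arch <- vae_architecture(mask, n_miRNA = 3, d_latent = 2, hidden_width = 3)
  init <- vae_init_params(arch, seed = 3)
  set.seed(7)
  n <- 5
  xg <- matrix(runif(n * 4), n, 4)
  xm <- matrix(runif(n * 3), n, 3)
  eps <- matrix(rnorm(n * 2), n, 2)
  res <- pathsurv:::vae_batch_grad(xg, xm, arch, init$params, init$stats,
    beta = 0.7, lambda1 = 0.01, epsilon = eps
  )
  lossfn <- function(params) {
    pathsurv:::vae_batch_grad(xg, xm, arch, params, init$stats,
      beta = 0.7, lambda1 = 0.01, epsilon = eps
    )$loss$total
  }
  modify <- function(tree, path, i, d) {
    if (length(path) == 1) {
      tree[[path]][i] <- tree[[path]][i] + d
    } else {
      tree[[path[1]]] <- modify(tree[[path[1]]], path[-1], i, d)
    }
    tree
  }
  paths <- list(
    "W_gp", c("bn_p", "gamma"), "W_h", c("bn_h", "beta"), "W_mu", "W_lv",
    "W_zh", "W_hm", "W_hp", c("bn_hp", "gamma"), "W_pg", "b_pg"
  )
  for (pth in paths) {
    g <- res$grads
    p <- init$params
    for (nm in pth) {
      g <- g[[nm]]
      p <- p[[nm]]
    }
    for (i in sample(length(p), min(3, length(p)))) {
      e <- 1e-5
      ng <- (lossfn(modify(init$params, pth, i, e)) -
               lossfn(modify(init$params, pth, i, -e))) / (2 * e)
      expect_equal(unname(g[i]), ng, tolerance = 1e-5)
    }
  }
})
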