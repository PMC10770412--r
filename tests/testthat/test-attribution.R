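random_net <- function(widths, seed = 1, funs = "tanh", bn = TRUE) {
  set.seed(seed)
  layers <- list()
  for (i in seq_len(length(widths) - 1)) {
    W <- matrix(rnorm(widths[i] * widths[i + 1], sd = 0.5), widths[i], widths[i + 1])
    layers <- c(layers, list(pathsurv:::layer_linear(W, rnorm(widths[i + 1], sd = 0.1))))
    if (i < length(widths) - 1) {
      layers <- c(layers, list(pathsurv:::layer_act(funs, widths[i + 1])))
      if (bn) {
        layers <- c(layers, list(pathsurv:::layer_bn(
          list(gamma = runif(widths[i + 1], 0.5, 1.5), beta = rnorm(widths[i + 1], sd = 0.2)),
          list(mean = rnorm(widths[i + 1], sd = 0.3), var = runif(widths[i + 1], 0.5, 2))
        )))
      }
    }
  }
  pathsurv:::seq_network(layers, paste0("in_", seq_len(widths[1])), "out")
}

test_that("batch-norm folding preserves outputs and is idempotent", {
  net <- random_net(c(4, 6, 3, 1), seed = 3)
  folded <- fold_inference_transforms(net)
  set.seed(4)
  x <- matrix(rnorm(400), 100, 4)
  expect_equal(net_forward(folded, x), net_forward(net, x), tolerance = 1e-6)
  refolded <- fold_inference_transforms(folded)
  expect_equal(net_forward(refolded, x), net_forward(folded, x))
  expect_length(refolded$layers, length(folded$layers))
  # only linear/activation layers remain after folding
  expect_true(all(vapply(folded$layers, `[[`, "", "type") %in% c("linear", "act")))

  # an identity batch norm leaves parameters unchanged
  id_bn <- pathsurv:::layer_bn(
    list(gamma = rep(1, 3), beta = rep(0, 3)),
    list(mean = rep(0, 3), var = rep(1 - 1e-5, 3))
  )
  expect_equal(id_bn$a, rep(1, 3))
  expect_equal(id_bn$c, rep(0, 3))
})

test_that("DeepLIFT attributions satisfy summation-to-delta", {
  net <- random_net(c(5, 7, 4, 1), seed = 6)
  folded <- fold_inference_transforms(net)
  set.seed(7)
  x <- rnorm(5)
  refs <- matrix(rnorm(15), 3, 5)
  contrib <- deeplift_attributions(folded, x, refs, target = 1)
  out_x <- net_forward(folded, matrix(x, 1))[1, 1]
  out_r <- net_forward(folded, refs)[, 1]
  expect_equal(rowSums(contrib), out_x - out_r, tolerance = 1e-10)

  # x equal to the reference: all contributions vanish
  expect_equal(
    deeplift_attributions(folded, x, matrix(x, 1))[1, ],
    stats::setNames(rep(0, 5), folded$input_ids)
  )
})

test_that("linear networks get the closed-form attribution exactly", {
  w <- c(2, -1, 0.5)
  net <- pathsurv:::seq_network(
    list(pathsurv:::layer_linear(matrix(w, 3, 1), 0.3)),
    c("a", "b", "c"), "out"
  )
  x <- c(1, 2, 3)
  ref <- c(0, 1, -1)
  contrib <- deeplift_attributions(net, x, ref)
  expect_equal(unname(contrib[1, ]), w * (x - ref))

  # DeepSHAP overall scores for a linear network match direct computation
  set.seed(8)
  expl <- matrix(rnorm(12), 4, 3)
  refs <- matrix(rnorm(9), 3, 3)
  at <- deepshap_scores(net, expl, refs)
  manual <- t(apply(expl, 1, function(xi) {
    colMeans(sweep(sweep(-refs, 2, xi, "+"), 2, w, "*"))
  }))
  expect_equal(unname(at$shap), unname(manual))
  expect_equal(
    at$overall$overall[match(c("a", "b", "c"), at$overall$feature)],
    unname(colMeans(abs(manual)))
  )
})

test_that("the rescale rule matches a hand computation through tanh", {
  # 2 inputs -> 1 tanh unit -> 1 output
  net <- pathsurv:::seq_network(
    list(
      pathsurv:::layer_linear(matrix(c(1, 2), 2, 1), 0.5),
      pathsurv:::layer_act("tanh", 1),
      pathsurv:::layer_linear(matrix(3, 1, 1), 0)
    ),
    c("x1", "x2"), "y"
  )
  x <- c(0.4, 0.3)
  ref <- c(0, 0)
  pre_x <- sum(c(1, 2) * x) + 0.5
  pre_r <- 0.5
  mult <- (tanh(pre_x) - tanh(pre_r)) / (pre_x - pre_r)
  expected <- 3 * mult * c(1, 2) * (x - ref)
  contrib <- deeplift_attributions(net, x, ref)
  expect_equal(unname(contrib[1, ]), expected)
  expect_equal(sum(contrib), 3 * (tanh(pre_x) - tanh(pre_r)))

  # near-zero input difference falls back to the derivative
  refn <- x - 1e-12
  contrib2 <- deeplift_attributions(net, x, refn)
  d <- 3 * (1 - tanh(pre_x)^2) * c(1, 2) * 1e-12
  expect_equal(unname(contrib2[1, ]), d, tolerance = 1e-6)
})

test_that("sequential views reproduce the trained forward passes", {
  pipe <- fit_small_pipeline(small_cohort(n = 150), vae_epochs = 10)
  # encoder network vs encode()
  enc_net <- fold_inference_transforms(build_encoder_network(pipe$vae))
  mu2 <- net_forward(enc_net, cbind(pipe$xg, pipe$xm))
  expect_equal(max(abs(mu2 - pipe$mu)), 0, tolerance = 1e-10)

  # pathway head + encoder tail compose to the same latents
  pw_net <- fold_inference_transforms(build_pathway_network(pipe$vae))
  pw_vals <- net_forward(pw_net, pipe$xg)
  tail_net <- fold_inference_transforms(build_latent_from_pathway_network(pipe$vae))
  mu3 <- net_forward(tail_net, cbind(pw_vals, pipe$xm))
  expect_equal(max(abs(mu3 - pipe$mu)), 0, tolerance = 1e-10)

  # composed omics+clinical -> PI network vs predict()
  comp <- fold_inference_transforms(build_composed_network(
    pipe$vae, pipe$surv, clinical_ids = colnames(pipe$clin)
  ))
  pi2 <- net_forward(comp, cbind(pipe$xg, pipe$xm, pipe$clin))
  expect_equal(as.numeric(pi2), predict(pipe$surv, pipe$feats)$pi,
    tolerance = 1e-10
  )
  # survival-network view
  snet <- build_lfsurv_network(pipe$surv, colnames(pipe$feats))
  expect_equal(
    as.numeric(net_forward(snet, pipe$feats)),
    predict(pipe$surv, pipe$feats)$pi
  )
})

test_that("deepshap orders features and a single self-reference zeroes out", {
  pipe <- fit_small_pipeline(small_cohort(n = 150), vae_epochs = 10)
  snet <- build_lfsurv_network(pipe$surv, colnames(pipe$feats))
  at0 <- deepshap_scores(snet, pipe$feats[1:3, ], pipe$feats[1:3, ][1, , drop = FALSE])
  expect_equal(unname(at0$shap[1, ]), rep(0, ncol(pipe$feats)))

  groups <- assign_risk_groups(predict(pipe$surv, pipe$feats))
  expect_warning(
    sel <- sample_attribution_groups(groups, n_each = 100, seed = 1),
    "using"
  )
  at <- deepshap_scores(
    snet, pipe$feats[sel$explained_ids, ], pipe$feats[sel$reference_ids, ],
    target = "PI"
  )
  ranked <- rank_latent_features(at)
  expect_setequal(ranked, colnames(pipe$feats))
  expect_equal(
    at$overall$overall, sort(at$overall$overall, decreasing = TRUE)
  )

  # ranking content unchanged by permuting the input feature order
  perm <- sample(ncol(pipe$feats))
  at_p <- deepshap_scores(
    pathsurv:::seq_network(
      list(
        pathsurv:::layer_linear(pipe$surv$params$W1[perm, , drop = FALSE],
                                pipe$surv$params$b1),
        pathsurv:::layer_act("tanh", ncol(pipe$surv$params$W1)),
        pathsurv:::layer_linear(pipe$surv$params$w2, 0)
      ),
      colnames(pipe$feats)[perm], "PI"
    ),
    pipe$feats[sel$explained_ids, perm], pipe$feats[sel$reference_ids, perm]
  )
  expect_equal(at_p$overall, at$overall)
})

test_that("key input factors are features recurring across latent top lists", {
  t1 <- structure(list(overall = tibble::tibble(
    feature = c("g1", "g2", "g3"), overall = c(3, 2, 1)
  )), class = "attribution_table")
  t2 <- structure(list(overall = tibble::tibble(
    feature = c("g2", "g4", "g5"), overall = c(5, 2, 1)
  )), class = "attribution_table")
  rep2 <- identify_kif(list(l1 = t1, l2 = t2), top_k = 3)
  expect_equal(rep2$factors$feature, "g2")
  expect_equal(rep2$factors$frequency, 2L)
  expect_false("g1" %in% rep2$factors$feature)

  expect_warning(r1 <- identify_kif(list(l1 = t1)), "fewer than two")
  expect_equal(nrow(r1$factors), 0)
})

test_that("planted survival signal surfaces as key input factors", {
  # factors 1-2 carry all survival signal; pathways 1-2 load on them, so
  # their genes are the planted signal set and pathways 3-4 provide nulls
  cohort <- generate_cohort(synthetic_config(
    n_samples = 400, n_genes = 60, n_miRNAs = 15, n_pathways = 4, d_true = 4,
    shared_fraction = 1, effect_weights = c(6, 6, 0, 0, 0.2, 0.2),
    noise_sd = 0.15, loading_scale = 1.5, seed = 91
  ))
  mask <- build_pathway_mask(cohort$pathways, colnames(cohort$gene),
    min_genes = 5, max_genes = 50
  )
  xg <- unclass(cohort$gene)[, rownames(mask)]
  xm <- unclass(cohort$miRNA)
  tr <- 1:320
  va <- 321:400
  arch <- vae_architecture(mask, ncol(xm), d_latent = 8, hidden_width = 16)
  vfit <- train_kl_pmvae(
    list(gene = xg[tr, ], miRNA = xm[tr, ]),
    list(gene = xg[va, ], miRNA = xm[va, ]),
    arch, beta_schedule(60, 2, 0.5), lr = 5e-3, seed = 13
  )
  mu <- extract_latent(xg, xm, vfit)
  clin <- as.matrix(cohort$clinical[, -1])
  feats <- cbind(mu, clin)
  rownames(feats) <- cohort$survival$sample_id
  sfit <- train_lfsurv(
    list(features = feats[tr, ], surv = cohort$survival[tr, ]),
    list(features = feats[va, ], surv = cohort$survival[va, ]),
    survnet_spec(ncol(feats), 8, 0),
    lambda2 = 1e-3, n_epochs = 200, seed = 14
  )
  groups <- assign_risk_groups(predict(sfit, feats))
  sel <- suppressWarnings(
    sample_attribution_groups(groups, n_each = 100, seed = 3)
  )

  snet <- build_lfsurv_network(sfit, colnames(feats))
  at_pi <- deepshap_scores(
    snet, feats[sel$explained_ids, ], feats[sel$reference_ids, ]
  )
  top_latents <- intersect(rank_latent_features(at_pi), colnames(mu))

  enc_net <- build_encoder_network(vfit)
  omics <- cbind(xg, xm)
  per_latent <- lapply(top_latents[1:3], function(tgt) {
    deepshap_scores(
      enc_net, omics[sel$explained_ids, ], omics[sel$reference_ids, ],
      target = tgt
    )
  })
  names(per_latent) <- top_latents[1:3]
  report <- identify_kif(per_latent, top_k = 10)
  expect_gte(nrow(report$factors), 1)
  expect_true(all(report$factors$frequency >= 2))
  # the recurring factors are drawn from the planted signal set
  loads <- cohort$gene_loadings[colnames(xg), ]
  signal_genes <- rownames(loads)[rowSums(abs(loads[, 1:2])) > 0]
  signal_mirnas <- rownames(cohort$mirna_loadings)[
    rowSums(abs(cohort$mirna_loadings[, 1:2])) > 0
  ]
  expect_gt(
    mean(report$factors$feature %in% c(signal_genes, signal_mirnas)), 0.5
  )

  # pathway-level attribution flags the signal pathways
  tail_net <- build_latent_from_pathway_network(vfit)
  pw_vals <- net_forward(
    fold_inference_transforms(build_pathway_network(vfit)), xg
  )
  colnames(pw_vals) <- colnames(mask)
  pw_in <- cbind(pw_vals, xm)
  per_latent_pw <- lapply(top_latents[1:3], function(tgt) {
    deepshap_scores(
      tail_net, pw_in[sel$explained_ids, ], pw_in[sel$reference_ids, ],
      target = tgt
    )
  })
  kpf <- identify_kif(per_latent_pw, top_k = 3)
  expect_gte(nrow(kpf$factors), 1)

  # signal genes dominate null genes in composed gene-to-PI attribution
  comp <- build_composed_network(vfit, sfit, clinical_ids = colnames(clin))
  full <- cbind(xg, xm, clin)
  at_comp <- deepshap_scores(
    comp, full[sel$explained_ids, ], full[sel$reference_ids, ]
  )
  null_genes <- setdiff(colnames(xg), signal_genes)
  sc <- at_comp$overall
  sig_scores <- sc$overall[sc$feature %in% signal_genes]
  null_scores <- sc$overall[sc$feature %in% null_genes]
  expect_gt(
    stats::median(sig_scores),
    stats::quantile(null_scores, 0.9)
  )
})
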