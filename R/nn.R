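# Dense-layer primitives used by the autoencoder and the survival network.
# Everything operates on row-major design matrices (samples x units) and
# returns forward caches so the matching *_backward() can compute exact
# gradients. Batch norm follows the standard per-column normalisation with
# running statistics for inference mode.

nn_linear_forward <- function(x, W, b = NULL) {
  out <- x %*% W
  if (!is.null(b)) out <- sweep(out, 2, b, "+")
  list(out = out, x = x)
}

nn_linear_backward <- function(dout, cache, W) {
  list(
    dx = dout %*% t(W),
    dW = t(cache$x) %*% dout,
    db = colSums(dout)
  )
}

nn_relu_forward <- function(x) list(out = pmax(x, 0), x = x)
nn_relu_backward <- function(dout, cache) dout * (cache$x > 0)

nn_tanh_forward <- function(x) {
  out <- tanh(x)
  list(out = out, t = out)
}
nn_tanh_backward <- function(dout, cache) dout * (1 - cache$t^2)

nn_sigmoid_forward <- function(x) {
  out <- 1 / (1 + exp(-x))
  list(out = out, s = out)
}
nn_sigmoid_backward <- function(dout, cache) dout * cache$s * (1 - cache$s)

nn_bn_init <- function(width) {
  list(
    gamma = rep(1, width), beta = rep(0, width),
    running_mean = rep(0, width), running_var = rep(1, width)
  )
}

nn_bn_forward <- function(x, bn, training = TRUE, momentum = 0.1, eps = 1e-5) {
  if (training) {
    n <- nrow(x)
    mu <- colMeans(x)
    xc <- sweep(x, 2, mu, "-")
    v <- colMeans(xc^2)
    inv_sd <- 1 / sqrt(v + eps)
    xhat <- sweep(xc, 2, inv_sd, "*")
    out <- sweep(sweep(xhat, 2, bn$gamma, "*"), 2, bn$beta, "+")
    bn$running_mean <- (1 - momentum) * bn$running_mean + momentum * mu
    # unbiased running variance, matching common framework behaviour
    v_unb <- if (n > 1) v * n / (n - 1) else v
    bn$running_var <- (1 - momentum) * bn$running_var + momentum * v_unb
    list(out = out, bn = bn, cache = list(xc = xc, inv_sd = inv_sd, xhat = xhat))
  } else {
    inv_sd <- 1 / sqrt(bn$running_var + eps)
    xhat <- sweep(sweep(x, 2, bn$running_mean, "-"), 2, inv_sd, "*")
    out <- sweep(sweep(xhat, 2, bn$gamma, "*"), 2, bn$beta, "+")
    list(out = out, bn = bn, cache = NULL)
  }
}

nn_bn_backward <- function(dout, cache, bn) {
  n <- nrow(dout)
  dgamma <- colSums(dout * cache$xhat)
  dbeta <- colSums(dout)
  dxhat <- sweep(dout, 2, bn$gamma, "*")
  # dx = (inv_sd / n) * (n*dxhat - colSums(dxhat) - xhat * colSums(dxhat*xhat))
  t1 <- n * dxhat
  t2 <- matrix(colSums(dxhat), n, ncol(dout), byrow = TRUE)
  t3 <- cache$xhat * matrix(colSums(dxhat * cache$xhat), n, ncol(dout), byrow = TRUE)
  dx <- sweep(t1 - t2 - t3, 2, cache$inv_sd / n, "*")
  list(dx = dx, dgamma = dgamma, dbeta = dbeta)
}

nn_dropout_forward <- function(x, rate, training = TRUE) {
  if (!training || rate <= 0) {
    return(list(out = x, mask = NULL))
  }
  mask <- matrix(stats::rbinom(length(x), 1, 1 - rate), nrow(x), ncol(x)) / (1 - rate)
  list(out = x * mask, mask = mask)
}

nn_dropout_backward <- function(dout, cache) {
  if (is.null(cache$mask)) dout else dout * cache$mask
}

# He-uniform style initialisation, deterministic under the caller's RNG state
nn_init_weight <- function(n_in, n_out) {
  lim <- sqrt(6 / n_in)
  matrix(stats::runif(n_in * n_out, -lim, lim), n_in, n_out)
}

# ---- generic parameter-tree helpers -------------------------------------

# walk two parallel nested lists of numeric arrays, applying f(leaf_a, leaf_b)
ptree_map2 <- function(a, b, f) {
  if (is.list(a)) {
    out <- mapply(ptree_map2, a, b, MoreArgs = list(f = f), SIMPLIFY = FALSE)
    names(out) <- names(a)
    out
  } else {
    f(a, b)
  }
}

ptree_map <- function(a, f) {
  if (is.list(a)) {
    out <- lapply(a, ptree_map, f = f)
    names(out) <- names(a)
    out
  } else {
    f(a)
  }
}

ptree_sumsq <- function(a) {
  if (is.list(a)) sum(vapply(a, ptree_sumsq, numeric(1))) else sum(a^2)
}

# L2 norm (not squared) of a parameter tree, as printed in the training
# objectives; its subgradient at the origin is taken as zero
ptree_l2norm <- function(a) sqrt(ptree_sumsq(a))

adam_init <- function(params) {
  list(
    m = ptree_map(params, function(p) p * 0),
    v = ptree_map(params, function(p) p * 0),
    t = 0
  )
}

adam_step <- function(params, grads, state, lr = 1e-3, beta1 = 0.9,
                      beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1
  state$m <- ptree_map2(state$m, grads, function(m, g) beta1 * m + (1 - beta1) * g)
  state$v <- ptree_map2(state$v, grads, function(v, g) beta2 * v + (1 - beta2) * g^2)
  mhat <- ptree_map(state$m, function(m) m / (1 - beta1^state$t))
  vhat <- ptree_map(state$v, function(v) v / (1 - beta2^state$t))
  upd <- ptree_map2(mhat, vhat, function(m, v) lr * m / (sqrt(v) + eps))
  params <- ptree_map2(params, upd, function(p, u) p - u)
  list(params = params, state = state)
}

# gradient of lambda * ||theta||_2 with respect to every leaf
ptree_l2norm_grad <- function(params, lambda) {
  nrm <- ptree_l2norm(params)
  if (nrm == 0 || lambda == 0) {
    return(ptree_map(params, function(p) p * 0))
  }
  ptree_map(params, function(p) lambda * p / nrm)
}

ptree_add <- function(a, b) ptree_map2(a, b, `+`)
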