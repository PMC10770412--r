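#' Specification of the latent-feature survival network
#'
#' A shallow feed-forward Cox network: one hidden layer with hyperbolic
#' tangent activation and dropout, then a single linear output unit with no
#' bias (the Cox log-risk function carries no intercept). Its scalar output
#' is the prognostic index (PI); higher PI means higher predicted hazard.
#'
#' @param n_inputs Number of input features (latent means plus clinical
#'   covariates).
#' @param hidden_width Hidden units (default 16).
#' @param dropout_rate Dropout probability in [0, 1) applied to the hidden
#'   activations during training (default 0.2).
#' @return A `survnet_spec` list.
#' @export
survnet_spec <- function(n_inputs, hidden_width = 16, dropout_rate = 0.2) {
  stopifnot(n_inputs >= 1, hidden_width >= 1,
            dropout_rate >= 0, dropout_rate < 1)
  structure(
    list(n_inputs = as.integer(n_inputs),
         hidden_width = as.integer(hidden_width),
         dropout_rate = dropout_rate),
    class = "survnet_spec"
  )
}

survnet_init <- function(spec, seed = 1L, zero = FALSE) {
  with_seed(seed, {
    if (zero) {
      list(
        W1 = matrix(0, spec$n_inputs, spec$hidden_width),
        b1 = rep(0, spec$hidden_width),
        w2 = matrix(0, spec$hidden_width, 1)
      )
    } else {
      list(
        W1 = nn_init_weight(spec$n_inputs, spec$hidden_width),
        b1 = rep(0, spec$hidden_width),
        w2 = nn_init_weight(spec$hidden_width, 1)
      )
    }
  })
}

#' Forward pass: features to prognostic index
#'
#' @param features Numeric matrix (samples x inputs): latent posterior means
#'   column-bound with clinical covariates. Row names are used as sample ids.
#' @param spec A [survnet_spec()].
#' @param params Network parameters (`W1`, `b1`, `w2`); defaults may come
#'   from a [train_lfsurv()] fit.
#' @param training Logical; dropout is active only when TRUE.
#' @return A tibble with columns `sample_id` and `pi`.
#' @export
forward_pi <- function(features, spec, params, training = FALSE) {
  features <- as.matrix(features)
  if (ncol(features) != spec$n_inputs) stop("feature width does not match spec")
  fw <- survnet_forward(features, spec, params, training = training)
  tibble::tibble(
    sample_id = rownames(features) %||% as.character(seq_len(nrow(features))),
    pi = as.numeric(fw$pi)
  )
}

survnet_forward <- function(x, spec, params, training = FALSE) {
  lin1 <- nn_linear_forward(x, params$W1, params$b1)
  act1 <- nn_tanh_forward(lin1$out)
  drop1 <- nn_dropout_forward(act1$out, spec$dropout_rate, training = training)
  pi <- drop1$out %*% params$w2 # linear, no bias
  list(pi = pi, lin1 = lin1, act1 = act1, drop1 = drop1, x = x)
}

#' Average negative log partial likelihood (Cox loss)
#'
#' Implements `-(1/n_events) * sum over events i of (PI_i - log sum_{j in
#' R(T_i)} exp(PI_j)) + lambda2 * ||theta||_2` with risk sets
#' `R(T_i) = {j : T_j >= T_i}`, so tied event times follow the Breslow
#' convention (every tied subject sits in every tied event's risk set). The
#' log-sum-exp is computed stably. The unpenalised loss is invariant to
#' adding a constant to every PI.
#'
#' @param pi A tibble from [forward_pi()] or a numeric vector of prognostic
#'   indices.
#' @param surv A survival tibble aligned with `pi` (matched by `sample_id`
#'   when `pi` carries ids).
#' @param lambda2 L2 penalty weight (default 0).
#' @param params Parameter tree penalised when `lambda2 > 0`.
#' @return The scalar loss.
#' @examples
#' surv <- tibble::tibble(sample_id = c("a", "b"), time = c(1, 2), event = c(1, 1))
#' cox_loss(c(a = 0, b = 0), surv) # log(2) / 2
#' @export
cox_loss <- function(pi, surv, lambda2 = 0, params = NULL) {
  pi_vec <- align_pi(pi, surv)
  res <- cox_loss_grad(pi_vec, surv$time, surv$event)
  pen <- if (lambda2 > 0 && !is.null(params)) lambda2 * ptree_l2norm(params) else 0
  res$loss + pen
}

align_pi <- function(pi, surv) {
  if (is.data.frame(pi)) {
    idx <- match(surv$sample_id, pi$sample_id)
    if (anyNA(idx)) stop("pi and survival tables do not share sample ids")
    pi$pi[idx]
  } else if (!is.null(names(pi))) {
    idx <- match(surv$sample_id, names(pi))
    if (anyNA(idx)) stop("pi names do not cover the survival table")
    unname(pi[idx])
  } else {
    stopifnot(length(pi) == nrow(surv))
    as.numeric(pi)
  }
}

# loss and d loss / d pi of the unpenalised average negative log partial
# likelihood; Breslow ties via risk sets {j : T_j >= T_i}
cox_loss_grad <- function(pi, time, event) {
  n_ev <- sum(event == 1)
  if (n_ev == 0) stop("partial likelihood undefined: no events")
  ord <- order(time, decreasing = TRUE)
  pi_o <- pi[ord]
  m <- max(pi_o)
  # running log-sum-exp over subjects with T >= t, walking times downward
  csum <- cumsum(exp(pi_o - m))
  # ties: every subject with the same time must be included
  time_o <- time[ord]
  last_idx <- cumsum(rle(time_o)$lengths)
  idx_full <- rep(last_idx, rle(time_o)$lengths)
  lse <- m + log(csum[idx_full])
  ev_o <- event[ord] == 1
  loss <- -sum(pi_o[ev_o] - lse[ev_o]) / n_ev

  # gradient: d/d pi_k = -(1/nev) * (delta_k - sum_{i events, T_k >= T_i} w_ik)
  # with w_ik = exp(pi_k) / sum_{j in R(T_i)} exp(pi_j)
  denom <- csum[idx_full] # scaled by exp(-m)
  inv_contrib <- ifelse(ev_o, 1 / denom, 0)
  # subjects sorted by decreasing time: R(T_i) = positions 1..idx_full[i]
  # sum over events i with position index >= position of k? No: k in R(T_i)
  # iff T_k >= T_i iff position(k) <= idx_full[i]. For subject at position q,
  # the relevant events are those i with idx_full[i] >= q.
  rev_cum <- rev(cumsum(rev(inv_contrib)))
  # include all events whose full risk-set endpoint covers q: since
  # idx_full[i] >= i always, events at positions >= q qualify iff
  # idx_full[i] >= q; idx_full is non-decreasing in i? time_o decreasing =>
  # idx_full non-decreasing. For q <= i, idx_full[i] >= idx_full[q] >= q.
  # For i < q, idx_full[i] >= q iff T_i == T_q tie block. rev_cum at the
  # start of k's tie block captures exactly these.
  first_idx <- c(1, utils::head(last_idx, -1) + 1)
  first_full <- rep(first_idx, rle(time_o)$lengths)
  s_k <- rev_cum[first_full]
  grad_o <- -(as.numeric(ev_o) - exp(pi_o - m) * s_k) / n_ev
  grad <- numeric(length(pi))
  grad[ord] <- grad_o
  list(loss = loss, grad = grad)
}

#' Train the survival network
#'
#' Full-batch Adam on the penalised average negative log partial likelihood
#' (risk sets are global, so full-batch gradients are exact). Model
#' selection keeps the epoch with the highest validation concordance index.
#'
#' @param train,valid Lists with `features` (matrix) and `surv` (survival
#'   tibble); `valid` may be NULL (final epoch kept).
#' @param spec A [survnet_spec()].
#' @param lambda2 L2 penalty weight (default 0).
#' @param lr Adam learning rate (default 0.01).
#' @param n_epochs Training epochs (default 200).
#' @param seed Integer seed (initialisation and dropout).
#' @return An `lfsurv_fit` with `params`, `spec`, `best_epoch` and a
#'   per-epoch `history` tibble (train loss, validation C-index).
#' @export
train_lfsurv <- function(train, valid = NULL, spec, lambda2 = 0, lr = 0.01,
                         n_epochs = 200, seed = 1L) {
  stopifnot(sum(train$surv$event) >= 1)
  x <- as.matrix(train$features)
  pi_order <- align_check(x, train$surv)
  params <- survnet_init(spec, seed = seed)
  opt <- adam_init(params)
  best <- list(cindex = -Inf, params = params, epoch = 0L)
  history <- vector("list", n_epochs)
  with_seed(seed + 1L, {
    for (epoch in seq_len(n_epochs)) {
      fw <- survnet_forward(x, spec, params, training = TRUE)
      cl <- cox_loss_grad(as.numeric(fw$pi)[pi_order], train$surv$time,
                          train$surv$event)
      if (!is.finite(cl$loss)) stop("Cox loss diverged (non-finite)")
      dpi <- numeric(nrow(x))
      dpi[pi_order] <- cl$grad
      dpi <- matrix(dpi, ncol = 1)
      g <- list(
        W1 = NULL, b1 = NULL,
        w2 = t(fw$drop1$out) %*% dpi
      )
      dh <- dpi %*% t(params$w2)
      dh <- nn_dropout_backward(dh, fw$drop1)
      dh <- nn_tanh_backward(dh, fw$act1)
      bk <- nn_linear_backward(dh, fw$lin1, params$W1)
      g$W1 <- bk$dW
      g$b1 <- bk$db
      if (lambda2 > 0) g <- ptree_add(g, ptree_l2norm_grad(params, lambda2))
      upd <- adam_step(params, g, opt, lr = lr)
      params <- upd$params
      opt <- upd$state
      val_c <- NA_real_
      if (!is.null(valid)) {
        vpi <- forward_pi(as.matrix(valid$features), spec, params)
        val_c <- concordance_index(vpi, valid$surv)$c_index
        if (val_c > best$cindex) {
          best <- list(cindex = val_c, params = params, epoch = epoch)
        }
      }
      history[[epoch]] <- tibble::tibble(
        epoch = epoch, train_loss = cl$loss, valid_cindex = val_c
      )
    }
  })
  if (is.null(valid) || best$epoch == 0L) {
    best <- list(cindex = NA_real_, params = params, epoch = n_epochs)
  }
  structure(
    list(
      params = best$params, spec = spec, best_epoch = best$epoch,
      valid_cindex = best$cindex,
      history = if (n_epochs > 0) dplyr::bind_rows(history) else tibble::tibble(),
      lambda2 = lambda2, seed = seed
    ),
    class = "lfsurv_fit"
  )
}

align_check <- function(x, surv) {
  ids <- rownames(x)
  if (is.null(ids)) {
    stopifnot(nrow(x) == nrow(surv))
    return(seq_len(nrow(x)))
  }
  idx <- match(surv$sample_id, ids)
  if (anyNA(idx)) stop("feature rows and survival table do not share sample ids")
  idx
}

#' Predict prognostic indices from a trained fit
#'
#' @param object An `lfsurv_fit`.
#' @param features Feature matrix with the same columns used in training.
#' @param ... Unused.
#' @return A tibble with `sample_id` and `pi`.
#' @export
predict.lfsurv_fit <- function(object, features, ...) {
  forward_pi(features, object$spec, object$params, training = FALSE)
}

#' Assign high/low risk groups by the tuning-set median PI
#'
#' The threshold `pi_med` is the median prognostic index of the tuning
#' cohort (mean of the two central order statistics for even n). Target
#' samples with `pi > pi_med` are labelled high risk; all others, including
#' exact ties, are low risk. The threshold cohort may differ from the
#' labelled cohort (cross-dataset risk grouping).
#'
#' @param tuning_pi Tibble (`sample_id`, `pi`) or numeric vector defining
#'   the threshold.
#' @param target_pi Samples to label; defaults to `tuning_pi`.
#' @return A `risk_groups` tibble (`sample_id`, `pi`, `risk_group`) with the
#'   threshold in attribute `pi_med`.
#' @examples
#' tune <- tibble::tibble(sample_id = as.character(1:4), pi = 1:4)
#' assign_risk_groups(tune, tibble::tibble(sample_id = "x", pi = 2.6))
#' @export
assign_risk_groups <- function(tuning_pi, target_pi = tuning_pi) {
  tp <- if (is.data.frame(tuning_pi)) tuning_pi$pi else as.numeric(tuning_pi)
  stopifnot(length(tp) > 0)
  pi_med <- stats::median(tp)
  tgt <- if (is.data.frame(target_pi)) {
    target_pi
  } else {
    tibble::tibble(
      sample_id = names(target_pi) %||% as.character(seq_along(target_pi)),
      pi = as.numeric(target_pi)
    )
  }
  out <- dplyr::mutate(
    tgt[, c("sample_id", "pi")],
    risk_group = ifelse(.data$pi > pi_med, "high", "low")
  )
  attr(out, "pi_med") <- pi_med
  class(out) <- c("risk_groups", class(out))
  out
}
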