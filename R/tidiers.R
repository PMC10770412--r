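#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy the per-epoch training history of a VAE fit
#'
#' @param x A `kl_pmvae_fit`.
#' @param ... Unused.
#' @return A tibble with one row per epoch: `beta`, the loss terms and the
#'   validation reconstruction loss.
#' @export
tidy.kl_pmvae_fit <- function(x, ...) {
  if (inherits(x, "concat_vae_fit")) {
    return(dplyr::bind_rows(
      dplyr::mutate(x$gene_fit$history, block = "gene"),
      dplyr::mutate(x$mirna_fit$history, block = "miRNA")
    ))
  }
  x$history
}

#' @rdname tidy.kl_pmvae_fit
#' @export
glance.kl_pmvae_fit <- function(x, ...) {
  h <- tidy(x)
  tibble::tibble(
    n_epochs = max(h$epoch %||% 0L),
    best_epoch = if (inherits(x, "concat_vae_fit")) NA_integer_ else x$best_epoch,
    best_valid_recon = suppressWarnings(min(h$valid_recon, na.rm = TRUE)),
    integration = x$arch$integration,
    d_latent = x$arch$d_latent
  )
}

#' Tidy the training history of a survival-network fit
#'
#' @param x An `lfsurv_fit`.
#' @param ... Unused.
#' @return The per-epoch tibble (`train_loss`, `valid_cindex`).
#' @export
tidy.lfsurv_fit <- function(x, ...) x$history

#' @rdname tidy.lfsurv_fit
#' @export
glance.lfsurv_fit <- function(x, ...) {
  tibble::tibble(
    n_epochs = nrow(x$history), best_epoch = x$best_epoch,
    valid_cindex = x$valid_cindex,
    hidden_width = x$spec$hidden_width,
    dropout_rate = x$spec$dropout_rate, lambda2 = x$lambda2
  )
}

#' Tidy an experiment report
#'
#' @param x An `experiment_report`.
#' @param ... Unused.
#' @return The per-repeat tibble (winning hyperparameters, validation
#'   metric, testing C-index).
#' @export
tidy.experiment_report <- function(x, ...) x$repeats

#' @rdname tidy.experiment_report
#' @export
glance.experiment_report <- function(x, ...) x$summary

#' Tidy an attribution table into long format
#'
#' @param x An `attribution_table`.
#' @param ... Unused.
#' @return A long tibble: `sample_id`, `feature`, `shap`.
#' @export
tidy.attribution_table <- function(x, ...) {
  df <- tibble::as_tibble(x$shap, .name_repair = "minimal")
  df$sample_id <- x$explained_sample_ids %||% as.character(seq_len(nrow(x$shap)))
  tidyr::pivot_longer(df, -"sample_id",
    names_to = "feature", values_to = "shap"
  )
}

#' @rdname tidy.attribution_table
#' @export
glance.attribution_table <- function(x, ...) {
  tibble::tibble(
    target = as.character(x$target),
    n_explained = nrow(x$shap), n_reference = length(x$reference_sample_ids),
    top_feature = x$overall$feature[1], top_score = x$overall$overall[1]
  )
}

#' Plot a Kaplan-Meier estimate
#'
#' @param object A `km_estimate` tibble.
#' @param ... Unused.
#' @return A ggplot step plot of the survival probability.
#' @export
autoplot.km_estimate <- function(object, ...) {
  df <- dplyr::bind_rows(
    tibble::tibble(time = 0, survival = 1),
    object[, c("time", "survival")]
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time, y = .data$survival)) +
    ggplot2::geom_step() +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "Time", y = "Survival probability") +
    ggplot2::theme_minimal()
}

#' Plot a cyclical KL-annealing schedule
#'
#' @param object An `annealing_schedule`.
#' @param ... Unused.
#' @return A ggplot of the per-epoch KL weight.
#' @export
autoplot.annealing_schedule <- function(object, ...) {
  df <- tibble::tibble(epoch = seq_along(object$beta_path), beta = object$beta_path)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$epoch, y = .data$beta)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::labs(x = "Epoch", y = expression(beta)) +
    ggplot2::theme_minimal()
}

#' Plot the top overall contribution scores of an attribution table
#'
#' @param object An `attribution_table`.
#' @param top_n How many features to show (default 15).
#' @param ... Unused.
#' @return A ggplot bar chart of mean |SHAP| per feature.
#' @export
autoplot.attribution_table <- function(object, top_n = 15, ...) {
  df <- utils::head(object$overall, top_n)
  df$feature <- factor(df$feature, levels = rev(df$feature))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$overall, y = .data$feature)) +
    ggplot2::geom_col() +
    ggplot2::labs(
      x = "Overall contribution (mean |SHAP|)", y = NULL,
      title = paste("Target:", object$target)
    ) +
    ggplot2::theme_minimal()
}

#' Plot the training history of a survival-network fit
#'
#' @param object An `lfsurv_fit`.
#' @param ... Unused.
#' @return A ggplot of training loss and validation C-index over epochs.
#' @export
autoplot.lfsurv_fit <- function(object, ...) {
  df <- tidyr::pivot_longer(object$history, -"epoch",
    names_to = "metric", values_to = "value"
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$epoch, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::theme_minimal()
}
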