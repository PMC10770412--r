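#' Construct an omics expression block
#'
#' An `omics_matrix` is a plain numeric matrix (samples in rows, features in
#' columns) carrying sample and feature identifiers in its dimnames plus an
#' `omics_kind` attribute (`"gene"` or `"miRNA"`). It is the container for a
#' single expression block throughout the package: min-max normalisation,
#' variance filtering, the pathway-masked autoencoder and the attribution
#' layer all consume and return it.
#'
#' @param values Numeric matrix (n_samples x n_features) or a data frame whose
#'   first column holds sample identifiers and remaining columns are numeric
#'   features.
#' @param sample_ids,feature_ids Character vectors; taken from dimnames when
#'   omitted.
#' @param omics_kind `"gene"` or `"miRNA"`.
#' @return An `omics_matrix` object.
#' @examples
#' m <- omics_matrix(matrix(runif(12), 3, 4,
#'   dimnames = list(paste0("s", 1:3), paste0("g", 1:4))), omics_kind = "gene")
#' dim(m)
#' @export
omics_matrix <- function(values, sample_ids = NULL, feature_ids = NULL,
                         omics_kind = c("gene", "miRNA")) {
  omics_kind <- match.arg(omics_kind)
  if (is.data.frame(values)) {
    ids <- as.character(values[[1]])
    values <- as.matrix(values[, -1, drop = FALSE])
    rownames(values) <- ids
  }
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (!is.null(sample_ids)) rownames(values) <- sample_ids
  if (!is.null(feature_ids)) colnames(values) <- feature_ids
  if (is.null(rownames(values))) {
    rownames(values) <- paste0("sample_", seq_len(nrow(values)))
  }
  if (is.null(colnames(values))) {
    colnames(values) <- paste0("feature_", seq_len(ncol(values)))
  }
  if (anyDuplicated(rownames(values))) stop("duplicate sample ids")
  if (anyDuplicated(colnames(values))) stop("duplicate feature ids")
  if (!all(is.finite(values))) stop("expression values must be finite")
  structure(values, omics_kind = omics_kind, class = c("omics_matrix", "matrix", "array"))
}

#' @export
print.omics_matrix <- function(x, ...) {
  cat(sprintf(
    "<omics_matrix> %s block: %d samples x %d features\n",
    attr(x, "omics_kind"), nrow(x), ncol(x)
  ))
  invisible(x)
}

omics_kind <- function(x) attr(x, "omics_kind") %||% "gene"

# restore class/attributes after matrix surgery
restore_omics <- function(values, template) {
  structure(values,
    omics_kind = omics_kind(template),
    class = c("omics_matrix", "matrix", "array")
  )
}

#' Convert an omics block to a tibble
#'
#' @param x An `omics_matrix`.
#' @param ... Unused.
#' @return A tibble with a `sample_id` column followed by one column per feature.
#' @importFrom tibble as_tibble
#' @method as_tibble omics_matrix
#' @export
as_tibble.omics_matrix <- function(x, ...) {
  out <- tibble::as_tibble(unclass(x), .name_repair = "minimal")
  dplyr::bind_cols(tibble::tibble(sample_id = rownames(x)), out)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
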