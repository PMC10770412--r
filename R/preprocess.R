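#' Min-max normalise an expression block to [0, 1]
#'
#' Rescales every feature to the unit interval: v -> (v - v_min) / (v_max -
#' v_min), with the per-feature minimum and maximum taken from the matrix
#' itself or, when `reference_stats` is supplied (e.g. tuning-set statistics
#' applied to held-out data), from the reference; values falling outside
#' [0, 1] under reference statistics are clipped. A constant feature maps to
#' all zeros with a warning rather than an error.
#'
#' @param matrix An [omics_matrix()].
#' @param reference_stats Optional result of [minmax_stats()] computed on
#'   another cohort slice; feature sets must match.
#' @return An `omics_matrix` with all values in [0, 1].
#' @examples
#' m <- omics_matrix(matrix(c(0, 5, 10, 2, 3, 7), 3, 2,
#'   dimnames = list(paste0("s", 1:3), c("g1", "g2"))))
#' minmax_normalize(m)
#' @seealso [variance_filter()]
#' @export
minmax_normalize <- function(matrix, reference_stats = NULL) {
  stopifnot(inherits(matrix, "omics_matrix"))
  if (is.null(reference_stats)) {
    reference_stats <- minmax_stats(matrix)
  } else {
    if (!identical(reference_stats$feature_ids, colnames(matrix))) {
      stop("reference_stats feature set does not match the matrix")
    }
  }
  vmin <- reference_stats$min
  vmax <- reference_stats$max
  rng <- vmax - vmin
  constant <- rng == 0
  if (any(constant)) {
    warning(sprintf(
      "%d constant feature(s) mapped to all zeros (v_max == v_min)",
      sum(constant)
    ))
    rng[constant] <- 1
  }
  out <- sweep(sweep(unclass(matrix), 2, vmin, "-"), 2, rng, "/")
  out[, constant] <- 0
  out[out < 0] <- 0
  out[out > 1] <- 1
  restore_omics(out, matrix)
}

#' Per-feature min/max statistics for min-max normalisation
#'
#' @param matrix An [omics_matrix()].
#' @return A list with `min`, `max` and `feature_ids`, suitable for the
#'   `reference_stats` argument of [minmax_normalize()].
#' @export
minmax_stats <- function(matrix) {
  stopifnot(inherits(matrix, "omics_matrix"))
  list(
    min = apply(unclass(matrix), 2, min),
    max = apply(unclass(matrix), 2, max),
    feature_ids = colnames(matrix)
  )
}

#' Remove low-variance features from a normalised block
#'
#' Drops features whose sample variance (n - 1 divisor) falls below
#' `threshold`, the standard denoising step applied to min-max normalised
#' expression on the tuning samples before model fitting. The returned
#' filter can be re-applied to other splits via `keep_ids`.
#'
#' @param matrix A min-max normalised [omics_matrix()].
#' @param threshold Minimum variance to retain a feature (default 0.02).
#' @param keep_ids Optional character vector: skip the variance computation
#'   and retain exactly these features (used to carry a tuning-set filter to
#'   validation/test splits).
#' @return A list with `matrix` (the filtered block), `kept` and `removed`
#'   feature id vectors.
#' @examples
#' m <- omics_matrix(matrix(c(0, 1, 0, 1, .5, .5, .5, .5), 4, 2,
#'   dimnames = list(paste0("s", 1:4), c("variable", "constant"))))
#' variance_filter(m)$removed
#' @export
variance_filter <- function(matrix, threshold = 0.02, keep_ids = NULL) {
  stopifnot(inherits(matrix, "omics_matrix"))
  if (is.null(keep_ids)) {
    v <- apply(unclass(matrix), 2, stats::var)
    keep <- v >= threshold
  } else {
    keep <- colnames(matrix) %in% keep_ids
  }
  if (!any(keep)) {
    stop(sprintf("variance filter at threshold %g removed every feature", threshold))
  }
  list(
    matrix = restore_omics(unclass(matrix)[, keep, drop = FALSE], matrix),
    kept = colnames(matrix)[keep],
    removed = colnames(matrix)[!keep]
  )
}

#' Build a binary gene-to-pathway connection mask
#'
#' Intersects each pathway's member set with the genes present in the
#' dataset, drops pathways whose realised size falls outside
#' `[min_genes, max_genes]`, then drops genes that belong to no retained
#' pathway. The resulting 0/1 matrix (genes x pathways) constrains the
#' first encoder transform and the last gene-decoder transform of the
#' pathway-masked autoencoder: a gene node connects to a pathway node only
#' if the gene is a member of that pathway.
#'
#' @param pathways A named list mapping pathway id to a character vector of
#'   gene ids (as returned by [read_gmt()] or [pathway_collection()]).
#' @param dataset_genes Character vector of genes present in the expression
#'   block.
#' @param min_genes,max_genes Realised pathway size bounds (defaults 15 and
#'   300).
#' @return A `pathway_mask`: binary matrix with gene ids as rownames and
#'   pathway ids as colnames.
#' @examples
#' pw <- list(P1 = c("g1", "g2"), P2 = c("g2", "g3"))
#' build_pathway_mask(pw, c("g1", "g2", "g3"), min_genes = 2, max_genes = 3)
#' @export
build_pathway_mask <- function(pathways, dataset_genes, min_genes = 15,
                               max_genes = 300) {
  if (inherits(pathways, "pathway_collection")) pathways <- pathways$pathways
  stopifnot(length(dataset_genes) > 0)
  realized <- lapply(pathways, intersect, y = dataset_genes)
  sizes <- lengths(realized)
  keep <- sizes >= min_genes & sizes <= max_genes
  if (!any(keep)) {
    stop(sprintf(
      "no pathway has between %d and %d genes in this dataset", min_genes, max_genes
    ))
  }
  realized <- realized[keep]
  genes <- sort(unique(unlist(realized)))
  mask <- matrix(0L, length(genes), length(realized),
    dimnames = list(genes, names(realized))
  )
  for (p in names(realized)) mask[realized[[p]], p] <- 1L
  structure(mask, class = c("pathway_mask", "matrix", "array"))
}

#' @export
print.pathway_mask <- function(x, ...) {
  cat(sprintf(
    "<pathway_mask> %d genes x %d pathways, %d connections\n",
    nrow(x), ncol(x), sum(x)
  ))
  invisible(x)
}

#' Reproducible test / train / validation split plan
#'
#' Randomly holds out `test_fraction` of the samples as a testing set (never
#' touched during tuning), then splits the remaining tuning set into
#' training and validation sets at the given ratio (default 4:1, i.e. 64%
#' and 16% of the whole cohort when `test_fraction = 0.2`). Sizes round
#' down; determinism is guaranteed by the seed.
#'
#' @param sample_ids Character vector of at least 10 ids.
#' @param seed Integer seed.
#' @param test_fraction Fraction held out for testing (default 0.2).
#' @param valid_fraction Fraction of the tuning set used for validation
#'   (default 0.2, the 4:1 train:validation ratio).
#' @return A `split_plan` list: `seed`, `test_ids`, `tuning_ids`,
#'   `train_ids`, `valid_ids`.
#' @examples
#' sp <- make_splits(paste0("s", 1:100), seed = 1)
#' lengths(sp[c("test_ids", "train_ids", "valid_ids")])
#' @export
make_splits <- function(sample_ids, seed, test_fraction = 0.2,
                        valid_fraction = 0.2) {
  stopifnot(length(sample_ids) >= 10, !anyDuplicated(sample_ids))
  n <- length(sample_ids)
  n_test <- floor(test_fraction * n)
  with_seed(seed, {
    test_ids <- sample(sample_ids, n_test)
    tuning_ids <- setdiff(sample_ids, test_ids)
    n_valid <- floor(valid_fraction * length(tuning_ids))
    valid_ids <- sample(tuning_ids, n_valid)
  })
  train_ids <- setdiff(tuning_ids, valid_ids)
  if (length(train_ids) == 0 || n_test == 0) {
    stop("too few samples to populate every split")
  }
  structure(
    list(
      seed = seed, test_ids = test_ids, tuning_ids = tuning_ids,
      train_ids = train_ids, valid_ids = valid_ids
    ),
    class = "split_plan"
  )
}

#' Re-split a tuning set into training and validation ids
#'
#' Used by the repeated-split protocol: the testing set stays fixed while the
#' tuning set is re-divided 4:1 with a fresh seed.
#'
#' @param tuning_ids Character vector of tuning-sample ids.
#' @param seed Integer seed.
#' @param valid_fraction Fraction assigned to validation (default 0.2).
#' @return A list with `train_ids` and `valid_ids`.
#' @export
split_tuning <- function(tuning_ids, seed, valid_fraction = 0.2) {
  n_valid <- floor(valid_fraction * length(tuning_ids))
  valid_ids <- with_seed(seed, sample(tuning_ids, n_valid))
  list(train_ids = setdiff(tuning_ids, valid_ids), valid_ids = valid_ids)
}

#' Restrict two cohorts to their common features
#'
#' Cross-dataset validation requires both cohorts to share a feature space;
#' this intersects the feature sets and reorders both blocks identically,
#' preserving each cohort's own samples.
#'
#' @param a,b Two [omics_matrix()] objects of the same `omics_kind`.
#' @return A list of the two restricted matrices.
#' @export
align_cohorts <- function(a, b) {
  stopifnot(inherits(a, "omics_matrix"), inherits(b, "omics_matrix"))
  if (!identical(omics_kind(a), omics_kind(b))) {
    stop("cohorts hold different omics kinds")
  }
  common <- intersect(colnames(a), colnames(b))
  if (length(common) == 0) stop("cohorts share no features")
  list(
    a = restore_omics(unclass(a)[, common, drop = FALSE], a),
    b = restore_omics(unclass(b)[, common, drop = FALSE], b)
  )
}

# run expr under a temporary RNG state
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}
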