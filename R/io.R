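#' Read an expression TSV (samples as rows)
#'
#' Expects a header row of feature ids, a first column of sample ids and
#' numeric values elsewhere. CRLF and LF line endings are both accepted.
#'
#' @param path Path to a TSV file.
#' @param omics_kind `"gene"` or `"miRNA"`.
#' @return An [omics_matrix()].
#' @export
read_expression_tsv <- function(path, omics_kind = c("gene", "miRNA")) {
  omics_kind <- match.arg(omics_kind)
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  omics_matrix(df, omics_kind = omics_kind)
}

#' Read a survival outcome TSV
#'
#' Requires columns `sample_id`, `time` (non-negative follow-up) and `event`
#' (1 = death observed, 0 = right-censored). Missing values in any of the
#' three columns are an error.
#'
#' @param path Path to a TSV file.
#' @return A tibble validated by [survival_table()].
#' @export
read_survival_tsv <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  survival_table(df)
}

#' Validate a survival table
#'
#' @param df Data frame with columns `sample_id`, `time`, `event`.
#' @return A tibble with the three validated columns.
#' @export
survival_table <- function(df) {
  stopifnot(all(c("sample_id", "time", "event") %in% names(df)))
  out <- tibble::as_tibble(df)[, c("sample_id", "time", "event")]
  out$sample_id <- as.character(out$sample_id)
  if (anyDuplicated(out$sample_id)) stop("duplicate sample ids in survival table")
  if (anyNA(out$time) || anyNA(out$event)) {
    stop("missing values are forbidden in survival columns")
  }
  if (any(out$time < 0)) stop("follow-up time must be non-negative")
  if (!all(out$event %in% c(0, 1))) stop("event indicator must be 0 or 1")
  out
}

#' Read a clinical covariate TSV
#'
#' First column must be `sample_id`; all remaining columns must be numeric
#' after encoding (age scaled to [0, 1], binary stage/grade/race dummies).
#'
#' @param path Path to a TSV file.
#' @return A tibble.
#' @export
read_clinical_tsv <- function(path) {
  df <- tibble::as_tibble(utils::read.delim(path, stringsAsFactors = FALSE))
  stopifnot(names(df)[1] == "sample_id")
  df$sample_id <- as.character(df$sample_id)
  num <- df[, -1, drop = FALSE]
  if (!all(vapply(num, is.numeric, logical(1)))) {
    stop("clinical covariates must be numeric after encoding")
  }
  if (!all(is.finite(as.matrix(num)))) stop("clinical covariates must be finite")
  df
}

#' Read pathway gene sets from a GMT file
#'
#' Standard GMT layout: pathway id, description, then tab-separated gene
#' ids. Parsed with `fgsea::gmtPathways()` when available, else by hand.
#'
#' @param path Path to a GMT file.
#' @return A [pathway_collection()].
#' @export
read_gmt <- function(path) {
  if (requireNamespace("fgsea", quietly = TRUE)) {
    sets <- fgsea::gmtPathways(path)
    lines <- readLines(path, warn = FALSE)
    fields <- strsplit(sub("\r$", "", lines), "\t", fixed = TRUE)
    names_map <- vapply(fields, function(f) f[2], character(1))
    names(names_map) <- vapply(fields, function(f) f[1], character(1))
  } else {
    lines <- readLines(path, warn = FALSE)
    fields <- strsplit(sub("\r$", "", lines), "\t", fixed = TRUE)
    sets <- lapply(fields, function(f) f[-(1:2)])
    names(sets) <- vapply(fields, function(f) f[1], character(1))
    names_map <- vapply(fields, function(f) f[2], character(1))
    names(names_map) <- names(sets)
  }
  pathway_collection(sets, names_map)
}

#' Construct a pathway collection
#'
#' @param pathways Named list mapping pathway id to a character vector of
#'   member gene ids; sets must be non-empty and ids unique.
#' @param descriptions Optional named character vector of pathway
#'   descriptions.
#' @return A `pathway_collection` list with elements `pathways` and `names`.
#' @export
pathway_collection <- function(pathways, descriptions = NULL) {
  stopifnot(is.list(pathways), length(pathways) > 0)
  if (is.null(names(pathways)) || anyDuplicated(names(pathways))) {
    stop("pathway ids must be present and unique")
  }
  if (any(lengths(pathways) == 0)) stop("pathway gene sets must be non-empty")
  if (is.null(descriptions)) {
    descriptions <- stats::setNames(names(pathways), names(pathways))
  }
  structure(
    list(pathways = pathways, names = descriptions),
    class = "pathway_collection"
  )
}

#' Write a pathway collection as GMT
#'
#' @param pathways A [pathway_collection()].
#' @param path Output path.
#' @export
write_gmt <- function(pathways, path) {
  stopifnot(inherits(pathways, "pathway_collection"))
  lines <- vapply(names(pathways$pathways), function(p) {
    paste(c(p, unname(pathways$names[p]), pathways$pathways[[p]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
}

#' Write an omics block as TSV (samples as rows)
#'
#' @param matrix An [omics_matrix()].
#' @param path Output path.
#' @export
write_expression_tsv <- function(matrix, path) {
  df <- data.frame(sample_id = rownames(matrix), unclass(matrix), check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}
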