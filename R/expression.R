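#' Construct a gene-by-sample expression matrix with sample metadata
#'
#' The container used throughout the pipeline: a numeric matrix of intensities
#' (genes in rows, samples in columns) paired with per-column metadata giving
#' the sampling clock time, the replicate label, and the tissue.
#'
#' @param values Numeric matrix, genes x samples; rownames are gene
#'   identifiers and must be unique, all values finite.
#' @param sample_meta data.frame with columns `sample_id`, `time_h`,
#'   `replicate`, `tissue`; one row per matrix column, `sample_id` matching
#'   `colnames(values)`.
#' @return An object of class `expr_matrix` with elements `values` and `meta`.
#' @export
expression_matrix <- function(values, sample_meta) {
  if (!is.matrix(values) || !is.numeric(values)) {
    stop("`values` must be a numeric matrix", call. = FALSE)
  }
  if (is.null(rownames(values)) || anyDuplicated(rownames(values))) {
    stop("`values` must have unique rownames (gene identifiers)",
         call. = FALSE)
  }
  if (!all(is.finite(values))) {
    bad <- which(!is.finite(values), arr.ind = TRUE)[1L, ]
    stop(sprintf("non-finite value at gene '%s', sample column %d",
                 rownames(values)[bad[1L]], bad[2L]), call. = FALSE)
  }
  req <- c("sample_id", "time_h", "replicate", "tissue")
  if (!is.data.frame(sample_meta) || !all(req %in% names(sample_meta))) {
    stop("`sample_meta` needs columns sample_id, time_h, replicate, tissue",
         call. = FALSE)
  }
  if (nrow(sample_meta) != ncol(values)) {
    stop(sprintf("metadata has %d rows but matrix has %d columns",
                 nrow(sample_meta), ncol(values)), call. = FALSE)
  }
  if (is.null(colnames(values))) {
    colnames(values) <- sample_meta$sample_id
  }
  if (!identical(colnames(values), as.character(sample_meta$sample_id))) {
    miss <- setdiff(colnames(values), sample_meta$sample_id)
    if (length(miss)) {
      stop(sprintf("matrix column(s) without metadata: %s",
                   paste(miss, collapse = ", ")), call. = FALSE)
    }
    sample_meta <- sample_meta[match(colnames(values), sample_meta$sample_id), ]
  }
  if (any(sample_meta$time_h < 0 | sample_meta$time_h >= 24)) {
    stop("sample times must lie in [0, 24)", call. = FALSE)
  }
  rownames(sample_meta) <- NULL
  structure(list(values = values, meta = sample_meta), class = "expr_matrix")
}

#' @export
print.expr_matrix <- function(x, ...) {
  cat(sprintf("expr_matrix: %d genes x %d samples (%s)\n",
              nrow(x$values), ncol(x$values),
              paste(unique(x$meta$tissue), collapse = ", ")))
  cat(sprintf("  times: %s h\n",
              paste(sort(unique(x$meta$time_h)), collapse = ", ")))
  invisible(x)
}

#' @export
dim.expr_matrix <- function(x) dim(x$values)

#' Gene identifiers of an expression matrix
#' @param x An `expr_matrix`.
#' @return Character vector of gene ids.
#' @export
gene_ids <- function(x) {
  stopifnot(inherits(x, "expr_matrix"))
  rownames(x$values)
}

#' Read an expression matrix and its sample metadata from TSV files
#'
#' The matrix file is tab-delimited with a header row of sample ids and gene
#' ids in the first column; the metadata file has columns `sample_id`,
#' `time_h`, `replicate`, `tissue`. Every matrix column must match exactly one
#' metadata row; errors name the offending sample, gene, or cell.
#'
#' @param matrix_path Path to the expression TSV.
#' @param meta_path Path to the sample-metadata TSV.
#' @return An `expr_matrix`.
#' @export
read_expression_matrix <- function(matrix_path, meta_path) {
  raw <- utils::read.delim(matrix_path, check.names = FALSE,
                           stringsAsFactors = FALSE)
  if (ncol(raw) < 2L) {
    stop("expression matrix needs a gene-id column plus >= 1 sample column",
         call. = FALSE)
  }
  ids <- as.character(raw[[1L]])
  if (anyDuplicated(ids)) {
    stop(sprintf("duplicate gene_id in %s: %s", matrix_path,
                 paste(unique(ids[duplicated(ids)]), collapse = ", ")),
         call. = FALSE)
  }
  vals <- raw[, -1L, drop = FALSE]
  for (j in seq_along(vals)) {
    v <- suppressWarnings(as.numeric(vals[[j]]))
    if (anyNA(v) & !anyNA(vals[[j]])) {
      bad <- which(is.na(v))[1L]
      stop(sprintf("non-numeric cell at row %d (gene '%s'), column '%s'",
                   bad, ids[bad], names(vals)[j]), call. = FALSE)
    }
    vals[[j]] <- v
  }
  m <- as.matrix(vals)
  rownames(m) <- ids
  meta <- utils::read.delim(meta_path, stringsAsFactors = FALSE)
  missing_meta <- setdiff(colnames(m), meta$sample_id)
  if (length(missing_meta)) {
    stop(sprintf("metadata %s is missing sample(s): %s", meta_path,
                 paste(missing_meta, collapse = ", ")), call. = FALSE)
  }
  expression_matrix(m, meta[match(colnames(m), meta$sample_id), , drop = FALSE])
}

#' Write an expression matrix and its sample metadata to TSV files
#'
#' @param x An `expr_matrix`.
#' @param matrix_path Output path for the expression TSV (gene rows, sample
#'   columns, `gene_id` first column).
#' @param meta_path Output path for the metadata TSV; omit to skip.
#' @return Invisibly, `matrix_path`.
#' @export
write_expression_matrix <- function(x, matrix_path, meta_path = NULL) {
  stopifnot(inherits(x, "expr_matrix"))
  df <- data.frame(gene_id = rownames(x$values), x$values,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, matrix_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  if (!is.null(meta_path)) {
    utils::write.table(x$meta, meta_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(matrix_path)
}

# internal: a study_design recovered from sample metadata (used when an
# expr_matrix arrives without its generating design)
design_from_meta <- function(meta) {
  times <- sort(unique(meta$time_h))
  reps <- as.integer(max(table(meta$time_h)))
  study_design(times = times, replicates_per_time = reps)
}
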