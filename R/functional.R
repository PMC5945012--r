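#' The fixed functional-group vocabulary
#'
#' The eight biological-function categories used to classify circadian genes,
#' plus the explicit `"Unannotated"` bucket. Annotation tables must use these
#' labels verbatim.
#'
#' @return Character vector of the 8 group names.
#' @export
functional_groups <- function() {
  c("Cell Cycle/Apoptosis",
    "Inflammation/Immune response",
    "Metabolism",
    "Transcription/Translation Regulation",
    "Signaling",
    "Cytoskeleton/ECM",
    "mRNA/Protein Processing",
    "Transport")
}

#' Read and validate a gene-to-functional-group annotation table
#'
#' A two-column TSV (`gene_id`, `group`). Each gene must carry exactly one
#' group from [functional_groups()] (or `"Unannotated"`); genes with several
#' plausible functions must be resolved to one group upstream. Foreign labels
#' or duplicate gene ids are errors listing the offending rows.
#'
#' @param path Path to the TSV, or a data.frame with the same columns.
#' @return Named character vector: `annotation[gene_id] -> group`.
#' @export
read_annotation <- function(path) {
  tab <- if (is.data.frame(path)) path else
    utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("gene_id", "group") %in% names(tab))) {
    stop("annotation needs columns `gene_id` and `group`", call. = FALSE)
  }
  vocab <- c(functional_groups(), "Unannotated")
  bad <- which(!(tab$group %in% vocab))
  if (length(bad)) {
    stop(sprintf("unknown functional group label(s) at row(s) %s: %s",
                 paste(utils::head(bad, 10L), collapse = ", "),
                 paste(unique(tab$group[bad]), collapse = "; ")),
         call. = FALSE)
  }
  dup <- which(duplicated(tab$gene_id))
  if (length(dup)) {
    stop(sprintf("gene(s) annotated more than once (rows %s): %s",
                 paste(utils::head(dup, 10L), collapse = ", "),
                 paste(unique(tab$gene_id[dup]), collapse = ", ")),
         call. = FALSE)
  }
  stats::setNames(tab$group, tab$gene_id)
}

#' Functional-group composition of a gene set
#'
#' Percentage of annotated genes per functional group (summing to 100 over
#' the 8 groups); genes absent from the annotation, or annotated
#' `"Unannotated"`, are reported separately as a count.
#'
#' @param genes Non-empty character vector of gene ids.
#' @param annotation Named character vector from [read_annotation()].
#' @return List with `percent` (named over [functional_groups()]),
#'   `n_annotated`, `n_unannotated`.
#' @export
group_percentages <- function(genes, annotation) {
  genes <- unique(genes)
  if (!length(genes)) stop("empty gene set", call. = FALSE)
  grp <- annotation[genes]
  grp[is.na(grp)] <- "Unannotated"
  annotated <- grp[grp != "Unannotated"]
  if (!length(annotated)) {
    stop("no gene in the set carries a functional annotation", call. = FALSE)
  }
  counts <- table(factor(annotated, levels = functional_groups()))
  list(
    percent = stats::setNames(100 * as.vector(counts) / length(annotated),
                              functional_groups()),
    n_annotated = length(annotated),
    n_unannotated = length(grp) - length(annotated)
  )
}

#' Per-group circular phase histograms
#'
#' For each selected functional group, counts the peak times of that group's
#' circadian genes in circular bins of `bin_width` hours over the 24-h day
#' (bins `[0, w), [w, 2w), ...`). Per-group counts sum to the group's gene
#' count; empty groups give all-zero rows.
#'
#' @param geneset data.frame with `gene_id` and `phase_h` (a `rhythm_result`
#'   restricted to circadian genes works directly).
#' @param annotation Named character vector from [read_annotation()].
#' @param groups Subset of [functional_groups()] to summarize (default: all
#'   groups present in the annotation).
#' @param bin_width Bin width in hours; must divide 24 evenly.
#' @return Integer matrix, groups x bins, with bin-start hours as column
#'   names.
#' @export
group_phase_histogram <- function(geneset, annotation, groups = NULL,
                                  bin_width = 2) {
  if (!all(c("gene_id", "phase_h") %in% names(geneset))) {
    stop("`geneset` needs columns gene_id and phase_h", call. = FALSE)
  }
  nb <- 24 / bin_width
  if (bin_width <= 0 || abs(nb - round(nb)) > 1e-9) {
    stop(sprintf("`bin_width` (%g) must divide 24 evenly", bin_width),
         call. = FALSE)
  }
  nb <- as.integer(round(nb))
  if (is.null(groups)) {
    groups <- intersect(functional_groups(), unique(annotation))
  } else if (!all(groups %in% functional_groups())) {
    stop("`groups` must be drawn from functional_groups()", call. = FALSE)
  }
  geneset <- geneset[!is.na(geneset$phase_h), , drop = FALSE]
  grp <- annotation[geneset$gene_id]
  bin <- pmin(floor((geneset$phase_h %% 24) / bin_width) + 1L, nb)
  out <- matrix(0L, nrow = length(groups), ncol = nb,
                dimnames = list(groups,
                                sprintf("%g", (seq_len(nb) - 1L) * bin_width)))
  for (g in groups) {
    idx <- which(!is.na(grp) & grp == g)
    if (length(idx)) {
      tb <- table(factor(bin[idx], levels = seq_len(nb)))
      out[g, ] <- as.integer(tb)
    }
  }
  out
}
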