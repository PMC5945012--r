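#' Partition a union of gene sets into disjoint overlap regions
#'
#' Classifies every gene of the union by its exact membership subset, the
#' regions of a k-set Venn diagram (2 <= k <= 4 tissues). Region labels join
#' the member set names with `&` in the order the sets were given.
#'
#' @param sets Named list of 2-4 character vectors of gene ids.
#' @return A `venn_partition`: data.frame `region`, `count` covering every
#'   non-empty label subset, with the set labels in attribute `"labels"` and
#'   per-region gene id lists in attribute `"members"`.
#' @export
#' @examples
#' venn_partition(list(A = c("g1", "g2", "g3"), B = c("g3", "g4")))
venn_partition <- function(sets) {
  if (!is.list(sets) || length(sets) < 2L || length(sets) > 4L ||
      is.null(names(sets)) || any(names(sets) == "")) {
    stop("`sets` must be a named list of 2-4 gene id vectors", call. = FALSE)
  }
  labels <- names(sets)
  sets <- lapply(sets, unique)
  universe <- unique(unlist(sets, use.names = FALSE))
  membership <- vapply(sets, function(s) universe %in% s,
                       logical(length(universe)))
  if (length(universe) == 1L) membership <- matrix(membership, nrow = 1L)
  subsets <- region_subsets(labels)
  region <- vapply(subsets, paste, character(1), collapse = "&")
  key <- apply(membership, 1L, function(m) paste(labels[m], collapse = "&"))
  members <- lapply(region, function(r) universe[key == r])
  out <- data.frame(region = region,
                    count = lengths(members),
                    stringsAsFactors = FALSE)
  structure(out, labels = labels, members = stats::setNames(members, region),
            class = c("venn_partition", "data.frame"))
}

# all non-empty subsets of the labels, smallest first, in label order
region_subsets <- function(labels) {
  k <- length(labels)
  out <- list()
  for (size in seq_len(k)) {
    cmb <- utils::combn(labels, size, simplify = FALSE)
    out <- c(out, cmb)
  }
  out
}

#' Assemble a Venn partition from published region counts
#'
#' Builds a `venn_partition` directly from region counts (for example the
#' printed counts of a published k-set diagram) without the underlying gene
#' lists; missing regions count 0.
#'
#' @param labels Character vector of 2-4 set labels.
#' @param counts Named numeric vector; names are region labels joining member
#'   sets with `&` (member order free), values the region counts.
#' @return A `venn_partition` (without gene id lists).
#' @export
venn_partition_from_counts <- function(labels, counts) {
  if (length(labels) < 2L || length(labels) > 4L) {
    stop("need 2-4 set labels", call. = FALSE)
  }
  if (any(counts < 0)) stop("region counts must be >= 0", call. = FALSE)
  subsets <- region_subsets(labels)
  region <- vapply(subsets, paste, character(1), collapse = "&")
  canon <- function(nm) {
    parts <- strsplit(nm, "&", fixed = TRUE)[[1L]]
    if (!all(parts %in% labels)) {
      stop(sprintf("region '%s' names unknown set(s)", nm), call. = FALSE)
    }
    paste(labels[labels %in% parts], collapse = "&")
  }
  names(counts) <- vapply(names(counts), canon, character(1))
  cnt <- stats::setNames(rep(0, length(region)), region)
  cnt[names(counts)] <- counts
  out <- data.frame(region = region, count = as.vector(cnt),
                    stringsAsFactors = FALSE)
  structure(out, labels = labels, class = c("venn_partition", "data.frame"))
}

#' Genes common to a pair of sets, from a Venn partition
#'
#' Sums the counts of every region whose membership subset contains both
#' labels; equals the size of the pairwise intersection.
#'
#' @param partition A `venn_partition`.
#' @param pair Character vector of two set labels.
#' @return Integer count.
#' @export
pairwise_common_count <- function(partition, pair) {
  stopifnot(inherits(partition, "venn_partition"))
  labels <- attr(partition, "labels")
  if (length(pair) != 2L || !all(pair %in% labels)) {
    stop(sprintf("`pair` must be two of: %s", paste(labels, collapse = ", ")),
         call. = FALSE)
  }
  in_region <- vapply(strsplit(partition$region, "&", fixed = TRUE),
                      function(m) all(pair %in% m), logical(1))
  as.integer(sum(partition$count[in_region]))
}

#' Circular phase lag between two peak times
#'
#' The phase difference of two 24-h rhythms measured around the circle:
#' `min(|phi_i - phi_j|, 24 - |phi_i - phi_j|)`, from 0 h for identical
#' phases to 12 h for antiphasic rhythms. Vectorized over gene pairs.
#'
#' @param phi_i,phi_j Peak times in hours, in `[0, 24)`.
#' @param period Period in hours (24).
#' @return Phase lag(s) in `[0, period/2]`.
#' @export
#' @examples
#' phase_lag(23, 1)  # 2, not 22
phase_lag <- function(phi_i, phi_j, period = 24) {
  if (any(phi_i < 0 | phi_i >= period) || any(phi_j < 0 | phi_j >= period)) {
    stop(sprintf("phases must lie in [0, %g)", period), call. = FALSE)
  }
  d <- abs(phi_i - phi_j)
  pmin(d, period - d)
}

#' Maximum pairwise phase lag among 3 or 4 tissues
#'
#' @param phases Numeric vector of 3 or 4 peak times in hours.
#' @param period Period in hours.
#' @return The largest [phase_lag()] over all unordered pairs.
#' @export
max_phase_lag <- function(phases, period = 24) {
  if (length(phases) < 3L || length(phases) > 4L) {
    stop("`phases` must have length 3 or 4 (use phase_lag() for pairs)",
         call. = FALSE)
  }
  pairs <- utils::combn(length(phases), 2L)
  max(phase_lag(phases[pairs[1L, ]], phases[pairs[2L, ]], period))
}

#' Percent amplitude difference between two tissues
#'
#' `(A_max - A_min) / A_max * 100`: 0 for equal amplitudes, approaching 100
#' when the lower amplitude is infinitesimally small. Vectorized.
#'
#' @param A_i,A_j Positive amplitudes.
#' @return Percent difference(s) in `[0, 100)`.
#' @export
amplitude_diff <- function(A_i, A_j) {
  if (any(A_i <= 0) || any(A_j <= 0)) {
    stop("amplitudes must be positive", call. = FALSE)
  }
  hi <- pmax(A_i, A_j)
  (hi - pmin(A_i, A_j)) / hi * 100
}

#' Maximum percent amplitude difference among 3 or 4 tissues
#'
#' Equals [amplitude_diff()] of the largest and smallest amplitude in the
#' list.
#'
#' @param amplitudes Numeric vector of 3 or 4 positive amplitudes.
#' @return Percent difference in `[0, 100)`.
#' @export
max_amplitude_diff <- function(amplitudes) {
  if (length(amplitudes) < 3L || length(amplitudes) > 4L) {
    stop("`amplitudes` must have length 3 or 4 (use amplitude_diff() ",
         "for pairs)", call. = FALSE)
  }
  amplitude_diff(max(amplitudes), min(amplitudes))
}

#' Circular correlation of paired peak times
#'
#' Fisher-Lee circular correlation of two paired angular samples: phases in
#' hours are converted to angles `a = 2*pi*phi/24`, each sample's circular
#' mean direction is the `atan2` of its mean sine and cosine, and
#' `r = sum(sin(a1 - abar1) * sin(a2 - abar2)) /
#'    sqrt(sum(sin^2(a1 - abar1)) * sum(sin^2(a2 - abar2)))`.
#' `r` is 1 for identical phase vectors, -1 for reflected ones, and invariant
#' to a common rotation of either vector.
#'
#' @param phases_1,phases_2 Paired numeric vectors (one entry per gene) of
#'   equal length >= 2, in hours unless `unit = "radians"`.
#' @param unit `"hours"` (default) or `"radians"`.
#' @return A `circular_correlation` list: `r`, `mean_direction_1`,
#'   `mean_direction_2` (radians), `n`.
#' @export
#' @examples
#' circular_correlation(c(1, 5, 9, 20), c(2, 6, 10, 21))$r
circular_correlation <- function(phases_1, phases_2,
                                 unit = c("hours", "radians")) {
  unit <- match.arg(unit)
  n <- length(phases_1)
  if (length(phases_2) != n) {
    stop("phase vectors must be paired (equal length)", call. = FALSE)
  }
  if (n < 2L) stop("need at least 2 phase pairs", call. = FALSE)
  a1 <- if (unit == "hours") phases_1 * 2 * pi / 24 else phases_1
  a2 <- if (unit == "hours") phases_2 * 2 * pi / 24 else phases_2
  m1 <- atan2(mean(sin(a1)), mean(cos(a1)))
  m2 <- atan2(mean(sin(a2)), mean(cos(a2)))
  s1 <- sin(a1 - m1)
  s2 <- sin(a2 - m2)
  den <- sqrt(sum(s1^2) * sum(s2^2))
  # guard includes fp residue when every angle sits on the mean axis
  if (den < n * 1e-12) {
    stop("undefined circular correlation: all phases at the mean direction",
         call. = FALSE)
  }
  structure(list(r = sum(s1 * s2) / den, mean_direction_1 = m1,
                 mean_direction_2 = m2, n = n),
            class = "circular_correlation")
}

#' @export
print.circular_correlation <- function(x, ...) {
  cat(sprintf("circular correlation r = %.4f (n = %d)\n", x$r, x$n))
  invisible(x)
}

#' Cross-species conservation of a circadian gene set
#'
#' Counts the genes of a reference-species circadian set also present in a
#' second species' set and expresses the overlap as a nearest-integer percent
#' of the reference set. If paired peak times are supplied (named vectors,
#' hours), the circular correlation of the conserved genes' phases is
#' returned too.
#'
#' @param set_ref Non-empty character vector, reference-species circadian
#'   gene ids (e.g. rat).
#' @param set_other Character vector, comparison-species circadian gene ids.
#' @param phases_ref,phases_other Optional named numeric vectors of peak
#'   times (hours) indexed by gene id.
#' @return List with `n_conserved`, `percent` (nearest integer), and
#'   `phase_correlation` (a [circular_correlation()] or NULL).
#' @export
species_overlap <- function(set_ref, set_other,
                            phases_ref = NULL, phases_other = NULL) {
  set_ref <- unique(set_ref)
  if (!length(set_ref)) stop("reference gene set is empty", call. = FALSE)
  conserved <- intersect(set_ref, unique(set_other))
  out <- list(
    n_conserved = length(conserved),
    percent = as.integer(round(100 * length(conserved) / length(set_ref))),
    phase_correlation = NULL
  )
  if (!is.null(phases_ref) && !is.null(phases_other) &&
      length(conserved) >= 2L) {
    out$phase_correlation <- circular_correlation(
      unname(phases_ref[conserved]), unname(phases_other[conserved]))
  }
  out
}

#' Histogram counts over fixed bin edges
#'
#' Bins values with the convention used for the phase-lag and
#' amplitude-difference summaries: bins are left-open/right-closed except the
#' first bin, which is closed at its left edge (so a value exactly on an
#' interior edge falls in the lower bin). Values outside the edge range are an
#' error naming the value.
#'
#' @param values Numeric vector.
#' @param edges Strictly increasing numeric vector of bin edges covering the
#'   value range.
#' @param right_closed `TRUE` (default) for the convention above; `FALSE`
#'   flips to left-closed/right-open bins with the last bin closed.
#' @return Integer counts named by bin, summing to `length(values)`.
#' @export
#' @examples
#' bin_values(c(0.5, 2, 3), seq(0, 12, 2))  # the exact 2.0 lands in (0, 2]
bin_values <- function(values, edges, right_closed = TRUE) {
  if (length(edges) < 2L || is.unsorted(edges, strictly = TRUE)) {
    stop("`edges` must be strictly increasing", call. = FALSE)
  }
  out_of_range <- values < edges[1L] | values > edges[length(edges)]
  if (any(out_of_range)) {
    stop(sprintf("value(s) outside [%g, %g]: %s", edges[1L],
                 edges[length(edges)],
                 paste(utils::head(values[out_of_range], 5L),
                       collapse = ", ")), call. = FALSE)
  }
  f <- cut(values, breaks = edges, right = right_closed,
           include.lowest = TRUE)
  counts <- as.integer(table(f))
  names(counts) <- levels(f)
  counts
}

#' Phase-lag and amplitude-difference summaries for genes shared by tissues
#'
#' For genes circadian in every supplied tissue, computes the per-gene phase
#' lag (pairwise) or maximum phase lag (3-4 tissues) and the percent
#' amplitude difference (or its maximum), plus their binned histograms
#' (phase: 2-h bins to 12 h; amplitude: 20% bins to 100%).
#'
#' @param results Named list of 2-4 `rhythm_result` tables (or data.frames
#'   with `gene_id`, `phase_h`, `amplitude`, `circadian`).
#' @param circadian_only Keep only genes flagged circadian in each tissue
#'   (default TRUE).
#' @return List with `genes` (a per-gene data.frame: `gene_id`, `delta_phi`,
#'   `delta_A`), `phase_hist`, `amplitude_hist`.
#' @export
compare_tissues <- function(results, circadian_only = TRUE) {
  if (length(results) < 2L || length(results) > 4L ||
      is.null(names(results))) {
    stop("`results` must be a named list of 2-4 rhythm tables",
         call. = FALSE)
  }
  keep <- lapply(results, function(r) {
    if (circadian_only) r <- r[r$circadian, , drop = FALSE]
    r[!is.na(r$phase_h) & r$amplitude > 0, , drop = FALSE]
  })
  common <- Reduce(intersect, lapply(keep, function(r) r$gene_id))
  phases <- vapply(keep, function(r) r$phase_h[match(common, r$gene_id)],
                   numeric(length(common)))
  amps <- vapply(keep, function(r) r$amplitude[match(common, r$gene_id)],
                 numeric(length(common)))
  if (length(common) == 0L) {
    genes <- data.frame(gene_id = character(0), delta_phi = numeric(0),
                        delta_A = numeric(0))
  } else {
    if (length(common) == 1L) {
      phases <- matrix(phases, nrow = 1L)
      amps <- matrix(amps, nrow = 1L)
    }
    if (length(results) == 2L) {
      dphi <- phase_lag(phases[, 1L], phases[, 2L])
      dA <- amplitude_diff(amps[, 1L], amps[, 2L])
    } else {
      dphi <- apply(phases, 1L, max_phase_lag)
      dA <- apply(amps, 1L, max_amplitude_diff)
    }
    genes <- data.frame(gene_id = common, delta_phi = dphi, delta_A = dA,
                        stringsAsFactors = FALSE)
  }
  list(
    genes = genes,
    phase_hist = bin_values(genes$delta_phi, seq(0, 12, by = 2)),
    amplitude_hist = bin_values(genes$delta_A, seq(0, 100, by = 20))
  )
}
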