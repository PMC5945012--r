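#' Run the end-to-end circadian analysis pipeline
#'
#' Ties the stages together: simulate multi-tissue data (or read supplied
#' matrices), two-step normalization, rhythm detection per tissue, cross-
#' tissue comparison (overlap partition, phase lags, amplitude differences,
#' circular phase correlations), and functional-group summaries when an
#' annotation is supplied. All results are written as schema-stable TSVs that
#' the package's own readers parse back; the same config and seed reproduce
#' identical files.
#'
#' @param config A list with elements:
#'   \describe{
#'     \item{outdir}{output directory (required).}
#'     \item{seed}{integer seed (default 1).}
#'     \item{design}{`study_design`, default [rat_design()].}
#'     \item{n_genes}{gene universe size for simulation (default 500).}
#'     \item{tissues}{named list of per-tissue generator specs, as in
#'       [generate_multitissue()] (required unless `matrices` given).}
#'     \item{shared}{`shared_config` for [generate_multitissue()].}
#'     \item{matrices}{optional named list of [expression_matrix()] inputs,
#'       bypassing simulation.}
#'     \item{phase_step,fdr}{detection parameters (defaults 1 h, 0.05).}
#'     \item{annotation}{optional annotation TSV path or data.frame.}
#'     \item{stages}{subset of `c("simulate", "normalize", "detect",
#'       "compare", "annotate")`; later stages require the earlier ones.}
#'   }
#' @return Invisibly, a list with the in-memory stage results and `files`,
#'   the paths written.
#' @export
run_pipeline <- function(config) {
  if (is.null(config$outdir)) stop("config$outdir is required", call. = FALSE)
  stages_all <- c("simulate", "normalize", "detect", "compare", "annotate")
  stages <- if (is.null(config$stages)) stages_all else config$stages
  if (!all(stages %in% stages_all)) {
    stop("unknown stage(s): ",
         paste(setdiff(stages, stages_all), collapse = ", "), call. = FALSE)
  }
  seed <- if (is.null(config$seed)) 1L else as.integer(config$seed)
  design <- if (is.null(config$design)) rat_design() else config$design
  phase_step <- if (is.null(config$phase_step)) 1 else config$phase_step
  fdr <- if (is.null(config$fdr)) 0.05 else config$fdr
  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
  files <- character(0)
  out <- list()
  log_lines <- c(
    sprintf("circatissue %s",
            as.character(utils::packageVersion("circatissue"))),
    sprintf("R %s", as.character(getRversion())),
    sprintf("seed: %d", seed),
    sprintf("phase_step: %g h, fdr: %g", phase_step, fdr),
    sprintf("design: %d times x %d replicates", length(design$times),
            design$replicates_per_time),
    sprintf("stages: %s", paste(stages, collapse = ", "))
  )
  fail <- function(stage, e) {
    stop(sprintf("pipeline stage '%s' failed: %s", stage,
                 conditionMessage(e)), call. = FALSE)
  }

  matrices <- config$matrices
  if ("simulate" %in% stages && is.null(matrices)) {
    tryCatch({
      sim <- generate_multitissue(
        design = design, tissue_specs = config$tissues,
        n_genes = if (is.null(config$n_genes)) 500L else config$n_genes,
        shared_config = if (is.null(config$shared))
          list(n_shared = 50L, offsets = NULL) else config$shared,
        seed = seed
      )
      files <- c(files, write_simulation(sim, file.path(config$outdir,
                                                        "simulated")))
      matrices <- sim$matrices
      out$truth <- sim$truth
      out$shared_genes <- sim$shared_genes
    }, error = function(e) fail("simulate", e))
  }
  out$matrices <- matrices
  if (is.null(matrices)) {
    writeLines(c(log_lines, "no matrices: stopped after configured stages"),
               file.path(config$outdir, "run_log.txt"))
    return(invisible(c(out, list(files = files))))
  }

  if ("normalize" %in% stages) {
    tryCatch({
      matrices <- lapply(matrices, normalize_two_step)
      for (tn in names(matrices)) {
        p <- file.path(config$outdir, paste0(tn, "_normalized.tsv"))
        write_expression_matrix(matrices[[tn]], p)
        files <- c(files, p)
      }
      out$normalized <- matrices
    }, error = function(e) fail("normalize", e))
  }

  results <- NULL
  if ("detect" %in% stages) {
    tryCatch({
      results <- lapply(matrices, detect_rhythms, design = design,
                        phase_step = phase_step, fdr = fdr)
      for (tn in names(results)) {
        p <- file.path(config$outdir, paste0(tn, "_rhythms.tsv"))
        write_rhythms(results[[tn]], p)
        files <- c(files, p)
        log_lines <- c(log_lines, sprintf("%s: %d/%d circadian at q < %g",
                                          tn, sum(results[[tn]]$circadian),
                                          nrow(results[[tn]]), fdr))
      }
      out$rhythms <- results
    }, error = function(e) fail("detect", e))
  }

  if ("compare" %in% stages && !is.null(results) && length(results) >= 2L) {
    tryCatch({
      circ_sets <- lapply(results, function(r) r$gene_id[r$circadian])
      vp <- venn_partition(circ_sets)
      utils::write.table(as.data.frame(vp),
                         file.path(config$outdir, "venn.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      files <- c(files, file.path(config$outdir, "venn.tsv"))
      out$venn <- vp

      pairs <- utils::combn(names(results), 2L, simplify = FALSE)
      lag_rows <- list(); hist_rows <- list(); cor_rows <- list()
      for (pr in pairs) {
        cmp <- compare_tissues(results[pr])
        key <- paste(pr, collapse = "_vs_")
        if (nrow(cmp$genes)) {
          lag_rows[[key]] <- data.frame(pair = key, cmp$genes,
                                        stringsAsFactors = FALSE)
        }
        hist_rows[[key]] <- data.frame(
          pair = key,
          bin = c(names(cmp$phase_hist), names(cmp$amplitude_hist)),
          metric = rep(c("delta_phi_h", "delta_A_pct"),
                       c(length(cmp$phase_hist),
                         length(cmp$amplitude_hist))),
          count = c(cmp$phase_hist, cmp$amplitude_hist),
          stringsAsFactors = FALSE
        )
        r_val <- if (nrow(cmp$genes) >= 2L) {
          ph1 <- results[[pr[1L]]]
          ph2 <- results[[pr[2L]]]
          tryCatch(circular_correlation(
            ph1$phase_h[match(cmp$genes$gene_id, ph1$gene_id)],
            ph2$phase_h[match(cmp$genes$gene_id, ph2$gene_id)])$r,
            error = function(e) NA_real_)
        } else NA_real_
        cor_rows[[key]] <- data.frame(pair = key, n = nrow(cmp$genes),
                                      r = signif(r_val, 6L),
                                      stringsAsFactors = FALSE)
      }
      wt <- function(rows, name) {
        p <- file.path(config$outdir, name)
        utils::write.table(do.call(rbind, rows), p, sep = "\t",
                           quote = FALSE, row.names = FALSE)
        p
      }
      if (length(lag_rows)) {
        files <- c(files, wt(lag_rows, "phase_amplitude_differences.tsv"))
      }
      files <- c(files, wt(hist_rows, "histograms.tsv"),
                 wt(cor_rows, "circular_corr.tsv"))
      out$circular_corr <- do.call(rbind, cor_rows)
    }, error = function(e) fail("compare", e))
  }

  if ("annotate" %in% stages && !is.null(results) &&
      !is.null(config$annotation)) {
    tryCatch({
      ann <- read_annotation(config$annotation)
      rows <- list()
      for (tn in names(results)) {
        circ <- results[[tn]][results[[tn]]$circadian, , drop = FALSE]
        if (!nrow(circ)) next
        gp <- group_percentages(circ$gene_id, ann)
        rows[[tn]] <- data.frame(tissue = tn, group = names(gp$percent),
                                 percent = signif(gp$percent, 6L),
                                 n_annotated = gp$n_annotated,
                                 n_unannotated = gp$n_unannotated,
                                 stringsAsFactors = FALSE)
      }
      p <- file.path(config$outdir, "functional_summary.tsv")
      utils::write.table(do.call(rbind, rows), p, sep = "\t", quote = FALSE,
                         row.names = FALSE)
      files <- c(files, p)
      out$functional <- do.call(rbind, rows)
    }, error = function(e) fail("annotate", e))
  }

  writeLines(log_lines, file.path(config$outdir, "run_log.txt"))
  files <- c(files, file.path(config$outdir, "run_log.txt"))
  out$files <- files
  invisible(out)
}

#' Read a pipeline configuration from a YAML file
#'
#' Convenience loader: the YAML maps directly onto the `config` list of
#' [run_pipeline()]; `design` may be given as `times` plus
#' `replicates_per_time`, and per-tissue `phase_distribution` as
#' `{kind: vonmises, mu: ..., kappa: ...}` (or `uniform`).
#'
#' @param path YAML file path.
#' @return A config list for [run_pipeline()].
#' @export
read_pipeline_config <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE)) {
    stop("reading YAML configs requires the `yaml` package", call. = FALSE)
  }
  cfg <- yaml::read_yaml(path)
  if (!is.null(cfg$design)) {
    cfg$design <- study_design(
      times = cfg$design$times,
      replicates_per_time = if (is.null(cfg$design$replicates_per_time)) 3L
                            else cfg$design$replicates_per_time)
  }
  parse_dist <- function(d) {
    if (is.null(d)) return(NULL)
    switch(d$kind,
           uniform = phase_uniform(),
           vonmises = phase_vonmises(d$mu, d$kappa),
           mixture = phase_mixture(lapply(d$components, parse_dist),
                                   d$weights),
           stop("unknown phase distribution kind: ", d$kind, call. = FALSE))
  }
  if (!is.null(cfg$tissues)) {
    cfg$tissues <- lapply(cfg$tissues, function(s) {
      if (!is.null(s$phase_distribution)) {
        s$phase_distribution <- parse_dist(s$phase_distribution)
      }
      s
    })
  }
  cfg
}
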