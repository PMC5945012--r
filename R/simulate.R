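#' Phase distributions for the synthetic generator
#'
#' Peak-time distributions on the 24-h circle. `phase_uniform()` spreads peaks
#' uniformly; `phase_vonmises()` concentrates them around a mean peak time
#' `mu` (hours) with concentration `kappa` (dimensionless; 0 recovers the
#' uniform); `phase_mixture()` mixes several von Mises components, e.g. the
#' bimodal "rush hour" clusters seen before dawn and dusk in rodent
#' transcriptomes.
#'
#' @param mu Mean peak time in hours, in `[0, 24)`.
#' @param kappa Non-negative concentration parameter.
#' @param components List of `phase_vonmises()` specs.
#' @param weights Mixture weights, one per component; normalized to sum 1.
#' @return A phase-distribution specification (class `phase_dist`).
#' @export
phase_uniform <- function() {
  structure(list(kind = "uniform"), class = "phase_dist")
}

#' @rdname phase_uniform
#' @export
phase_vonmises <- function(mu, kappa) {
  if (mu < 0 || mu >= 24) stop("`mu` must be in [0, 24)", call. = FALSE)
  if (kappa < 0) stop("`kappa` must be >= 0", call. = FALSE)
  structure(list(kind = "vonmises", mu = mu, kappa = kappa),
            class = "phase_dist")
}

#' @rdname phase_uniform
#' @export
phase_mixture <- function(components, weights = NULL) {
  if (!length(components) ||
      !all(vapply(components, inherits, logical(1), "phase_dist")) ||
      !all(vapply(components, function(c) c$kind == "vonmises", logical(1)))) {
    stop("`components` must be a list of phase_vonmises() specs",
         call. = FALSE)
  }
  if (is.null(weights)) weights <- rep(1, length(components))
  if (length(weights) != length(components) || any(weights < 0) ||
      sum(weights) <= 0) {
    stop("invalid mixture weights", call. = FALSE)
  }
  structure(list(kind = "mixture", components = components,
                 weights = weights / sum(weights)),
            class = "phase_dist")
}

# von Mises sampler (Best & Fisher 1979 rejection scheme), angles in radians
rvonmises_rad <- function(n, mu, kappa) {
  if (n == 0L) return(numeric(0))
  if (kappa < 1e-8) return(stats::runif(n, 0, 2 * pi))
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(n)
  i <- 0L
  while (i < n) {
    u <- stats::runif(3)
    z <- cos(pi * u[1L])
    f <- (1 + r * z) / (r + z)
    cc <- kappa * (r - f)
    if (cc * (2 - cc) - u[2L] > 0 || log(cc / u[2L]) + 1 - cc >= 0) {
      i <- i + 1L
      out[i] <- (mu + sign(u[3L] - 0.5) * acos(f)) %% (2 * pi)
    }
  }
  out
}

# draw n peak times (hours in [0,24)) from a phase_dist spec
sample_phases <- function(n, dist) {
  if (!inherits(dist, "phase_dist")) {
    stop("unknown phase distribution; use phase_uniform(), phase_vonmises() ",
         "or phase_mixture()", call. = FALSE)
  }
  switch(dist$kind,
    uniform = stats::runif(n, 0, 24),
    vonmises = rvonmises_rad(n, dist$mu * 2 * pi / 24, dist$kappa) * 24 / (2 * pi),
    mixture = {
      comp <- sample.int(length(dist$components), n, replace = TRUE,
                         prob = dist$weights)
      phases <- numeric(n)
      for (k in seq_along(dist$components)) {
        idx <- which(comp == k)
        phases[idx] <- rvonmises_rad(length(idx),
                                     dist$components[[k]]$mu * 2 * pi / 24,
                                     dist$components[[k]]$kappa) * 24 / (2 * pi)
      }
      phases
    },
    stop("unknown phase distribution kind: ", dist$kind, call. = FALSE)
  )
}

# evaluate the noiseless cosine signal of one gene at times tt (hours)
cosine_signal <- function(tt, mesor, amplitude, phase, period = 24) {
  mesor + amplitude * cos(2 * pi * (tt - phase) / period)
}

# run expr with the RNG seeded by `seed`, restoring the caller's RNG state
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  force(expr)
}

#' Simulate one tissue's expression time series with known rhythmic truth
#'
#' Generates a genes x samples intensity matrix under the cosine model: a
#' rhythmic gene's expected signal at clock time t is
#' `mesor + A * cos(2*pi*(t - phase)/24)` and a non-rhythmic gene is flat at
#' its mesor; additive Gaussian noise with standard deviation `noise_sd` is
#' applied on the normalized scale (profiles oscillate around 1, as after
#' two-step normalization). An optional log-normal noise model multiplies the
#' signal by `exp(N(0, sd))` instead.
#'
#' @param design A `study_design`; defaults are taken from `rat_design()`.
#' @param n_genes Number of genes to simulate.
#' @param frac_rhythmic Fraction of genes that are rhythmic, in `[0, 1]`;
#'   the rhythmic count is `round(frac_rhythmic * n_genes)` and the rhythmic
#'   genes are the first rows.
#' @param phase_distribution A `phase_dist` spec for the rhythmic peak times.
#' @param amplitude_range Length-2 interval; amplitudes are drawn uniformly
#'   from it (a single value fixes the amplitude).
#' @param noise_sd Non-negative noise standard deviation.
#' @param seed Integer seed; identical seed and parameters reproduce the
#'   output bit-for-bit. The caller's RNG state is left untouched.
#' @param tissue Tissue label for the sample metadata.
#' @param mesor Baseline expression level (default 1, the normalized scale).
#' @param noise_model `"gaussian"` (additive, default) or `"lognormal"`
#'   (multiplicative).
#' @return A list with `matrix` (an [expression_matrix()]) and `truth`, a
#'   data.frame with one row per gene: `gene_id`, `tissue`, `rhythmic`,
#'   `mesor`, `amplitude_true`, `phase_true`, `noise_sd`.
#' @export
#' @examples
#' sim <- generate_tissue(rat_design(), n_genes = 50, frac_rhythmic = 0.3,
#'                        noise_sd = 0.1, seed = 1)
#' table(sim$truth$rhythmic)
generate_tissue <- function(design = rat_design(), n_genes,
                            frac_rhythmic = 0.3,
                            phase_distribution = phase_uniform(),
                            amplitude_range = c(0.2, 0.6),
                            noise_sd = 0.1, seed = 1L,
                            tissue = "tissue1", mesor = 1,
                            noise_model = c("gaussian", "lognormal")) {
  stopifnot(inherits(design, "study_design"))
  noise_model <- match.arg(noise_model)
  if (n_genes < 1L) stop("`n_genes` must be >= 1", call. = FALSE)
  if (frac_rhythmic < 0 || frac_rhythmic > 1) {
    stop("`frac_rhythmic` must lie in [0, 1]", call. = FALSE)
  }
  if (noise_sd < 0) stop("`noise_sd` must be >= 0", call. = FALSE)
  if (length(amplitude_range) == 1L) {
    amplitude_range <- rep(amplitude_range, 2L)
  }
  if (length(amplitude_range) != 2L || any(amplitude_range < 0) ||
      amplitude_range[1L] > amplitude_range[2L]) {
    stop("`amplitude_range` must be a non-negative interval", call. = FALSE)
  }
  if (!inherits(phase_distribution, "phase_dist")) {
    stop("`phase_distribution` must be a phase_dist spec ",
         "(phase_uniform(), phase_vonmises(), phase_mixture())",
         call. = FALSE)
  }

  n_rhythmic <- as.integer(round(frac_rhythmic * n_genes))
  meta <- design_samples(design, tissue)

  with_seed(seed, {
    phases <- sample_phases(n_rhythmic, phase_distribution)
    amps <- stats::runif(n_rhythmic, amplitude_range[1L], amplitude_range[2L])
    truth <- data.frame(
      gene_id = sprintf("g%05d", seq_len(n_genes)),
      tissue = tissue,
      rhythmic = seq_len(n_genes) <= n_rhythmic,
      mesor = mesor,
      amplitude_true = c(amps, rep(0, n_genes - n_rhythmic)),
      phase_true = c(phases %% 24, rep(NA_real_, n_genes - n_rhythmic)),
      noise_sd = noise_sd,
      stringsAsFactors = FALSE
    )
    signal <- matrix(mesor, nrow = n_genes, ncol = nrow(meta))
    if (n_rhythmic > 0L) {
      tt <- meta$time_h
      ph <- truth$phase_true[seq_len(n_rhythmic)]
      am <- truth$amplitude_true[seq_len(n_rhythmic)]
      signal[seq_len(n_rhythmic), ] <-
        mesor + am * cos(2 * pi * outer(ph, tt, function(p, t) t - p) /
                           design$period)
    }
    noise <- matrix(stats::rnorm(length(signal), 0, noise_sd),
                    nrow = n_genes)
    values <- if (noise_model == "gaussian") signal + noise
              else signal * exp(noise)
    rownames(values) <- truth$gene_id
    colnames(values) <- meta$sample_id
    list(matrix = expression_matrix(values, meta), truth = truth)
  })
}

#' Simulate several tissues sharing rhythmic genes with known phase offsets
#'
#' All tissues draw from one gene universe with consistent identifiers. The
#' first `n_shared` genes are rhythmic in every tissue: each carries a base
#' peak time (drawn from the first tissue's phase distribution) plus a
#' configured per-tissue offset, so the true pairwise phase lags and the true
#' circular phase correlation between tissues are known exactly. Shared genes
#' keep one amplitude across tissues (true amplitude difference 0); each
#' tissue additionally gets its own disjoint block of tissue-specific rhythmic
#' genes to fill its rhythmic fraction.
#'
#' @param design A `study_design` common to all tissues.
#' @param tissue_specs Named list (>= 2 tissues); each element is a list with
#'   any of `frac_rhythmic`, `phase_distribution`, `amplitude_range`,
#'   `noise_sd` overriding the defaults of [generate_tissue()].
#' @param n_genes Genes per tissue (one shared universe).
#' @param shared_config List with `n_shared` (count of genes rhythmic in all
#'   tissues) and `offsets`: per-tissue phase offsets in hours, each either a
#'   single number (applied to every shared gene), a numeric vector of length
#'   `n_shared`, or a `phase_dist` spec from which offsets are drawn. The
#'   first tissue conventionally has offset 0.
#' @param seed Integer seed.
#' @return List with `matrices` (named list of [expression_matrix()]),
#'   `truth` (row-bound per-tissue truth tables), and `shared_genes`, a
#'   data.frame `gene_id`, `tissue`, `phase_true`, `amplitude_true` restricted
#'   to the shared genes.
#' @export
generate_multitissue <- function(design = rat_design(), tissue_specs,
                                 n_genes = 1000L,
                                 shared_config = list(n_shared = 50L,
                                                      offsets = NULL),
                                 seed = 1L) {
  stopifnot(inherits(design, "study_design"))
  if (length(tissue_specs) < 2L || is.null(names(tissue_specs)) ||
      any(names(tissue_specs) == "")) {
    stop("`tissue_specs` must be a named list of >= 2 tissues", call. = FALSE)
  }
  tissues <- names(tissue_specs)
  n_shared <- as.integer(shared_config$n_shared)
  if (is.na(n_shared) || n_shared < 0L) {
    stop("shared_config$n_shared must be a non-negative integer",
         call. = FALSE)
  }
  offsets <- shared_config$offsets
  if (is.null(offsets)) {
    offsets <- stats::setNames(as.list(rep(0, length(tissues))), tissues)
  }
  if (!all(tissues %in% names(offsets))) {
    stop("shared_config$offsets must name every tissue", call. = FALSE)
  }

  spec_of <- function(s, field, default) {
    if (!is.null(s[[field]])) s[[field]] else default
  }
  n_rhy <- vapply(tissue_specs, function(s) {
    as.integer(round(spec_of(s, "frac_rhythmic", 0.3) * n_genes))
  }, integer(1))
  if (any(n_shared > n_rhy)) {
    stop(sprintf(
      "n_shared (%d) exceeds the rhythmic gene count of tissue(s): %s",
      n_shared, paste(tissues[n_shared > n_rhy], collapse = ", ")),
      call. = FALSE)
  }
  n_specific <- n_rhy - n_shared
  if (n_shared + sum(n_specific) > n_genes) {
    stop("tissue-specific rhythmic blocks do not fit the gene universe; ",
         "increase n_genes or lower the rhythmic fractions", call. = FALSE)
  }

  all_ids <- sprintf("g%05d", seq_len(n_genes))
  shared_ids <- all_ids[seq_len(n_shared)]
  block_start <- n_shared + c(0L, cumsum(n_specific))[seq_along(tissues)]
  base_dist <- spec_of(tissue_specs[[1L]], "phase_distribution",
                       phase_uniform())

  with_seed(seed, {
    base_phase <- sample_phases(n_shared, base_dist) %% 24
    first_amp_range <- spec_of(tissue_specs[[1L]], "amplitude_range",
                               c(0.2, 0.6))
    if (length(first_amp_range) == 1L) {
      first_amp_range <- rep(first_amp_range, 2L)
    }
    shared_amp <- stats::runif(n_shared, first_amp_range[1L],
                               first_amp_range[2L])
    tissue_offsets <- lapply(tissues, function(tn) {
      off <- offsets[[tn]]
      if (inherits(off, "phase_dist")) {
        # centre draws on 0 so an offset spec with mu = 0 means "around zero"
        o <- sample_phases(n_shared, off)
        ifelse(o > 12, o - 24, o)
      } else if (is.numeric(off) && length(off) == 1L) {
        rep(off, n_shared)
      } else if (is.numeric(off) && length(off) == n_shared) {
        off
      } else {
        stop(sprintf("invalid offset spec for tissue '%s'", tn),
             call. = FALSE)
      }
    })
    names(tissue_offsets) <- tissues

    matrices <- list()
    truths <- list()
    for (k in seq_along(tissues)) {
      tn <- tissues[[k]]
      s <- tissue_specs[[k]]
      meta <- design_samples(design, tn)
      tt <- meta$time_h
      amp_range <- spec_of(s, "amplitude_range", c(0.2, 0.6))
      if (length(amp_range) == 1L) amp_range <- rep(amp_range, 2L)
      noise_sd <- spec_of(s, "noise_sd", 0.1)
      if (noise_sd < 0) stop("`noise_sd` must be >= 0", call. = FALSE)

      # truth layout: shared block first, then this tissue's own specific
      # block (disjoint across tissues), remaining rows flat
      rhythmic <- logical(n_genes)
      amp <- numeric(n_genes)
      ph <- rep(NA_real_, n_genes)
      if (n_shared > 0L) {
        rhythmic[seq_len(n_shared)] <- TRUE
        amp[seq_len(n_shared)] <- shared_amp
        ph[seq_len(n_shared)] <- (base_phase + tissue_offsets[[tn]]) %% 24
      }
      if (n_specific[k] > 0L) {
        idx <- block_start[k] + seq_len(n_specific[k])
        rhythmic[idx] <- TRUE
        ph[idx] <- sample_phases(n_specific[k],
                                 spec_of(s, "phase_distribution",
                                         phase_uniform())) %% 24
        amp[idx] <- stats::runif(n_specific[k], amp_range[1L], amp_range[2L])
      }
      signal <- matrix(1, n_genes, length(tt))
      ridx <- which(rhythmic)
      if (length(ridx)) {
        signal[ridx, ] <- 1 + amp[ridx] *
          cos(2 * pi * outer(ph[ridx], tt, function(p, t) t - p) /
                design$period)
      }
      values <- signal + matrix(stats::rnorm(length(signal), 0, noise_sd),
                                n_genes)
      rownames(values) <- all_ids
      colnames(values) <- meta$sample_id
      truths[[tn]] <- data.frame(
        gene_id = all_ids, tissue = tn, rhythmic = rhythmic,
        mesor = 1, amplitude_true = amp, phase_true = ph,
        noise_sd = noise_sd, stringsAsFactors = FALSE
      )
      matrices[[tn]] <- expression_matrix(values, meta)
    }

    truth_all <- do.call(rbind, truths)
    rownames(truth_all) <- NULL
    shared <- truth_all[truth_all$gene_id %in% shared_ids,
                        c("gene_id", "tissue", "phase_true",
                          "amplitude_true")]
    rownames(shared) <- NULL
    list(matrices = matrices, truth = truth_all, shared_genes = shared)
  })
}

#' Write a synthetic simulation to disk
#'
#' Emits per-tissue expression and metadata TSVs plus one truth TSV, the
#' plain-text exchange format of the pipeline.
#'
#' @param sim Result of [generate_tissue()] or [generate_multitissue()].
#' @param outdir Output directory, created if needed.
#' @return Invisibly, a character vector of the files written.
#' @export
write_simulation <- function(sim, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  mats <- if (!is.null(sim$matrices)) sim$matrices else
    stats::setNames(list(sim$matrix), sim$truth$tissue[1L])
  paths <- character(0)
  for (tn in names(mats)) {
    mp <- file.path(outdir, paste0(tn, "_matrix.tsv"))
    sp <- file.path(outdir, paste0(tn, "_samples.tsv"))
    write_expression_matrix(mats[[tn]], mp, sp)
    paths <- c(paths, mp, sp)
  }
  tp <- file.path(outdir, "truth.tsv")
  utils::write.table(sim$truth, tp, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(paths, tp))
}
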