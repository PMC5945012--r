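#!/usr/bin/env Rscript
# Stage 1: simulate a four-tissue circadian expression study.
#
# The synthetic study mirrors the rat design: 18 unequally spaced sampling
# times over 24 h (dense at the light/dark transitions), 3 replicate animals
# per time, four tissues with very different rhythmic fractions (liver ~14%,
# muscle ~5%, adipose ~6%, lung ~30% of the genome) and tissue-specific peak
# time structure: liver concentrated at the dark/light transition, muscle and
# adipose bimodal ("rush hours" before dawn and dusk), lung peaking in the
# light phase. Fifty genes - the stand-in for the core-clock and strongly
# clock-controlled set - oscillate in all four tissues with nearly synchronous
# phases. Raw intensities are put on an arbitrary chip scale so that the
# normalization stage has real work to do.

library(circatissue)

outdir <- "results/analysis/simulated"
seed <- 20260926L

rush_hours <- phase_mixture(list(phase_vonmises(7, 3), phase_vonmises(19, 3)))
specs <- list(
  liver   = list(frac_rhythmic = 0.14, phase_distribution = phase_vonmises(23, 2),
                 noise_sd = 0.12),
  muscle  = list(frac_rhythmic = 0.05, phase_distribution = rush_hours,
                 noise_sd = 0.12),
  adipose = list(frac_rhythmic = 0.06, phase_distribution = rush_hours,
                 noise_sd = 0.12),
  lung    = list(frac_rhythmic = 0.30, phase_distribution = phase_vonmises(4, 2),
                 noise_sd = 0.12)
)

sim <- generate_multitissue(
  design = rat_design(),
  tissue_specs = specs,
  n_genes = 800L,
  shared_config = list(
    n_shared = 40L,
    offsets = list(liver = 0, muscle = phase_vonmises(0, 16),
                   adipose = phase_vonmises(0, 16),
                   lung = phase_vonmises(0, 16))),
  seed = seed)

# put each tissue on a raw intensity scale with per-chip factors, so the
# matrices look like unnormalized arrays
set.seed(seed + 1L)
for (tn in names(sim$matrices)) {
  m <- sim$matrices[[tn]]
  chip_factor <- exp(rnorm(ncol(m$values), log(200), 0.25))
  sim$matrices[[tn]] <- expression_matrix(
    sweep(m$values, 2L, chip_factor, "*"), m$meta)
}

files <- write_simulation(sim, outdir)
cat(sprintf("wrote %d files to %s\n", length(files), outdir))
tab <- table(sim$truth$tissue[sim$truth$rhythmic])
for (tn in names(tab)) {
  cat(sprintf("  %-8s %3d rhythmic genes of 800\n", tn, tab[[tn]]))
}
cat(sprintf("  %d genes rhythmic in all four tissues\n",
            length(unique(sim$shared_genes$gene_id))))
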