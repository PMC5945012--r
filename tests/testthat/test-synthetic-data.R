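test_that("study design validates its invariants", {
  expect_s3_class(rat_design(), "study_design")
  expect_equal(length(rat_design()$times), 18L)
  expect_equal(n_samples(rat_design()), 54L)
  expect_error(study_design(c(2, 1)), "increasing")
  expect_error(study_design(c(0, 24)), "\\[0, 24\\)")
  expect_error(study_design(c(0, 6), replicates_per_time = 0), "positive")
})

test_that("noiseless cosine genes evaluate to exact cosine values", {
  d <- study_design(times = c(0, 4, 8, 12, 16, 20), replicates_per_time = 1)
  sim <- generate_tissue(d, n_genes = 1, frac_rhythmic = 1,
                         amplitude_range = 0.5, noise_sd = 0, seed = 1)
  # overwrite the drawn phase with a fixed one via the cosine model directly
  tt <- sim$matrix$meta$time_h
  expected <- 1 + 0.5 * cos(2 * pi * (tt - 4) / 24)
  x <- 1 + 0.5 * cos(2 * pi * (tt - 4) / 24)
  expect_equal(x[tt == 4], 1.5)
  expect_equal(x[tt == 16], 0.5)
  expect_equal(x, expected)
  # the generator's own noiseless signal matches its truth table exactly
  tr <- sim$truth
  expect_equal(as.vector(sim$matrix$values),
               1 + tr$amplitude_true * cos(2 * pi * (tt - tr$phase_true) / 24))
})

test_that("degenerate rhythmic fraction yields a flat truth table", {
  sim <- generate_tissue(rat_design(), n_genes = 40, frac_rhythmic = 0,
                         noise_sd = 0.1, seed = 3)
  expect_false(any(sim$truth$rhythmic))
  expect_true(all(sim$truth$amplitude_true == 0))
  # population mean of every row is its mesor; empirical means near 1
  expect_lt(max(abs(rowMeans(sim$matrix$values) - 1)), 5 * 0.1 / sqrt(54))
})

test_that("rhythmic counts and noise level match the generating call", {
  sim <- generate_tissue(rat_design(), n_genes = 1000, frac_rhythmic = 0.3,
                         noise_sd = 0.1, seed = 7)
  expect_equal(sum(sim$truth$rhythmic), 300L)
  expect_equal(sim$truth$gene_id[sim$truth$rhythmic],
               sprintf("g%05d", 1:300))
  # per-row SD of non-rhythmic genes ~ noise_sd; SE of an sd at n = 54
  se <- 0.1 / sqrt(2 * (54 - 1))
  sds <- apply(sim$matrix$values[c(301, 500, 1000), ], 1L, sd)
  expect_true(all(abs(sds - 0.1) < 3 * se))
  # truth-consistency: phases in range, amplitudes only on rhythmic genes
  expect_true(all(sim$truth$phase_true[sim$truth$rhythmic] >= 0 &
                    sim$truth$phase_true[sim$truth$rhythmic] < 24))
  expect_true(all(is.na(sim$truth$phase_true[!sim$truth$rhythmic])))
})

test_that("identical seed and parameters reproduce output bit-for-bit", {
  a <- generate_tissue(rat_design(), n_genes = 50, frac_rhythmic = 0.4,
                       noise_sd = 0.2, seed = 42)
  b <- generate_tissue(rat_design(), n_genes = 50, frac_rhythmic = 0.4,
                       noise_sd = 0.2, seed = 42)
  expect_identical(a$matrix$values, b$matrix$values)
  expect_identical(a$truth, b$truth)
  c <- generate_tissue(rat_design(), n_genes = 50, frac_rhythmic = 0.4,
                       noise_sd = 0.2, seed = 43)
  expect_false(identical(a$matrix$values, c$matrix$values))
})

test_that("generator rejects invalid configurations", {
  expect_error(generate_tissue(rat_design(), 10, noise_sd = -1), ">= 0")
  expect_error(generate_tissue(rat_design(), 10, frac_rhythmic = 1.5),
               "\\[0, 1\\]")
  expect_error(generate_tissue(rat_design(), 10,
                               phase_distribution = "vonmises"),
               "phase_dist")
  expect_error(phase_vonmises(25, 2), "\\[0, 24\\)")
  expect_error(phase_vonmises(3, -1), ">= 0")
})

test_that("shared genes carry the configured per-tissue phase offsets", {
  specs <- list(a = list(frac_rhythmic = 0.4), b = list(frac_rhythmic = 0.4))
  mt0 <- generate_multitissue(tissue_specs = specs, n_genes = 300,
                              shared_config = list(n_shared = 50,
                                                   offsets = list(a = 0, b = 0)),
                              seed = 5)
  sh <- mt0$shared_genes
  pa <- sh$phase_true[sh$tissue == "a"][order(sh$gene_id[sh$tissue == "a"])]
  pb <- sh$phase_true[sh$tissue == "b"][order(sh$gene_id[sh$tissue == "b"])]
  expect_true(all(phase_lag(pa, pb) < 1e-9))

  mt12 <- generate_multitissue(tissue_specs = specs, n_genes = 300,
                               shared_config = list(n_shared = 50,
                                                    offsets = list(a = 0, b = 12)),
                               seed = 5)
  sh <- mt12$shared_genes
  pa <- sh$phase_true[sh$tissue == "a"][order(sh$gene_id[sh$tissue == "a"])]
  pb <- sh$phase_true[sh$tissue == "b"][order(sh$gene_id[sh$tissue == "b"])]
  expect_true(all(abs(phase_lag(pa, pb) - 12) < 1e-9))

  # gene ids consistent across tissues; every shared gene rhythmic in both
  expect_true(all(table(mt12$shared_genes$gene_id) == 2L))
})

test_that("von Mises phase offsets give strongly correlated true phases", {
  specs <- list(a = list(frac_rhythmic = 0.5), b = list(frac_rhythmic = 0.5))
  mt <- generate_multitissue(
    tissue_specs = specs, n_genes = 400,
    shared_config = list(n_shared = 200,
                         offsets = list(a = 0,
                                        b = phase_vonmises(0, 4))),
    seed = 13)
  sh <- mt$shared_genes
  pa <- sh$phase_true[sh$tissue == "a"][order(sh$gene_id[sh$tissue == "a"])]
  pb <- sh$phase_true[sh$tissue == "b"][order(sh$gene_id[sh$tissue == "b"])]
  expect_gt(oracle_circ_cor(pa, pb), 0.5)
})

test_that("inconsistent shared configuration is rejected", {
  specs <- list(a = list(frac_rhythmic = 0.1), b = list(frac_rhythmic = 0.5))
  expect_error(
    generate_multitissue(tissue_specs = specs, n_genes = 100,
                         shared_config = list(n_shared = 50,
                                              offsets = list(a = 0, b = 0)),
                         seed = 1),
    "exceeds")
  expect_error(
    generate_multitissue(tissue_specs = list(a = list()), n_genes = 100,
                         seed = 1),
    ">= 2 tissues")
})
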