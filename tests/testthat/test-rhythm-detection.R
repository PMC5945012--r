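test_that("reference waveforms follow the cosine tie structure", {
  d <- study_design(times = c(0, 6, 12, 18), replicates_per_time = 1)
  refs <- build_references(d, phase_step = 12)
  expect_length(refs, 2L)
  r0 <- refs[[1]]
  # cos at (0, 6, 12, 18) is (1, 0, -1, 0): the two zeros tie
  expect_equal(r0$time_groups, c(3L, 2L, 1L, 2L))
  expect_equal(sort(r0$group_sizes), c(1L, 1L, 2L))

  expect_length(build_references(d, phase_step = 1), 24L)
  expect_error(build_references(d, phase_step = 0), "positive")
  expect_error(build_references(d, phase_step = 7), "divide")
})

test_that("references at the dense design match direct cosine evaluation", {
  d <- rat_design()
  refs <- build_references(d, phase_step = 1)
  for (r in refs[c(1, 7, 13, 24)]) {
    cc <- cos(2 * pi * (d$times - r$offset) / 24)
    expect_lte(max(r$time_groups), 18L)
    # group order must match cosine order wherever cosines differ clearly
    for (i in 1:17) for (j in (i + 1):18) {
      if (abs(cc[i] - cc[j]) > 1e-6) {
        expect_equal(sign(r$time_groups[j] - r$time_groups[i]),
                     sign(cc[j] - cc[i]))
      } else {
        expect_equal(r$time_groups[i], r$time_groups[j])
      }
    }
  }
})

test_that("Kendall S matches perfect-concordance arithmetic and brute force", {
  d <- study_design(times = c(0, 3, 6, 9), replicates_per_time = 1)
  refs <- build_references(d, phase_step = 12)
  ref <- refs[[2]]  # offset 12: cosines strictly increasing? check via groups
  # build a reference with 4 distinct increasing groups
  stopifnot(length(unique(ref$sample_groups)) == 4L)
  inc <- order(ref$sample_groups)
  vals <- numeric(4); vals[inc] <- 1:4
  expect_equal(jt_statistic(vals, ref), 6L)
  vals_rev <- numeric(4); vals_rev[inc] <- 4:1
  expect_equal(jt_statistic(vals_rev, ref), -6L)
  expect_error(jt_statistic(1:3, ref), "3 values")

  # property: S equals the double-loop oracle on random data with ties
  set.seed(21)
  d2 <- rat_design(replicates_per_time = 2)
  refs2 <- build_references(d2, phase_step = 3)
  for (k in 1:20) {
    ref <- refs2[[sample(length(refs2), 1)]]
    v <- sample(1:8, length(ref$sample_groups), replace = TRUE)
    expect_identical(jt_statistic(v, ref),
                     brute_jt_statistic(v, ref$sample_groups))
  }
})

test_that("exact null distribution matches enumeration on small designs", {
  d <- exact_null_distribution(c(1, 1))
  expect_equal(d$s, c(-1L, 1L))
  expect_equal(d$prob, c(0.5, 0.5))

  d22 <- exact_null_distribution(c(2, 2))
  expect_equal(d22$prob[d22$s == max(d22$s)], 1 / 6)

  d222 <- exact_null_distribution(c(2, 2, 2))
  en <- enumerate_null(c(2, 2, 2))
  expect_equal(d222$s[d222$prob > 0], en$s)
  expect_equal(d222$prob[d222$prob > 0], en$prob, tolerance = 1e-12)

  expect_error(exact_null_distribution(c(2, 0, 2)), "positive")
})

test_that("null distribution is symmetric about zero and sums to one", {
  for (sizes in list(c(3, 3, 3), c(1, 2, 3, 4), rep(3L, 18L))) {
    d <- exact_null_distribution(sizes)
    expect_equal(sum(d$prob), 1, tolerance = 1e-12)
    expect_equal(d$prob, rev(d$prob), tolerance = 1e-12)
    expect_equal(d$s, -rev(d$s))
  }
})

test_that("phase-scanned p-values behave at the extremes", {
  d <- rat_design()
  refs <- build_references(d, phase_step = 1)
  # constant gene: no ordering signal
  out <- gene_pvalue(rep(2, 54), refs)
  expect_equal(out$p_adj, 1)
  expect_true(is.na(out$best_phase_offset))

  # noiseless cosine at phase 8: the matching reference wins decisively
  tt <- rep(d$times, each = 3)
  x <- 1 + 0.4 * cos(2 * pi * (tt - 8) / 24)
  out <- gene_pvalue(x, refs)
  expect_equal(out$best_phase_offset, 8)
  expect_lt(out$p_adj, 1e-20)
})

test_that("pure-noise p-values are conservative after Bonferroni", {
  # Monte-Carlo calibration at reduced scale: adjusted p should be
  # stochastically >= uniform, i.e. P(p_adj <= a) <= a
  d <- rat_design()
  refs <- build_references(d, phase_step = 2)
  set.seed(99)
  p <- replicate(400, gene_pvalue(rnorm(54), refs)$p_adj)
  for (a in c(0.05, 0.2, 0.5)) {
    expect_lte(mean(p <= a), a + 3 * sqrt(a * (1 - a) / 400))
  }
})

test_that("S, p, phase are invariant to positive scaling and shifts", {
  d <- rat_design()
  set.seed(5)
  tt <- rep(d$times, each = 3)
  x <- 1 + 0.3 * cos(2 * pi * (tt - 5) / 24) + rnorm(54, 0, 0.2)
  refs <- build_references(d, phase_step = 1)
  base <- gene_pvalue(x, refs)
  for (tf in list(function(v) 3.7 * v, function(v) v + 11)) {
    tr <- gene_pvalue(tf(x), refs)
    expect_identical(tr$best_S, base$best_S)
    expect_equal(tr$p_adj, base$p_adj)
    expect_equal(tr$best_phase_offset, base$best_phase_offset)
  }
  est <- estimate_phase_amplitude(x, d, base$best_phase_offset)
  est_scaled <- estimate_phase_amplitude(3.7 * x, d, base$best_phase_offset)
  est_shift <- estimate_phase_amplitude(x + 11, d, base$best_phase_offset)
  expect_equal(est_scaled$amplitude, 3.7 * est$amplitude)
  expect_equal(est_shift$amplitude, est$amplitude)
})

test_that("noiseless cosines are recovered exactly; flat genes never flagged", {
  d <- rat_design()
  tt <- rep(d$times, each = 3)
  X <- t(vapply(0:23, function(p) 1 + 0.5 * cos(2 * pi * (tt - p) / 24),
                numeric(54)))
  X <- rbind(X, matrix(1, 6, 54))
  rownames(X) <- sprintf("g%02d", seq_len(nrow(X)))
  res <- detect_rhythms(X, d)
  cosg <- res[match(sprintf("g%02d", 1:24), res$gene_id), ]
  expect_equal(cosg$phase_h, as.numeric(0:23))
  expect_equal(cosg$amplitude, rep(0.5, 24), tolerance = 1e-9)
  expect_true(all(cosg$circadian))
  flats <- res[match(sprintf("g%02d", 25:30), res$gene_id), ]
  expect_false(any(flats$circadian))
  expect_equal(flats$amplitude, rep(0, 6))
})

test_that("flat-gene estimator returns zero amplitude", {
  d <- rat_design()
  est <- estimate_phase_amplitude(rep(1, 54), d, 4)
  expect_equal(est$amplitude, 0)
  expect_equal(est$phase, 4)
  d1 <- study_design(0, replicates_per_time = 3)
  expect_error(estimate_phase_amplitude(rep(1, 3), d1, 0), "degenerate")
})

test_that("detection output is well-formed and BH-monotone", {
  sim <- generate_tissue(rat_design(), n_genes = 120, frac_rhythmic = 0.3,
                         amplitude_range = c(0.3, 0.5), noise_sd = 0.1,
                         seed = 17)
  res <- detect_rhythms(sim$matrix)
  expect_named(res, c("gene_id", "p_adj", "q", "phase_h", "amplitude",
                      "circadian"))
  expect_true(all(res$p_adj >= 0 & res$p_adj <= 1))
  expect_true(all(res$q >= 0 & res$q <= 1))
  expect_true(!is.unsorted(res$q))               # sorted by q
  expect_equal(res$circadian, res$q < 0.05)
  expect_true(all(res$amplitude >= 0))
  ph <- res$phase_h[!is.na(res$phase_h)]
  expect_true(all(ph >= 0 & ph < 24))
  expect_error(detect_rhythms(sim$matrix, fdr = 1.2), "\\(0, 1\\)")
  expect_error(detect_rhythms(matrix(numeric(0), 0, 54), rat_design()),
               "empty")
})

test_that("an all-flat matrix yields zero circadian genes", {
  d <- rat_design()
  X <- matrix(rep(c(1, 1.2, 0.9), each = 54), nrow = 3, byrow = TRUE)
  rownames(X) <- c("a", "b", "c")
  res <- detect_rhythms(X, d)
  expect_false(any(res$circadian))
  expect_true(all(res$p_adj == 1))
})
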