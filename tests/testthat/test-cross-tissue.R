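test_that("venn partition handles disjoint, identical, and random sets", {
  vp <- venn_partition(list(A = c("a", "b", "c"), B = c("d", "e", "f", "g", "h")))
  expect_equal(vp$count[vp$region == "A"], 3L)
  expect_equal(vp$count[vp$region == "B"], 5L)
  expect_equal(vp$count[vp$region == "A&B"], 0L)

  vp2 <- venn_partition(list(A = letters[1:4], B = letters[1:4]))
  expect_equal(vp2$count[vp2$region == "A&B"], 4L)
  expect_equal(sum(vp2$count), 4L)

  # randomized 4-set instance vs per-gene brute-force classification
  set.seed(31)
  univ <- sprintf("g%03d", 1:150)
  sets <- lapply(1:4, function(i) sample(univ, sample(30:90, 1)))
  names(sets) <- c("liver", "muscle", "adipose", "lung")
  vp4 <- venn_partition(sets)
  expect_equal(sum(vp4$count), length(unique(unlist(sets))))
  for (g in unique(unlist(sets))) {
    membership <- names(sets)[vapply(sets, function(s) g %in% s, logical(1))]
    region <- paste(membership, collapse = "&")
    expect_true(g %in% attr(vp4, "members")[[region]])
  }
  # pairwise counts agree with direct intersections
  for (pr in list(c("liver", "lung"), c("muscle", "adipose"))) {
    expect_equal(pairwise_common_count(vp4, pr),
                 length(intersect(sets[[pr[1]]], sets[[pr[2]]])))
  }
  expect_error(venn_partition(list(A = "x")), "2-4")
  expect_error(pairwise_common_count(vp4, c("liver", "heart")), "two of")
})

test_that("phase lag uses the circular convention with wrap at 24 h", {
  expect_equal(phase_lag(6, 6), 0)
  expect_equal(phase_lag(0, 12), 12)
  expect_equal(phase_lag(23, 1), 2)
  expect_equal(phase_lag(1, 23), 2)  # symmetry
  expect_error(phase_lag(24, 3), "\\[0, 24\\)")

  expect_equal(max_phase_lag(c(4, 4, 4)), 0)
  expect_equal(max_phase_lag(c(0, 6, 12)), 12)
  expect_equal(max_phase_lag(c(1, 2, 3, 23)), 4)
  expect_error(max_phase_lag(c(1, 2)), "length 3 or 4")

  # triangle-type bound: the max dominates every pairwise lag
  set.seed(7)
  for (k in 1:20) {
    ph <- runif(4, 0, 24)
    mx <- max_phase_lag(ph)
    prs <- combn(4, 2)
    expect_true(all(phase_lag(ph[prs[1, ]], ph[prs[2, ]]) <= mx + 1e-12))
  }
})

test_that("percent amplitude difference follows (Amax - Amin)/Amax * 100", {
  expect_equal(amplitude_diff(0.4, 0.4), 0)
  expect_equal(amplitude_diff(2, 1), 50)
  expect_equal(amplitude_diff(1, 2), 50)
  expect_equal(amplitude_diff(10, 1), 90)
  expect_error(amplitude_diff(0, 1), "positive")

  expect_equal(max_amplitude_diff(c(1, 1, 1)), 0)
  expect_equal(max_amplitude_diff(c(1, 2, 4)), 75)
  expect_equal(max_amplitude_diff(c(0.5, 1, 2, 5)), 90)
  expect_error(max_amplitude_diff(c(1, 2)), "length 3 or 4")
})

test_that("circular correlation meets its exact contracts", {
  ph <- c(1, 5, 9, 14, 20, 22)
  expect_equal(circular_correlation(ph, ph)$r, 1)
  expect_equal(circular_correlation(ph, (24 - ph) %% 24)$r, -1)

  # rotation invariance: adding any constant rotation leaves r unchanged
  set.seed(3)
  a <- runif(30, 0, 24)
  b <- (a + rnorm(30, 0, 2)) %% 24
  r0 <- circular_correlation(a, b)$r
  for (rot in c(3, 11.5, 20)) {
    expect_equal(circular_correlation((a + rot) %% 24, (b + rot) %% 24)$r, r0)
    expect_equal(circular_correlation((a + rot) %% 24, b)$r, r0)
  }

  # agreement with an independent transcription of the formula
  set.seed(13)
  p1 <- runif(20, 0, 24)
  p2 <- runif(20, 0, 24)
  expect_equal(circular_correlation(p1, p2)$r, oracle_circ_cor(p1, p2),
               tolerance = 1e-12)

  expect_error(circular_correlation(1:3, 1:4), "paired")
  expect_error(circular_correlation(c(5, 5), c(3, 15)), "undefined")
})

test_that("species overlap reports nearest-integer conservation percent", {
  rat <- sprintf("r%04d", 1:2027)
  mouse <- c(rat[1:791], sprintf("m%04d", 1:500))
  ov <- species_overlap(rat, mouse)
  expect_equal(ov$n_conserved, 791L)
  expect_equal(ov$percent, 39L)  # 791/2027 = 39.02%
  expect_equal(species_overlap(rat, rat)$percent, 100L)
  expect_equal(species_overlap(rat, c("x", "y"))$percent, 0L)
  expect_error(species_overlap(character(0), rat), "empty")

  pr <- setNames(runif(length(rat), 0, 24), rat)
  ov2 <- species_overlap(rat, mouse, pr, pr)
  expect_equal(ov2$phase_correlation$r, 1)
})

test_that("binning uses first-bin-closed then right-closed edges", {
  edges <- seq(0, 12, by = 2)
  expect_equal(unname(bin_values(c(0.5, 3), edges)),
               c(1L, 1L, 0L, 0L, 0L, 0L))
  # a value exactly on an interior edge falls in the lower bin
  expect_equal(unname(bin_values(c(0.5, 2), edges)),
               c(2L, 0L, 0L, 0L, 0L, 0L))
  expect_equal(unname(bin_values(0, edges))[1], 1L)  # left edge included
  expect_error(bin_values(13, edges), "13")
  expect_error(bin_values(1, c(3, 2)), "increasing")

  set.seed(11)
  v <- runif(1000, 0, 12)
  expect_equal(unname(bin_values(v, edges)), brute_bin(v, edges))
  expect_equal(sum(bin_values(v, edges)), 1000L)
})

test_that("tissue comparison summarizes shared circadian genes", {
  mk <- function(ids, phase, amp) {
    structure(data.frame(gene_id = ids, p_adj = 0, q = 0, phase_h = phase,
                         amplitude = amp, circadian = TRUE,
                         stringsAsFactors = FALSE),
              class = c("rhythm_result", "data.frame"))
  }
  a <- mk(c("g1", "g2", "g3"), c(1, 6, 23), c(1, 2, 4))
  b <- mk(c("g2", "g3", "g4"), c(8, 1, 4), c(1, 2, 1))
  cmp <- compare_tissues(list(a = a, b = b))
  expect_equal(cmp$genes$gene_id, c("g2", "g3"))
  expect_equal(cmp$genes$delta_phi, c(2, 2))
  expect_equal(cmp$genes$delta_A, c(50, 50))
  expect_equal(sum(cmp$phase_hist), 2L)
  expect_equal(sum(cmp$amplitude_hist), 2L)

  cc <- mk(c("g2", "g3"), c(20, 13), c(8, 0.5))
  cmp3 <- compare_tissues(list(a = a, b = b, c = cc))
  expect_equal(cmp3$genes$delta_phi,
               c(max_phase_lag(c(6, 8, 20)), max_phase_lag(c(23, 1, 13))))
  expect_equal(cmp3$genes$delta_A,
               c(amplitude_diff(8, 1), amplitude_diff(4, 0.5)))
})
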