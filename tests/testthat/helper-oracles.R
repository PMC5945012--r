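# Independent oracles used across the suite. These deliberately use the
# slowest, most literal formulation of each quantity so they stay independent
# of the package's implementation paths.

# Kendall S by explicit double loop over sample pairs
brute_jt_statistic <- function(values, groups) {
  s <- 0L
  n <- length(values)
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      if (groups[i] == groups[j]) next
      lo <- if (groups[i] < groups[j]) i else j
      hi <- if (groups[i] < groups[j]) j else i
      s <- s + sign(values[hi] - values[lo])
    }
  }
  as.integer(s)
}

# all permutations of 1..n as an n! x n matrix
all_perms <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- all_perms(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(i) {
    shifted <- sub + (sub >= i)
    cbind(rep(i, nrow(sub)), shifted)
  }))
}

# exact null of S by exhaustive enumeration over all rank permutations
enumerate_null <- function(group_sizes) {
  n <- sum(group_sizes)
  groups <- rep(seq_along(group_sizes), group_sizes)
  P <- all_perms(n)
  pairs <- which(outer(groups, groups, "<"), arr.ind = TRUE)
  s <- rep(0L, nrow(P))
  for (k in seq_len(nrow(pairs))) {
    s <- s + sign(P[, pairs[k, 2L]] - P[, pairs[k, 1L]])
  }
  tab <- table(s)
  list(s = as.integer(names(tab)), prob = as.vector(tab) / nrow(P))
}

# literal transcription of the circular correlation formula, written with
# complex arithmetic for the mean directions
oracle_circ_cor <- function(phi1_h, phi2_h) {
  a1 <- phi1_h / 24 * 2 * pi
  a2 <- phi2_h / 24 * 2 * pi
  t1 <- Arg(sum(complex(modulus = 1, argument = a1)))
  t2 <- Arg(sum(complex(modulus = 1, argument = a2)))
  num <- 0
  d1 <- 0
  d2 <- 0
  for (k in seq_along(a1)) {
    num <- num + sin(a1[k] - t1) * sin(a2[k] - t2)
    d1 <- d1 + sin(a1[k] - t1)^2
    d2 <- d2 + sin(a2[k] - t2)^2
  }
  num / sqrt(d1 * d2)
}

# brute-force loop classifier for first-bin-closed, right-closed binning
brute_bin <- function(values, edges) {
  counts <- integer(length(edges) - 1L)
  for (v in values) {
    for (b in seq_len(length(edges) - 1L)) {
      lo_ok <- if (b == 1L) v >= edges[1L] else v > edges[b]
      if (lo_ok && v <= edges[b + 1L]) {
        counts[b] <- counts[b] + 1L
        break
      }
    }
  }
  counts
}

# all ordered compositions of n into parts >= 1
compositions <- function(n) {
  if (n == 1L) return(list(1L))
  out <- list()
  for (first in seq_len(n)) {
    if (first == n) {
      out <- c(out, list(n))
    } else {
      for (rest in compositions(n - first)) {
        out <- c(out, list(c(first, rest)))
      }
    }
  }
  out
}

# circular absolute phase error in hours
circ_err_h <- function(est, truth) {
  d <- abs(est - truth) %% 24
  pmin(d, 24 - d)
}
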