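# Independent oracles used to check the package implementations.

# Brute-force robustness: neighbour-list survival trace, written against a
# plain adjacency matrix and independent of the package's cascade engine.
oracle_surviving <- function(adj, removed_idx,
                             cascade = c("degree_zero", "none")) {
  cascade <- match.arg(cascade)
  n <- nrow(adj)
  alive <- setdiff(seq_len(n), removed_idx)
  if (cascade == "none") return(length(alive))
  repeat {
    deg <- sapply(alive, function(i) sum(adj[i, alive]))
    dead <- alive[deg == 0]
    if (!length(dead)) break
    alive <- setdiff(alive, dead)
  }
  length(alive)
}

# Mean robustness over every removal set of size k (exhaustive enumeration).
oracle_robustness_exhaustive <- function(adj, k, cascade = "degree_zero") {
  n <- nrow(adj)
  sets <- utils::combn(n, k)
  mean(apply(sets, 2L, function(s)
    oracle_surviving(adj, s, cascade) / n))
}

# Exact two-sided rank-sum p by direct tail counting over all group
# assignments; tolerates midrank ties.
oracle_wilcoxon_p <- function(x, y) {
  v <- c(x, y)
  rk <- rank(v)
  n1 <- length(x)
  assignments <- utils::combn(length(v), n1)
  sums <- apply(assignments, 2L, function(i) sum(rk[i]))
  w <- sum(rk[seq_len(n1)])
  lo <- sum(sums <= w + 1e-9) / length(sums)
  hi <- sum(sums >= w - 1e-9) / length(sums)
  min(1, 2 * min(lo, hi))
}

# PERMANOVA pseudo-F computed straight from the definition with loops.
oracle_permanova_f <- function(d, groups) {
  n <- nrow(d)
  lev <- unique(groups)
  sst <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n) sst <- sst + d[i, j]^2
  sst <- sst / n
  ssw <- 0
  for (g in lev) {
    idx <- which(groups == g)
    s <- 0
    if (length(idx) > 1)
      for (a in seq_along(idx)[-length(idx)])
        for (b in (a + 1):length(idx)) s <- s + d[idx[a], idx[b]]^2
    ssw <- ssw + s / length(idx)
  }
  ((sst - ssw) / (length(lev) - 1)) / (ssw / (n - length(lev)))
}

oracle_permanova_exhaustive_p <- function(d, groups) {
  f_obs <- oracle_permanova_f(d, groups)
  n1 <- sum(groups == unique(groups)[1L])
  sets <- utils::combn(length(groups), n1)
  f_all <- apply(sets, 2L, function(i) {
    g <- ifelse(seq_along(groups) %in% i, "A", "B")
    oracle_permanova_f(d, g)
  })
  mean(f_all >= f_obs - 1e-12)
}
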