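# Two-group statistics: rank tests with FDR, Spearman screens,
# Bray-Curtis distances, and distance-based PERMANOVA.

# Exact two-sided rank-sum p-value with midrank ties, by complete
# enumeration of group assignments.  Feasible for combined n <= ~12.
wilcoxon_exact_p <- function(x, y) {
  ranks <- rank(c(x, y))
  n1 <- length(x)
  w_obs <- sum(ranks[seq_len(n1)])
  sets <- utils::combn(length(ranks), n1)
  w_all <- colSums(matrix(ranks[sets], nrow = n1))
  tol <- 1e-9
  p_lo <- mean(w_all <= w_obs + tol)
  p_hi <- mean(w_all >= w_obs - tol)
  min(1, 2 * min(p_lo, p_hi))
}

#' Per-feature Wilcoxon rank-sum tests with BH adjustment
#'
#' Each feature (row) is compared between the two groups with the Wilcoxon
#' rank-sum test: exact enumeration with midrank ties when the combined
#' sample size is at most `exact_max_n`, otherwise the normal
#' approximation with tie and continuity corrections.  Raw p-values are
#' adjusted across features by Benjamini-Hochberg.
#'
#' @param table feature x sample numeric matrix.
#' @param groups group label per sample (exactly two levels).
#' @param exact_max_n combined-n cut-off for the exact branch.
#' @return data.frame with `feature`, `statistic` (rank sum of the first
#'   group), `p`, `padj`.
#' @export
wilcoxon_fdr <- function(table, groups, exact_max_n = 12L) {
  groups <- as.factor(groups)
  if (nlevels(groups) != 2L) stop("exactly two groups required")
  if (any(table(groups) < 2L)) stop("each group needs >= 2 samples")
  if (length(groups) != ncol(table)) stop("groups must match samples")
  ga <- groups == levels(groups)[1L]
  res <- t(apply(table, 1L, function(v) {
    x <- v[ga]; y <- v[!ga]
    w <- sum(rank(v)[ga])
    if (stats::var(v) == 0) return(c(w, 1))
    p <- if (length(v) <= exact_max_n) {
      wilcoxon_exact_p(x, y)
    } else {
      suppressWarnings(stats::wilcox.test(x, y, exact = FALSE,
                                          correct = TRUE)$p.value)
    }
    c(w, p)
  }))
  data.frame(feature = rownames(table), statistic = res[, 1L],
             p = res[, 2L], padj = bh_adjust(res[, 2L]),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjustment with enforced monotonicity, mapped back to the input
#' order; a thin validated wrapper over [stats::p.adjust()].
#'
#' @param p p-values in `[0, 1]`.
#' @return adjusted p-values, same order, each in `[0, 1]`.
#' @export
bh_adjust <- function(p) {
  if (any(is.na(p)) || any(p < 0 | p > 1)) stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Spearman correlation screen of features against a phenotype
#'
#' Features are gated at `min_prevalence` (fraction of samples with a
#' nonzero value), samples with a missing phenotype are dropped
#' (pairwise-complete), rho is computed from midranks and the p-value from
#' the t approximation on `n - 2` degrees of freedom.  Constant features
#' or phenotypes have no defined rank correlation and are flagged with
#' `NA` and excluded from the BH family.
#'
#' @param table feature x sample matrix.
#' @param phenotype numeric phenotype per sample (`NA` = missing).
#' @param min_prevalence minimum detection fraction gate.
#' @return data.frame with `feature`, `rho`, `p`, `padj`, `n_used`.
#' @export
spearman_screen <- function(table, phenotype, min_prevalence = 0.5) {
  if (length(phenotype) != ncol(table))
    stop("phenotype length must match sample count")
  keep_s <- !is.na(phenotype)
  tab <- table[, keep_s, drop = FALSE]
  ph <- phenotype[keep_s]
  gate <- rowSums(tab > 0) >= min_prevalence * ncol(tab)
  tab <- tab[gate, , drop = FALSE]
  n <- length(ph)
  if (n < 4L) stop("need >= 4 paired observations")
  ph_const <- stats::sd(ph) == 0
  stat <- t(apply(tab, 1L, function(v) {
    if (ph_const || stats::sd(v) == 0) return(c(NA_real_, NA_real_))
    rho <- stats::cor(rank(v), rank(ph))
    if (abs(rho) >= 1) return(c(rho, 0))
    tt <- rho * sqrt((n - 2) / (1 - rho^2))
    c(rho, 2 * stats::pt(-abs(tt), df = n - 2))
  }))
  padj <- rep(NA_real_, nrow(stat))
  ok <- !is.na(stat[, 2L])
  padj[ok] <- bh_adjust(stat[ok, 2L])
  data.frame(feature = rownames(tab), rho = stat[, 1L], p = stat[, 2L],
             padj = padj, n_used = n,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Bray-Curtis distance matrix between samples
#'
#' `BC_ij = sum|a - b| / sum(a + b)` over taxa, via [vegan::vegdist()].
#'
#' @param table abundance table (taxa x samples, non-negative).
#' @return symmetric sample x sample distance matrix in `[0, 1]`.
#' @export
bray_curtis <- function(table) {
  if (any(table < 0)) stop("negative abundances")
  zero <- colSums(table) == 0
  if (sum(zero) >= 2L)
    stop("Bray-Curtis undefined between all-zero samples: ",
         paste(colnames(table)[zero], collapse = ", "))
  m <- as.matrix(vegan::vegdist(t(table), method = "bray"))
  diag(m) <- 0
  validate_distance_matrix(m)
}

# Pseudo-F for a distance matrix and a grouping, Anderson's formulation:
# SS_total = sum_{i<j} d_ij^2 / n;  SS_within = sum_g sum_{i<j in g} d^2/n_g.
permanova_f <- function(d2, groups) {
  n <- nrow(d2)
  a <- nlevels(groups)
  sst <- sum(d2[upper.tri(d2)]) / n
  ssw <- 0
  for (g in levels(groups)) {
    i <- which(groups == g)
    ssw <- ssw + sum(d2[i, i][upper.tri(d2[i, i])]) / length(i)
  }
  ((sst - ssw) / (a - 1)) / (ssw / (n - a))
}

#' PERMANOVA: permutational multivariate analysis of variance
#'
#' One-factor PERMANOVA on a distance matrix.  The pseudo-F statistic
#' follows Anderson's sums-of-squared-distances formulation; the p-value
#' is `(1 + #(F_perm >= F_obs)) / (B + 1)` over `B` uniform random label
#' permutations, or the exact proportion over all distinct group splits
#' when `permutations = "exhaustive"` (feasible for small n).
#'
#' @param d distance matrix (as from [bray_curtis()] or
#'   [read_distance_matrix()]).
#' @param groups group label per sample (>= 2 groups, each >= 2 samples).
#' @param permutations number of random permutations, or `"exhaustive"`.
#' @param seed integer seed for the random permutations.
#' @return list of class `permanova` with `F`, `p`, `permutations`.
#' @export
permanova <- function(d, groups, permutations = 1000L, seed = NULL) {
  d <- as.matrix(d)
  groups <- as.factor(groups)
  if (length(groups) != nrow(d)) stop("groups must match the matrix")
  if (nlevels(groups) < 2L) stop("need >= 2 groups")
  if (any(table(groups) < 2L)) stop("singleton group")
  d2 <- d^2
  f_obs <- permanova_f(d2, groups)
  if (identical(permutations, "exhaustive")) {
    if (nlevels(groups) != 2L)
      stop("exhaustive enumeration supports exactly 2 groups")
    n1 <- sum(groups == levels(groups)[1L])
    sets <- utils::combn(length(groups), n1)
    f_all <- apply(sets, 2L, function(i) {
      g <- factor(ifelse(seq_along(groups) %in% i,
                         levels(groups)[1L], levels(groups)[2L]))
      permanova_f(d2, g)
    })
    p <- mean(f_all >= f_obs - 1e-12)
    b <- ncol(sets)
  } else {
    b <- as.integer(permutations)
    f_perm <- with_seed(seed, vapply(seq_len(b), function(k) {
      permanova_f(d2, sample(groups))
    }, numeric(1L)))
    p <- (1 + sum(f_perm >= f_obs - 1e-12)) / (b + 1)
  }
  structure(list(F = f_obs, p = p, permutations = b), class = "permanova")
}

#' @export
print.permanova <- function(x, ...) {
  cat(sprintf("PERMANOVA: pseudo-F = %.4f, p = %.4g (%d permutations)\n",
              x$F, x$p, x$permutations))
  invisible(x)
}
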