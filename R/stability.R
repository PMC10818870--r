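# Network stability: removal simulations with secondary extinctions, and
# abundance-weighted null-corrected cohesion.

# Shared cascade engine on an adjacency representation.  `removed` is a
# logical vector over the original nodes; returns the logical survivor set.
apply_cascade <- function(adj, wadj, removed,
                          cascade = c("degree_zero", "abundance_threshold",
                                      "none"),
                          theta = 0.5) {
  cascade <- match.arg(cascade)
  alive <- !removed
  if (cascade == "none") return(alive)
  if (cascade == "degree_zero") {
    # deleting an isolated node cannot isolate another: one pass suffices
    deg <- as.vector(adj %*% alive)
    alive & (deg > 0)
  } else {
    s0 <- as.vector(wadj %*% rep(1, ncol(wadj)))
    repeat {
      s <- as.vector(wadj %*% alive)
      drop <- alive & (s < theta * s0 | s <= 0)
      if (!any(drop)) break
      alive <- alive & !drop
    }
    alive
  }
}

net_adjacency <- function(net) {
  adj <- igraph::as_adjacency_matrix(net, sparse = FALSE)
  ab <- igraph::V(net)$abundance
  if (is.null(ab)) ab <- rep(1, igraph::vcount(net))
  el <- igraph::as_edgelist(net, names = FALSE)
  w <- abs(igraph::E(net)$correlation %||% rep(1, igraph::ecount(net)))
  wadj <- matrix(0, nrow(adj), ncol(adj))
  if (nrow(el)) {
    # abundance-weighted link strength: |r_ij| * abundance of the partner
    wadj[el] <- w * ab[el[, 2L]]
    wadj[el[, 2:1, drop = FALSE]] <- w * ab[el[, 1L]]
  }
  list(adj = adj, wadj = wadj)
}

#' Network robustness under random node removal
#'
#' Per replicate, `floor(fraction * N)` nodes are removed uniformly at
#' random; a secondary-extinction cascade then removes nodes that can no
#' longer persist.  The default `degree_zero` rule extinguishes nodes whose
#' degree falls to zero; the `abundance_threshold` rule extinguishes nodes
#' whose abundance-weighted link sum falls below `theta` times its original
#' value, iterated to a fixed point; `none` disables cascades (robustness
#' is then exactly `1 - removed/N`).  Robustness is the proportion of the
#' original nodes remaining.
#'
#' @param net an `igraph` network.
#' @param fraction fraction of nodes removed, in `(0, 1)`.
#' @param replicates number of random removal replicates.
#' @param cascade secondary-extinction rule.
#' @param theta retention threshold for the weighted rule.
#' @param seed integer seed.
#' @return object of class `robustness`: `values` (per replicate), `mean`,
#'   `sd`, and the parameters.
#' @export
robustness_random <- function(net, fraction = 0.5, replicates = 100L,
                              cascade = "degree_zero", theta = 0.5,
                              seed = NULL) {
  n <- igraph::vcount(net)
  if (n == 0L) stop("empty network")
  if (fraction <= 0 || fraction >= 1) stop("fraction must lie in (0, 1)")
  n_remove <- floor(fraction * n)
  if (n_remove < 1L) stop("fraction * N < 1: nothing would be removed")
  ad <- net_adjacency(net)
  values <- with_seed(seed, vapply(seq_len(replicates), function(b) {
    removed <- logical(n)
    removed[sample.int(n, n_remove)] <- TRUE
    sum(apply_cascade(ad$adj, ad$wadj, removed, cascade, theta)) / n
  }, numeric(1L)))
  structure(list(values = values, mean = mean(values), sd = stats::sd(values),
                 mode = "random", fraction = fraction,
                 replicates = replicates, cascade = cascade, theta = theta),
            class = "robustness")
}

#' Network robustness under targeted hub removal
#'
#' Removes the top `n_hubs` module hubs (role `module_hub` in the Zi-Pi
#' table, ranked by Zi descending with ties broken by Pi ascending then
#' node id), applies the secondary-extinction cascade, and reports the
#' proportion of nodes remaining.  If fewer module hubs exist than
#' requested, the ranking falls back to the highest-Zi nodes overall and
#' the result is flagged.
#'
#' @param net an `igraph` network.
#' @param zipi_table Zi-Pi table from [zipi()].
#' @param n_hubs number of hubs to remove.
#' @param cascade,theta see [robustness_random()].
#' @return object of class `robustness` with a single `values` entry, the
#'   removed hub ids, and a `fallback` flag.
#' @export
robustness_targeted <- function(net, zipi_table, n_hubs = 3L,
                                cascade = "degree_zero", theta = 0.5) {
  n <- igraph::vcount(net)
  if (n == 0L) stop("empty network")
  hubs <- zipi_table[zipi_table$role %in% c("module_hub", "network_hub"), ,
                     drop = FALSE]
  fallback <- nrow(hubs) < n_hubs
  pool <- if (fallback) zipi_table else hubs
  ord <- order(-pool$Zi, pool$Pi, pool$node)
  target <- utils::head(pool$node[ord], n_hubs)
  ad <- net_adjacency(net)
  removed <- igraph::V(net)$name %in% target
  value <- sum(apply_cascade(ad$adj, ad$wadj, removed, cascade, theta)) / n
  if (fallback)
    warning("only ", nrow(hubs), " module hub(s) present; removed top-Zi ",
            "nodes instead")
  structure(list(values = value, mean = value, sd = NA_real_,
                 mode = "targeted", removed_nodes = target,
                 fallback = fallback, cascade = cascade, theta = theta),
            class = "robustness")
}

#' @export
print.robustness <- function(x, ...) {
  cat(sprintf("Network robustness (%s removal, cascade = %s): %.4f",
              x$mode, x$cascade, x$mean))
  if (x$mode == "random")
    cat(sprintf(" +/- %.4f sd over %d replicates", x$sd, x$replicates))
  cat("\n")
  invisible(x)
}

#' Per-taxon connectedness: null-corrected average correlations
#'
#' Observed pairwise Pearson correlations of relative abundances are
#' corrected by a taxa-shuffle null model: in each null iteration every
#' taxon's abundance vector is permuted across samples independently, and
#' the mean null correlation is subtracted from the observed one.  A
#' taxon's positive connectedness is the mean of its positive corrected
#' correlations with all other taxa; negative connectedness the mean of
#' the negative ones (0 when a taxon has none of that sign).
#'
#' @param reltable relative-abundance table (taxa x samples, >= 3 samples).
#' @param null_reps number of null permutation iterations.
#' @param seed integer seed.
#' @return data.frame of class `connectedness` with `taxon`, `c_plus`
#'   (>= 0), `c_minus` (<= 0).
#' @export
connectedness <- function(reltable, null_reps = 200L, seed = NULL) {
  if (ncol(reltable) < 3L) stop("need at least 3 samples")
  x <- t(reltable)                       # samples x taxa
  nt <- ncol(x)
  ns <- nrow(x)
  zero_var <- apply(x, 2L, stats::sd) == 0
  if (any(zero_var))
    message("zero-variance taxa get connectedness 0: ",
            paste(colnames(x)[zero_var], collapse = ", "))
  r_obs <- suppressWarnings(stats::cor(x))
  r_obs[is.na(r_obs)] <- 0
  null_mean <- with_seed(seed, {
    acc <- matrix(0, nt, nt)
    for (b in seq_len(null_reps)) {
      xp <- apply(x, 2L, sample)
      rn <- suppressWarnings(stats::cor(xp))
      rn[is.na(rn)] <- 0
      acc <- acc + rn
    }
    acc / null_reps
  })
  rhat <- r_obs - null_mean
  diag(rhat) <- NA
  c_plus <- apply(rhat, 1L, function(v) {
    v <- v[!is.na(v) & v > 0]
    if (length(v)) mean(v) else 0
  })
  c_minus <- apply(rhat, 1L, function(v) {
    v <- v[!is.na(v) & v < 0]
    if (length(v)) mean(v) else 0
  })
  c_plus[zero_var] <- 0
  c_minus[zero_var] <- 0
  structure(data.frame(taxon = rownames(reltable), c_plus = c_plus,
                       c_minus = c_minus, row.names = NULL,
                       stringsAsFactors = FALSE),
            class = c("connectedness", "data.frame"))
}

#' Per-sample community cohesion
#'
#' Positive (negative) cohesion of a sample is the abundance-weighted sum
#' of its taxa's positive (negative) connectedness:
#' `C+_i = sum_j a_ij * c+_j`, with `a_ij` the relative abundance of taxon
#' `j` in sample `i`.  High positive cohesion marks a cooperative
#' community, strongly negative cohesion a competitive one.
#'
#' @param reltable relative-abundance table.
#' @param conn [connectedness()] result on the same taxa.
#' @return data.frame with `sample_id`, `cohesion_pos` (>= 0),
#'   `cohesion_neg` (<= 0).
#' @export
cohesion <- function(reltable, conn) {
  if (!identical(sort(rownames(reltable)), sort(conn$taxon)))
    stop("taxa in the table and connectedness result differ")
  cp <- stats::setNames(conn$c_plus, conn$taxon)[rownames(reltable)]
  cm <- stats::setNames(conn$c_minus, conn$taxon)[rownames(reltable)]
  data.frame(sample_id = colnames(reltable),
             cohesion_pos = as.numeric(crossprod(reltable, cp)),
             cohesion_neg = as.numeric(crossprod(reltable, cm)),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Two-sample Student's t comparison of stability metrics
#'
#' Equal-variance Student's t by default (Welch optional), two-sided.
#' Degenerate input with zero variance in both groups and equal means
#' returns `t = 0`, `p = 1` rather than an error.
#'
#' @param a,b numeric vectors (>= 2 values each).
#' @param var_equal pool the variance (Student) or not (Welch).
#' @return list with `t`, `df`, `p`, group means.
#' @export
compare_stability <- function(a, b, var_equal = TRUE) {
  if (length(a) < 2L || length(b) < 2L) stop("need >= 2 values per group")
  if (stats::sd(a) == 0 && stats::sd(b) == 0) {
    same <- isTRUE(all.equal(mean(a), mean(b)))
    return(list(t = if (same) 0 else Inf, df = length(a) + length(b) - 2L,
                p = if (same) 1 else 0,
                mean_a = mean(a), mean_b = mean(b)))
  }
  ht <- stats::t.test(a, b, var.equal = var_equal)
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       p = ht$p.value, mean_a = mean(a), mean_b = mean(b))
}
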