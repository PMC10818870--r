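#' Pairwise Pearson correlation of log abundances
#'
#' Correlates taxa (rows) across samples.  Taxa with zero variance cannot
#' carry a correlation signal: their off-diagonal entries are set to 0 and
#' their ids reported in the `zero_variance` field so they drop out of any
#' thresholded network.
#'
#' @param logtable log-transformed abundance table (taxa x samples);
#'   any numeric taxa-by-samples matrix is accepted.
#' @return object of class `corr_matrix`: list with `r` (symmetric, unit
#'   diagonal), `taxon_ids`, `zero_variance`, `n_samples`.
#' @export
pearson_matrix <- function(logtable) {
  if (ncol(logtable) < 3L) stop("need at least 3 samples")
  sds <- apply(logtable, 1L, stats::sd)
  zv <- rownames(logtable)[sds == 0]
  r <- suppressWarnings(stats::cor(t(logtable)))
  r[is.na(r)] <- 0
  diag(r) <- 1
  structure(list(r = r, taxon_ids = rownames(logtable),
                 zero_variance = zv, n_samples = ncol(logtable)),
            class = "corr_matrix")
}

#' Nearest-neighbour spacing distribution of an eigenvalue spectrum
#'
#' The spectrum is unfolded by mapping each eigenvalue through a smoothed
#' empirical cumulative spectral function (a monotone piecewise-cubic fit
#' to the eigenvalue staircase), so that spacings have unit mean density.
#' The spacing histogram is then scored against the two random-matrix
#' reference laws: Poisson `P(d) = exp(-d)` (uncorrelated levels — the
#' signature of a modular, non-random correlation structure) and the GOE
#' Wigner surmise `P(d) = (pi d / 2) exp(-pi d^2 / 4)` (level repulsion —
#' the signature of a noise-dominated matrix).
#'
#' @param eigenvalues numeric vector of eigenvalues (any order).
#' @param bins number of equal-width histogram bins on `support`.
#' @param support spacing range for the histogram; spacings beyond it fall
#'   into an overflow cell that still enters the chi-square.
#' @param knots number of knots for the monotone spline unfolding;
#'   default `max(5, floor(sqrt(n)))`.
#' @return list with `spacings` (unit mean), `chi2_poisson`, `chi2_goe`,
#'   `p_poisson` (chi-square goodness-of-fit p-value vs Poisson), `df`.
#' @export
nnsd <- function(eigenvalues, bins = 20L, support = c(0, 3), knots = NULL) {
  ev <- sort(as.numeric(eigenvalues))
  n <- length(ev)
  if (n < 3L) stop("need at least 3 eigenvalues")
  # smoothed empirical spectral CDF: monotone cubic through a thinned set
  # of (eigenvalue, cumulative fraction) knots
  if (is.null(knots)) knots <- max(5L, floor(sqrt(n)))
  idx <- unique(round(seq(1L, n, length.out = min(knots, n))))
  kx <- ev[idx]
  ky <- idx / n
  dup <- duplicated(kx)
  if (any(dup)) {            # tied eigenvalues: keep the upper step
    ky <- rev(tapply(rev(ky), rev(match(kx, unique(kx))), max))
    kx <- unique(kx)
  }
  if (length(kx) < 2L) stop("degenerate spectrum: all eigenvalues equal")
  fcdf <- stats::splinefun(kx, ky, method = "monoH.FC")
  unfolded <- n * pmin(1, pmax(0, fcdf(ev)))
  d <- diff(unfolded)
  d <- d[d >= 0]
  if (mean(d) <= 0) stop("degenerate spectrum: zero mean spacing")
  d <- d / mean(d)

  brk <- seq(support[1L], support[2L], length.out = bins + 1L)
  inside <- d < support[2L]
  obs <- c(tabulate(findInterval(d[inside], brk, rightmost.closed = TRUE),
                    nbins = bins),
           sum(!inside))
  p_pois <- c(exp(-brk[-length(brk)]) - exp(-brk[-1L]), exp(-support[2L]))
  p_goe <- c(exp(-pi * brk[-length(brk)]^2 / 4) - exp(-pi * brk[-1L]^2 / 4),
             exp(-pi * support[2L]^2 / 4))
  m <- length(d)
  chi2 <- function(p) sum((obs - m * p)^2 / (m * p))
  df <- bins                                  # cells - 1
  structure(list(spacings = d,
                 chi2_poisson = chi2(p_pois), chi2_goe = chi2(p_goe),
                 p_poisson = stats::pchisq(chi2(p_pois), df,
                                           lower.tail = FALSE),
                 df = df, n_eigenvalues = n),
            class = "nnsd")
}

#' RMT scan: select the correlation threshold automatically
#'
#' For each candidate cut-off `s` the correlation matrix is hard-thresholded
#' (entries with `|r| < s` zeroed), taxa left without any off-diagonal entry
#' are dropped, and the nearest-neighbour spacing distribution of the
#' surviving matrix's eigenvalues is scored against the Poisson and GOE
#' laws.  The transition from GOE-like to Poisson-like spacing marks the
#' point where random noise correlations have been removed and only the
#' modular biological signal remains; the selected threshold is the
#' smallest `s` whose Poisson goodness-of-fit p-value exceeds `alpha` and
#' whose GOE chi-square exceeds its Poisson chi-square, among scans with at
#' least `min_eigs` surviving taxa.  If no threshold qualifies, the scan
#' falls back to the `s` minimising the Poisson chi-square and flags the
#' result as degraded.
#'
#' @param corr a `corr_matrix` from [pearson_matrix()].
#' @param grid increasing candidate thresholds.
#' @param min_eigs minimum surviving taxa for a reliable spacing fit.
#' @param alpha Poisson goodness-of-fit level.
#' @param bins,support passed to [nnsd()].
#' @return object of class `rmt_scan`: `scan` data.frame (threshold,
#'   n_nodes, chi2_poisson, chi2_goe, p_poisson), `selected_threshold`,
#'   `degraded`, `unreliable` flags.
#' @export
select_threshold <- function(corr, grid = seq(0.30, 0.95, by = 0.01),
                             min_eigs = 50L, alpha = 0.05,
                             bins = 20L, support = c(0, 3)) {
  stopifnot(inherits(corr, "corr_matrix"))
  if (!length(grid)) stop("empty threshold grid")
  if (is.unsorted(grid, strictly = TRUE)) stop("grid must strictly increase")
  r <- corr$r
  rows <- lapply(grid, function(s) {
    a <- r
    a[abs(a) < s] <- 0
    diag(a) <- 1
    keep <- rowSums(a != 0) > 1L          # has at least one off-diagonal entry
    n_surv <- sum(keep)
    if (n_surv < 3L)
      return(data.frame(threshold = s, n_nodes = n_surv,
                        chi2_poisson = NA_real_, chi2_goe = NA_real_,
                        p_poisson = NA_real_))
    # spectra too degenerate to unfold (e.g. a handful of identical
    # components) carry no usable spacing statistics at this threshold
    sp <- tryCatch(
      nnsd(eigen(a[keep, keep, drop = FALSE], symmetric = TRUE,
                 only.values = TRUE)$values,
           bins = bins, support = support),
      error = function(e) NULL)
    if (is.null(sp))
      return(data.frame(threshold = s, n_nodes = n_surv,
                        chi2_poisson = NA_real_, chi2_goe = NA_real_,
                        p_poisson = NA_real_))
    data.frame(threshold = s, n_nodes = n_surv,
               chi2_poisson = sp$chi2_poisson, chi2_goe = sp$chi2_goe,
               p_poisson = sp$p_poisson)
  })
  scan <- do.call(rbind, rows)

  eligible <- !is.na(scan$p_poisson) & scan$n_nodes >= min_eigs
  qualifies <- eligible & scan$p_poisson > alpha &
    scan$chi2_goe > scan$chi2_poisson
  degraded <- FALSE
  unreliable <- FALSE
  if (any(qualifies)) {
    sel <- scan$threshold[which(qualifies)[1L]]
  } else {
    degraded <- TRUE
    pool <- if (any(eligible)) which(eligible) else which(!is.na(scan$p_poisson))
    if (!length(pool)) {                  # nothing survives anywhere
      unreliable <- TRUE
      sel <- NA_real_
    } else {
      if (!any(eligible)) unreliable <- TRUE
      sel <- scan$threshold[pool[which.min(scan$chi2_poisson[pool])]]
    }
  }
  structure(list(scan = scan, selected_threshold = sel,
                 degraded = degraded, unreliable = unreliable,
                 min_eigs = min_eigs, alpha = alpha),
            class = "rmt_scan")
}

#' @export
print.rmt_scan <- function(x, ...) {
  cat("RMT threshold scan over", nrow(x$scan), "candidate cut-offs\n")
  if (is.na(x$selected_threshold)) {
    cat("no usable threshold: no candidate leaves a connected matrix\n")
  } else {
    cat(sprintf("selected threshold: %.2f%s\n", x$selected_threshold,
                if (x$degraded) " (degraded: Poisson fit never qualified)"
                else ""))
    if (x$unreliable)
      cat("warning: fewer than", x$min_eigs,
          "surviving taxa at every threshold; fit unreliable\n")
  }
  invisible(x)
}

#' Build the co-occurrence network at a threshold
#'
#' Nodes are taxa, weighted by mean relative abundance; an undirected edge
#' joins taxa `i`, `j` whenever `|r_ij| >= threshold`, carrying the signed
#' correlation as its `correlation` attribute.  Isolated taxa are removed.
#'
#' @param corr a `corr_matrix`.
#' @param threshold correlation cut-off in `(0, 1]`.
#' @param abundances named per-taxon abundance weights (e.g. mean relative
#'   abundance); missing taxa get weight 0.
#' @return an `igraph` graph with vertex attributes `name`, `abundance`
#'   and edge attribute `correlation`; the threshold is stored as a graph
#'   attribute.
#' @export
build_network <- function(corr, threshold, abundances = NULL) {
  stopifnot(inherits(corr, "corr_matrix"))
  if (is.na(threshold) || threshold <= 0 || threshold > 1)
    stop("threshold must lie in (0, 1]")
  r <- corr$r
  adj <- abs(r) >= threshold
  diag(adj) <- FALSE
  keep <- rowSums(adj) > 0
  adj <- adj[keep, keep, drop = FALSE]
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  el <- igraph::as_edgelist(g, names = TRUE)
  igraph::E(g)$correlation <- r[cbind(match(el[, 1L], rownames(r)),
                                      match(el[, 2L], rownames(r)))]
  ab <- rep(0, igraph::vcount(g))
  if (!is.null(abundances)) {
    hit <- match(igraph::V(g)$name, names(abundances))
    ab <- ifelse(is.na(hit), 0, abundances[hit])
  }
  igraph::V(g)$abundance <- as.numeric(ab)
  g <- igraph::set_graph_attr(g, "threshold", threshold)
  g
}

#' Fit a co-occurrence network to a community count table
#'
#' The one-stop fitting interface: prevalence-filters the counts, converts
#' to relative abundance, log-transforms, computes pairwise Pearson
#' correlations, selects the cut-off by the RMT spacing criterion (unless a
#' fixed `threshold` is given), builds the thresholded graph, detects
#' modules and classifies nodes in the Zi-Pi plane.
#'
#' @param table counts table (taxa x samples).
#' @param prevalence minimum detection fraction, see [prevalence_filter()];
#'   `NULL` skips the filter.
#' @param threshold fixed correlation cut-off; `NULL` (default) selects it
#'   automatically via [select_threshold()].
#' @param grid,min_eigs,alpha passed to [select_threshold()].
#' @param pseudocount_rule passed to [log_transform()].
#' @param seed seed for module detection tie-breaking.
#' @return object of class `conet`: the graph, the RMT scan, the
#'   correlation matrix, module partition, Zi-Pi table and topology
#'   summary, with `print`, `summary` and `plot` methods.
#' @examples
#' sim <- generate_counts(synthetic_design(n_taxa = 60, seed = 7))
#' fit <- conet(sim$counts)
#' fit
#' @export
conet <- function(table, prevalence = 1 / 3, threshold = NULL,
                  grid = seq(0.30, 0.95, by = 0.01), min_eigs = 50L,
                  alpha = 0.05, pseudocount_rule = "half_min_nonzero",
                  seed = NULL) {
  stopifnot_counts(table)
  filt <- if (is.null(prevalence)) table
          else prevalence_filter(table, prevalence)
  rel <- relative_abundance(filt)
  lg <- log_transform(rel, rule = pseudocount_rule)
  corr <- pearson_matrix(lg)
  scan <- NULL
  if (is.null(threshold)) {
    scan <- select_threshold(corr, grid = grid, min_eigs = min_eigs,
                             alpha = alpha)
    threshold <- scan$selected_threshold
  }
  if (is.na(threshold))
    stop("no usable correlation threshold: the matrix has no entries ",
         "above the scan grid")
  g <- build_network(corr, threshold, abundances = rowMeans(rel))
  mods <- if (igraph::vcount(g) > 0) detect_modules(g, seed = seed) else NULL
  zp <- if (!is.null(mods)) zipi(g, mods$membership) else NULL
  if (!is.null(mods)) {
    igraph::V(g)$module <- unname(mods$membership[igraph::V(g)$name])
    igraph::V(g)$Zi <- zp$Zi[match(igraph::V(g)$name, zp$node)]
    igraph::V(g)$Pi <- zp$Pi[match(igraph::V(g)$name, zp$node)]
  }
  structure(list(graph = g, scan = scan, correlation = corr,
                 threshold = threshold, modules = mods, zipi = zp,
                 topology = if (igraph::vcount(g) > 0) topology_summary(g)
                            else NULL,
                 n_taxa_in = nrow(table), n_taxa_filtered = nrow(filt),
                 call = match.call()),
            class = "conet")
}

#' @export
print.conet <- function(x, ...) {
  cat("Co-occurrence network (RMT-thresholded Pearson correlations)\n")
  cat(sprintf("  taxa: %d supplied, %d after prevalence filter\n",
              x$n_taxa_in, x$n_taxa_filtered))
  cat(sprintf("  threshold: %.2f%s\n", x$threshold,
              if (!is.null(x$scan) && x$scan$degraded) " (degraded scan)"
              else ""))
  if (is.null(x$topology)) {
    cat("  empty network: no correlations at or above the threshold\n")
  } else {
    t <- x$topology
    cat(sprintf("  nodes: %d  edges: %d  avg degree: %.2f  avg distance: %.2f\n",
                t$node_count, t$edge_count, t$average_degree,
                t$average_distance))
    if (!is.null(x$modules))
      cat(sprintf("  modules: %d (modularity %.3f); hubs: %d module, %d network\n",
                  x$modules$n_modules, x$modules$modularity,
                  sum(x$zipi$role == "module_hub"),
                  sum(x$zipi$role == "network_hub")))
  }
  invisible(x)
}

#' @export
summary.conet <- function(object, ...) {
  out <- list(topology = object$topology,
              threshold = object$threshold,
              degraded = !is.null(object$scan) && object$scan$degraded,
              modules = object$modules,
              role_counts = if (!is.null(object$zipi))
                table(object$zipi$role) else NULL)
  class(out) <- "summary.conet"
  out
}

#' @export
print.summary.conet <- function(x, ...) {
  cat("Threshold:", format(x$threshold), if (x$degraded) "(degraded)", "\n")
  if (is.null(x$topology)) { cat("Empty network\n"); return(invisible(x)) }
  t <- x$topology
  cat(sprintf(paste0("Nodes: %d\nEdges: %d\nAverage degree (2E/N): %.4f\n",
                     "Average distance: %.4f\nComponents: %d\n"),
              t$node_count, t$edge_count, t$average_degree,
              t$average_distance, t$n_components))
  if (!is.null(x$modules))
    cat(sprintf("Modules: %d, modularity %.4f\n",
                x$modules$n_modules, x$modules$modularity))
  if (!is.null(x$role_counts)) {
    cat("Node roles:\n")
    print(x$role_counts)
  }
  invisible(x)
}

#' Plot a fitted co-occurrence network
#'
#' Left panel: the network, nodes coloured by module and sized by
#' abundance, positive edges solid and negative dashed.  Right panel: the
#' Zi-Pi plane with the module-hub (`Zi > 2.5`) and connector (`Pi > 0.62`)
#' boundaries.
#'
#' @param x a `conet` fit.
#' @param which `"network"`, `"zipi"`, or `"both"`.
#' @param ... passed to [igraph::plot.igraph()].
#' @export
plot.conet <- function(x, which = c("both", "network", "zipi"), ...) {
  which <- match.arg(which)
  g <- x$graph
  if (igraph::vcount(g) == 0) stop("empty network; nothing to plot")
  if (which == "both") {
    op <- graphics::par(mfrow = c(1, 2))
    on.exit(graphics::par(op))
  }
  if (which %in% c("both", "network")) {
    mem <- if (!is.null(x$modules)) x$modules$membership[igraph::V(g)$name]
           else rep(1L, igraph::vcount(g))
    igraph::plot.igraph(
      g, vertex.size = 3 + 10 * sqrt(igraph::V(g)$abundance),
      vertex.label = NA, vertex.color = grDevices::rainbow(max(mem))[mem],
      edge.lty = ifelse(igraph::E(g)$correlation >= 0, 1, 2), ...)
  }
  if (which %in% c("both", "zipi") && !is.null(x$zipi)) {
    zp <- x$zipi
    graphics::plot(zp$Pi, zp$Zi, xlab = "Participation coefficient (Pi)",
                   ylab = "Within-module degree z-score (Zi)",
                   pch = 19, col = ifelse(zp$role == "peripheral", "grey50",
                                          "firebrick"),
                   xlim = c(0, 1))
    graphics::abline(h = 2.5, v = 0.62, lty = 3)
  }
  invisible(x)
}
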