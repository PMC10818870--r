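#' Topological summary of a network
#'
#' Node and edge counts, average degree `2E/N`, and average distance (mean
#' shortest-path length over connected node pairs; pairs split across
#' components are excluded and the component count is reported so the
#' convention is visible).
#'
#' @param net an `igraph` network.
#' @return list of class `topology_summary` with `node_count`,
#'   `edge_count`, `average_degree`, `average_distance`, `n_components`.
#' @export
topology_summary <- function(net) {
  n <- igraph::vcount(net)
  if (n == 0L) stop("empty network")
  e <- igraph::ecount(net)
  structure(list(
    node_count = n,
    edge_count = e,
    average_degree = 2 * e / n,
    average_distance = if (e > 0)
      igraph::mean_distance(net, directed = FALSE, unconnected = TRUE)
      else NA_real_,
    n_components = igraph::components(net)$no),
    class = "topology_summary")
}

#' @export
print.topology_summary <- function(x, ...) {
  cat(sprintf(paste0("nodes %d, edges %d, average degree %.2f, ",
                     "average distance %.2f (%d component%s)\n"),
              x$node_count, x$edge_count, x$average_degree,
              x$average_distance, x$n_components,
              if (x$n_components == 1L) "" else "s"))
  invisible(x)
}

#' Detect network modules by greedy modularity maximisation
#'
#' Fast-greedy agglomerative modularity optimisation on the unweighted
#' graph (deterministic; the `seed` argument is accepted for interface
#' stability and future stochastic methods).
#'
#' @param net an `igraph` network (simple, undirected).
#' @param seed unused by the deterministic greedy method.
#' @return list with `membership` (named integer vector), `modularity`,
#'   `n_modules`.
#' @export
detect_modules <- function(net, seed = NULL) {
  if (igraph::vcount(net) == 0L) stop("empty network")
  cl <- with_seed(seed, igraph::cluster_fast_greedy(
    net, weights = NULL, merges = FALSE, modularity = TRUE))
  mem <- igraph::membership(cl)
  list(membership = stats::setNames(as.integer(mem), igraph::V(net)$name),
       modularity = igraph::modularity(net, mem),
       n_modules = length(unique(mem)))
}

#' Zi-Pi classification of node roles
#'
#' `Zi` is the within-module degree z-score: how well connected node `i`
#' is inside its own module relative to that module's members (0 when the
#' module's within-degrees have zero spread).  `Pi` is the participation
#' coefficient `1 - sum_m (k_im / k_i)^2`: 0 when all links stay inside
#' one module, approaching 1 when links spread evenly across modules.
#' Roles use the molecular-ecological-network cut-offs: module hub
#' (`Zi > 2.5`, `Pi <= 0.62`), connector (`Pi > 0.62`, `Zi <= 2.5`),
#' network hub (both exceeded), else peripheral.
#'
#' @param net an `igraph` network.
#' @param membership named module assignment covering every node.
#' @param zi_cut,pi_cut role thresholds.
#' @return data.frame with `node`, `module`, `degree`, `Zi`, `Pi`, `role`.
#' @export
zipi <- function(net, membership, zi_cut = 2.5, pi_cut = 0.62) {
  nodes <- igraph::V(net)$name
  if (!all(nodes %in% names(membership)))
    stop("membership must cover every node")
  mem <- membership[nodes]
  adj <- igraph::as_adjacency_matrix(net, sparse = FALSE)
  k <- rowSums(adj)
  if (any(k == 0))
    stop("degree-0 node '", nodes[which(k == 0)[1L]],
         "'; remove isolated nodes first")
  mods <- sort(unique(mem))
  # k_im: links from each node into each module
  kim <- sapply(mods, function(m) rowSums(adj[, mem == m, drop = FALSE]))
  if (is.null(dim(kim))) kim <- matrix(kim, nrow = length(nodes))
  k_within <- kim[cbind(seq_along(nodes), match(mem, mods))]
  zi <- numeric(length(nodes))
  for (m in mods) {
    i <- mem == m
    mu <- mean(k_within[i])
    s <- stats::sd(k_within[i])
    zi[i] <- if (is.na(s) || s == 0) 0 else (k_within[i] - mu) / s
  }
  pi_ <- 1 - rowSums((kim / k)^2)
  role <- ifelse(zi > zi_cut & pi_ > pi_cut, "network_hub",
          ifelse(zi > zi_cut, "module_hub",
          ifelse(pi_ > pi_cut, "connector", "peripheral")))
  data.frame(node = nodes, module = as.integer(mem), degree = k,
             Zi = zi, Pi = pi_, role = role,
             row.names = NULL, stringsAsFactors = FALSE)
}
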