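# Fixtures built in code.

# A correlation matrix with planted exchangeable blocks over near-zero
# noise correlations, bypassing sampling: the idealised planted-partition
# input for threshold-selection tests.
make_block_corr <- function(n_taxa = 150, blocks = list(1:15, 16:30),
                            rho = 0.95, noise_sd = 0.02, seed = 1) {
  set.seed(seed)
  r <- matrix(stats::rnorm(n_taxa^2, 0, noise_sd), n_taxa)
  r <- (r + t(r)) / 2
  for (b in blocks)
    r[b, b] <- rho + matrix(stats::rnorm(length(b)^2, 0, noise_sd / 2),
                            length(b))
  r <- (r + t(r)) / 2
  r <- pmin(pmax(r, -0.999), 0.999)
  diag(r) <- 1
  dimnames(r) <- list(sprintf("T%03d", 1:n_taxa), sprintf("T%03d", 1:n_taxa))
  structure(list(r = r, taxon_ids = rownames(r),
                 zero_variance = character(), n_samples = NA_integer_),
            class = "corr_matrix")
}

# Small deterministic counts table.
toy_counts <- function() {
  m <- matrix(c(4, 6, 0,
                1, 9, 2,
                0, 0, 5), nrow = 3, byrow = TRUE,
              dimnames = list(paste0("ASV_", 1:3), paste0("S", 1:3)))
  abundance_table(m, kind = "counts")
}

edge_key <- function(a, b) paste(pmin(a, b), pmax(a, b))

graph_from_edges <- function(edges, n = NULL, names = NULL) {
  g <- igraph::graph_from_edgelist(edges, directed = FALSE)
  if (!is.null(n) && igraph::vcount(g) < n)
    g <- igraph::add_vertices(g, n - igraph::vcount(g))
  if (!is.null(names)) igraph::V(g)$name <- names
  igraph::E(g)$correlation <- rep(0.9, igraph::ecount(g))
  igraph::V(g)$abundance <- rep(1 / igraph::vcount(g), igraph::vcount(g))
  g
}
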