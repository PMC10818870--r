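test_that("pearson matrix handles duplicates, negation and zero variance", {
  x <- rnorm(10)
  m <- rbind(a = x, b = x, c = 2 * mean(x) - x, flat = rep(1, 10))
  colnames(m) <- paste0("s", 1:10)
  pm <- pearson_matrix(m)
  expect_equal(pm$r["a", "b"], 1)
  expect_equal(pm$r["a", "c"], -1)
  expect_identical(pm$zero_variance, "flat")
  expect_true(all(pm$r["flat", c("a", "b", "c")] == 0))
  expect_equal(diag(pm$r), setNames(rep(1, 4), rownames(m)))
  expect_error(pearson_matrix(m[, 1:2]), "3 samples")
})

test_that("pearson matrix is invariant under positive affine rescaling", {
  set.seed(4)
  m <- matrix(rnorm(50), 5, 10,
              dimnames = list(paste0("t", 1:5), paste0("s", 1:10)))
  r1 <- pearson_matrix(m)$r
  r2 <- pearson_matrix(m * runif(5, 0.5, 3) + rnorm(5))$r
  expect_equal(r1, r2, tolerance = 1e-12)
})

test_that("independent rows correlate weakly at large n", {
  set.seed(5)
  m <- matrix(rnorm(2000), 2, 1000,
              dimnames = list(c("a", "b"), paste0("s", 1:1000)))
  expect_lt(abs(pearson_matrix(m)$r["a", "b"]), 0.1)
})

test_that("nnsd separates Poisson from GOE spacing statistics", {
  set.seed(1)
  n <- 300
  a <- matrix(rnorm(n * n), n)
  goe <- (a + t(a)) / sqrt(2 * n)
  s_goe <- nnsd(eigen(goe, symmetric = TRUE, only.values = TRUE)$values)
  expect_gt(s_goe$chi2_poisson, s_goe$chi2_goe)

  s_pois <- nnsd(sort(runif(n)))   # iid levels: Poisson spacings
  expect_gt(s_pois$chi2_goe, s_pois$chi2_poisson)

  expect_equal(mean(s_goe$spacings), 1, tolerance = 1e-9)
  expect_equal(mean(s_pois$spacings), 1, tolerance = 1e-9)
  expect_error(nnsd(c(1, 2)), "3 eigenvalues")
})

test_that("threshold scan flags degenerate input and stays monotone", {
  r <- diag(10)
  dimnames(r) <- list(paste0("t", 1:10), paste0("t", 1:10))
  corr <- structure(list(r = r, taxon_ids = rownames(r),
                         zero_variance = character(), n_samples = 24L),
                    class = "corr_matrix")
  scan <- select_threshold(corr)
  expect_true(scan$degraded)
  expect_true(scan$unreliable)
  expect_true(is.na(scan$selected_threshold))
  expect_error(select_threshold(corr, grid = numeric()), "grid")
})

test_that("threshold scan recovers an idealised planted partition", {
  # two planted blocks at r ~ 0.95 over noise correlations ~ 0
  corr <- make_block_corr(n_taxa = 150, blocks = list(1:15, 16:30),
                          rho = 0.95, noise_sd = 0.02, seed = 1)
  scan <- select_threshold(corr, min_eigs = 20L)
  # with noise ~ 0 the very first grid point can already qualify
  expect_gte(scan$selected_threshold, 0.30)
  expect_lte(scan$selected_threshold, 0.95)
  expect_true(all(diff(scan$scan$n_nodes) <= 0))   # survivors non-increasing

  net <- build_network(corr, scan$selected_threshold)
  el <- igraph::as_edgelist(net)
  blk <- rep(0L, 150)
  blk[1:15] <- 1L; blk[16:30] <- 2L
  names(blk) <- corr$taxon_ids
  within <- blk[el[, 1]] > 0 & blk[el[, 1]] == blk[el[, 2]]
  expect_gte(mean(within), 0.95)
})

test_that("build_network applies the absolute threshold and drops isolates", {
  r <- diag(3)
  dimnames(r) <- list(c("a", "b", "c"), c("a", "b", "c"))
  r["a", "b"] <- r["b", "a"] <- 0.9
  r["a", "c"] <- r["c", "a"] <- 0.2
  corr <- structure(list(r = r, taxon_ids = rownames(r),
                         zero_variance = character(), n_samples = 10L),
                    class = "corr_matrix")
  g <- build_network(corr, 0.8, abundances = c(a = 0.5, b = 0.3, c = 0.2))
  expect_setequal(igraph::V(g)$name, c("a", "b"))
  expect_equal(igraph::ecount(g), 1L)
  expect_equal(igraph::E(g)$correlation, 0.9)
  expect_equal(igraph::V(g)$abundance[match("a", igraph::V(g)$name)], 0.5)

  expect_equal(igraph::vcount(build_network(corr, 1)), 0L)
  expect_error(build_network(corr, 0), "threshold")
})

test_that("edge set is reproducible from the stored threshold and matrix", {
  corr <- make_block_corr(n_taxa = 40, blocks = list(1:6), rho = 0.9,
                          noise_sd = 0.1, seed = 3)
  g1 <- build_network(corr, 0.5)
  g2 <- build_network(corr, 0.5)
  expect_identical(igraph::as_edgelist(g1), igraph::as_edgelist(g2))
  n_above <- sum(abs(corr$r[upper.tri(corr$r)]) >= 0.5)
  expect_equal(igraph::ecount(g1), n_above)
})

test_that("pure-noise tables give near-empty networks", {
  hits <- sapply(1:10, function(s) {
    set.seed(s)
    m <- matrix(rnorm(50 * 100), 50, 100,
                dimnames = list(sprintf("t%02d", 1:50), sprintf("s%03d", 1:100)))
    corr <- pearson_matrix(m)
    scan <- select_threshold(corr, min_eigs = 20L)
    if (is.na(scan$selected_threshold)) return(TRUE)
    g <- build_network(corr, scan$selected_threshold)
    igraph::ecount(g) / choose(50, 2) <= 0.02
  })
  expect_gte(mean(hits), 0.95)
})

test_that("conet returns a classed fit with topology and roles", {
  sim <- generate_counts(synthetic_design(n_taxa = 60, n_blocks = 2,
                                          block_size = 8, seed = 2))
  fit <- conet(sim$counts)
  expect_s3_class(fit, "conet")
  expect_s3_class(fit$scan, "rmt_scan")
  expect_true(igraph::vcount(fit$graph) > 0)
  expect_equal(fit$topology$average_degree,
               2 * fit$topology$edge_count / fit$topology$node_count)
  expect_output(print(fit), "threshold")
  expect_output(print(summary(fit)), "Average degree")
})
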