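k_named <- function(n, prefix = "v") {
  g <- igraph::make_full_graph(n)
  igraph::V(g)$name <- paste0(prefix, seq_len(n))
  g
}

test_that("random removal on a complete graph has no cascade", {
  rob <- robustness_random(k_named(10), fraction = 0.5, replicates = 30,
                           seed = 1)
  expect_true(all(rob$values == 0.5))
})

test_that("cascade-off robustness equals one minus the removal fraction", {
  for (g in list(k_named(10), igraph::make_ring(12),
                 with_seed(2, igraph::sample_gnm(20, 30)))) {
    rob <- robustness_random(g, fraction = 0.5, replicates = 10,
                             cascade = "none", seed = 3)
    expect_true(all(rob$values == 1 - 0.5))
  }
})

test_that("cascades only ever remove nodes", {
  set.seed(9)
  for (i in 1:5) {
    g <- igraph::sample_gnm(15, 18)
    g <- igraph::delete_vertices(g, which(igraph::degree(g) == 0))
    a <- robustness_random(g, 0.4, replicates = 50, cascade = "none",
                           seed = i)
    b <- robustness_random(g, 0.4, replicates = 50, cascade = "degree_zero",
                           seed = i)
    expect_true(all(b$values <= a$values + 1e-12))
  }
})

test_that("Monte-Carlo robustness matches the exhaustive oracle on P6", {
  p6 <- igraph::make_ring(6, circular = FALSE)
  igraph::V(p6)$name <- paste0("p", 1:6)
  adj <- igraph::as_adjacency_matrix(p6, sparse = FALSE)
  exact <- oracle_robustness_exhaustive(adj, 3, "degree_zero")
  mc <- robustness_random(p6, fraction = 0.5, replicates = 4000, seed = 11)
  se <- mc$sd / sqrt(length(mc$values))
  expect_lt(abs(mc$mean - exact), 3 * se + 1e-9)
})

test_that("targeted hub removal traces cascades exactly", {
  # star: removing the hub extinguishes every leaf
  star <- igraph::make_star(10, mode = "undirected", center = 1)
  igraph::V(star)$name <- c("hub", paste0("leaf", 1:9))
  mem <- setNames(rep(1L, 10), igraph::V(star)$name)
  zp <- zipi(star, mem)
  rob <- suppressWarnings(robustness_targeted(star, zp, n_hubs = 1))
  expect_equal(rob$values, 0)
  expect_identical(rob$removed_nodes, "hub")

  # two 4-cliques joined through a cut node: removing it spares both cliques
  el <- rbind(t(combn(paste0("a", 1:4), 2)), t(combn(paste0("b", 1:4), 2)),
              c("cut", "a1"), c("cut", "b1"))
  g <- igraph::graph_from_edgelist(el, directed = FALSE)
  zp2 <- data.frame(node = igraph::V(g)$name,
                    module = 1L, degree = igraph::degree(g),
                    Zi = ifelse(igraph::V(g)$name == "cut", 3, 0),
                    Pi = 0, role = ifelse(igraph::V(g)$name == "cut",
                                          "module_hub", "peripheral"))
  rob2 <- robustness_targeted(g, zp2, n_hubs = 1)
  expect_equal(rob2$values, 8 / 9)
  expect_false(rob2$fallback)

  # deterministic ranking: Zi desc, then Pi asc, then id
  zp3 <- zp2
  zp3$role <- "module_hub"
  zp3$Zi <- 1; zp3$Pi <- 0.1
  r_a <- robustness_targeted(g, zp3, n_hubs = 2)
  r_b <- robustness_targeted(g, zp3, n_hubs = 2)
  expect_identical(r_a$removed_nodes, r_b$removed_nodes)
  expect_identical(r_a$removed_nodes, c("a1", "a2"))
})

test_that("connectedness corrects perfectly correlated pairs to ~1", {
  set.seed(21)
  base <- runif(30, 0.5, 1.5)
  m <- rbind(t1 = base, t2 = base * 2,         # perfectly correlated pair
             t3 = runif(30), t4 = runif(30), t5 = runif(30))
  colnames(m) <- paste0("s", 1:30)
  rel <- relative_abundance(abundance_table(m, "counts"))
  conn <- connectedness(rel, null_reps = 100, seed = 1)
  # the pair's corrected correlation dominates its c_plus
  expect_gt(conn$c_plus[conn$taxon == "t1"], 0.4)
  expect_true(all(conn$c_plus >= 0))
  expect_true(all(conn$c_minus <= 0))
})

test_that("connectedness vanishes for independent taxa as n grows", {
  mean_abs_c <- function(n, s) {
    set.seed(s)
    m <- matrix(rexp(20 * n), 20, n,
                dimnames = list(sprintf("t%02d", 1:20), sprintf("s%03d", 1:n)))
    rel <- relative_abundance(abundance_table(m, "counts"))
    conn <- connectedness(rel, null_reps = 100, seed = s)
    c(abs_c = mean(abs(c(conn$c_plus, conn$c_minus))),
      net = mean(conn$c_plus + conn$c_minus))
  }
  lo <- rowMeans(sapply(1:3, function(s) mean_abs_c(25, s)))
  hi <- rowMeans(sapply(1:3, function(s) mean_abs_c(400, s)))
  # per-sign magnitudes shrink at the 1/sqrt(n) sampling rate ...
  expect_lt(hi["abs_c"], lo["abs_c"] / 2)
  expect_lt(hi["abs_c"], 0.05)
  # ... while the net connectedness is centred at zero throughout
  expect_lt(abs(lo["net"]), 0.05)
  expect_lt(abs(hi["net"]), 0.05)
})

test_that("cohesion is the abundance-weighted connectedness", {
  rel <- relative_abundance(toy_counts())
  conn <- data.frame(taxon = rownames(rel), c_plus = c(0.3, 0.3, 0.3),
                     c_minus = c(-0.1, -0.1, -0.1))
  coh <- cohesion(rel, conn)
  # constant connectedness: cohesion equals that constant in every sample
  expect_equal(coh$cohesion_pos, rep(0.3, 3))
  expect_equal(coh$cohesion_neg, rep(-0.1, 3))

  # all abundance on one taxon: cohesion is that taxon's connectedness
  one <- abundance_table(matrix(c(0, 1, 0), 3, 1,
                                dimnames = list(rownames(rel), "s")),
                         "relative")
  conn2 <- data.frame(taxon = rownames(rel), c_plus = c(0.1, 0.7, 0.2),
                      c_minus = c(-0.2, -0.05, 0))
  expect_equal(cohesion(one, conn2)$cohesion_pos, 0.7)

  # linear in abundance: mixing samples mixes cohesions with same weights
  mix <- 0.3 * rel[, 1] + 0.7 * rel[, 2]
  mtab <- abundance_table(cbind(mix = mix), "relative")
  cm <- cohesion(mtab, conn2)
  c12 <- cohesion(rel, conn2)
  expect_equal(cm$cohesion_pos,
               0.3 * c12$cohesion_pos[1] + 0.7 * c12$cohesion_pos[2])

  expect_error(cohesion(rel[1:2, ], conn2), "differ")
})

test_that("stability comparison is a two-sided Student t", {
  r <- compare_stability(c(1, 2, 3), c(4, 5, 6))
  expect_equal(r$t, -3.674, tolerance = 1e-3)
  expect_equal(r$p, 0.02131, tolerance = 1e-3)
  swapped <- compare_stability(c(4, 5, 6), c(1, 2, 3))
  expect_equal(swapped$t, -r$t)
  expect_equal(swapped$p, r$p)
  same <- compare_stability(c(1, 1, 1), c(1, 1, 1))
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)
})
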