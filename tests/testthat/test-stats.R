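test_that("exact Wilcoxon branch matches enumeration for small layouts", {
  m <- matrix(c(1, 2, 3, 4), 1, dimnames = list("f", paste0("s", 1:4)))
  res <- wilcoxon_fdr(m, c("A", "A", "B", "B"))
  expect_equal(res$p, 1 / 3)                    # 2/6 by enumeration

  # tie-free layouts agree with wilcox.test's exact branch
  set.seed(31)
  for (i in 1:5) {
    n1 <- sample(2:5, 1); n2 <- sample(2:5, 1)
    x <- rnorm(n1); y <- rnorm(n2)
    mm <- matrix(c(x, y), 1,
                 dimnames = list("f", paste0("s", seq_len(n1 + n2))))
    p_pkg <- wilcoxon_fdr(mm, rep(c("A", "B"), c(n1, n2)))$p
    p_ref <- wilcox.test(x, y, exact = TRUE)$p.value
    expect_equal(p_pkg, p_ref, tolerance = 1e-12)
  }

  # tied layouts agree with the independent tail-counting oracle
  set.seed(32)
  for (i in 1:5) {
    n1 <- sample(2:5, 1); n2 <- sample(2:5, 1)
    x <- sample(1:3, n1, replace = TRUE); y <- sample(1:3, n2, replace = TRUE)
    if (var(c(x, y)) == 0) next
    mm <- matrix(c(x, y), 1,
                 dimnames = list("f", paste0("s", seq_len(n1 + n2))))
    expect_equal(wilcoxon_fdr(mm, rep(c("A", "B"), c(n1, n2)))$p,
                 oracle_wilcoxon_p(x, y), tolerance = 1e-12)
  }
})

test_that("degenerate and single-feature Wilcoxon cases behave", {
  m <- matrix(rep(2, 8), 1, dimnames = list("flat", paste0("s", 1:8)))
  expect_equal(wilcoxon_fdr(m, rep(c("A", "B"), each = 4))$p, 1)
  m2 <- matrix(c(1, 2, 5, 6, 7, 8), 1,
               dimnames = list("f", paste0("s", 1:6)))
  res <- wilcoxon_fdr(m2, rep(c("A", "B"), each = 3))
  expect_equal(res$padj, res$p)                 # m = 1: BH is the identity
  expect_error(wilcoxon_fdr(m2, rep("A", 6)), "two groups")
})

test_that("large-sample Wilcoxon branch uses the corrected normal approx", {
  set.seed(33)
  x <- rnorm(12); y <- rnorm(12) + 1
  m <- matrix(c(x, y), 1, dimnames = list("f", paste0("s", 1:24)))
  p_pkg <- wilcoxon_fdr(m, rep(c("A", "B"), each = 12))$p
  p_ref <- wilcox.test(x, y, exact = FALSE, correct = TRUE)$p.value
  expect_equal(p_pkg, p_ref)
})

test_that("BH adjustment matches the step-up arithmetic", {
  expect_equal(bh_adjust(c(0.01, 0.04, 0.03)), c(0.03, 0.04, 0.04))
  expect_equal(bh_adjust(rep(0.2, 5)), rep(0.2, 5))
  set.seed(34)
  p <- runif(50)^2
  adj <- bh_adjust(p)
  expect_true(all(adj <= 1))
  expect_true(all(adj >= p))
  expect_false(is.unsorted(adj[order(p)]))      # monotone w.r.t. raw p order
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("Spearman screen matches the d^2 arithmetic and gates", {
  m <- rbind(up = 1:5, down = 5:1, ex = c(1, 3, 2, 5, 4))
  colnames(m) <- paste0("s", 1:5)
  res <- spearman_screen(m, c(1, 2, 3, 4, 5), min_prevalence = 0)
  expect_equal(res$rho[res$feature == "up"], 1)
  expect_equal(res$rho[res$feature == "down"], -1)
  expect_equal(res$rho[res$feature == "ex"], 0.8)
  tt <- 0.8 * sqrt(3 / (1 - 0.64))
  expect_equal(res$p[res$feature == "ex"], 2 * pt(-tt, 3))

  # constant features are flagged NA and leave the BH family
  m2 <- rbind(m, flat = rep(1, 5))
  res2 <- spearman_screen(m2, c(1, 2, 3, 4, 5), min_prevalence = 0)
  expect_true(is.na(res2$p[res2$feature == "flat"]))
  expect_false(anyNA(res2$p[res2$feature != "flat"]))

  # prevalence gate and pairwise-complete filtering
  m3 <- rbind(rare = c(1, 0, 0, 0, 0), common = c(5, 4, 3, 2, 1))
  colnames(m3) <- paste0("s", 1:5)
  res3 <- spearman_screen(m3, c(1, 2, 3, 4, NA), min_prevalence = 0.5)
  expect_identical(res3$feature, "common")
  expect_equal(res3$n_used, 4)
  expect_error(spearman_screen(m3[, 1:3], c(1, NA, 2)), "4 paired")
})

test_that("Bray-Curtis matches the worked examples and its bounds", {
  a <- matrix(c(1, 1, 1, 3), 2, dimnames = list(c("t1", "t2"), c("A", "B")))
  expect_equal(bray_curtis(a)["A", "B"], 1 / 3)

  ident <- matrix(c(2, 3, 2, 3), 2,
                  dimnames = list(c("t1", "t2"), c("A", "B")))
  expect_equal(bray_curtis(ident)["A", "B"], 0)

  disj <- matrix(c(4, 0, 0, 7), 2,
                 dimnames = list(c("t1", "t2"), c("A", "B")))
  expect_equal(bray_curtis(disj)["A", "B"], 1)

  set.seed(35)
  m <- matrix(rpois(60, 8), 6, 10,
              dimnames = list(paste0("t", 1:6), paste0("s", 1:10)))
  bc <- bray_curtis(m)
  expect_true(all(bc >= 0 & bc <= 1))
  expect_equal(bc, t(bc))
  expect_true(all(diag(bc) == 0))

  zz <- matrix(c(0, 0, 0, 0, 1, 2), 3,
               dimnames = list(paste0("t", 1:3), c("z1", "z2")))
  expect_error(bray_curtis(cbind(zz, zz)[, c(1, 3)]), "all-zero")
})

test_that("PERMANOVA agrees with vegan and the exhaustive oracle", {
  set.seed(36)
  m <- matrix(rpois(8 * 12, 10), 8, 12,
              dimnames = list(paste0("t", 1:8), paste0("s", 1:12)))
  g <- rep(c("A", "B"), each = 6)
  bc <- bray_curtis(m)
  fit <- permanova(bc, g, permutations = 99, seed = 1)
  ref <- vegan::adonis2(as.dist(bc) ~ g, permutations = 99)
  expect_equal(fit$F, ref$F[1], tolerance = 1e-10)

  # exhaustive branch at n = 3 + 3 equals full-enumeration oracle
  d6 <- bc[1:6, 1:6]
  g6 <- rep(c("A", "B"), each = 3)
  ex <- permanova(d6, g6, permutations = "exhaustive")
  expect_equal(ex$p, oracle_permanova_exhaustive_p(d6, g6), tolerance = 1e-12)
  expect_equal(ex$permutations, choose(6, 3))

  # two well-separated clusters reach the minimum attainable p (n large
  # enough that random permutations essentially never recreate the split)
  n <- 20
  sep <- matrix(10, n, n, dimnames = list(paste0("x", 1:n), paste0("x", 1:n)))
  sep[1:10, 1:10] <- 0.1
  sep[11:20, 11:20] <- 0.1
  diag(sep) <- 0
  ps <- permanova(sep, rep(c("A", "B"), each = 10), permutations = 199,
                  seed = 2)
  expect_equal(ps$p, 1 / 200)

  expect_error(permanova(bc, c("A", rep("B", 11))), "singleton")
})

test_that("PERMANOVA p-values are calibrated under the null", {
  # exchangeable distances, random labels: p near-uniform on its
  # (discrete) support
  ps <- sapply(1:60, function(s) {
    set.seed(s)
    m <- matrix(rexp(6 * 12), 6, 12,
                dimnames = list(paste0("t", 1:6), paste0("s", 1:12)))
    permanova(bray_curtis(m), rep(c("A", "B"), each = 6),
              permutations = 199, seed = s)$p
  })
  expect_gt(mean(ps), 0.35)
  expect_lt(mean(ps), 0.65)
  expect_lte(mean(ps <= 0.1), 0.25)  # no inflation of small p
})

test_that("pseudo-F is invariant under consistent relabeling", {
  set.seed(37)
  m <- matrix(rpois(50, 6), 5, 10,
              dimnames = list(paste0("t", 1:5), paste0("s", 1:10)))
  bc <- bray_curtis(m)
  g <- rep(c("A", "B"), each = 5)
  perm <- sample(10)
  f1 <- permanova(bc, g, permutations = 9, seed = 1)$F
  f2 <- permanova(bc[perm, perm], g[perm], permutations = 9, seed = 1)$F
  expect_equal(f1, f2, tolerance = 1e-12)
})
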