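test_that("pairwise beta partition follows the Sorensen family formulas", {
  same <- beta_pairwise(c("x", "y", "z"), c("x", "y", "z"))
  expect_equal(unlist(same[1, 1:3]), c(beta_sor = 0, beta_sim = 0,
                                       beta_sne = 0))
  nested <- beta_pairwise(c(1, 2, 3), c(1, 2))
  expect_equal(nested$beta_sor, 0.2)
  expect_equal(nested$beta_sim, 0)
  expect_equal(nested$beta_sne, 0.2)
  disjoint <- beta_pairwise(c("a", "b"), c("c", "d"))
  expect_equal(unlist(disjoint[1, 1:3]), c(beta_sor = 1, beta_sim = 1,
                                           beta_sne = 0))
  expect_error(beta_pairwise(character(), character()), "empty")
})

test_that("multisite partition reduces to pairwise and matches brute force", {
  ident <- rbind(a = c(1, 1, 0), b = c(1, 1, 0))
  expect_equal(unlist(beta_multisite(ident)[1, 1:3]),
               c(beta_sor = 0, beta_sim = 0, beta_sne = 0))
  expect_error(beta_multisite(matrix(0, 3, 4)), "all-zero")
  set.seed(101)
  for (r in 1:50) {
    m <- random_pa(sample(2:8, 1), sample(5:40, 1))
    got <- beta_multisite(m)
    ref <- brute_beta_multisite(m)
    expect_equal(got$beta_sor, unname(ref["beta_sor"]), tolerance = 1e-12)
    expect_equal(got$beta_sim, unname(ref["beta_sim"]), tolerance = 1e-12)
    # 2-site case equals the pairwise partition exactly
    m2 <- m[sample(nrow(m), 2), , drop = FALSE]
    if (sum(m2) > 0) {
      bp <- beta_pairwise(which(m2[1, ] == 1), which(m2[2, ] == 1))
      bm <- beta_multisite(m2)
      expect_equal(bm$beta_sor, bp$beta_sor, tolerance = 1e-12)
      expect_equal(bm$beta_sim, bp$beta_sim, tolerance = 1e-12)
      expect_equal(bm$beta_sne, bp$beta_sne, tolerance = 1e-12)
    }
  }
})

test_that("Jaccard dissimilarity matches vegan and its own arithmetic", {
  m <- rbind(g1 = c(1, 1, 1), g2 = c(1, 1, 0))
  d <- jaccard_matrix(m)
  expect_equal(d["g1", "g2"], 1 - 2 / 3)
  expect_equal(diag(d), c(g1 = 0, g2 = 0))
  expect_error(jaccard_matrix(rbind(c(1, 2), c(0, 1))), "binary")
  expect_warning(d0 <- jaccard_matrix(rbind(a = c(0, 0), b = c(0, 0),
                                            c = c(1, 0))), "empty rows")
  expect_equal(d0["a", "b"], 0)
  set.seed(7)
  pa <- random_pa(10, 25)
  expect_equal(jaccard_matrix(pa),
               as.matrix(vegan::vegdist(pa, "jaccard")),
               tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("PCoA reproduces Euclidean geometry and flags bad input", {
  set.seed(5)
  pts <- matrix(rnorm(21), 7, 3)
  D <- as.matrix(dist(pts))
  rownames(D) <- colnames(D) <- paste0("p", 1:7)
  pc <- pcoa(D)
  rec <- as.matrix(dist(as.matrix(pc$points[, -1])))
  expect_lt(max(abs(rec - D)), 1e-8)
  # two points one unit apart sit at +/- 0.5 on axis 1
  D2 <- matrix(c(0, 1, 1, 0), 2, dimnames = list(c("a", "b"),
                                                 c("a", "b")))
  pc2 <- pcoa(D2)
  expect_equal(sort(pc2$points$Axis1), c(-0.5, 0.5))
  # zero matrix: no positive eigenvalues
  Dz <- matrix(0, 3, 3, dimnames = list(letters[1:3], letters[1:3]))
  expect_equal(max(abs(pcoa(Dz)$eigenvalues)), 0)
  expect_error(pcoa(matrix(c(0, 1, 2, 0), 2)), "symmetric")
  # eigenvalues agree with the ape implementation
  pa <- random_pa(8, 30)
  Dj <- jaccard_matrix(pa)
  ref <- ape::pcoa(stats::as.dist(Dj))
  k <- length(ref$values$Eigenvalues)
  expect_equal(pcoa(Dj)$eigenvalues[seq_len(k)], ref$values$Eigenvalues,
               tolerance = 1e-9)
})

test_that("cophenetic distances are path sums over the tree", {
  expect_equal(cophenetic_distances("(A:1,B:1);")["A", "B"], 2)
  d <- cophenetic_distances("((A:1,B:1):1,C:2);")
  expect_equal(d["A", "C"], 4)
  expect_equal(unname(diag(d)), rep(0, 3))
  expect_error(cophenetic_distances("((A,B),C);"), "branch length")
})

test_that("Mantel statistic and permutation p behave correctly", {
  set.seed(11)
  pts <- matrix(rnorm(20), 10, 2)
  D1 <- as.matrix(dist(pts))
  rownames(D1) <- colnames(D1) <- paste0("t", 1:10)
  mt <- mantel_test(D1, D1, n_perm = 99, seed = 1)
  expect_equal(mt$r, 1)
  expect_lte(mt$p, 0.05)
  # r equals the vegan Mantel statistic
  D2 <- as.matrix(dist(rnorm(10))); dimnames(D2) <- dimnames(D1)
  mt2 <- mantel_test(D1, D2, n_perm = 99, seed = 1)
  ref <- vegan::mantel(stats::as.dist(D1), stats::as.dist(D2),
                       permutations = 9)
  expect_equal(mt2$r, unname(ref$statistic), tolerance = 1e-12)
  # deterministic given seed
  expect_identical(mt2$p, mantel_test(D1, D2, n_perm = 99, seed = 1)$p)
  bad <- D2; rownames(bad) <- colnames(bad) <- paste0("x", 1:10)
  expect_error(mantel_test(D1, bad), "labels")
  expect_error(mantel_test(D1[1:2, 1:2], D2[1:2, 1:2]), "at least 3")
})

test_that("Mantel p matches exhaustive enumeration at n = 5", {
  set.seed(13)
  D1 <- as.matrix(dist(rnorm(5))); rownames(D1) <- colnames(D1) <- letters[1:5]
  D2 <- as.matrix(dist(rnorm(5))); dimnames(D2) <- dimnames(D1)
  v1 <- D1[upper.tri(D1)]
  r_obs <- cor(v1, D2[upper.tri(D2)])
  perms <- rbind(1:5)
  all_p <- as.matrix(expand.grid(rep(list(1:5), 5)))
  all_p <- all_p[apply(all_p, 1, function(x) length(unique(x)) == 5), ]
  r_all <- apply(all_p, 1, function(p) {
    Dp <- D2[p, p]; cor(v1, Dp[upper.tri(Dp)])
  })
  exact_p <- mean(r_all >= r_obs - 1e-12)
  mt <- mantel_test(D1, D2, n_perm = 999, seed = 3)
  expect_lt(abs(mt$p - exact_p), 0.05)
})

test_that("PERMANOVA equals classical regression on Euclidean distances", {
  set.seed(19)
  n <- 18
  x <- rnorm(n); z <- rnorm(n)
  y <- 0.8 * x + rnorm(n)
  D <- as.matrix(dist(y)); rownames(D) <- colnames(D) <- paste0("s", 1:n)
  fit <- permanova(D, data.frame(x = x, z = z), n_perm = 99, seed = 1)
  ref <- anova(lm(y ~ x + z))
  expect_equal(fit$f, ref$`F value`[1:2], tolerance = 1e-8,
               ignore_attr = TRUE)
  expect_equal(sum(fit$r2) + fit$r2_res, 1, tolerance = 1e-9)
  # sequential SS match vegan adonis2 on a non-Euclidean matrix
  pa <- random_pa(12, 30)
  Dj <- jaccard_matrix(pa)
  x1 <- rnorm(12); x2 <- rnorm(12)
  ours <- permanova(Dj, data.frame(pc1 = x1, pc2 = x2), n_perm = 49,
                    seed = 2)
  ref2 <- vegan::adonis2(stats::as.dist(Dj) ~ pc1 + pc2,
                         data = data.frame(pc1 = x1, pc2 = x2),
                         permutations = 9, by = "terms")
  expect_equal(ours$f, ref2$F[1:2], tolerance = 1e-9, ignore_attr = TRUE)
  expect_equal(ours$r2, ref2$R2[1:2], tolerance = 1e-9, ignore_attr = TRUE)
  expect_error(permanova(Dj, data.frame(a = x1, b = 2 * x1)), "collinear")
})

test_that("phylogenetic PCs select k by the cumulative-variance rule", {
  # rank-1 distance pattern: distances from collinear points
  pts <- seq(0, 1, length.out = 6)
  D <- as.matrix(dist(pts)); rownames(D) <- colnames(D) <- paste0("t", 1:6)
  pp <- phylo_pcs(D, var_threshold = 0.8)
  expect_equal(pp$k, 1L)
  expect_gte(pp$var_frac[1], 0.8)
  expect_equal(phylo_pcs(D, var_threshold = 0)$k, 1L)
  # variance fractions are non-increasing and sum to 1
  pa <- random_pa(9, 20)
  pp2 <- phylo_pcs(jaccard_matrix(pa))
  expect_true(all(diff(pp2$var_frac) <= 1e-12))
  expect_equal(sum(pp2$var_frac), 1, tolerance = 1e-9)
  expect_gte(sum(pp2$var_frac[seq_len(pp2$k)]), 0.8)
})

test_that("partial F-test matches its closed form and limits", {
  set.seed(1)
  x <- rnorm(40); y <- 2 * x + rnorm(40)
  df <- data.frame(y = y, x = x, w = rnorm(40))
  got <- partial_f_test(df, "y", "x", covariates = "w")
  # independent matrix-algebra computation
  X0 <- cbind(1, df$w); X1 <- cbind(1, df$w, df$x)
  r0 <- y - X0 %*% solve(crossprod(X0), crossprod(X0, y))
  r1 <- y - X1 %*% solve(crossprod(X1), crossprod(X1, y))
  f_ref <- ((sum(r0^2) - sum(r1^2)) / 1) / (sum(r1^2) / (40 - 3))
  expect_equal(got$statistic, f_ref, tolerance = 1e-9)
  # exact linear response: unbounded F, p -> 0
  exact <- data.frame(y = 3 * x, x = x)
  res <- partial_f_test(exact, "y", "x")
  expect_equal(res$statistic, Inf)
  expect_equal(res$p.value, 0)
  # predictor orthogonal to the response residuals: F is exactly zero
  yy <- rnorm(40)
  q <- stats::residuals(lm(rnorm(40) ~ yy))
  res2 <- partial_f_test(data.frame(y = yy, q = q), "y", "q")
  expect_lt(res2$statistic, 1e-10)
})
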