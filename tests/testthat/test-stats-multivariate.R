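rand_dist <- function(n, p = 6, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  x <- matrix(rexp(n * p), n, p)
  rownames(x) <- paste0("s", seq_len(n))
  bray_curtis(x)
}

test_that("Bray-Curtis matches hand calculations and vegan", {
  expect_equal(bray_curtis(rbind(a = c(1, 0), b = c(0, 1)))["a", "b"], 1)
  expect_equal(bray_curtis(rbind(a = c(3, 4), b = c(3, 4)))["a", "b"], 0)
  expect_equal(bray_curtis(rbind(a = c(6, 2), b = c(2, 2)))["a", "b"],
               1 / 3, tolerance = 1e-12)
  set.seed(61)
  x <- matrix(rexp(8 * 12), 8, 12)
  rownames(x) <- paste0("s", 1:8)
  expect_equal(bray_curtis(x),
               as.matrix(vegan::vegdist(x, method = "bray")),
               tolerance = 1e-12, ignore_attr = TRUE)
  expect_error(bray_curtis(rbind(a = c(1, 1), b = c(0, 0))), "all-zero")
})

test_that("MRPP separates planted groups and matches vegan's delta", {
  d <- rand_dist(10, seed = 62)
  g <- rep(c("a", "b"), each = 5)
  res <- mrpp(d, g, n_perm = 499, seed = 1)
  ref <- vegan::mrpp(stats::as.dist(d), g, permutations = 499)
  expect_equal(res$statistic, ref$delta, tolerance = 1e-12)
  # strongly separated groups: delta near zero, p at the floor
  xs <- rbind(matrix(rnorm(12, 0, 0.01), 4), matrix(rnorm(12, 10, 0.01), 4))
  rownames(xs) <- paste0("s", 1:8)
  ds <- as.matrix(stats::dist(xs))
  res2 <- mrpp(ds, rep(c("a", "b"), each = 4), n_perm = 999, seed = 2)
  expect_lt(res2$p, 0.05)
  expect_gt(res2$A, 0)
})

test_that("MRPP sampled p agrees with exhaustive label enumeration", {
  d <- rand_dist(6, seed = 63)
  g <- rep(c("a", "b"), each = 3)
  exact <- oracle_mrpp_p(d, g)
  res <- mrpp(d, g, n_perm = 1999, seed = 3)
  se <- sqrt(exact * (1 - exact) / 1999)
  expect_lt(abs(res$p - exact), 4 * se + 2 / 1999)
})

test_that("MRPP excludes singleton groups with a warning", {
  d <- rand_dist(7, seed = 64)
  expect_warning(res <- mrpp(d, c("a", "a", "a", "b", "b", "b", "c"),
                             n_perm = 99, seed = 1), "size 1")
  expect_true(res$p > 0 && res$p <= 1)
})

test_that("PERMANOVA SS decomposition matches the group-sum identity", {
  # n = 4 toy instances, one-way design
  set.seed(65)
  for (rep in 1:5) {
    d <- rand_dist(4)
    g <- c("a", "a", "b", "b")
    res <- permanova(d, ~ grp, data.frame(grp = g), n_perm = 99, seed = 1)
    o <- oracle_oneway_ss(d, g)
    expect_equal(res$ss_total, o$total, tolerance = 1e-10)
    expect_equal(res$terms$ss[1], o$between, tolerance = 1e-10)
    expect_equal(res$ss_residual, o$within, tolerance = 1e-10)
  }
})

test_that("PERMANOVA gives R2 = 1 on the two-cluster degenerate case", {
  d <- matrix(1, 4, 4) - diag(4)
  d[1, 2] <- d[2, 1] <- 0
  d[3, 4] <- d[4, 3] <- 0
  rownames(d) <- colnames(d) <- paste0("s", 1:4)
  res <- permanova(d, ~ grp, data.frame(grp = c("a", "a", "b", "b")),
                   n_perm = 99, seed = 1)
  expect_equal(res$terms$r2[1], 1, tolerance = 1e-10)
})

test_that("PERMANOVA matches vegan::adonis2 with sequential terms", {
  d <- rand_dist(12, seed = 66)
  meta <- data.frame(grp = rep(c("a", "b", "c"), each = 4),
                     cov = rnorm(12))
  res <- permanova(d, ~ grp + cov, meta, n_perm = 199, seed = 4)
  ref <- vegan::adonis2(stats::as.dist(d) ~ grp + cov, data = meta,
                        permutations = 199, by = "terms")
  expect_equal(res$terms$ss, ref$SumOfSqs[1:2], tolerance = 1e-10)
  expect_equal(res$terms$r2, ref$R2[1:2], tolerance = 1e-10)
  expect_equal(res$terms$pseudo_f, ref$F[1:2], tolerance = 1e-10)
})

test_that("orthogonal balanced designs make R2 order-invariant", {
  d <- rand_dist(8, seed = 67)
  meta <- data.frame(f1 = rep(c("a", "b"), each = 4),
                     f2 = rep(c("x", "y"), 4))
  r12 <- permanova(d, ~ f1 + f2, meta, n_perm = 49, seed = 1)
  r21 <- permanova(d, ~ f2 + f1, meta, n_perm = 49, seed = 1)
  expect_equal(r12$terms$r2[r12$terms$term == "f1"],
               r21$terms$r2[r21$terms$term == "f1"], tolerance = 1e-10)
  expect_equal(r12$terms$r2[r12$terms$term == "f2"],
               r21$terms$r2[r21$terms$term == "f2"], tolerance = 1e-10)
})

test_that("Mantel statistic is exact under linear scaling", {
  d1 <- rand_dist(7, seed = 68)
  res <- mantel_test(d1, 2 * d1, n_perm = 99, seed = 1)
  expect_equal(res$statistic, 1, tolerance = 1e-12)
  expect_error(mantel_test(d1, 0 * d1), "constant")
})

test_that("Mantel sampled p agrees with exhaustive enumeration at n = 5", {
  d1 <- rand_dist(5, seed = 69)
  d2 <- rand_dist(5)
  exact <- oracle_mantel_p(d1, d2)
  res <- mantel_test(d1, d2, n_perm = 1999, seed = 5)
  se <- sqrt(exact * (1 - exact) / 1999)
  expect_lt(abs(res$p - exact), 4 * se + 2 / 1999)
})

test_that("Mantel agrees with vegan on statistic and seeded p scale", {
  d1 <- rand_dist(9, seed = 70)
  d2 <- rand_dist(9)
  res <- mantel_test(d1, d2, n_perm = 999, seed = 6)
  ref <- vegan::mantel(stats::as.dist(d1), stats::as.dist(d2),
                       permutations = 999)
  expect_equal(res$statistic, unname(ref$statistic), tolerance = 1e-12)
})

test_that("NMDS embeds an equilateral triangle with zero stress", {
  d <- matrix(1, 3, 3) - diag(3)
  rownames(d) <- colnames(d) <- c("a", "b", "c")
  res <- nmds(d, k = 2, restarts = 5, seed = 7)
  expect_lte(res$stress, 1e-6)
  expect_equal(colMeans(res$points), c(NMDS1 = 0, NMDS2 = 0),
               tolerance = 1e-8)
})

test_that("NMDS recovers planted 2-D configurations rank-perfectly", {
  set.seed(71)
  xy <- matrix(rnorm(20), 10, 2)
  d <- as.matrix(stats::dist(xy))
  rownames(d) <- colnames(d) <- paste0("s", 1:10)
  res <- nmds(d, k = 2, restarts = 20, seed = 8)
  expect_lte(res$stress, 0.01)
  d_out <- as.matrix(stats::dist(res$points))
  expect_equal(rank(d_out[lower.tri(d_out)]), rank(d[lower.tri(d)]))
  expect_true(res$converged)
})

test_that("NMDS is reproducible for a fixed seed", {
  d <- rand_dist(8, seed = 72)
  r1 <- nmds(d, seed = 9)
  r2 <- nmds(d, seed = 9)
  expect_identical(r1$points, r2$points)
  expect_identical(r1$stress, r2$stress)
})

test_that("vector fitting recovers an axis-aligned variable with r2 = 1", {
  d <- rand_dist(10, seed = 73)
  ord <- nmds(d, seed = 10)
  fits <- envfit_vectors(ord, data.frame(v = ord$points[, 1]),
                         n_perm = 199, seed = 1)
  expect_equal(fits$r2, 1, tolerance = 1e-10)
  expect_equal(abs(fits$NMDS1), 1, tolerance = 1e-8)
  expect_lt(fits$p, 0.05)
})

test_that("envfit r2 is invariant under rigid rotation of the ordination", {
  d <- rand_dist(9, seed = 74)
  ord <- nmds(d, seed = 11)
  v <- data.frame(v = rnorm(9))
  theta <- 0.83
  rot <- matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)), 2, 2)
  pts_rot <- ord$points %*% rot
  colnames(pts_rot) <- colnames(ord$points)
  f1 <- envfit_vectors(ord$points, v, n_perm = 99, seed = 2)
  f2 <- envfit_vectors(pts_rot, v, n_perm = 99, seed = 2)
  expect_equal(f1$r2, f2$r2, tolerance = 1e-10)
})

test_that("envfit skips constant variables with a warning", {
  d <- rand_dist(8, seed = 75)
  ord <- nmds(d, seed = 12)
  expect_warning(f <- envfit_vectors(ord, data.frame(flat = rep(1, 8),
                                                     ok = rnorm(8)),
                                     n_perm = 99, seed = 3), "constant")
  expect_equal(f$variable, "ok")
})

test_that("UPGMA reproduces the hand-worked three-leaf case", {
  d <- matrix(c(0, 2, 4, 2, 0, 4, 4, 4, 0), 3, 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  tree <- upgma(d)
  # ((A:1,B:1):1,C:2); up to child order
  ph <- ape::read.tree(text = tree$newick)
  expect_setequal(ph$tip.label, c("A", "B", "C"))
  depth <- ape::node.depth.edgelength(ph)
  expect_equal(unname(depth[1:3]), rep(2, 3))  # root height 2 to every leaf
  expect_equal(tree$height, 2)
  expect_equal(tree$cophenetic["A", "B"], 2)
  expect_equal(tree$cophenetic["A", "C"], 4)
  # two leaves: a cherry at half the distance
  d2 <- matrix(c(0, 3, 3, 0), 2, 2, dimnames = list(c("x", "y"), c("x", "y")))
  expect_equal(upgma(d2)$height, 1.5)
})

test_that("UPGMA output is ultrametric and matches average-linkage hclust", {
  set.seed(76)
  for (rep in 1:10) {
    d <- rand_dist(sample(4:9, 1))
    tree <- upgma(d)
    hc <- stats::hclust(stats::as.dist(d), method = "average")
    expect_equal(tree$cophenetic,
                 as.matrix(stats::cophenetic(hc))[rownames(d), rownames(d)],
                 tolerance = 1e-12)
    # root-to-leaf depths all equal
    ph <- ape::read.tree(text = tree$newick)
    depth <- ape::node.depth.edgelength(ph)
    leaf_depth <- depth[seq_along(ph$tip.label)]
    expect_lt(max(leaf_depth) - min(leaf_depth), 1e-9)
  }
})

test_that("permutation p-values are reproducible and use (b+1)/(m+1)", {
  d1 <- rand_dist(8, seed = 77)
  d2 <- rand_dist(8)
  r1 <- mantel_test(d1, d2, n_perm = 99, seed = 13)
  r2 <- mantel_test(d1, d2, n_perm = 99, seed = 13)
  expect_identical(r1$p, r2$p)
  expect_true(r1$p >= 1 / 100 && r1$p <= 1)
  m1 <- mrpp(d1, rep(c("a", "b"), each = 4), n_perm = 99, seed = 14)
  expect_true(m1$p >= 1 / 100 && m1$p <= 1)
})
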