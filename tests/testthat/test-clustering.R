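test_that("correlation distance matches the direct covariance formula", {
  m <- matrix(c(1, 2, 3, 2, 4, 6), nrow = 3)  # proportional columns
  expect_equal(as.matrix(correlation_distance(m))[1, 2], 0)
  m2 <- cbind(c(1, 2, 3), c(3, 2, 1))
  expect_equal(as.matrix(correlation_distance(m2))[1, 2], 2)
  set.seed(10)
  m3 <- matrix(rnorm(60), 10, 6, dimnames = list(NULL, letters[1:6]))
  d <- as.matrix(correlation_distance(m3))
  for (i in 1:5) for (j in (i + 1):6) {
    x <- m3[, i]; y <- m3[, j]
    r <- sum((x - mean(x)) * (y - mean(y))) /
      sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
    expect_lt(abs(d[i, j] - (1 - r)), 1e-12)
  }
  expect_error(correlation_distance(cbind(c(1, 1, 1), c(1, 2, 3))), "constant")
})

test_that("UPGMA reproduces the hand-computed 3-point dendrogram", {
  d <- as.dist(matrix(c(0, 1, 4, 1, 0, 4, 4, 4, 0), 3,
                      dimnames = list(c("A", "B", "C"), c("A", "B", "C"))))
  tree <- upgma(d)
  expect_equal(tree$height, c(1, 4))
  expect_equal(sort(tree$labels[-tree$merge[1, ]]), c("A", "B"))
})

test_that("UPGMA recovers an ultrametric exactly", {
  set.seed(14)
  base <- hclust(dist(matrix(rnorm(40), 8)), method = "average")
  um <- cophenetic(base)  # ultrametric by construction
  tree <- upgma(um)
  expect_equal(as.matrix(cophenetic(tree)), as.matrix(um), tolerance = 1e-12)
})

test_that("UPGMA agrees with the stats::hclust average-linkage oracle", {
  set.seed(15)
  for (i in 1:8) {
    d <- dist(matrix(rnorm(8 * 4), 8, 4))
    attr(d, "Labels") <- sprintf("L%d", 1:8)
    mine <- upgma(d)
    ref <- hclust(d, method = "average")
    expect_equal(sort(mine$height), sort(ref$height), tolerance = 1e-12)
    expect_equal(as.matrix(cophenetic(mine)), as.matrix(cophenetic(ref)),
                 tolerance = 1e-12)
  }
})

test_that("cutting at a correlation threshold yields the expected clusters", {
  d <- as.dist(matrix(c(0, 0.01, 0.1, 0.01, 0, 0.1, 0.1, 0.1, 0), 3,
                      dimnames = list(c("A", "B", "C"), c("A", "B", "C"))))
  tree <- upgma(d)
  cl <- cut_at_correlation(tree, threshold = 0.95)  # cut height 0.05
  expect_equal(length(unique(cl$cluster)), 2)
  expect_equal(cl$cluster[cl$label == "A"], cl$cluster[cl$label == "B"])
  expect_false(cl$cluster[cl$label == "A"] == cl$cluster[cl$label == "C"])
  # cut above the root -> one cluster; below the first merge -> all singletons
  expect_equal(length(unique(cut_at_correlation(tree, 0.5)$cluster)), 1)
  expect_equal(length(unique(cut_at_correlation(tree, 0.999)$cluster)), 3)
  expect_error(cut_at_correlation(tree, 0), "threshold")
  expect_error(cut_at_correlation(tree, 1.2), "threshold")
})

# within-cluster correlation ~ 25/26 (> 0.95), between-cluster ~ 0.4
two_cluster_matrix <- function(n_feat = 50, n_per = 5, delta = 10, seed = 16) {
  set.seed(seed)
  profile_a <- rnorm(n_feat, 0, 5)
  profile_b <- profile_a + rnorm(n_feat, 0, delta)
  m <- cbind(
    replicate(n_per, profile_a + rnorm(n_feat)),
    replicate(n_per, profile_b + rnorm(n_feat))
  )
  colnames(m) <- c(sprintf("a%d", 1:n_per), sprintf("b%d", 1:n_per))
  m
}

test_that("well-separated sample groups get AU support above 0.95", {
  m <- two_cluster_matrix()
  res <- multiscale_bootstrap_au(m, B = 100, seed = 3)
  truth_a <- sort(sprintf("a%d", 1:5))
  truth_b <- sort(sprintf("b%d", 1:5))
  keys <- vapply(res$support$members, function(x) paste(sort(x), collapse = ","),
                 character(1))
  ia <- match(paste(truth_a, collapse = ","), keys)
  ib <- match(paste(truth_b, collapse = ","), keys)
  expect_false(is.na(ia))
  expect_false(is.na(ib))
  expect_gt(res$support$au[ia], 0.95)
  expect_gt(res$support$au[ib], 0.95)
  # the 0.95 correlation cut recovers the planted bipartition
  cl <- cut_at_correlation(res$tree, 0.95)
  expect_equal(length(unique(cl$cluster)), 2)
  expect_equal(length(unique(cl$cluster[grepl("^a", cl$label)])), 1)
  expect_equal(length(unique(cl$cluster[grepl("^b", cl$label)])), 1)
})

test_that("bootstrap resampling is reproducible under a fixed seed", {
  m <- two_cluster_matrix(n_feat = 30, seed = 17)
  r1 <- multiscale_bootstrap_au(m, B = 30, seed = 99)
  r2 <- multiscale_bootstrap_au(m, B = 30, seed = 99)
  expect_identical(r1$support$au, r2$support$au)
  expect_identical(r1$support$bp, r2$support$bp)
})

test_that("AU is invariant under leaf relabeling", {
  m <- two_cluster_matrix(n_feat = 30, seed = 18)
  perm <- sample(ncol(m))
  r1 <- multiscale_bootstrap_au(m, B = 50, seed = 5)
  r2 <- multiscale_bootstrap_au(m[, perm], B = 50, seed = 5)
  k1 <- vapply(r1$support$members, function(x) paste(sort(x), collapse = ","),
               character(1))
  k2 <- vapply(r2$support$members, function(x) paste(sort(x), collapse = ","),
               character(1))
  shared <- intersect(k1, k2)
  expect_gt(length(shared), 0)
  # identical resampling cannot be forced across permuted inputs, so compare
  # support within Monte-Carlo error
  for (k in shared) {
    expect_lt(abs(r1$support$au[match(k, k1)] - r2$support$au[match(k, k2)]),
              0.15)
  }
})

test_that("the AU fit recovers the analytic model, collapsing to BP without curvature", {
  scales <- seq(0.5, 1.4, by = 0.1)
  B <- rep(10000L, length(scales))
  for (v in c(-1, -0.3, 0.5)) {
    for (cc in c(0, 0.2)) {
      bp <- 1 - pnorm(v * sqrt(scales) + cc / sqrt(scales))
      fit <- rhizolink:::fit_au(round(bp * B), B, scales)
      expect_equal(fit$v, v, tolerance = 0.02)
      expect_equal(fit$c, cc, tolerance = 0.02)
      expect_equal(fit$au, 1 - pnorm(v - cc), tolerance = 0.01)
      if (cc == 0) {
        # no curvature: AU equals the plain bootstrap probability at r = 1
        expect_equal(fit$au, fit$bp1, tolerance = 0.01)
      }
    }
  }
  # degenerate all-present cluster: AU pinned at the clipping bound
  all_in <- rhizolink:::fit_au(B, B, scales)
  expect_gte(all_in$au, 1 - 1 / (B[1] + 1) - 1e-12)
  all_out <- rhizolink:::fit_au(rep(0L, length(scales)), B, scales)
  expect_lte(all_out$au, 1 / (B[1] + 1) + 1e-12)
})

test_that("Newick export round-trips through ape with correct heights", {
  skip_if_not_installed("ape")
  set.seed(19)
  d <- dist(matrix(rnorm(24), 6))
  attr(d, "Labels") <- sprintf("T%d", 1:6)
  tree <- upgma(d)
  path <- withr::local_tempfile(fileext = ".nwk")
  write_newick(tree, path)
  phy <- ape::read.tree(path)
  expect_setequal(phy$tip.label, tree$labels)
  # cophenetic distances in the phylogeny equal twice the merge heights
  coph_hc <- as.matrix(cophenetic(tree))
  coph_phy <- ape::cophenetic.phylo(phy)[rownames(coph_hc), colnames(coph_hc)]
  expect_equal(coph_phy, 2 * coph_hc, tolerance = 1e-8)
})
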