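test_that("alpha diversity matches closed forms", {
  ft <- make_ft(matrix(c(5, 5, 0,
                         10, 0, 0,
                         3, 3, 3), 3, 3))
  # columns: (5,5,0), (10,0,0), (3,3,3)
  expect_equal(unname(alpha_diversity(ft, "richness")), c(2, 1, 3))
  two <- make_ft(matrix(c(5, 5), 2, 1))
  expect_equal(unname(alpha_diversity(two, "shannon")), log(2))
  expect_equal(unname(alpha_diversity(two, "pielou_evenness")), 1)
  one <- make_ft(matrix(c(10, 0, 0), 3, 1))
  expect_equal(unname(alpha_diversity(one, "shannon")), 0)
  expect_true(is.na(alpha_diversity(one, "pielou_evenness")))
  for (S in c(2, 5, 9)) {
    unif <- make_ft(matrix(rep(4, S), S, 1))
    expect_equal(unname(alpha_diversity(unif, "pielou_evenness")), 1)
  }
})

test_that("beta diversity matches closed forms and handles empty pairs", {
  ft <- make_ft(matrix(c(1, 1, 0,
                         0, 1, 1,
                         1, 1, 0), 3, 3))
  # samples: u=(1,0,1), v=(1,1,1), w=(0,1,0)
  uv <- make_ft(matrix(c(1, 1, 0, 0, 1, 1), 3, 2))
  expect_equal(as.matrix(beta_diversity(uv, "jaccard"))[1, 2], 2 / 3)
  expect_equal(as.matrix(beta_diversity(uv, "braycurtis"))[1, 2], 1 / 2)
  same <- make_ft(matrix(c(2, 3, 2, 3), 2, 2))
  expect_equal(as.matrix(beta_diversity(same, "braycurtis"))[1, 2], 0)
  disj <- make_ft(matrix(c(1, 0, 0, 2), 2, 2))
  expect_equal(as.matrix(beta_diversity(disj, "braycurtis"))[1, 2], 1)
  expect_equal(as.matrix(beta_diversity(disj, "jaccard"))[1, 2], 1)
  zz <- make_ft(matrix(c(1, 0, 0, 0, 0, 0), 2, 3))
  expect_warning(dz <- beta_diversity(zz, "braycurtis"), "all-zero")
  expect_equal(as.matrix(dz)["s02", "s03"], 0)
})

test_that("PCoA reproduces Euclidean geometry and orders axes", {
  set.seed(8)
  P <- matrix(rnorm(18), 6, 3)
  d <- dist_from_points(P)
  ord <- pcoa(d)
  expect_true(all(diff(ord$explained) <= 1e-12))
  # distances in the recovered space equal the input distances
  rec <- as.matrix(dist(ord$coordinates))
  expect_equal(unname(rec), unname(unclass(d)), tolerance = 1e-8)
  # and the configuration matches the original points up to rotation
  expect_lt(procrustes_m2(ord$coordinates[, 1:3], P, k_axes = 3), 1e-10)
  # axes orthogonal
  cc <- crossprod(scale(ord$coordinates, center = TRUE, scale = FALSE))
  expect_lt(max(abs(cc[upper.tri(cc)])), 1e-8)
  # collinear points: one axis carries everything
  line <- dist_from_points(cbind(c(0, 1, 2, 3), 0))
  ol <- pcoa(line)
  expect_gt(ol$explained[1], 1 - 1e-10)
  expect_error(pcoa(matrix(0, 2, 2, dimnames = list(c("a", "b"), NULL))),
               "at least 3")
})

test_that("PCA of z-scored data equals correlation-matrix PCA", {
  set.seed(3)
  ft <- make_ft(matrix(rnorm(40, sd = rep(c(1, 10), each = 20)), 4, 10),
                transform = "log")
  o1 <- pca(zscore_normalize(ft))
  o2 <- pca(ft, scale = TRUE)
  # population vs sample sd differ by a uniform sqrt(n/(n-1)) factor, which
  # rescales coordinates but leaves axes and explained variance untouched
  n <- ncol(ft$values)
  expect_equal(abs(o1$coordinates[, 1:3]),
               abs(o2$coordinates[, 1:3]) * sqrt(n / (n - 1)),
               tolerance = 1e-6)
  expect_equal(o1$explained, o2$explained, tolerance = 1e-8)
})

test_that("biplot vectors are axis correlations scaled by their sum", {
  set.seed(4)
  d <- dist_from_points(matrix(rnorm(30), 10, 3))
  ord <- pcoa(d)
  ax1 <- ord$coordinates[, 1]
  # a variable equal to axis 1
  v <- biplot_vectors(ord, data.frame(ax = ax1))
  expect_equal(v$r1, 1, tolerance = 1e-12)
  expect_equal(v$r2, 0, tolerance = 1e-8)
  expect_equal(v$scale, 1, tolerance = 1e-8)
  # orthogonalised noise has scale near 0
  z <- residuals(lm(rnorm(10) ~ ord$coordinates[, 1] + ord$coordinates[, 2]))
  vz <- biplot_vectors(ord, data.frame(z = z))
  expect_lt(vz$scale, 1e-8)
  # axis sign flip flips r, preserves scale
  flip <- ord
  flip$coordinates[, 1] <- -flip$coordinates[, 1]
  vf <- biplot_vectors(flip, data.frame(ax = ax1))
  expect_equal(vf$r1, -1, tolerance = 1e-12)
  expect_equal(vf$scale, v$scale, tolerance = 1e-8)
  expect_message(
    biplot_vectors(ord, data.frame(ax = ax1, k = rep(2, 10))), "constant")
})

test_that("PERMANOVA agrees with the vegan oracle and nails extreme cases", {
  for (s in 1:3) {
    set.seed(s)
    n <- 12
    g <- rep(c("a", "b", "c"), each = 4)
    d <- dist_from_points(matrix(rnorm(n * 2), n, 2))
    ours <- permanova(d, g, n_perm = 99, seed = s)
    orac <- vegan::adonis2(as.dist(d) ~ factor(g), permutations = 99)
    expect_equal(ours$pseudo_F, orac$F[1], tolerance = 1e-10)
    expect_equal(ours$R2, orac$R2[1], tolerance = 1e-10)
  }
  # two tight, well-separated clusters (groups big enough that no random
  # permutation reproduces the partition and ties the observed F)
  P <- rbind(matrix(rnorm(16, sd = 1e-3), 8, 2),
             matrix(rnorm(16, mean = 50, sd = 1e-3), 8, 2))
  res <- permanova(dist_from_points(P), rep(c("x", "y"), each = 8),
                   n_perm = 199, seed = 1)
  expect_equal(res$p, 1 / 200)
  expect_gt(res$R2, 0.99)
  expect_error(permanova(dist_from_points(P), c(rep("x", 15), "y")),
               "at least 2 samples")
  # deterministic under seed
  d2 <- dist_from_points(matrix(rnorm(20), 10, 2))
  g2 <- rep(1:2, each = 5)
  expect_identical(permanova(d2, g2, seed = 7), permanova(d2, g2, seed = 7))
})

test_that("PERMDISP distances equal the vegan centroid oracle", {
  set.seed(21)
  ft <- make_ft(matrix(rexp(8 * 18), 8, 18))
  d <- beta_diversity(ft, "braycurtis")  # semimetric: negative eigenvalues
  g <- factor(rep(c("a", "b", "c"), each = 6))
  ours <- permdisp(d, g, n_perm = 99, seed = 1)
  orac <- vegan::betadisper(stats::as.dist(d), g, type = "centroid")
  expect_equal(unname(ours$distances), unname(orac$distances),
               tolerance = 1e-10)
  expect_equal(as.vector(ours$group_means),
               as.vector(tapply(orac$distances, g, mean)), tolerance = 1e-10)
})

test_that("PERMDISP has power for scale differences and is zero for duplicates", {
  set.seed(2)
  P <- rbind(matrix(rnorm(30), 15, 2), matrix(rnorm(30, sd = 3), 15, 2))
  g <- rep(c("small", "big"), each = 15)
  res <- permdisp(dist_from_points(P), g, n_perm = 199, seed = 2)
  expect_lt(res$p, 0.05)
  expect_gt(res$group_means[["big"]], res$group_means[["small"]])
  # a duplicated point has zero distance to its group centroid
  dup <- rbind(matrix(rnorm(8), 4, 2), matrix(1, 3, 2))
  gd <- rep(c("a", "b"), c(4, 3))
  rd <- permdisp(dist_from_points(dup), gd, n_perm = 49, seed = 1)
  expect_equal(unname(rd$group_means[["b"]]), 0, tolerance = 1e-10)
})

test_that("nested PERMANOVA strata exactly equal subset-and-run results", {
  set.seed(31)
  n <- 24
  prim <- rep(c("w1", "w2"), each = 12)
  sec <- rep(rep(c("d1", "d2", "d3"), each = 4), 2)
  d <- dist_from_points(matrix(rnorm(n * 3), n, 3))
  nest <- nested_permanova(d, prim, sec, n_perm = 99, seed = 5)
  for (lev in c("w1", "w2")) {
    idx <- prim == lev
    ref <- permanova(unclass(d)[idx, idx], sec[idx], n_perm = 99, seed = 5)
    row <- nest[nest$test == "within" & nest$stratum == lev, ]
    expect_identical(row$pseudo_F, ref$pseudo_F)
    expect_identical(row$R2, ref$R2)
    expect_identical(row$p, ref$p)
  }
  # global row equals a plain primary PERMANOVA
  ref_g <- permanova(d, prim, n_perm = 99, seed = 5)
  expect_identical(nest$pseudo_F[nest$test == "global"], ref_g$pseudo_F)
  # BH correction applied over the within-stratum family
  expect_equal(nest$q[nest$test == "within"],
               p.adjust(nest$p[nest$test == "within"], "BH"))
  # strata without secondary variation are skipped
  sec2 <- sec
  sec2[prim == "w2"] <- "d1"
  expect_message(n2 <- nested_permanova(d, prim, sec2, n_perm = 49, seed = 1),
                 "skipping stratum")
  expect_equal(sum(n2$test == "within"), 1L)
})
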