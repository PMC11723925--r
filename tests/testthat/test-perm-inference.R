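test_that("pseudo-F matches the hand-enumerated worked example", {
  D <- as.matrix(dist(c(0, 1, 3, 5)))
  r <- permanova(D, c("A", "A", "B", "B"), exhaustive = TRUE)
  expect_equal(r$statistic, 9.8, tolerance = 1e-10)
  expect_equal(r$R2, 12.25 / 14.75, tolerance = 1e-10)
  expect_equal(r$p, 1 / 3, tolerance = 1e-12)
  expect_equal(unname(r$df), c(1, 2))
  # also equals classical one-way ANOVA F on the raw 1-D points
  a <- anova(lm(y ~ g, data.frame(y = c(0, 1, 3, 5),
                                  g = c("A", "A", "B", "B"))))
  expect_equal(r$statistic, a$`F value`[1], tolerance = 1e-10)
})

test_that("sums of squares partition exactly and are label-invariant", {
  with_seed_local(31, {
    X <- matrix(rnorm(60), 20, 3)
    D <- as.matrix(dist(X))
    lab <- sample(rep(c("a", "b", "c"), length.out = 20))
    D2 <- D^2
    n <- 20
    ss_t <- sum(D2) / (2 * n)
    li <- as.integer(factor(lab))
    ss_w <- morphodist:::ss_within(D2, li, 3)
    r <- permanova(D, lab, n_perm = 49, seed = 1)
    expect_equal(r$R2, (ss_t - ss_w) / ss_t, tolerance = 1e-12)
    # renaming groups and jointly permuting object order leave F unchanged
    perm <- sample(n)
    r2 <- permanova(D[perm, perm], c(a = "Q", b = "R", c = "S")[lab][perm],
                    n_perm = 49, seed = 1)
    expect_equal(r2$statistic, r$statistic, tolerance = 1e-12)
    expect_equal(r2$R2, r$R2, tolerance = 1e-12)
  })
})

test_that("pseudo-F and R2 agree with the vegan implementation", {
  with_seed_local(33, {
    X <- matrix(rnorm(90), 30, 3)
    lab <- rep(c("a", "b", "c"), each = 10)
    D <- dist(X)
    ref <- vegan::adonis2(D ~ g, data.frame(g = lab), permutations = 99)
    r <- permanova(as.matrix(D), lab, n_perm = 99, seed = 2)
    expect_equal(r$statistic, ref$F[1], tolerance = 1e-10)
    expect_equal(r$R2, ref$R2[1], tolerance = 1e-10)
  })
})

test_that("maximally separated zero-diameter clusters floor the p-value", {
  X <- rep(c(0, 10), each = 12)
  D <- as.matrix(dist(X))
  r <- permanova(D, rep(c("a", "b"), each = 12), n_perm = 99, seed = 1)
  expect_equal(r$statistic, Inf)
  expect_equal(r$p, 1 / 100)
})

test_that("principal coordinates recover Euclidean configurations", {
  with_seed_local(41, {
    X <- cbind(rnorm(15), rnorm(15))
    pc <- pcoa(as.matrix(dist(X)))
    expect_true(all(pc$eigenvalues >= -1e-8))
    expect_equal(ncol(pc$imag_vectors), 0)
    expect_lt(max(abs(colMeans(pc$vectors))), 1e-10)
    # Procrustes match to the original coordinates
    Xc <- scale(X, scale = FALSE)
    V <- pc$vectors[, 1:2]
    sv <- svd(crossprod(V, Xc))
    rot <- sv$u %*% t(sv$v)
    expect_lt(sqrt(mean((V %*% rot - Xc)^2)), 1e-8)
    # eigenvalues agree with the ape implementation
    ref <- ape::pcoa(dist(X))
    expect_equal(pc$eigenvalues[1:2], ref$values$Eigenvalues[1:2],
                 tolerance = 1e-8)
  })
})

test_that("non-Euclidean distance sets yield flagged imaginary axes", {
  # star tree: three leaves at distance 1 from a hub and 2 apart cannot
  # be embedded in Euclidean space
  D <- matrix(2, 4, 4) - diag(2, 4)
  D[1, 2:4] <- D[2:4, 1] <- 1
  pc <- pcoa(D)
  expect_gt(ncol(pc$imag_vectors), 0)
  expect_gt(pc$negative_mass, 0)
  expect_true(any(pc$eigenvalues < 0))
})

test_that("dispersion test matches the enumerated worked example", {
  D <- as.matrix(dist(c(-1, 1, -3, 3)))
  r <- permdisp(D, c("A", "A", "B", "B"), exhaustive = TRUE)
  expect_equal(r$statistic, Inf)
  expect_equal(r$p, 1 / 3, tolerance = 1e-12)
  expect_equal(unname(r$profile$distance), c(1, 1, 3, 3), tolerance = 1e-10)
})

test_that("translated groups show no dispersion difference", {
  X <- c(0, 1, 2, 10, 11, 12)
  D <- as.matrix(dist(X))
  r <- permdisp(D, rep(c("a", "b"), each = 3), n_perm = 199, seed = 3)
  expect_equal(r$statistic, 0, tolerance = 1e-10)
  expect_gt(r$p, 0.9)
})

test_that("centroid distances agree with direct coordinates and vegan", {
  with_seed_local(51, {
    X <- cbind(rnorm(24), rnorm(24), rnorm(24))
    lab <- rep(c("a", "b"), each = 12)
    D <- as.matrix(dist(X))
    r <- permdisp(D, lab, n_perm = 49, seed = 1)
    # coordinate oracle
    z_ref <- numeric(24)
    for (g in c("a", "b")) {
      idx <- lab == g
      ctr <- colMeans(X[idx, ])
      z_ref[idx] <- sqrt(rowSums((X[idx, ] -
                                    rep(ctr, each = sum(idx)))^2))
    }
    expect_equal(r$profile$distance, z_ref, tolerance = 1e-8)
    bd <- vegan::betadisper(dist(X), lab, type = "centroid")
    expect_equal(unname(r$profile$distance), unname(bd$distances),
                 tolerance = 1e-8)
    expect_equal(r$statistic, anova(bd)$`F value`[1], tolerance = 1e-8)
  })
})

test_that("spatial-median centroids reproduce the vegan default", {
  with_seed_local(52, {
    X <- cbind(rnorm(30), rnorm(30))
    lab <- rep(c("a", "b"), each = 15)
    D <- as.matrix(dist(X))
    r <- permdisp(D, lab, n_perm = 19, seed = 1, centroid = "median")
    bd <- vegan::betadisper(dist(X), lab, type = "median")
    expect_equal(unname(r$profile$distance), unname(bd$distances),
                 tolerance = 1e-4)
  })
})

test_that("balanced down-sampling equalises two group sizes", {
  lab <- rep(c("big", "small"), c(10, 5))
  idx <- balanced_downsample(lab, seed = 1)
  expect_equal(as.integer(table(lab[idx])), c(5, 5))
  expect_identical(idx, balanced_downsample(lab, seed = 1))
  expect_false(identical(idx, balanced_downsample(lab, seed = 2)))
  # the study's phase 1 vs 2 contrast: 761 vs 1,689 -> 1,522 objects
  lab2 <- rep(c("p1", "p2"), c(761, 1689))
  expect_equal(length(balanced_downsample(lab2, seed = 1)), 1522)
  expect_error(balanced_downsample(rep(c("a", "b", "c"), 2)))
})

test_that("pairwise testing produces Bonferroni-starred contrasts", {
  with_seed_local(61, {
    X <- rbind(matrix(rnorm(40), 20, 2),
               matrix(rnorm(40, 2), 20, 2),
               matrix(rnorm(40, 4), 20, 2),
               matrix(rnorm(30, 6), 15, 2))
    lab <- rep(c("1", "2", "3", "4"), c(20, 20, 20, 15))
    D <- as.matrix(dist(X))
  })
  pt <- pairwise_tests(D, lab, n_perm = 199, seed = 1)
  expect_equal(nrow(pt), 12)  # 6 pairs x {PERMANOVA, PERMDISP}
  expect_equal(attr(pt, "alpha_adjusted"), 0.05 / 6)
  expect_true(all(pt$df_model == 1))
  expect_true(all(pt$n %% 2 == 0))       # balanced after down-sampling
  expect_true(all(pt$R2 >= 0 & pt$R2 <= 1))
  expect_true(all(pt$p >= 1 / 200 & pt$p <= 1))
  # the clearly separated pair is significant
  expect_true(pt$bonferroni_sig[pt$pair == "1 vs. 4" &
                                  pt$test == "PERMANOVA"])
  # reproducible given the seed
  pt2 <- pairwise_tests(D, lab, n_perm = 199, seed = 1)
  expect_equal(pt, pt2, ignore_attr = TRUE)
  # p-value floor at the permutation resolution
  expect_equal(min(pt$p), 1 / 200)
})

test_that("the p-value floor matches the (b+1)/(m+1) convention", {
  with_seed_local(81, {
    X <- c(rnorm(12), rnorm(12, 50))
  })
  lab <- rep(c("a", "b"), each = 12)
  r <- permanova(as.matrix(dist(X)), lab, n_perm = 1000, seed = 1)
  expect_equal(r$p, 1 / 1001, tolerance = 1e-12)
})

test_that("Gower identity matches coordinate distances to centroids", {
  # 1-D group {0, 2}: object at 0 is 1 away from the centroid
  D <- as.matrix(dist(c(0, 2)))
  dp <- dist_to_group_centroid(D, c("g", "g"))
  expect_equal(dp$profile$distance, c(1, 1), tolerance = 1e-12)
  # object identical to every group member
  D0 <- matrix(0, 3, 3)
  expect_equal(dist_to_group_centroid(D0, rep("g", 3))$profile$distance,
               rep(0, 3))
  # Euclidean oracle
  with_seed_local(71, {
    X <- cbind(rnorm(30), rnorm(30))
    lab <- rep(c("a", "b"), each = 15)
    dp2 <- dist_to_group_centroid(as.matrix(dist(X)), lab)
    z_ref <- numeric(30)
    for (g in c("a", "b")) {
      idx <- lab == g
      ctr <- colMeans(X[idx, ])
      z_ref[idx] <- sqrt(rowSums((X[idx, ] -
                                    rep(ctr, each = sum(idx)))^2))
    }
    expect_equal(dp2$profile$distance, z_ref, tolerance = 1e-8)
    expect_named(dp2$group_summary, c("group", "n", "median", "lower",
                                      "upper"))
  })
})
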