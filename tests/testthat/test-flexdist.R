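test_that("imputation resamples the observed empirical distribution", {
  tab <- mini_table(60, seed = 12, missing_rate = 0.25)
  done <- impute_once(tab, seed = 1)
  expect_equal(sum(is.na(done[, 1:5])), 0)
  # complete cells untouched
  for (v in names(tab)[1:5]) {
    obs <- !is.na(tab[[v]])
    expect_equal(done[[v]][obs], tab[[v]][obs])
    # imputed values come from the observed support
    expect_true(all(done[[v]][!obs] %in% tab[[v]][obs]))
  }
  # imputed category frequencies track observed frequencies
  v <- "PTY"
  obs_freq <- prop.table(table(tab[[v]]))
  draws <- unlist(lapply(1:1000, function(i) {
    d <- impute_once(tab, seed = i)
    as.character(d[[v]][is.na(tab[[v]])])
  }))
  imp_freq <- prop.table(table(factor(draws, levels = names(obs_freq))))
  expect_lt(max(abs(imp_freq - obs_freq)), 0.03)
  # fully missing variable errors by name
  tab$EPA[] <- NA
  expect_error(impute_once(tab), "EPA")
})

test_that("mixed PCA reduces to correlation-matrix PCA on continuous data", {
  tab <- cont_table(60, p = 4, seed = 3)
  m <- mixed_pca(tab)
  X <- as.matrix(tab[, 1:4])
  ref <- eigen(cor(X), symmetric = TRUE)
  expect_equal(m$eigenvalues, ref$values, tolerance = 1e-10)
  # scores are the standardized data projected on the eigenvectors
  Z <- scale(X)
  ref_scores <- Z %*% ref$vectors
  for (j in 1:4) {
    expect_equal(abs(cor(m$scores[, j], ref_scores[, j])), 1,
                 tolerance = 1e-8)
  }
  # scores centred and uncorrelated across PCs
  expect_lt(max(abs(colMeans(m$scores))), 1e-10)
  cc <- crossprod(m$scores) / (nrow(X) - 1)
  expect_lt(max(abs(cc[upper.tri(cc)])), 1e-10)
})

test_that("mixed PCA handles isotropic and degenerate geometries", {
  with_seed_local(2, {
    df <- data.frame(V1 = rnorm(4000), V2 = rnorm(4000), group = "g")
  })
  m <- mixed_pca(flake_table(df, cont_schema(2)))
  expect_equal(m$eigenvalues, c(1, 1), tolerance = 0.1)
  # perfectly collinear data: PC1 explains 100%
  df2 <- data.frame(V1 = 1:20, V2 = 2 * (1:20), group = "g")
  m2 <- mixed_pca(flake_table(df2, cont_schema(2)))
  expect_equal(variance_explained(m2)[1], 100, tolerance = 1e-8)
  expect_error(mixed_pca(flake_table(df2[1, ], cont_schema(2))),
               "at least 2")
  expect_error(mixed_pca(mini_table(10, missing_rate = 0.5)), "complete")
})

test_that("variance explained is a nonincreasing percentage of the total", {
  expect_equal(variance_explained(c(3, 1)), c(75, 25))
  tab <- mini_table(50, seed = 4)
  pv <- variance_explained(mixed_pca(tab))
  expect_equal(sum(pv), 100)
  expect_true(all(diff(pv) <= 1e-10))
})

test_that("distances equal the classical Mahalanobis distance", {
  tab <- cont_table(40, p = 2, seed = 9, corr = 0.7)
  m <- mixed_pca(tab)
  D <- mahalanobis_distances(m)
  X <- as.matrix(tab[, 1:2])
  Sinv <- solve(cov(X))
  ref <- outer(1:40, 1:40, Vectorize(function(i, j) {
    sqrt(mahalanobis(X[i, ], X[j, ], cov(X)))
  }))
  expect_equal(D, ref, tolerance = 1e-8, ignore_attr = TRUE)
  expect_equal(diag(D), rep(0, 40), ignore_attr = TRUE)
  # triangle inequality on random triples
  with_seed_local(1, {
    for (t in 1:200) {
      ijk <- sample(40, 3)
      expect_lte(D[ijk[1], ijk[2]],
                 D[ijk[1], ijk[3]] + D[ijk[3], ijk[2]] + 1e-10)
    }
  })
})

test_that("identical records are at distance zero", {
  df <- data.frame(V1 = c(1, 1, 3), V2 = c(2, 2, 5), V3 = c(0, 0, 1),
                   group = "g")
  D <- mahalanobis_distances(mixed_pca(flake_table(df, cont_schema(3))))
  expect_equal(D[1, 2], 0, tolerance = 1e-10)
  expect_gt(D[1, 3], 0)
})

test_that("correlation circle arrows have norm at most one", {
  tab <- mini_table(80, seed = 14)
  m <- mixed_pca(tab)
  cc <- correlation_circle(m)
  expect_true(all(cc$norm <= 1 + 1e-10))
  # a column equal to the PC1 score has arrow (1, 0)
  df <- data.frame(V1 = scale(m$scores[, 1])[, 1], group = "g")
  m1 <- mixed_pca(flake_table(df, cont_schema(1)))
  cc1 <- correlation_circle(m1)
  expect_equal(abs(cc1$pc1), 1, tolerance = 1e-10)
  expect_equal(cc1$pc2, 0)
})

test_that("complete tables yield zero-width intervals and degenerate ellipses", {
  tab <- mini_table(40, seed = 16)
  fx <- run_flexdist(tab, n_iterations = 25, seed = 2)
  expect_equal(fx$config$n_iterations, 1)  # collapses to a single run
  expect_identical(fx$distances$lower, fx$distances$median)
  expect_identical(fx$distances$upper, fx$distances$median)
  expect_true(all(fx$ordination$objects$a == 0))
  expect_equal(sum(fx$ordination$pct_variance), 100)
})

test_that("interval bounds bracket the median elementwise", {
  tab <- mini_table(50, seed = 17, missing_rate = 0.2)
  fx <- run_flexdist(tab, n_iterations = 15, seed = 3)
  expect_true(all(fx$distances$lower <= fx$distances$median + 1e-12))
  expect_true(all(fx$distances$median <= fx$distances$upper + 1e-12))
  expect_equal(diag(fx$distances$median), rep(0, 50), ignore_attr = TRUE)
  expect_equal(fx$distances$median, t(fx$distances$median))
  expect_error(run_flexdist(tab, n_iterations = 1), ">= 2")
})

test_that("pair-block streaming does not change the combined distances", {
  tab <- mini_table(30, seed = 18, missing_rate = 0.15)
  fx1 <- run_flexdist(tab, n_iterations = 8, seed = 5)
  fx2 <- run_flexdist(tab, n_iterations = 8, seed = 5, pair_block = 17L)
  expect_equal(fx1$distances, fx2$distances, tolerance = 1e-12)
})

test_that("sign-flipped imputations are re-aligned before averaging", {
  tab <- mini_table(40, seed = 19)
  m <- mixed_pca(tab)
  flipped <- m
  flipped$scores <- -m$scores
  flipped$loadings <- -m$loadings
  al <- morphodist:::align_to_reference(flipped, m)
  expect_equal(al$scores[, 1:2], m$scores[, 1:2], tolerance = 1e-8)
})

test_that("group centroids and ellipses are exported per phase", {
  cfg <- assemblage_config(n_per_group = 25, shift_per_group = 0.8,
                           missing_rate = 0.1, seed = 23)
  sim <- simulate_assemblage(cfg)
  fx <- run_flexdist(sim$table, n_iterations = 10, seed = 4)
  g <- fx$ordination$groups
  expect_equal(nrow(g), 4)
  expect_true(all(g$a >= 0 & g$b >= 0))
  d <- tempfile()
  write_flexdist(fx, d)
  expect_true(all(file.exists(file.path(d, c(
    "distances_long.csv", "object_centroids.csv", "group_centroids.csv",
    "eigenvalues.csv", "correlation_circle.csv")))))
  long <- read.csv(file.path(d, "distances_long.csv"))
  expect_equal(nrow(long), choose(100, 2))
  expect_true(all(long$lower <= long$median & long$median <= long$upper))
})
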