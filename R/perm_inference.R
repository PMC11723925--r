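# Permutation inference on distance matrices: PERMANOVA, principal
# coordinates, PERMDISP, balanced pairwise contrasts with Bonferroni
# correction and distance-to-centroid dispersion profiles.

as_dist_matrix <- function(D) {
  D <- as.matrix(D)
  if (nrow(D) != ncol(D) || max(abs(D - t(D))) > 1e-8 ||
      any(abs(diag(D)) > 1e-12)) {
    stop("D must be a symmetric distance matrix with zero diagonal",
         call. = FALSE)
  }
  D
}

# within-group sum over pairs of squared distances, divided by group
# size, summed over groups; labels given as an integer vector
ss_within <- function(D2, labels, n_levels) {
  s <- 0
  for (g in seq_len(n_levels)) {
    z <- labels == g
    ng <- sum(z)
    if (ng > 0) s <- s + sum(D2[z, z]) / (2 * ng)
  }
  s
}

# all distinct permutations of a label vector (used for exhaustive
# tests on small n); returns a matrix with one permutation per column
all_label_permutations <- function(labels, cap = 100000L) {
  n <- length(labels)
  # enumerate permutations of positions, map to labels, deduplicate the
  # distinct label sequences
  res <- matrix(labels[perm_matrix(n, cap)], nrow = n)
  unique_cols(res)
}

# all n! permutations of 1..n, one per column, built by inserting n at
# every position of each permutation of 1..(n-1)
perm_matrix <- function(n, cap) {
  if (factorial(n) > cap) {
    stop("exhaustive enumeration infeasible for n = ", n, call. = FALSE)
  }
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- perm_matrix(n - 1, cap)
  out <- matrix(0L, n, n * ncol(sub))
  col <- 1L
  for (pos in seq_len(n)) {
    for (j in seq_len(ncol(sub))) {
      out[, col] <- c(if (pos > 1) sub[seq_len(pos - 1), j] else integer(0),
                      n,
                      if (pos <= n - 1) sub[pos:(n - 1), j] else integer(0))
      col <- col + 1L
    }
  }
  out
}

unique_cols <- function(m) {
  key <- apply(m, 2, paste, collapse = "\r")
  m[, !duplicated(key), drop = FALSE]
}

#' Permutational multivariate analysis of variance (one factor)
#'
#' Partitions the total sum of squared inter-object distances into
#' between- and within-group components and compares them with a
#' pseudo-F statistic whose null distribution is obtained by permuting
#' group labels.  `SS_T = sum_{i<j} d_ij^2 / N`,
#' `SS_W = sum_g sum_{i<j in g} d_ij^2 / n_g`, `SS_A = SS_T - SS_W`,
#' `F = (SS_A / (a - 1)) / (SS_W / (N - a))`, `R^2 = SS_A / SS_T`.
#' The p-value uses the `(b + 1) / (m + 1)` convention with ties counted
#' as exceedances; `exhaustive = TRUE` instead enumerates every distinct
#' label permutation and reports the exact proportion with
#' `F_perm >= F_obs` (identity included).
#'
#' @param D distance matrix (or `dist`).
#' @param labels group label per object (>= 2 groups, each with >= 2
#'   objects).
#' @param n_perm number of random permutations (default 999).
#' @param seed optional RNG seed.
#' @param exhaustive enumerate all distinct permutations instead of
#'   sampling (small n only).
#' @return Object of class `perm_test`: `n`, `df` (model, residual),
#'   `statistic` (pseudo-F), `R2`, `p`, `n_perm`, `method`.
#' @export
permanova <- function(D, labels, n_perm = 999, seed = NULL,
                      exhaustive = FALSE) {
  D <- as_dist_matrix(D)
  labels <- droplevels(as.factor(labels))
  n <- nrow(D)
  stopifnot(length(labels) == n)
  if (nlevels(labels) < 2 || any(table(labels) < 2)) {
    stop("need >= 2 groups with >= 2 objects each", call. = FALSE)
  }
  a <- nlevels(labels)
  D2 <- D^2
  ss_t <- sum(D2) / (2 * n)
  tol <- 1e-12 * (ss_t + 1e-300)
  f_stat <- function(lab_int) {
    ssw <- ss_within(D2, lab_int, a)
    ssa <- ss_t - ssw
    if (abs(ssa) < tol) ssa <- 0
    if (ssw < tol) ssw <- 0
    (ssa / (a - 1)) / (ssw / (n - a))
  }
  li <- as.integer(labels)
  F_obs <- f_stat(li)
  ss_w <- ss_within(D2, li, a)
  R2 <- (ss_t - ss_w) / ss_t
  if (exhaustive) {
    P <- all_label_permutations(li)
    Fp <- apply(P, 2, f_stat)
    p <- sum(Fp >= F_obs - 1e-12, na.rm = TRUE) / ncol(P)
    n_perm <- ncol(P)
  } else {
    p <- with_seed(seed, {
      b <- 0L
      for (t in seq_len(n_perm)) {
        Fp <- f_stat(sample(li))
        if (!is.nan(Fp) && Fp >= F_obs - 1e-12) b <- b + 1L
      }
      (b + 1) / (n_perm + 1)
    })
  }
  structure(list(n = n, df = c(model = a - 1, residual = n - a),
                 statistic = F_obs, R2 = R2, p = p, n_perm = n_perm,
                 method = "PERMANOVA"),
            class = "perm_test")
}

#' @export
print.perm_test <- function(x, ...) {
  cat(sprintf("%s: n = %d, df = %d; %d, F = %.4f, R2 = %.4f, p = %.4g (%d permutations)\n",
              x$method, x$n, x$df[1], x$df[2], x$statistic, x$R2, x$p,
              x$n_perm))
  invisible(x)
}

#' Principal coordinates analysis
#'
#' Eigen-decomposition of the double-centred `-0.5 * D^2` matrix.  Axes
#' with negative eigenvalues (non-Euclidean distance sets) are kept,
#' scaled by the square root of the absolute eigenvalue and flagged
#' imaginary.
#'
#' @param D distance matrix (or `dist`).
#' @param tol eigenvalues within `tol * max(|eigenvalue|)` of zero are
#'   dropped.
#' @return Object of class `pcoa_result`: `vectors` (real axes),
#'   `imag_vectors` (imaginary axes), `eigenvalues` (all retained, in
#'   decreasing order), `negative_mass` (sum of |negative eigenvalues| /
#'   sum of |eigenvalues|).
#' @export
pcoa <- function(D, tol = 1e-9) {
  D <- as_dist_matrix(D)
  n <- nrow(D)
  A <- -0.5 * D^2
  C <- diag(n) - matrix(1 / n, n, n)
  B <- C %*% A %*% C
  B <- (B + t(B)) / 2
  e <- eigen(B, symmetric = TRUE)
  thr <- tol * max(abs(e$values), 1e-300)
  keep_pos <- e$values > thr
  keep_neg <- e$values < -thr
  V <- e$vectors[, keep_pos, drop = FALSE] *
    rep(sqrt(e$values[keep_pos]), each = n)
  Vi <- e$vectors[, keep_neg, drop = FALSE] *
    rep(sqrt(-e$values[keep_neg]), each = n)
  ev <- e$values[keep_pos | keep_neg]
  neg_mass <- if (any(keep_neg)) {
    sum(abs(e$values[keep_neg])) / sum(abs(ev))
  } else 0
  structure(list(vectors = V, imag_vectors = Vi, eigenvalues = ev,
                 negative_mass = neg_mass),
            class = "pcoa_result")
}

# per-object distances to own-group centroids in PCoA space, with the
# squared imaginary-axis contribution subtracted (Gower correction);
# centroid = "mean" or "median" (spatial median via Nelder-Mead)
centroid_distances <- function(pc, labels, centroid = "mean") {
  V <- pc$vectors
  Vi <- pc$imag_vectors
  n <- nrow(V)
  z2 <- numeric(n)
  clamped <- 0L
  for (g in levels(labels)) {
    idx <- which(labels == g)
    if (centroid == "mean") {
      cr <- colMeans(V[idx, , drop = FALSE])
      ci <- if (ncol(Vi)) colMeans(Vi[idx, , drop = FALSE]) else numeric(0)
    } else {
      cm <- spatial_median(V[idx, , drop = FALSE], Vi[idx, , drop = FALSE])
      cr <- cm$real
      ci <- cm$imag
    }
    d2 <- rowSums((V[idx, , drop = FALSE] -
                     rep(cr, each = length(idx)))^2)
    if (ncol(Vi)) {
      d2 <- d2 - rowSums((Vi[idx, , drop = FALSE] -
                            rep(ci, each = length(idx)))^2)
    }
    clamped <- clamped + sum(d2 < 0)
    z2[idx] <- pmax(d2, 0)
  }
  list(z = sqrt(z2), clamped = clamped)
}

spatial_median <- function(V, Vi) {
  k <- ncol(V)
  ki <- ncol(Vi)
  obj <- function(c_) {
    d2 <- rowSums((V - rep(c_[seq_len(k)], each = nrow(V)))^2)
    if (ki) {
      d2 <- d2 - rowSums((Vi - rep(c_[k + seq_len(ki)],
                                   each = nrow(Vi)))^2)
    }
    sum(sqrt(pmax(d2, 0)))
  }
  start <- c(colMeans(V), if (ki) colMeans(Vi) else numeric(0))
  opt <- stats::optim(start, obj, method = "Nelder-Mead",
                      control = list(maxit = 500))
  list(real = opt$par[seq_len(k)],
       imag = if (ki) opt$par[k + seq_len(ki)] else numeric(0))
}

anova_f <- function(z, labels) {
  n <- length(z)
  a <- nlevels(labels)
  gm <- mean(z)
  means <- tapply(z, labels, mean)
  ns <- tabulate(labels)
  ssb <- sum(ns * (means - gm)^2)
  ssw <- sum((z - means[as.integer(labels)])^2)
  # guard against FP noise around exact degeneracy (constant z)
  tol <- 1e-10 * (sum(z^2) + 1e-300)
  if (ssb < tol) ssb <- 0
  if (ssw < tol) ssw <- 0
  (ssb / (a - 1)) / (ssw / (n - a))
}

#' Permutational analysis of multivariate dispersion
#'
#' Multivariate analogue of Levene's test: objects are embedded by
#' principal coordinates, each object's distance to its group centroid
#' is computed (with the squared imaginary-axis contribution
#' subtracted and negative corrected squares clamped to zero), and a
#' one-way ANOVA F on these distances is compared against its
#' permutation distribution.  By default group assignments are permuted
#' and the centroid distances recomputed per permutation
#' (`permute = "assignments"`); `permute = "z"` permutes the fixed
#' distances instead (faster, less strict).
#'
#' @inheritParams permanova
#' @param centroid `"mean"` (default) or `"median"` (spatial median).
#' @param permute `"assignments"` (default) or `"z"`.
#' @return Object of class `perm_test` with additional elements
#'   `profile` (data frame `object`, `group`, `distance`),
#'   `group_summary` (per-group median and 2.5/97.5 percentiles) and
#'   `n_clamped`.
#' @export
permdisp <- function(D, labels, n_perm = 999, seed = NULL,
                     centroid = c("mean", "median"),
                     permute = c("assignments", "z"),
                     exhaustive = FALSE) {
  centroid <- match.arg(centroid)
  permute <- match.arg(permute)
  D <- as_dist_matrix(D)
  labels <- droplevels(as.factor(labels))
  n <- nrow(D)
  stopifnot(length(labels) == n)
  if (nlevels(labels) < 2 || any(table(labels) < 2)) {
    stop("need >= 2 groups with >= 2 objects each", call. = FALSE)
  }
  a <- nlevels(labels)
  pc <- pcoa(D)
  cd <- centroid_distances(pc, labels, centroid)
  z <- cd$z
  F_obs <- anova_f(z, labels)
  ssb_r2 <- function(zz, lab) {
    gm <- mean(zz)
    means <- tapply(zz, lab, mean)
    ns <- tabulate(lab)
    ssb <- sum(ns * (means - gm)^2)
    sst <- sum((zz - gm)^2)
    if (sst == 0) 0 else ssb / sst
  }
  R2 <- ssb_r2(z, labels)

  stat_for <- function(lab) {
    if (permute == "assignments") {
      anova_f(centroid_distances(pc, lab, centroid)$z, lab)
    } else {
      # permuting z is equivalent to permuting assignments of fixed z
      anova_f(z, lab)
    }
  }
  if (exhaustive) {
    P <- all_label_permutations(as.integer(labels))
    Fp <- apply(P, 2, function(l) {
      stat_for(factor(levels(labels)[l], levels = levels(labels)))
    })
    ge <- vapply(Fp, function(f) {
      isTRUE(f >= F_obs - 1e-12) ||
        (is.infinite(F_obs) && is.infinite(f) && f > 0)
    }, TRUE)
    p <- sum(ge) / ncol(P)
    n_perm <- ncol(P)
  } else {
    p <- with_seed(seed, {
      b <- 0L
      for (t in seq_len(n_perm)) {
        lab <- labels[sample(n)]
        Fp <- stat_for(lab)
        if (!is.nan(Fp) &&
            (Fp >= F_obs - 1e-12 ||
             (is.infinite(F_obs) && is.infinite(Fp) && Fp > 0))) {
          b <- b + 1L
        }
      }
      (b + 1) / (n_perm + 1)
    })
  }
  profile <- data.frame(object = seq_len(n), group = labels, distance = z)
  gsum <- do.call(rbind, lapply(levels(labels), function(g) {
    zg <- z[labels == g]
    q <- stats::quantile(zg, c(0.025, 0.975), names = FALSE)
    data.frame(group = g, n = length(zg), median = stats::median(zg),
               lower = q[1], upper = q[2])
  }))
  structure(list(n = n, df = c(model = a - 1, residual = n - a),
                 statistic = F_obs, R2 = R2, p = p, n_perm = n_perm,
                 method = "PERMDISP", profile = profile,
                 group_summary = gsum, n_clamped = cd$clamped,
                 negative_mass = pc$negative_mass),
            class = c("permdisp_test", "perm_test"))
}

#' Balanced down-sampling of the larger of two groups
#'
#' Draws a uniform random subset of the larger group equal in size to
#' the smaller one; the smaller group is kept in full.
#'
#' @param labels two-group label vector.
#' @param seed optional RNG seed.
#' @return Sorted integer indices of the retained objects.
#' @export
balanced_downsample <- function(labels, seed = NULL) {
  labels <- droplevels(as.factor(labels))
  stopifnot(nlevels(labels) == 2)
  with_seed(seed, {
    n_by <- table(labels)
    small <- names(which.min(n_by))
    large <- setdiff(levels(labels), small)
    keep_large <- sample(which(labels == large), min(n_by))
    sort(c(which(labels == small), keep_large))
  })
}

#' Pairwise centroid and dispersion tests with Bonferroni correction
#'
#' For every unordered pair of groups: restrict the distance matrix to
#' the pair, down-sample the larger group to the size of the smaller,
#' then run [permanova()] and [permdisp()] on the balanced subset.
#' Significance is starred at the Bonferroni-adjusted level
#' `alpha / n_pairs`.  All randomness (down-sampling and permutations)
#' comes from one RNG stream seeded once, so results are reproducible
#' given `seed`.
#'
#' @param D distance matrix (typically the median matrix of a
#'   [run_flexdist()] result).
#' @param labels group label per object (>= 2 groups).
#' @param n_perm permutations per test (default 999).
#' @param seed RNG seed (default 1).
#' @param alpha family-wise significance level (default 0.05).
#' @param centroid passed to [permdisp()].
#' @param permute passed to [permdisp()].
#' @return Data frame with one row per test type per pair: `pair`,
#'   `test`, `n`, `df_model`, `df_resid`, `F`, `R2`, `p`, `n_perm`,
#'   `bonferroni_sig`.
#' @export
pairwise_tests <- function(D, labels, n_perm = 999, seed = 1,
                           alpha = 0.05, centroid = "mean",
                           permute = "assignments") {
  D <- as_dist_matrix(D)
  labels <- droplevels(as.factor(labels))
  gl <- levels(labels)
  pairs <- utils::combn(gl, 2)
  n_pairs <- ncol(pairs)
  alpha_adj <- alpha / n_pairs
  with_seed(seed, {
    rows <- list()
    for (k in seq_len(n_pairs)) {
      g1 <- pairs[1, k]
      g2 <- pairs[2, k]
      in_pair <- which(labels %in% c(g1, g2))
      lab_pair <- droplevels(labels[in_pair])
      keep <- balanced_downsample(lab_pair)
      idx <- in_pair[keep]
      Dk <- D[idx, idx]
      labk <- droplevels(labels[idx])
      pa <- permanova(Dk, labk, n_perm = n_perm)
      pd <- permdisp(Dk, labk, n_perm = n_perm, centroid = centroid,
                     permute = permute)
      rows[[length(rows) + 1L]] <- data.frame(
        pair = paste(g1, "vs.", g2), test = "PERMANOVA", n = pa$n,
        df_model = pa$df[1], df_resid = pa$df[2], F = pa$statistic,
        R2 = pa$R2, p = pa$p, n_perm = pa$n_perm,
        bonferroni_sig = pa$p < alpha_adj)
      rows[[length(rows) + 1L]] <- data.frame(
        pair = paste(g1, "vs.", g2), test = "PERMDISP", n = pd$n,
        df_model = pd$df[1], df_resid = pd$df[2], F = pd$statistic,
        R2 = pd$R2, p = pd$p, n_perm = pd$n_perm,
        bonferroni_sig = pd$p < alpha_adj)
    }
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    attr(out, "alpha_adjusted") <- alpha_adj
    out
  })
}

#' Distance of each object to its group centroid (Gower identity)
#'
#' Squared distance of object `i` to the centroid of its group `G`,
#' computed directly from the distance matrix:
#' `d^2(i, c_G) = (1/n_G) sum_{j in G} d_ij^2 -
#'  (1/n_G^2) sum_{j<k in G} d_jk^2`; negative values (non-Euclidean
#' distances) are clamped to zero.
#'
#' @param D distance matrix.
#' @param labels group label per object.
#' @return List of class `dispersion_profile`: `profile` (data frame
#'   `object`, `group`, `distance`) and `group_summary` (per-group
#'   median and 2.5/97.5 interpercentile range), ready for sina-plot
#'   export.
#' @export
dist_to_group_centroid <- function(D, labels) {
  D <- as_dist_matrix(D)
  labels <- droplevels(as.factor(labels))
  D2 <- D^2
  n <- nrow(D)
  d <- numeric(n)
  for (g in levels(labels)) {
    idx <- which(labels == g)
    ng <- length(idx)
    within_mean <- sum(D2[idx, idx]) / (2 * ng^2)
    d2 <- rowSums(D2[idx, idx, drop = FALSE]) / ng - within_mean
    d[idx] <- sqrt(pmax(d2, 0))
  }
  profile <- data.frame(object = seq_len(n), group = labels, distance = d)
  gsum <- do.call(rbind, lapply(levels(labels), function(g) {
    zg <- d[labels == g]
    q <- stats::quantile(zg, c(0.025, 0.975), names = FALSE)
    data.frame(group = g, n = length(zg), median = stats::median(zg),
               lower = q[1], upper = q[2])
  }))
  structure(list(profile = profile, group_summary = gsum),
            class = "dispersion_profile")
}
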