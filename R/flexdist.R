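# Resemblance core: multiple imputation, mixed-data PCA,
# Mahalanobis-type distances, and their combination into median
# distance matrices with confidence bounds plus ordination summaries.

#' Impute missing cells once by marginal resampling
#'
#' Every missing cell is replaced by a random draw from the observed
#' empirical distribution of its variable (observed values for
#' continuous variables, observed levels for categorical ones).  With
#' `conditional = TRUE` draws are taken within the record's group when
#' the group has observed values (hot-deck), falling back to the
#' marginal pool otherwise.
#'
#' @param table a `flake_table`.
#' @param seed optional RNG seed.
#' @param conditional within-group hot-deck resampling (default FALSE).
#' @return A `flake_table` with no missing attribute cells.
#' @export
impute_once <- function(table, seed = NULL, conditional = FALSE) {
  with_seed(seed, {
    vars <- schema_names(tbl_schema(table))
    grp <- tbl_groups(table)
    for (v in vars) {
      x <- table[[v]]
      miss <- which(is.na(x))
      if (!length(miss)) next
      obs <- x[!is.na(x)]
      if (!length(obs)) {
        stop("variable '", v, "' has no observed values to impute from",
             call. = FALSE)
      }
      if (conditional && !is.null(grp)) {
        for (g in levels(grp)) {
          mg <- miss[grp[miss] == g & !is.na(grp[miss])]
          if (!length(mg)) next
          pool <- x[!is.na(x) & grp == g]
          if (!length(pool)) pool <- obs
          x[mg] <- sample(pool, length(mg), replace = TRUE)
        }
        miss <- which(is.na(x))
      }
      if (length(miss)) x[miss] <- sample(obs, length(miss), replace = TRUE)
      table[[v]] <- x
    }
    table
  })
}

# FAMD-style encoding of a complete table: continuous and ordinal
# (integer rank codes) columns are z-scored; nominal categories become
# centred one-hot indicators weighted by 1/sqrt(category frequency).
# Zero-variance columns are dropped (recorded in `dropped`).
encode_mixed <- function(table, schema) {
  n <- nrow(table)
  mats <- list()
  info <- list()
  for (i in seq_len(nrow(schema))) {
    v <- schema$name[i]
    sc <- schema$scale[i]
    if (sc == "nominal") {
      f <- table[[v]]
      for (l in schema$levels[[i]]) {
        ind <- as.numeric(f == l)
        p <- mean(ind)
        nm <- paste0(v, ":", l)
        if (p == 0 || p == 1) {
          info[[nm]] <- list(variable = v, level = l, dropped = TRUE)
          next
        }
        mats[[nm]] <- (ind - p) / sqrt(p)
        info[[nm]] <- list(variable = v, level = l, dropped = FALSE)
      }
    } else {
      x <- if (sc == "ordinal") as.numeric(table[[v]]) else table[[v]]
      s <- stats::sd(x)
      if (is.na(s) || s == 0) {
        info[[v]] <- list(variable = v, level = NA, dropped = TRUE)
        next
      }
      mats[[v]] <- (x - mean(x)) / s
      info[[v]] <- list(variable = v, level = NA, dropped = FALSE)
    }
  }
  E <- do.call(cbind, mats)
  colnames(E) <- names(mats)
  dropped <- names(info)[vapply(info, `[[`, TRUE, "dropped")]
  list(E = E, dropped = dropped,
       column_variable = vapply(mats, function(z) NA_character_, ""),
       info = info)
}

#' Mixed-data principal component analysis
#'
#' Encodes a complete mixed-scale table (continuous and ordinal columns
#' z-scored, ordinal via integer level ranks; nominal categories as
#' centred one-hot indicators weighted by the reciprocal square root of
#' the category frequency) and eigen-decomposes the encoded matrix.  On
#' an all-continuous table this reduces exactly to classical
#' correlation-matrix PCA.
#'
#' @param table a complete `flake_table` (no missing attribute cells).
#' @param schema schema; defaults to the table's own.
#' @return Object of class `mixed_pca`: `scores` (n x k, centred,
#'   variance of column j equal to `eigenvalues[j]`), `loadings`
#'   (encoded columns x k, orthonormal), `eigenvalues` (nonincreasing),
#'   `encoded` (the encoded matrix), `dropped` (zero-variance columns).
#' @export
mixed_pca <- function(table, schema = NULL) {
  if (is.null(schema)) schema <- tbl_schema(table)
  if (nrow(table) < 2) stop("need at least 2 records", call. = FALSE)
  vars <- schema_names(schema)
  if (anyNA(table[, vars])) {
    stop("mixed_pca requires a complete table; impute first",
         call. = FALSE)
  }
  enc <- encode_mixed(table, schema)
  E <- enc$E
  n <- nrow(E)
  sv <- svd(E / sqrt(n - 1))
  k <- sum(sv$d > max(sv$d) * 1e-12)
  d <- sv$d[seq_len(k)]
  scores <- sv$u[, seq_len(k), drop = FALSE] * rep(d * sqrt(n - 1), each = n)
  loadings <- sv$v[, seq_len(k), drop = FALSE]
  rownames(loadings) <- colnames(E)
  colnames(loadings) <- colnames(scores) <- paste0("PC", seq_len(k))
  structure(list(scores = scores, loadings = loadings,
                 eigenvalues = d^2, encoded = E, dropped = enc$dropped),
            class = "mixed_pca")
}

#' Percent variance explained per principal component
#'
#' @param x a `mixed_pca` model or a numeric vector of eigenvalues.
#' @return Numeric vector of percentages summing to 100.
#' @export
variance_explained <- function(x) {
  ev <- if (inherits(x, "mixed_pca")) x$eigenvalues else as.numeric(x)
  100 * ev / sum(ev)
}

#' Mahalanobis-type distances from a mixed PCA model
#'
#' Euclidean distance over the retained principal component scores, each
#' standardised to unit variance; equivalently the Mahalanobis distance
#' in the encoded space restricted to the retained components.
#'
#' @param model a `mixed_pca`.
#' @param pc_retention either `"nonzero"` (all components with
#'   eigenvalue above `1e-8` times the largest; default) or an integer
#'   count of leading components.
#' @return A symmetric n x n distance matrix.
#' @export
mahalanobis_distances <- function(model, pc_retention = "nonzero") {
  keep <- retained_components(model$eigenvalues, pc_retention)
  W <- model$scores[, keep, drop = FALSE] /
    rep(sqrt(model$eigenvalues[keep]), each = nrow(model$scores))
  as.matrix(stats::dist(W))
}

retained_components <- function(ev, pc_retention) {
  if (identical(pc_retention, "nonzero")) {
    which(ev > max(ev) * 1e-8)
  } else {
    seq_len(min(as.integer(pc_retention), length(ev)))
  }
}

# first two score columns, zero-padded when the model is rank 1
leading_plane <- function(scores) {
  if (ncol(scores) >= 2) scores[, 1:2, drop = FALSE]
  else cbind(scores[, 1], 0)
}

#' Correlation circle of a mixed PCA
#'
#' Correlation of every encoded column (single nominal categories are
#' individual arrows) with the first two principal component scores.
#'
#' @param model a `mixed_pca`.
#' @return Data frame `column`, `pc1`, `pc2`, `norm` (all norms <= 1).
#' @export
correlation_circle <- function(model) {
  S <- leading_plane(model$scores)
  r <- suppressWarnings(stats::cor(model$encoded, S))
  r[!is.finite(r)] <- 0  # rank-1 models have a degenerate second axis
  data.frame(column = rownames(r), pc1 = r[, 1], pc2 = r[, 2],
             norm = sqrt(rowSums(r^2)), row.names = NULL)
}

# Sign-align (all PCs) and Procrustes-rotate (first two PCs) one
# imputation's model to the reference model.  Returns the adjusted
# scores and the 2x2 rotation applied to the leading plane.
align_to_reference <- function(model, ref) {
  k <- min(ncol(model$loadings), ncol(ref$loadings))
  common <- intersect(rownames(model$loadings), rownames(ref$loadings))
  sgn <- vapply(seq_len(k), function(j) {
    s <- sum(model$loadings[common, j] * ref$loadings[common, j])
    if (s < 0) -1 else 1
  }, 0)
  scores <- model$scores
  scores[, seq_len(k)] <- scores[, seq_len(k), drop = FALSE] *
    rep(sgn, each = nrow(scores))
  loadings <- model$loadings
  loadings[, seq_len(k)] <- loadings[, seq_len(k), drop = FALSE] *
    rep(sgn, each = nrow(loadings))
  # orthogonal Procrustes on the leading plane, for plotting only
  R <- diag(2)
  if (k >= 2) {
    M <- crossprod(loadings[common, 1:2], ref$loadings[common, 1:2])
    sv <- svd(M)
    R <- sv$u %*% t(sv$v)
    scores[, 1:2] <- scores[, 1:2, drop = FALSE] %*% R
  }
  list(scores = scores, loadings = loadings, rotation = R)
}

# 95% (or other level) ellipse parameters from a 2x2 covariance.
ellipse_params <- function(cov2, center, level) {
  if (anyNA(cov2) || all(cov2 == 0)) {
    return(c(center, a = 0, b = 0, angle = 0))
  }
  e <- eigen(cov2, symmetric = TRUE)
  r <- sqrt(pmax(e$values, 0) * stats::qchisq(level, 2))
  ang <- atan2(e$vectors[2, 1], e$vectors[1, 1])
  c(center, a = r[1], b = r[2], angle = ang)
}

#' Resemblance analysis under multiple imputation
#'
#' Runs the four-step resemblance procedure: (1) `n_iterations`
#' independent marginal-resampling imputations of the missing cells;
#' (2) a mixed-data PCA per imputed dataset; (3) a Mahalanobis-type
#' inter-object distance matrix per dataset, combined per pair into the
#' median and the central `ci_level` interval; (4) per-object centroids
#' of the (sign- and Procrustes-aligned) leading-plane scores with
#' uncertainty ellipses, group centroids and dispersion ellipses, the
#' eigenvalue spectrum, and the correlation circle.  With a complete
#' table all imputations coincide, so a single run is performed and the
#' interval has zero width.
#'
#' @param table a filtered `flake_table`.
#' @param schema schema; defaults to the table's own.
#' @param n_iterations number of imputed datasets (>= 2 whenever any
#'   cell is missing).
#' @param ci_level central interval level (default 0.95).
#' @param pc_retention see [mahalanobis_distances()].
#' @param conditional passed to [impute_once()].
#' @param seed RNG seed.
#' @param pair_block number of object pairs processed per block when
#'   combining distance matrices (bounds memory; default 200000).
#' @return List of class `flexdist_result` with elements `distances`
#'   (class `distance_summary`: `median`, `lower`, `upper` matrices),
#'   `ordination` (object/group centroids and ellipses, eigenvalue
#'   spectrum with percent variance, correlation-circle arrows) and
#'   `config`.
#' @export
run_flexdist <- function(table, schema = NULL, n_iterations = 1000,
                         ci_level = 0.95, pc_retention = "nonzero",
                         conditional = FALSE, seed = NULL,
                         pair_block = 200000L) {
  if (is.null(schema)) schema <- tbl_schema(table)
  vars <- schema_names(schema)
  n <- nrow(table)
  any_missing <- anyNA(table[, vars])
  if (any_missing && n_iterations < 2) {
    stop("n_iterations must be >= 2 when the table has missing cells",
         call. = FALSE)
  }
  m <- if (any_missing) n_iterations else 1L
  grp <- tbl_groups(table)

  with_seed(seed, {
    ref <- NULL
    score_list <- vector("list", m)    # whitened scores for distances
    plane <- array(NA_real_, c(n, 2, m))  # aligned PC1/PC2 scores
    ev_list <- vector("list", m)
    arrow_sum <- NULL
    arrow_cnt <- NULL
    for (it in seq_len(m)) {
      tab_i <- if (any_missing) impute_once(table,
                                            conditional = conditional)
      else table
      mod <- mixed_pca(tab_i, schema)
      if (is.null(ref)) ref <- mod
      al <- align_to_reference(mod, ref)
      keep <- retained_components(mod$eigenvalues, pc_retention)
      score_list[[it]] <- mod$scores[, keep, drop = FALSE] /
        rep(sqrt(mod$eigenvalues[keep]), each = n)
      plane[, , it] <- leading_plane(al$scores)
      ev_list[[it]] <- mod$eigenvalues
      # arrows in the aligned frame: correlations of encoded columns
      # with the aligned leading-plane scores
      r <- suppressWarnings(stats::cor(mod$encoded,
                                       leading_plane(al$scores)))
      r[!is.finite(r)] <- 0
      if (is.null(arrow_sum)) {
        arrow_sum <- r
        arrow_cnt <- matrix(1, nrow(r), 2,
                            dimnames = dimnames(r))
      } else {
        common <- intersect(rownames(arrow_sum), rownames(r))
        arrow_sum[common, ] <- arrow_sum[common, ] + r[common, ]
        arrow_cnt[common, ] <- arrow_cnt[common, ] + 1
      }
    }

    dsum <- combine_distances(score_list, ci_level, pair_block)

    # per-object centroids and uncertainty ellipses on the leading plane
    cent <- apply(plane, c(1, 2), mean)
    obj_ell <- t(vapply(seq_len(n), function(i) {
      cv <- if (m > 1) stats::cov(t(plane[i, , ])) else matrix(0, 2, 2)
      ellipse_params(cv, cent[i, ], ci_level)
    }, numeric(5)))
    colnames(obj_ell) <- c("pc1", "pc2", "a", "b", "angle")
    obj_ell <- data.frame(object = seq_len(n), group = grp, obj_ell)

    grp_ell <- NULL
    if (!is.null(grp)) {
      grp_ell <- do.call(rbind, lapply(levels(grp), function(g) {
        idx <- which(grp == g)
        cc <- colMeans(cent[idx, , drop = FALSE])
        cv <- if (length(idx) > 1) stats::cov(cent[idx, , drop = FALSE])
        else matrix(0, 2, 2)
        p <- ellipse_params(cv, cc, ci_level)
        data.frame(group = g, pc1 = p[1], pc2 = p[2], a = p[["a"]],
                   b = p[["b"]], angle = p[["angle"]], n = length(idx))
      }))
    }

    kmax <- max(vapply(ev_list, length, 0L))
    evm <- vapply(ev_list, function(e) c(e, rep(0, kmax - length(e))),
                  numeric(kmax))
    ev_mean <- if (kmax == 1) mean(evm) else rowMeans(evm)
    arrows <- data.frame(column = rownames(arrow_sum),
                         pc1 = arrow_sum[, 1] / arrow_cnt[, 1],
                         pc2 = arrow_sum[, 2] / arrow_cnt[, 2],
                         row.names = NULL)
    arrows$norm <- sqrt(arrows$pc1^2 + arrows$pc2^2)

    structure(list(
      distances = dsum,
      ordination = list(objects = obj_ell, groups = grp_ell,
                        eigenvalues = ev_mean,
                        pct_variance = 100 * ev_mean / sum(ev_mean),
                        arrows = arrows),
      config = list(n_iterations = m, ci_level = ci_level,
                    pc_retention = pc_retention,
                    conditional = conditional, seed = seed)
    ), class = "flexdist_result")
  })
}

# Combine per-imputation whitened score matrices into per-pair median /
# lower / upper distance matrices, processing pairs in blocks so that at
# most `pair_block * m` distance values are materialised at once.
combine_distances <- function(score_list, ci_level, pair_block) {
  m <- length(score_list)
  n <- nrow(score_list[[1]])
  if (m == 1L) {
    D <- as.matrix(stats::dist(score_list[[1]]))
    return(structure(list(median = D, lower = D, upper = D),
                     class = "distance_summary"))
  }
  idx <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  np <- nrow(idx)
  med <- lo <- up <- matrix(0, n, n)
  alpha <- (1 - ci_level) / 2
  sq <- lapply(score_list, function(S) rowSums(S^2))
  start <- 1L
  while (start <= np) {
    end <- min(start + pair_block - 1L, np)
    ii <- idx[start:end, 1]
    jj <- idx[start:end, 2]
    block <- vapply(seq_len(m), function(t) {
      S <- score_list[[t]]
      d2 <- sq[[t]][ii] + sq[[t]][jj] -
        2 * rowSums(S[ii, , drop = FALSE] * S[jj, , drop = FALSE])
      sqrt(pmax(d2, 0))
    }, numeric(length(ii)))
    if (is.null(dim(block))) block <- matrix(block, nrow = 1)
    qs <- t(apply(block, 1, stats::quantile,
                  probs = c(alpha, 0.5, 1 - alpha), names = FALSE))
    lin <- cbind(c(ii, jj), c(jj, ii))
    lo[lin] <- rep(qs[, 1], 2)
    med[lin] <- rep(qs[, 2], 2)
    up[lin] <- rep(qs[, 3], 2)
    start <- end + 1L
  }
  structure(list(median = med, lower = lo, upper = up),
            class = "distance_summary")
}

#' @export
print.flexdist_result <- function(x, ...) {
  n <- nrow(x$distances$median)
  pv <- x$ordination$pct_variance
  cat("Resemblance analysis:", n, "objects,",
      x$config$n_iterations, "imputation(s)\n")
  cat(sprintf("PC1 + PC2 variance: %.1f%%\n", sum(pv[1:min(2, length(pv))])))
  invisible(x)
}

#' Export a resemblance result as plot-ready tables
#'
#' Writes the distance summary (long CSV `i`, `j`, `median`, `lower`,
#' `upper`), object and group centroid/ellipse tables, eigenvalue
#' spectrum and correlation-circle arrows.
#'
#' @param x a `flexdist_result`.
#' @param dir output directory.
#' @export
write_flexdist <- function(x, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  D <- x$distances
  n <- nrow(D$median)
  idx <- which(upper.tri(D$median), arr.ind = TRUE)
  long <- data.frame(i = idx[, 1], j = idx[, 2],
                     median = D$median[idx], lower = D$lower[idx],
                     upper = D$upper[idx])
  utils::write.csv(long, file.path(dir, "distances_long.csv"),
                   row.names = FALSE)
  utils::write.csv(x$ordination$objects,
                   file.path(dir, "object_centroids.csv"),
                   row.names = FALSE)
  if (!is.null(x$ordination$groups)) {
    utils::write.csv(x$ordination$groups,
                     file.path(dir, "group_centroids.csv"),
                     row.names = FALSE)
  }
  utils::write.csv(
    data.frame(pc = seq_along(x$ordination$eigenvalues),
               eigenvalue = x$ordination$eigenvalues,
               pct_variance = x$ordination$pct_variance),
    file.path(dir, "eigenvalues.csv"), row.names = FALSE)
  utils::write.csv(x$ordination$arrows,
                   file.path(dir, "correlation_circle.csv"),
                   row.names = FALSE)
  invisible(dir)
}
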