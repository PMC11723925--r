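# Heterogeneous correlation matrix for mixed-scale variables:
# Pearson (continuous x continuous), polychoric/tetrachoric
# (ordinal/binary x ordinal/binary) and polyserial/biserial
# (continuous x ordinal/binary), all two-step latent-Gaussian
# estimators with pairwise-complete cases.

# Gauss-Legendre nodes/weights on [-1, 1] via Golub-Welsch.
gauss_legendre <- function(n) {
  i <- seq_len(n - 1)
  b <- i / sqrt(4 * i^2 - 1)
  J <- matrix(0, n, n)
  J[cbind(i, i + 1)] <- b
  J[cbind(i + 1, i)] <- b
  e <- eigen(J, symmetric = TRUE)
  list(nodes = rev(e$values), weights = rev(2 * e$vectors[1, ]^2))
}

.gl48 <- NULL
gl48 <- function() {
  if (is.null(.gl48)) {
    utils::assignInMyNamespace(".gl48", gauss_legendre(48))
  }
  .gl48
}

#' Standard bivariate normal CDF
#'
#' `P(X <= h, Y <= k)` for standard bivariate normal `(X, Y)` with
#' correlation `rho`.  Moderate correlations use Gauss-Legendre
#' quadrature on the Drezner-Wesolowsky single-integral form; `|rho|`
#' near 1 falls back to an adaptive conditioning integral.  Absolute
#' accuracy is about 1e-12.
#'
#' @param h,k upper limits (scalars; `Inf`/`-Inf` allowed).
#' @param rho correlation in `[-1, 1]`.
#' @return Probability in `[0, 1]`.
#' @export
pbvnorm <- function(h, k, rho) {
  stopifnot(length(h) == 1, length(k) == 1, abs(rho) <= 1)
  if (is.infinite(h) && h < 0) return(0)
  if (is.infinite(k) && k < 0) return(0)
  if (is.infinite(h)) return(stats::pnorm(k))
  if (is.infinite(k)) return(stats::pnorm(h))
  if (rho == 0) return(stats::pnorm(h) * stats::pnorm(k))
  if (rho >= 1) return(stats::pnorm(min(h, k)))
  if (rho <= -1) return(max(0, stats::pnorm(h) + stats::pnorm(k) - 1))
  if (abs(rho) <= 0.95) {
    # Phi2(h,k,r) = Phi(h)Phi(k) +
    #   (1/2pi) int_0^r exp(-(h^2 - 2 t h k + k^2) / (2(1-t^2))) /
    #                 sqrt(1-t^2) dt
    gl <- gl48()
    t <- rho / 2 * (gl$nodes + 1)
    w <- gl$weights * rho / 2
    f <- exp(-(h^2 - 2 * t * h * k + k^2) / (2 * (1 - t^2))) /
      sqrt(1 - t^2)
    p <- stats::pnorm(h) * stats::pnorm(k) + sum(w * f) / (2 * pi)
  } else {
    # conditioning integral: int_-inf^h phi(x) Phi((k - rho x)/s) dx.
    # The inner CDF steps sharply near x = k/rho when |rho| -> 1, so the
    # interval is split around that boundary layer.
    s <- sqrt(1 - rho^2)
    f <- function(x) stats::dnorm(x) * stats::pnorm((k - rho * x) / s)
    cp <- k / rho
    brk <- sort(unique(pmin(pmax(c(cp - 20 * s, cp, cp + 20 * s),
                                 -38), h)))
    lims <- unique(c(-Inf, brk[brk < h], h))
    p <- 0
    for (i in seq_len(length(lims) - 1)) {
      p <- p + stats::integrate(f, lims[i], lims[i + 1],
                                rel.tol = 1e-12, abs.tol = 1e-14)$value
    }
  }
  min(1, max(0, p))
}

# Rectangle probabilities for all cells of a grid defined by thresholds
# a (rows) and b (cols), both without the infinite outer bounds.
bvn_cell_probs <- function(a, b, rho) {
  aa <- c(-Inf, a, Inf)
  bb <- c(-Inf, b, Inf)
  Fm <- outer(aa, bb, Vectorize(function(x, y) pbvnorm(x, y, rho)))
  nr <- length(aa) - 1L
  nc <- length(bb) - 1L
  Fm[2:(nr + 1), 2:(nc + 1), drop = FALSE] -
    Fm[1:nr, 2:(nc + 1), drop = FALSE] -
    Fm[2:(nr + 1), 1:nc, drop = FALSE] +
    Fm[1:nr, 1:nc, drop = FALSE]
}

#' Pearson correlation over pairwise-complete cases
#'
#' @param x,y numeric vectors of equal length, `NA` allowed.
#' @return Correlation, or `NA` (with a warning) if fewer than 3
#'   complete pairs remain or either margin has zero variance.
#' @export
pearson_pairwise <- function(x, y) {
  ok <- !is.na(x) & !is.na(y)
  if (sum(ok) < 3) {
    warning("fewer than 3 pairwise-complete observations", call. = FALSE)
    return(NA_real_)
  }
  if (stats::sd(x[ok]) == 0 || stats::sd(y[ok]) == 0) {
    warning("zero variance in a margin; correlation undefined",
            call. = FALSE)
    return(NA_real_)
  }
  stats::cor(x[ok], y[ok])
}

#' Polychoric correlation from a two-way contingency table
#'
#' Two-step estimator: thresholds from the inverse-normal cumulative
#' marginals, then the latent correlation maximising the bivariate
#' normal cell-probability likelihood, clamped to `[-0.999, 0.999]`.
#' A 2x2 table gives the tetrachoric correlation (same code path).
#'
#' @param ctab matrix of nonnegative counts with at least 2 rows and 2
#'   columns and positive total.
#' @return Estimated latent correlation, or `NA` (with a warning) when a
#'   margin is degenerate (all mass in one level).
#' @export
polychoric <- function(ctab) {
  ctab <- as.matrix(ctab)
  stopifnot(nrow(ctab) >= 2, ncol(ctab) >= 2, all(ctab >= 0))
  n <- sum(ctab)
  stopifnot(n > 0)
  rm_ <- rowSums(ctab)
  cm_ <- colSums(ctab)
  if (sum(rm_ > 0) < 2 || sum(cm_ > 0) < 2) {
    warning("degenerate margin: all mass in one level", call. = FALSE)
    return(NA_real_)
  }
  a <- stats::qnorm(cumsum(rm_ / n))[-nrow(ctab)]
  b <- stats::qnorm(cumsum(cm_ / n))[-ncol(ctab)]
  nll <- function(rho) {
    p <- bvn_cell_probs(a, b, rho)
    -sum(ctab[ctab > 0] * log(pmax(p[ctab > 0], 1e-300)))
  }
  opt <- stats::optimize(nll, c(-0.999, 0.999), tol = 1e-7)
  unname(opt$minimum)
}

#' Polyserial correlation between a continuous and an ordinal variable
#'
#' Two-step estimator: ordinal thresholds from the cumulative marginals,
#' continuous variable standardised, then the latent correlation
#' maximising the conditional likelihood
#' `prod_i phi(z_i) * [Phi((t_{y_i} - rho z_i)/s) - Phi((t_{y_i - 1} - rho z_i)/s)]`.
#' With two ordinal levels this is the biserial correlation.
#'
#' @param x numeric vector; `NA` allowed.
#' @param y ordinal values: a factor or integer level codes; `NA` allowed.
#' @return Estimated latent correlation in `[-0.999, 0.999]`, or `NA`
#'   (with a warning) on degenerate margins or fewer than 10 complete
#'   pairs.
#' @export
polyserial <- function(x, y) {
  y <- if (is.factor(y)) as.integer(y) else as.integer(as.factor(y))
  ok <- !is.na(x) & !is.na(y)
  if (sum(ok) < 10) {
    warning("fewer than 10 pairwise-complete observations", call. = FALSE)
    return(NA_real_)
  }
  x <- x[ok]
  y <- y[ok]
  if (length(unique(y)) < 2 || stats::sd(x) == 0) {
    warning("degenerate margin; polyserial undefined", call. = FALSE)
    return(NA_real_)
  }
  y <- as.integer(factor(y))  # compress to observed levels
  k <- max(y)
  p <- tabulate(y, k) / length(y)
  tau <- c(-Inf, stats::qnorm(cumsum(p))[-k], Inf)
  z <- (x - mean(x)) / stats::sd(x)
  nll <- function(rho) {
    s <- sqrt(1 - rho^2)
    up <- stats::pnorm((tau[y + 1L] - rho * z) / s)
    lo <- stats::pnorm((tau[y] - rho * z) / s)
    -sum(log(pmax(up - lo, 1e-300)))
  }
  opt <- stats::optimize(nll, c(-0.999, 0.999), tol = 1e-7)
  unname(opt$minimum)
}

# Encode a table for correlation purposes: continuous columns as numeric,
# ordinal as ordered integer codes, binary nominal as a single 0/1
# indicator, multi-category nominal as one indicator per category.
hetcor_columns <- function(table, schema) {
  cols <- list()
  for (i in seq_len(nrow(schema))) {
    v <- schema$name[i]
    sc <- schema$scale[i]
    if (sc == "continuous") {
      cols[[v]] <- list(values = table[[v]], kind = "continuous")
    } else if (sc == "ordinal") {
      cols[[v]] <- list(values = as.integer(table[[v]]), kind = "ordinal")
    } else {
      lev <- schema$levels[[i]]
      if (length(lev) == 2L) {
        cols[[v]] <- list(values = as.integer(table[[v]] == lev[2]) + 1L,
                          kind = "binary")
      } else {
        for (l in lev) {
          nm <- paste0(v, ":", l)
          cols[[nm]] <- list(values = as.integer(table[[v]] == l) + 1L,
                             kind = "binary")
        }
      }
    }
  }
  cols
}

#' Heterogeneous correlation matrix of a mixed-scale table
#'
#' Dispatches per pair of encoded columns: Pearson for two continuous
#' variables, polychoric (tetrachoric when both are binary) for two
#' categorical variables, polyserial (biserial) for continuous x
#' categorical.  Nominal variables with more than two categories enter
#' as per-category binary indicators (`VAR:level` columns), so single
#' categories are individually interpretable.  Missing values are
#' handled by pairwise deletion.
#'
#' @param table a `flake_table`.
#' @param schema schema; defaults to the table's own.
#' @param psd_repair clip negative eigenvalues to restore positive
#'   semi-definiteness (default TRUE); whether repair occurred is
#'   recorded.
#' @return An object of class `hetcor_matrix`: list with `rho`
#'   (correlation matrix), `method` (character matrix of estimator used
#'   per pair), `n` (pairwise-complete counts), `psd_repaired` flag.
#' @export
hetero_corr_matrix <- function(table, schema = NULL, psd_repair = TRUE) {
  if (is.null(schema)) schema <- tbl_schema(table)
  cols <- hetcor_columns(table, schema)
  p <- length(cols)
  nm <- names(cols)
  rho <- diag(1, p)
  meth <- matrix("", p, p, dimnames = list(nm, nm))
  npair <- matrix(NA_integer_, p, p, dimnames = list(nm, nm))
  dimnames(rho) <- list(nm, nm)
  diag(meth) <- "self"
  for (i in seq_len(p - 1)) {
    for (j in (i + 1):p) {
      xi <- cols[[i]]
      xj <- cols[[j]]
      ok <- !is.na(xi$values) & !is.na(xj$values)
      npair[i, j] <- npair[j, i] <- sum(ok)
      cont_i <- xi$kind == "continuous"
      cont_j <- xj$kind == "continuous"
      r <- suppressWarnings(
        if (cont_i && cont_j) {
          m <- "pearson"
          pearson_pairwise(xi$values, xj$values)
        } else if (!cont_i && !cont_j) {
          m <- if (xi$kind == "binary" && xj$kind == "binary")
            "tetrachoric" else "polychoric"
          tb <- table(factor(xi$values[ok]), factor(xj$values[ok]))
          if (nrow(tb) < 2 || ncol(tb) < 2) NA_real_ else polychoric(tb)
        } else {
          m <- if ((cont_i && xj$kind == "binary") ||
                   (cont_j && xi$kind == "binary")) "biserial"
          else "polyserial"
          if (cont_i) polyserial(xi$values, xj$values)
          else polyserial(xj$values, xi$values)
        }
      )
      rho[i, j] <- rho[j, i] <- r
      meth[i, j] <- meth[j, i] <- m
    }
  }
  repaired <- FALSE
  if (psd_repair && !anyNA(rho)) {
    e <- eigen(rho, symmetric = TRUE)
    if (min(e$values) < -1e-8) {
      repaired <- TRUE
      v <- pmax(e$values, 1e-8)
      R <- e$vectors %*% (v * t(e$vectors))
      d <- sqrt(diag(R))
      rho <- R / tcrossprod(d)
      dimnames(rho) <- list(nm, nm)
    }
  }
  structure(list(rho = rho, method = meth, n = npair,
                 psd_repaired = repaired),
            class = "hetcor_matrix")
}

#' @export
print.hetcor_matrix <- function(x, ...) {
  cat("Heterogeneous correlation matrix (", nrow(x$rho), " columns",
      if (x$psd_repaired) ", PSD-repaired" else "", ")\n", sep = "")
  print(round(x$rho, 2))
  invisible(x)
}

#' Export a heterogeneous correlation matrix
#'
#' Writes the square matrix (`hetcor_matrix.csv`) and a long format
#' (`hetcor_long.csv`: `var1`, `var2`, `rho`, `method`, `n`) suitable
#' for heatmap rendering.
#'
#' @param x a `hetcor_matrix`.
#' @param dir output directory.
#' @export
write_hetcor <- function(x, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(x$rho, file.path(dir, "hetcor_matrix.csv"))
  nm <- rownames(x$rho)
  idx <- which(upper.tri(x$rho), arr.ind = TRUE)
  long <- data.frame(var1 = nm[idx[, 1]], var2 = nm[idx[, 2]],
                     rho = x$rho[idx], method = x$method[idx],
                     n = x$n[idx])
  utils::write.csv(long, file.path(dir, "hetcor_long.csv"),
                   row.names = FALSE)
  invisible(dir)
}
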