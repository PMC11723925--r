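# Synthetic assemblage generator: artefact tables with known phase
# structure, mixed scales, latent correlation, graded centroid shifts,
# per-group dispersion multipliers and MCAR missingness.

# Run code under a temporary RNG state seeded with `seed`; restores the
# caller's stream afterwards so simulations do not perturb it.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(code)
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  code
}

#' Configure a synthetic assemblage
#'
#' The generator draws, per object, a vector of correlated latent
#' Gaussian dimensions with a group-specific mean shift and a
#' group-specific scale (dispersion) multiplier.  Continuous variables
#' are affine maps of latent dimensions, with geometry measurements kept
#' strictly positive through a log-normal link and the percent-cortex
#' variable clipped to `[0, 100]`.  Ordinal variables arise by
#' thresholding a latent dimension at configured cut points; nominal
#' variables are drawn from group-conditional category probability
#' tables.  Defaults mirror the 16-variable flake schema with four
#' ordered phases.
#'
#' @param n_per_group objects per group (scalar or vector of length
#'   `n_groups`).
#' @param n_groups number of ordered groups (default 4).
#' @param shift_per_group latent mean offsets in latent-SD units: a
#'   scalar step (group g gets `(g-1) * step` on the shifted dimensions),
#'   a vector of per-group offsets, or an `n_groups x n_latent` matrix.
#' @param shift_dims indices of latent dimensions receiving the shift
#'   when `shift_per_group` is not a full matrix (default `1:3`).
#' @param dispersion_scale_per_group per-group multiplier on the latent
#'   SD (default all 1).
#' @param latent_corr correlation matrix among the latent dimensions
#'   (unit diagonal, positive semi-definite); default an exchangeable
#'   matrix with correlation `0.3` among the first five (geometry)
#'   dimensions and `0.1` elsewhere.
#' @param missing_rate MCAR per-cell missingness probability in `[0, 1)`.
#' @param schema the variable schema to emulate (default
#'   [sibhudu_schema()]).
#' @param level_probs named list of baseline level probabilities for the
#'   categorical variables; default proportional to
#'   [sibhudu_level_counts()].
#' @param nominal_group_probs optional named list: per nominal variable,
#'   an `n_groups x n_levels` matrix of group-conditional probabilities
#'   (overrides `level_probs` for that variable).
#' @param seed RNG seed.
#' @return A list of class `assemblage_config`.
#' @export
assemblage_config <- function(n_per_group = 100, n_groups = 4,
                              shift_per_group = 0, shift_dims = 1:3,
                              dispersion_scale_per_group = 1,
                              latent_corr = NULL, missing_rate = 0,
                              schema = sibhudu_schema(),
                              level_probs = NULL,
                              nominal_group_probs = NULL, seed = NULL) {
  n_per_group <- rep_len(as.integer(n_per_group), n_groups)
  dispersion <- rep_len(dispersion_scale_per_group, n_groups)
  stopifnot(all(n_per_group >= 1), all(dispersion > 0),
            missing_rate >= 0, missing_rate < 1)

  cont <- schema$name[schema$scale == "continuous"]
  ordv <- schema$name[schema$scale == "ordinal"]
  # one latent dimension per continuous + ordinal variable, geometry first
  latent_vars <- c(schema$name[schema$geometry],
                   setdiff(cont, schema$name[schema$geometry]), ordv)
  d <- length(latent_vars)

  if (is.null(latent_corr)) {
    latent_corr <- matrix(0.1, d, d)
    ng <- sum(schema$geometry)
    if (ng > 1) latent_corr[1:ng, 1:ng] <- 0.3
    diag(latent_corr) <- 1
  }
  if (nrow(latent_corr) != d || ncol(latent_corr) != d) {
    stop("latent_corr must be ", d, " x ", d,
         " (one dimension per continuous + ordinal variable)",
         call. = FALSE)
  }
  if (max(abs(latent_corr - t(latent_corr))) > 1e-8 ||
      min(eigen(latent_corr, symmetric = TRUE,
                only.values = TRUE)$values) < -1e-8) {
    stop("latent_corr must be a symmetric positive semi-definite ",
         "correlation matrix", call. = FALSE)
  }

  if (is.matrix(shift_per_group)) {
    stopifnot(nrow(shift_per_group) == n_groups,
              ncol(shift_per_group) == d)
    shifts <- shift_per_group
  } else {
    offsets <- if (length(shift_per_group) == 1L) {
      (seq_len(n_groups) - 1) * shift_per_group
    } else {
      rep_len(shift_per_group, n_groups)
    }
    shifts <- matrix(0, n_groups, d)
    shifts[, shift_dims] <- offsets
  }

  if (is.null(level_probs)) {
    counts <- sibhudu_level_counts()
    level_probs <- lapply(counts, function(x) x / sum(x))
  }
  for (v in c(ordv, schema$name[schema$scale == "nominal"])) {
    if (is.null(level_probs[[v]])) {
      k <- length(schema_var(schema, v)$levels)
      level_probs[[v]] <- rep(1 / k, k)
    }
  }

  structure(list(
    n_per_group = n_per_group, n_groups = n_groups, schema = schema,
    latent_vars = latent_vars, latent_corr = latent_corr, shifts = shifts,
    dispersion = dispersion, missing_rate = missing_rate,
    level_probs = level_probs, nominal_group_probs = nominal_group_probs,
    seed = seed
  ), class = "assemblage_config")
}

# Affine/log-normal links mapping a standard latent value to a variable on
# its natural measurement scale; magnitudes chosen to resemble typical
# flake measurements (lengths in mm, angles in degrees, cortex in %).
continuous_link <- function(var, z) {
  switch(var,
    LEN = exp(3.45 + 0.30 * z),
    WID = exp(3.35 + 0.30 * z),
    THI = exp(2.05 + 0.35 * z),
    PWI = exp(2.80 + 0.40 * z),
    PTH = exp(1.75 + 0.45 * z),
    CPE = pmin(100, pmax(0, 45 * z - 10)),
    EPA = 82 + 8 * z,
    20 + 5 * z  # generic continuous variable
  )
}

#' Simulate a synthetic assemblage
#'
#' @param cfg an [assemblage_config()].
#' @return A list with elements `table` (a `flake_table`, after MCAR
#'   masking) and `truth` (group means and dispersion multipliers in
#'   latent space, the ordinal thresholds used, and the complete
#'   pre-missingness table).
#' @export
simulate_assemblage <- function(cfg) {
  stopifnot(inherits(cfg, "assemblage_config"))
  with_seed(cfg$seed, {
    schema <- cfg$schema
    n <- sum(cfg$n_per_group)
    group <- factor(rep(seq_len(cfg$n_groups), cfg$n_per_group))
    d <- length(cfg$latent_vars)

    L <- chol(cfg$latent_corr + diag(1e-10, d))
    Z <- matrix(stats::rnorm(n * d), n, d) %*% L
    Z <- Z * cfg$dispersion[as.integer(group)]
    Z <- Z + cfg$shifts[as.integer(group), , drop = FALSE]
    colnames(Z) <- cfg$latent_vars

    out <- data.frame(row.names = seq_len(n))
    thresholds <- list()
    for (i in seq_len(nrow(schema))) {
      v <- schema$name[i]
      if (schema$scale[i] == "continuous") {
        out[[v]] <- continuous_link(v, Z[, v])
      } else if (schema$scale[i] == "ordinal") {
        p <- cfg$level_probs[[v]]
        cuts <- stats::qnorm(cumsum(p)[-length(p)])
        thresholds[[v]] <- cuts
        lev <- schema$levels[[i]]
        out[[v]] <- lev[findInterval(Z[, v], cuts) + 1L]
      } else {
        gp <- cfg$nominal_group_probs[[v]]
        lev <- schema$levels[[i]]
        if (is.null(gp)) {
          out[[v]] <- sample(lev, n, replace = TRUE,
                             prob = cfg$level_probs[[v]])
        } else {
          stopifnot(nrow(gp) == cfg$n_groups, ncol(gp) == length(lev))
          out[[v]] <- vapply(seq_len(n), function(j) {
            sample(lev, 1L, prob = gp[as.integer(group[j]), ])
          }, "")
        }
      }
    }
    out$group <- group
    complete <- flake_table(out, schema,
                            group_levels = levels(group))
    tab <- if (cfg$missing_rate > 0) {
      inject_missing(complete, cfg$missing_rate)
    } else {
      complete
    }
    list(table = tab,
         truth = list(group_means = cfg$shifts,
                      dispersion = cfg$dispersion,
                      thresholds = thresholds,
                      complete = complete))
  })
}

#' Mask cells completely at random
#'
#' Each attribute cell is independently set missing with probability
#' `rate`; group labels are never masked.
#'
#' @param table a `flake_table`.
#' @param rate per-cell missingness probability in `[0, 1)`.
#' @param seed optional RNG seed.
#' @return The masked `flake_table`.
#' @export
inject_missing <- function(table, rate, seed = NULL) {
  stopifnot(rate >= 0, rate < 1)
  if (rate == 0) return(table)
  with_seed(seed, {
    vars <- schema_names(tbl_schema(table))
    n <- nrow(table)
    for (v in vars) {
      table[[v]][stats::runif(n) < rate] <- NA
    }
    table
  })
}
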