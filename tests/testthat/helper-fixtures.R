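# Fixture builders shared across the suite.  Everything is generated in
# code; nothing is read from disk except through temp files written here.

# minimal 3-scale schema: one geometry-free continuous, two geometry
# measurements, one ordinal, one nominal
mini_schema <- function() {
  variable_schema(
    name = c("EPA", "LEN", "WID", "BUL", "PTY"),
    scale = c("continuous", "continuous", "continuous", "ordinal",
              "nominal"),
    levels = list(NULL, NULL, NULL,
                  c("Absent", "Developed", "Well-developed"),
                  c("Plain", "Facetted", "Linear/punctiform")),
    geometry = c(FALSE, TRUE, TRUE, FALSE, FALSE)
  )
}

mini_table <- function(n = 30, seed = 1, missing_rate = 0) {
  with_seed_local(seed, {
    df <- data.frame(
      EPA = rnorm(n, 80, 5),
      LEN = exp(rnorm(n, 3.4, 0.3)),
      WID = exp(rnorm(n, 3.3, 0.3)),
      BUL = sample(c("Absent", "Developed", "Well-developed"), n, TRUE),
      PTY = sample(c("Plain", "Facetted", "Linear/punctiform"), n, TRUE),
      group = rep(c("1", "2"), length.out = n)
    )
    tab <- flake_table(df, mini_schema())
    if (missing_rate > 0) tab <- inject_missing(tab, missing_rate)
    tab
  })
}

# all-continuous schema/table for PCA oracle comparisons
cont_schema <- function(p = 4) {
  variable_schema(name = paste0("V", seq_len(p)),
                  scale = rep("continuous", p))
}

cont_table <- function(n = 50, p = 4, seed = 1, corr = 0.5) {
  with_seed_local(seed, {
    S <- matrix(corr, p, p)
    diag(S) <- 1
    X <- matrix(rnorm(n * p), n, p) %*% chol(S)
    df <- as.data.frame(X)
    names(df) <- paste0("V", seq_len(p))
    df$group <- rep(c("a", "b"), length.out = n)
    flake_table(df, cont_schema(p))
  })
}

# seed-scoped RNG without touching the caller's stream
with_seed_local <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  code
}

# draw an ordinal pair from a latent bivariate normal with given rho and
# equal-probability thresholds per margin
latent_ordinal_pair <- function(n, rho, k = 5, seed = 1) {
  with_seed_local(seed, {
    z1 <- rnorm(n)
    z2 <- rho * z1 + sqrt(1 - rho^2) * rnorm(n)
    cuts <- qnorm(seq_len(k - 1) / k)
    cbind(findInterval(z1, cuts), findInterval(z2, cuts))
  })
}
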