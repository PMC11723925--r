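# End-to-end orchestration: filter -> shape transform -> heterogeneous
# correlations -> resemblance -> pairwise inference -> dispersion
# profile, for the main analysis and its sensitivity variants.

VARIANTS <- c("main", "complete_cases", "no_size_correction",
              "exclude_raw_material", "dolerite_only",
              "group_by_raw_material")

#' Run one analysis variant end-to-end
#'
#' Executes the full pipeline on an artefact table: record filtering
#' (group attribution plus the missingness cap), geometric-mean shape
#' transform of the geometry measurements, heterogeneous correlation
#' matrix, multiple-imputation resemblance analysis, balanced pairwise
#' PERMANOVA/PERMDISP contrasts with Bonferroni correction, and the
#' distance-to-centroid dispersion profile.  Variants modify the main
#' run: `complete_cases` admits no missing cells;
#' `no_size_correction` skips the shape transform;
#' `exclude_raw_material` drops the raw-material variable;
#' `dolerite_only` restricts to dolerite objects (and then drops the
#' constant raw-material variable); `group_by_raw_material` swaps the
#' grouping from phase to raw material (dropping raw material from the
#' attributes).
#'
#' @param table a `flake_table` (e.g. from [read_flake_table()] or
#'   [simulate_assemblage()]).
#' @param variant one of `"main"`, `"complete_cases"`,
#'   `"no_size_correction"`, `"exclude_raw_material"`,
#'   `"dolerite_only"`, `"group_by_raw_material"`.
#' @param max_missing_fraction missingness cap for the main filter
#'   (default 0.20; forced to 0 by `complete_cases`).
#' @param n_iterations imputed datasets for the resemblance step
#'   (default 1000).
#' @param n_perm permutations per test (default 1000).
#' @param ci_level interval level (default 0.95).
#' @param seed RNG seed (default 1); drives imputation, down-sampling
#'   and permutations.
#' @param out_dir optional directory: when given, all tables and a JSON
#'   run manifest are written there.
#' @param raw_material_var name of the raw-material variable (default
#'   `"RMA"`).
#' @param raw_material_keep level kept by `dolerite_only` (default
#'   `"Dolerite"`).
#' @param hetcor compute the heterogeneous correlation matrix (default
#'   TRUE; the slowest descriptive step).
#' @param quiet suppress stage messages.
#' @return List of class `variant_result`: `variant`, `counts`
#'   (retained per group), `hetcor`, `flexdist`, `tests`, `dispersion`,
#'   `manifest`.
#' @export
run_variant <- function(table, variant = "main",
                        max_missing_fraction = 0.20, n_iterations = 1000,
                        n_perm = 1000, ci_level = 0.95, seed = 1,
                        out_dir = NULL, raw_material_var = "RMA",
                        raw_material_keep = "Dolerite", hetcor = TRUE,
                        quiet = FALSE) {
  variant <- match.arg(variant, VARIANTS)
  t0 <- Sys.time()
  say <- function(...) if (!quiet) message("[", variant, "] ", ...)

  frac <- if (variant == "complete_cases") 0 else max_missing_fraction

  if (variant == "dolerite_only") {
    if (!raw_material_var %in% names(table)) {
      stop("variant 'dolerite_only': variable '", raw_material_var,
           "' not present", call. = FALSE)
    }
    table <- subset_rows(table, !is.na(table[[raw_material_var]]) &
                           table[[raw_material_var]] == raw_material_keep)
    table <- drop_variables(table, raw_material_var)
    say("restricted to ", raw_material_keep, ": ", nrow(table), " records")
  }
  if (variant == "exclude_raw_material") {
    table <- drop_variables(table, raw_material_var)
  }
  if (variant == "group_by_raw_material") {
    g <- as.character(table[[raw_material_var]])
    table <- drop_variables(table, raw_material_var)
    table[[tbl_group_col(table)]] <- factor(g)
  }

  filtered <- filter_flakes(table, max_missing_fraction = frac,
                            quiet = quiet)
  if (nrow(filtered) == 0) {
    stop("stage 'filter': no records retained", call. = FALSE)
  }
  counts <- attr(filtered, "retained_by_group")

  analysed <- if (variant == "no_size_correction") filtered
  else to_shape_variables(filtered)
  say("shape transform ",
      if (variant == "no_size_correction") "skipped" else "applied")

  hc <- NULL
  if (hetcor) {
    say("heterogeneous correlation matrix ...")
    hc <- hetero_corr_matrix(analysed)
  }

  say("resemblance analysis (", n_iterations, " iterations) ...")
  fx <- run_flexdist(analysed, n_iterations = n_iterations,
                     ci_level = ci_level, seed = seed)

  say("pairwise tests (", n_perm, " permutations) ...")
  tests <- pairwise_tests(fx$distances$median, tbl_groups(analysed),
                          n_perm = n_perm, seed = seed)
  disp <- dist_to_group_centroid(fx$distances$median,
                                 tbl_groups(analysed))

  manifest <- list(
    variant = variant, n_input = nrow(table), n_analysed = nrow(filtered),
    counts_by_group = as.list(counts),
    max_missing_fraction = frac, n_iterations = n_iterations,
    n_perm = n_perm, ci_level = ci_level, seed = seed,
    r_version = as.character(getRversion()),
    package_version = as.character(utils::packageVersion("morphodist")),
    elapsed_sec = as.numeric(difftime(Sys.time(), t0, units = "secs"))
  )

  res <- structure(list(variant = variant, counts = counts, hetcor = hc,
                        flexdist = fx, tests = tests, dispersion = disp,
                        table = analysed, manifest = manifest),
                   class = "variant_result")
  if (!is.null(out_dir)) export_variant(res, out_dir)
  res
}

#' @export
print.variant_result <- function(x, ...) {
  cat("Variant '", x$variant, "': ", sum(x$counts), " records (",
      paste(sprintf("%s=%d", names(x$counts), as.integer(x$counts)),
            collapse = ", "), ")\n", sep = "")
  pv <- x$flexdist$ordination$pct_variance
  cat(sprintf("PC1 + PC2 variance: %.1f%%\n",
              sum(pv[seq_len(min(2, length(pv)))])))
  print(x$tests[, c("pair", "test", "n", "F", "R2", "p",
                    "bonferroni_sig")], digits = 4, row.names = FALSE)
  invisible(x)
}

export_variant <- function(res, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write_flake_table(res$table, file.path(out_dir, "analysed_table.csv"))
  write_flake_summary(summarize_flakes(res$table), out_dir)
  if (!is.null(res$hetcor)) write_hetcor(res$hetcor, out_dir)
  write_flexdist(res$flexdist, out_dir)
  utils::write.csv(res$tests, file.path(out_dir, "pairwise_tests.csv"),
                   row.names = FALSE)
  utils::write.csv(res$dispersion$profile,
                   file.path(out_dir, "dispersion_profile.csv"),
                   row.names = FALSE)
  utils::write.csv(res$dispersion$group_summary,
                   file.path(out_dir, "dispersion_summary.csv"),
                   row.names = FALSE)
  jsonlite::write_json(res$manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(out_dir)
}

#' Render a report from exported variant tables
#'
#' Reads the CSV exports of [run_variant()] from a directory and writes
#' `report.md` summarising them, plus (when ggplot2 is available) PNG
#' panels: eigenvalue bars, the ordination scatter with group
#' centroids, a correlation-matrix heatmap, the correlation-circle
#' arrows, jittered distance-to-centroid distributions and the pairwise
#' test table.  Missing exports are listed in the report; the report is
#' still produced.
#'
#' @param dir directory containing the exports of one variant.
#' @return Invisibly, the path to `report.md`.
#' @export
make_report <- function(dir) {
  path <- function(f) file.path(dir, f)
  have <- function(f) file.exists(path(f))
  lines <- c("# Analysis report", "")
  missing_exports <- character(0)

  if (have("manifest.json")) {
    mf <- jsonlite::read_json(path("manifest.json"))
    lines <- c(lines,
               sprintf("Variant: **%s** | records analysed: %s | seed: %s",
                       mf$variant, mf$n_analysed, mf$seed), "")
  } else missing_exports <- c(missing_exports, "manifest.json")

  has_gg <- requireNamespace("ggplot2", quietly = TRUE)
  figs <- character(0)
  save_fig <- function(p, name) {
    f <- path(name)
    ggplot2::ggsave(f, p, width = 6, height = 4.5, dpi = 120)
    figs <<- c(figs, name)
  }

  if (have("eigenvalues.csv")) {
    ev <- utils::read.csv(path("eigenvalues.csv"))
    lines <- c(lines, sprintf("PC1 + PC2 variance: %.1f%%",
                              sum(ev$pct_variance[1:min(2, nrow(ev))])), "")
    if (has_gg) {
      save_fig(ggplot2::ggplot(ev, ggplot2::aes(pc, pct_variance)) +
                 ggplot2::geom_col() +
                 ggplot2::labs(x = "PC", y = "% variance"),
               "fig_eigenvalues.png")
    }
  } else missing_exports <- c(missing_exports, "eigenvalues.csv")

  if (have("object_centroids.csv")) {
    oc <- utils::read.csv(path("object_centroids.csv"))
    if (has_gg) {
      p <- ggplot2::ggplot(oc, ggplot2::aes(pc1, pc2,
                                            colour = factor(group))) +
        ggplot2::geom_point(size = 0.6, alpha = 0.6) +
        ggplot2::labs(colour = "group")
      if (have("group_centroids.csv")) {
        gc <- utils::read.csv(path("group_centroids.csv"))
        p <- p + ggplot2::geom_point(data = gc, shape = 15, size = 3)
      }
      save_fig(p, "fig_ordination.png")
    }
  } else missing_exports <- c(missing_exports, "object_centroids.csv")

  if (have("hetcor_long.csv")) {
    hl <- utils::read.csv(path("hetcor_long.csv"))
    if (has_gg) {
      save_fig(ggplot2::ggplot(hl, ggplot2::aes(var1, var2, fill = rho)) +
                 ggplot2::geom_tile() +
                 ggplot2::scale_fill_gradient2(limits = c(-1, 1)) +
                 ggplot2::theme(axis.text.x =
                                  ggplot2::element_text(angle = 90)),
               "fig_hetcor.png")
    }
  } else missing_exports <- c(missing_exports, "hetcor_long.csv")

  if (have("correlation_circle.csv")) {
    cc <- utils::read.csv(path("correlation_circle.csv"))
    if (has_gg) {
      save_fig(ggplot2::ggplot(cc) +
                 ggplot2::geom_segment(
                   ggplot2::aes(x = 0, y = 0, xend = pc1, yend = pc2),
                   arrow = grid::arrow(length = grid::unit(2, "mm"))) +
                 ggplot2::geom_text(ggplot2::aes(pc1, pc2, label = column),
                                    size = 2, vjust = -0.5) +
                 ggplot2::coord_equal(xlim = c(-1, 1), ylim = c(-1, 1)),
               "fig_correlation_circle.png")
    }
  } else missing_exports <- c(missing_exports, "correlation_circle.csv")

  if (have("dispersion_profile.csv")) {
    dp <- utils::read.csv(path("dispersion_profile.csv"))
    if (has_gg) {
      save_fig(ggplot2::ggplot(dp, ggplot2::aes(factor(group), distance)) +
                 ggplot2::geom_jitter(width = 0.25, size = 0.4,
                                      alpha = 0.4) +
                 ggplot2::stat_summary(fun = stats::median,
                                       geom = "point", colour = "red") +
                 ggplot2::labs(x = "group", y = "distance to centroid"),
               "fig_dispersion.png")
    }
  } else missing_exports <- c(missing_exports, "dispersion_profile.csv")

  if (have("pairwise_tests.csv")) {
    pt <- utils::read.csv(path("pairwise_tests.csv"))
    lines <- c(lines, "## Pairwise tests", "",
               "| pair | test | n | df | F | R2 | p | sig |",
               "|---|---|---|---|---|---|---|---|",
               sprintf("| %s | %s | %d | %d; %d | %.4f | %.4f | %.4g | %s |",
                       pt$pair, pt$test, pt$n, pt$df_model, pt$df_resid,
                       pt$F, pt$R2, pt$p,
                       ifelse(pt$bonferroni_sig, "*", "")), "")
  } else missing_exports <- c(missing_exports, "pairwise_tests.csv")

  if (length(figs)) {
    lines <- c(lines, "## Figures", "",
               sprintf("![](%s)", figs), "")
  }
  if (length(missing_exports)) {
    lines <- c(lines, "## Missing exports", "",
               paste("-", missing_exports), "")
  }
  writeLines(lines, path("report.md"))
  invisible(path("report.md"))
}
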