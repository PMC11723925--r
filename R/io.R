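# Artefact table construction, validation, filtering and the
# geometric-mean shape transform.

MISSING_TOKENS <- c("", "NA", "N/A", "NA´s", "NA's", "na", ".")

#' Build a validated artefact table
#'
#' An artefact (flake) table is a data frame with one row per object, one
#' column per schema variable and a group (phase) column.  Continuous
#' variables are numeric; ordinal and nominal variables are factors with
#' the schema's levels (ordered for ordinal variables).  Missing cells
#' are `NA`.
#'
#' @param data data frame containing all schema variables and the group
#'   column.  Categorical values may be given as level labels or as the
#'   schema's numeric codes.
#' @param schema a [variable_schema()].
#' @param group_col name of the group column (default `"group"`).
#' @param group_levels optional ordered vector of group labels; defaults
#'   to the sorted unique observed labels.
#' @return A data frame of class `flake_table` with attributes `schema`
#'   and `group_col`.
#' @export
flake_table <- function(data, schema, group_col = "group",
                        group_levels = NULL) {
  missing_cols <- setdiff(c(schema$name, group_col), names(data))
  if (length(missing_cols)) {
    stop("missing required column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  out <- data.frame(row.names = seq_len(nrow(data)))
  for (i in seq_len(nrow(schema))) {
    nm <- schema$name[i]
    out[[nm]] <- parse_column(data[[nm]], schema_var(schema, nm))
  }
  g <- data[[group_col]]
  g <- as.character(g)
  g[g %in% MISSING_TOKENS] <- NA
  if (is.null(group_levels)) {
    group_levels <- sort(unique(g[!is.na(g)]))
  }
  out[[group_col]] <- factor(g, levels = group_levels)
  attr(out, "schema") <- schema
  attr(out, "group_col") <- group_col
  class(out) <- c("flake_table", "data.frame")
  out
}

# Parse one raw column by its declared scale.  Continuous: unparseable
# tokens become NA.  Categorical: values are matched against codes first,
# then labels; anything else is a validation error naming the rows.
parse_column <- function(x, var) {
  x <- as.character(x)
  x[x %in% MISSING_TOKENS] <- NA
  if (var$scale == "continuous") {
    suppressWarnings(as.numeric(x))
  } else {
    idx <- match(x, var$codes)
    lab <- match(x, var$levels)
    idx[is.na(idx)] <- lab[is.na(idx)]
    bad <- which(!is.na(x) & is.na(idx))
    if (length(bad)) {
      stop("variable '", var$name, "': value(s) outside declared levels ",
           "at row(s) ", paste(utils::head(bad, 5), collapse = ", "),
           if (length(bad) > 5) " ..." else "",
           " (e.g. '", x[bad[1]], "')", call. = FALSE)
    }
    factor(var$levels[idx], levels = var$levels,
           ordered = var$scale == "ordinal")
  }
}

tbl_schema <- function(table) {
  s <- attr(table, "schema")
  if (is.null(s)) stop("not a validated flake table (no schema attribute)",
                       call. = FALSE)
  s
}

tbl_group_col <- function(table) attr(table, "group_col") %||% "group"

`%||%` <- function(a, b) if (is.null(a)) b else a

tbl_groups <- function(table) table[[tbl_group_col(table)]]

# Keep flake_table class and attributes through row subsetting.
subset_rows <- function(table, keep) {
  out <- table[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "schema") <- attr(table, "schema")
  attr(out, "group_col") <- attr(table, "group_col")
  class(out) <- class(table)
  out
}

# Drop schema variables (and their columns) from a table.
drop_variables <- function(table, vars) {
  schema <- tbl_schema(table)
  keep <- !(schema$name %in% vars)
  new_schema <- schema[keep, , drop = FALSE]
  class(new_schema) <- class(schema)
  out <- table[, c(new_schema$name, tbl_group_col(table)), drop = FALSE]
  attr(out, "schema") <- new_schema
  attr(out, "group_col") <- tbl_group_col(table)
  class(out) <- class(table)
  out
}

#' Read an artefact table from CSV
#'
#' Cells are parsed according to the declared scale of each schema
#' variable; empty strings and `NA`-style tokens become missing.  Row
#' order is preserved.
#'
#' @inheritParams flake_table
#' @param path path to a delimited text file with a header row.
#' @param sep field separator (default `","`).
#' @return A `flake_table`.
#' @export
read_flake_table <- function(path, schema, group_col = "group",
                             group_levels = NULL, sep = ",") {
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           colClasses = "character", check.names = FALSE,
                           na.strings = NULL, quote = "\"",
                           fileEncoding = "UTF-8")
  flake_table(raw, schema, group_col = group_col,
              group_levels = group_levels)
}

#' @rdname read_flake_table
#' @param table a `flake_table`.
#' @export
write_flake_table <- function(table, path) {
  utils::write.csv(as.data.frame(table), path, row.names = FALSE, na = "")
  invisible(path)
}

#' Per-object missing-cell counts over the schema variables
#' @param table a `flake_table`.
#' @return Integer vector, one count per record.
#' @export
missing_counts <- function(table) {
  vars <- schema_names(tbl_schema(table))
  rowSums(is.na(table[, vars, drop = FALSE]))
}

#' Maximum number of missing variables admitted by a proportional cap
#'
#' With 16 variables and a 20% cap this is 3: the largest integer not
#' exceeding `fraction * n_vars`.
#'
#' @param n_vars number of attribute variables (>= 1).
#' @param fraction maximum missing proportion in `[0, 1]`.
#' @return Integer count.
#' @export
#' @examples
#' max_missing_count(16, 0.20)  # 3
max_missing_count <- function(n_vars, fraction) {
  stopifnot(n_vars >= 1, fraction >= 0, fraction <= 1)
  # round() guards against 0.2 * 15 = 3.0000000000000004-style FP noise
  as.integer(floor(round(fraction * n_vars, 9)))
}

#' Filter records by group attribution and missingness
#'
#' Retains records that carry a group label (if required) and have no
#' more than `max_missing_count(n_vars, max_missing_fraction)` missing
#' attribute cells.
#'
#' @param table a `flake_table`.
#' @param max_missing_fraction proportion in `[0, 1]`; default 0.20.
#' @param require_group drop records without a group label (default TRUE).
#' @param quiet suppress the per-group retention message.
#' @return The filtered `flake_table`, with attribute `retained_by_group`
#'   (a named count table).
#' @export
filter_flakes <- function(table, max_missing_fraction = 0.20,
                          require_group = TRUE, quiet = FALSE) {
  schema <- tbl_schema(table)
  cap <- max_missing_count(nrow(schema), max_missing_fraction)
  keep <- missing_counts(table) <= cap
  if (require_group) keep <- keep & !is.na(tbl_groups(table))
  out <- subset_rows(table, keep)
  counts <- table(tbl_groups(out))
  if (!quiet) {
    message("retained ", nrow(out), " of ", nrow(table), " records (",
            paste(sprintf("%s=%d", names(counts), as.integer(counts)),
                  collapse = ", "), ")")
  }
  if (nrow(out) == 0L) {
    warning("filtering removed every record", call. = FALSE)
  }
  attr(out, "retained_by_group") <- counts
  out
}

#' Convert geometry measurements to scale-free shape variables
#'
#' Each geometry measurement of a record is divided by the geometric mean
#' of that record's geometry measurements, removing gross size so that
#' objects of different sizes but similar proportions become comparable.
#' By default the geometric mean is taken over the non-missing geometry
#' values of the record, so partially measured (broken) objects remain
#' size-corrected; with `partial = FALSE` records with any missing
#' geometry cell are left untransformed.
#'
#' @param table a `flake_table` whose schema flags geometry variables.
#' @param partial use the geometric mean of the observed subset for
#'   records with missing geometry cells (default TRUE).
#' @return The transformed `flake_table`.
#' @export
to_shape_variables <- function(table, partial = TRUE) {
  schema <- tbl_schema(table)
  gvars <- schema$name[schema$geometry]
  if (length(gvars) == 0L) return(table)
  G <- as.matrix(table[, gvars, drop = FALSE])
  if (any(G <= 0, na.rm = TRUE)) {
    stop("non-positive geometry measurement: geometric mean undefined",
         call. = FALSE)
  }
  n_obs <- rowSums(!is.na(G))
  gm <- exp(rowSums(log(G), na.rm = TRUE) / pmax(n_obs, 1L))
  use <- if (partial) n_obs > 0L else n_obs == length(gvars)
  G[use, ] <- G[use, , drop = FALSE] / gm[use]
  for (v in gvars) table[[v]] <- G[, v]
  table
}

#' Summary statistics per variable
#'
#' Continuous variables get min / quartiles / median / mean / max and the
#' missing count; ordinal and nominal variables get per-level counts and
#' the missing count.
#'
#' @param table a `flake_table`.
#' @return A list of class `flake_summary` with elements `continuous`
#'   (data frame of the six summary statistics plus `n_missing`) and
#'   `levels` (long data frame `variable`, `level`, `count`, including an
#'   `<NA>` row per variable).
#' @export
summarize_flakes <- function(table) {
  schema <- tbl_schema(table)
  cont <- schema$name[schema$scale == "continuous"]
  cat_ <- schema$name[schema$scale != "continuous"]
  cs <- do.call(rbind, lapply(cont, function(v) {
    x <- table[[v]]
    ok <- !is.na(x)
    if (!any(ok)) {
      data.frame(variable = v, min = NA_real_, q1 = NA_real_,
                 median = NA_real_, mean = NA_real_, q3 = NA_real_,
                 max = NA_real_, n_missing = sum(!ok))
    } else {
      q <- stats::quantile(x[ok], c(0.25, 0.75))
      data.frame(variable = v, min = min(x[ok]), q1 = unname(q[1]),
                 median = stats::median(x[ok]), mean = mean(x[ok]),
                 q3 = unname(q[2]), max = max(x[ok]), n_missing = sum(!ok))
    }
  }))
  ls_ <- do.call(rbind, lapply(cat_, function(v) {
    x <- table[[v]]
    cnt <- table(x, useNA = "always")
    data.frame(variable = v,
               level = ifelse(is.na(names(cnt)) | names(cnt) == "",
                              "<NA>", names(cnt)),
               count = as.integer(cnt))
  }))
  structure(list(continuous = cs, levels = ls_, n = nrow(table)),
            class = "flake_summary")
}

#' @export
print.flake_summary <- function(x, ...) {
  cat("Summary of", x$n, "records\n\nContinuous variables:\n")
  print(x$continuous, row.names = FALSE, digits = 4)
  cat("\nCategorical variables:\n")
  for (v in unique(x$levels$variable)) {
    sub <- x$levels[x$levels$variable == v, ]
    cat(sprintf("  %-4s %s\n", v,
                paste(sprintf("%s=%d", sub$level, sub$count),
                      collapse = "; ")))
  }
  invisible(x)
}

#' @rdname summarize_flakes
#' @param summary a `flake_summary`.
#' @param dir directory in which to write `summary_continuous.csv` and
#'   `summary_levels.csv`.
#' @export
write_flake_summary <- function(summary, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(summary$continuous,
                   file.path(dir, "summary_continuous.csv"),
                   row.names = FALSE)
  utils::write.csv(summary$levels, file.path(dir, "summary_levels.csv"),
                   row.names = FALSE)
  invisible(dir)
}
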