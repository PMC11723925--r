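#' Declare a mixed-scale variable schema
#'
#' A schema lists, for every attribute column of an artefact table, its
#' measurement scale and (for ordinal/nominal variables) the admissible
#' levels.  Five continuous variables may be flagged as overall-geometry
#' measurements; these are the ones divided by their per-object geometric
#' mean when converting sizes to scale-free shape variables.
#'
#' @param name character vector of unique short variable labels.
#' @param scale character vector, each one of `"continuous"`, `"ordinal"`,
#'   `"nominal"`.
#' @param levels list of character vectors (level labels, ordered for
#'   ordinal variables); entries for continuous variables must be `NULL`.
#' @param codes list of character vectors of the same lengths as `levels`,
#'   giving the numeric codes under which levels may be recorded in input
#'   files (e.g. `"1"` for `"Dolerite"`); `NULL` entries default to
#'   `1, 2, ...` per level.
#' @param geometry logical vector flagging the geometry measurements.
#'
#' @return An object of class `morpho_schema`: a data frame with columns
#'   `name`, `scale`, `geometry` and list-columns `levels`, `codes`.
#' @export
#' @examples
#' variable_schema(
#'   name = c("LEN", "BUL"),
#'   scale = c("continuous", "ordinal"),
#'   levels = list(NULL, c("Absent", "Present")),
#'   geometry = c(TRUE, FALSE)
#' )
variable_schema <- function(name, scale, levels = NULL, codes = NULL,
                            geometry = FALSE) {
  name <- as.character(name)
  scale <- match.arg(as.character(scale),
                     c("continuous", "ordinal", "nominal"),
                     several.ok = TRUE)
  scale <- rep_len(scale, length(name))
  geometry <- rep_len(as.logical(geometry), length(name))
  if (is.null(levels)) levels <- vector("list", length(name))
  if (is.null(codes)) codes <- vector("list", length(name))
  if (anyDuplicated(name)) {
    stop("schema variable names must be unique", call. = FALSE)
  }
  for (i in seq_along(name)) {
    if (scale[i] == "continuous") {
      if (!is.null(levels[[i]])) {
        stop("continuous variable '", name[i], "' must not declare levels",
             call. = FALSE)
      }
    } else {
      lv <- as.character(levels[[i]])
      if (length(lv) < 1L) {
        stop("variable '", name[i], "' (", scale[i],
             ") must declare at least one level", call. = FALSE)
      }
      if (anyDuplicated(lv)) {
        stop("duplicated levels for variable '", name[i], "'", call. = FALSE)
      }
      levels[[i]] <- lv
      if (is.null(codes[[i]])) {
        codes[[i]] <- as.character(seq_along(lv))
      } else {
        codes[[i]] <- as.character(codes[[i]])
        if (length(codes[[i]]) != length(lv)) {
          stop("codes/levels length mismatch for variable '", name[i], "'",
               call. = FALSE)
        }
      }
    }
    if (geometry[i] && scale[i] != "continuous") {
      stop("geometry variable '", name[i], "' must be continuous",
           call. = FALSE)
    }
  }
  out <- data.frame(name = name, scale = scale, geometry = geometry,
                    stringsAsFactors = FALSE)
  out$levels <- levels
  out$codes <- codes
  class(out) <- c("morpho_schema", "data.frame")
  out
}

#' @export
print.morpho_schema <- function(x, ...) {
  cat("Variable schema with", nrow(x), "variables",
      sprintf("(%d geometry)\n", sum(x$geometry)))
  for (i in seq_len(nrow(x))) {
    lv <- if (x$scale[i] == "continuous") "" else
      paste0(" [", paste(x$levels[[i]], collapse = ", "), "]")
    cat(sprintf("  %-4s %-10s%s%s\n", x$name[i], x$scale[i],
                if (x$geometry[i]) " (geometry)" else "", lv))
  }
  invisible(x)
}

schema_names <- function(schema) schema$name

schema_var <- function(schema, name) {
  i <- match(name, schema$name)
  if (is.na(i)) stop("unknown schema variable '", name, "'", call. = FALSE)
  list(name = schema$name[i], scale = schema$scale[i],
       levels = schema$levels[[i]], codes = schema$codes[[i]],
       geometry = schema$geometry[i])
}

#' Default 16-variable lithic flake schema
#'
#' The standard attribute set for unretouched flakes from the Sibhudu
#' sequence: five continuous geometry measurements (length, width,
#' thickness, platform width, platform thickness), percent dorsal cortex,
#' exterior platform angle, two ordinal variables (bulb expression, number
#' of dorsal negatives) and eight nominal variables (raw material, shape,
#' eraillure scar, lip, Hertzian cone, platform type, orientation of
#' dorsal negatives).
#'
#' @return A [variable_schema()] object with 16 variables.
#' @export
sibhudu_schema <- function() {
  variable_schema(
    name = c("RMA", "CPE", "LEN", "WID", "THI", "EPA", "SHA", "BUL",
             "ESC", "LIP", "HCO", "PTY", "PWI", "PTH", "NNU", "NOR"),
    scale = c("nominal", "continuous", "continuous", "continuous",
              "continuous", "continuous", "nominal", "ordinal",
              "nominal", "nominal", "nominal", "nominal",
              "continuous", "continuous", "ordinal", "nominal"),
    levels = list(
      c("Dolerite", "Hornfels", "Sandstone", "Quartzite", "Quartz"),
      NULL, NULL, NULL, NULL, NULL,
      c("Convergent", "Divergent", "Round/oval", "Parallel/sub-parallel",
        "Rectangular"),
      c("Absent", "Poor-developed", "Developed", "Shattered",
        "Well-developed"),
      c("Absent", "Present"),
      c("Absent", "Present"),
      c("Absent", "Present"),
      c("Cortical", "Plain", "Facetted", "Dihedral", "Crushed/shattered",
        "Linear/punctiform"),
      NULL, NULL,
      as.character(0:9),
      c("Parallel", "Opposed", "Convergent", "Orthogonal", "Centripetal")
    ),
    codes = list(
      as.character(1:5), NULL, NULL, NULL, NULL, NULL,
      as.character(1:5), as.character(1:5),
      c("0", "1"), c("0", "1"), c("0", "1"),
      as.character(1:6), NULL, NULL,
      as.character(0:9), as.character(1:5)
    ),
    geometry = c(FALSE, FALSE, TRUE, TRUE, TRUE, FALSE, FALSE, FALSE,
                 FALSE, FALSE, FALSE, FALSE, TRUE, TRUE, FALSE, FALSE)
  )
}

#' Observed level frequencies of the default flake schema
#'
#' Marginal level counts for the categorical variables of the default
#' 16-variable flake schema, as tabulated for the filtered Sibhudu flake
#' assemblage (n = 4,512).  They parameterise the defaults of the
#' synthetic-assemblage generator and the raw-material mixture
#' (dolerite-dominant at roughly 71%).
#'
#' @return Named list of named integer count vectors, one per categorical
#'   variable.
#' @export
sibhudu_level_counts <- function() {
  list(
    RMA = c(Dolerite = 3189L, Hornfels = 263L, Sandstone = 638L,
            Quartzite = 250L, Quartz = 172L),
    SHA = c("Convergent" = 725L, "Divergent" = 675L, "Round/oval" = 331L,
            "Parallel/sub-parallel" = 742L, "Rectangular" = 922L),
    BUL = c("Absent" = 692L, "Poor-developed" = 1107L, "Developed" = 1200L,
            "Shattered" = 996L, "Well-developed" = 476L),
    ESC = c(Absent = 4353L, Present = 159L),
    LIP = c(Absent = 4149L, Present = 363L),
    HCO = c(Absent = 4386L, Present = 126L),
    PTY = c("Cortical" = 302L, "Plain" = 2958L, "Facetted" = 505L,
            "Dihedral" = 364L, "Crushed/shattered" = 251L,
            "Linear/punctiform" = 85L),
    NNU = c("0" = 75L, "1" = 487L, "2" = 1256L, "3" = 1500L, "4" = 804L,
            "5" = 289L, "6" = 70L, "7" = 18L, "8" = 3L, "9" = 1L),
    NOR = c("Parallel" = 1281L, "Opposed" = 504L, "Convergent" = 153L,
            "Orthogonal" = 1024L, "Centripetal" = 820L)
  )
}

#' Read or write a schema as YAML
#'
#' The YAML document is a list of variable entries with fields `name`,
#' `scale` and, for categorical variables, `levels` (and optionally
#' `codes` and `geometry`).
#'
#' @param path file path.
#' @return `read_schema()` returns a [variable_schema()] object;
#'   `write_schema()` invisibly returns `path`.
#' @export
read_schema <- function(path) {
  doc <- yaml::read_yaml(path)
  variable_schema(
    name = vapply(doc, `[[`, "", "name"),
    scale = vapply(doc, `[[`, "", "scale"),
    levels = lapply(doc, function(v) {
      if (is.null(v$levels)) NULL else as.character(v$levels)
    }),
    codes = lapply(doc, function(v) {
      if (is.null(v$codes)) NULL else as.character(v$codes)
    }),
    geometry = vapply(doc, function(v) isTRUE(v$geometry), logical(1))
  )
}

#' @rdname read_schema
#' @param schema a [variable_schema()] object.
#' @export
write_schema <- function(schema, path) {
  doc <- lapply(seq_len(nrow(schema)), function(i) {
    v <- list(name = schema$name[i], scale = schema$scale[i])
    if (schema$scale[i] != "continuous") {
      v$levels <- as.list(schema$levels[[i]])
      v$codes <- as.list(schema$codes[[i]])
    }
    if (schema$geometry[i]) v$geometry <- TRUE
    v
  })
  yaml::write_yaml(doc, path)
  invisible(path)
}
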