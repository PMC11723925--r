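test_that("schema declares scales, levels and geometry flags", {
  s <- sibhudu_schema()
  expect_s3_class(s, "morpho_schema")
  expect_equal(nrow(s), 16)
  expect_equal(sum(s$geometry), 5)
  expect_setequal(s$name[s$geometry], c("LEN", "WID", "THI", "PWI", "PTH"))
  expect_false(anyDuplicated(s$name) > 0)
  # ordinal levels are ordered as declared
  expect_equal(schema_var <- s$levels[[match("NNU", s$name)]],
               as.character(0:9))
  expect_error(variable_schema("A", "ordinal", levels = list(NULL)),
               "at least one level")
  expect_error(variable_schema(c("A", "A"), "continuous"), "unique")
  expect_error(variable_schema("G", "nominal",
                               levels = list(c("x", "y")),
                               geometry = TRUE),
               "must be continuous")
})

test_that("schema round-trips through YAML", {
  f <- tempfile(fileext = ".yaml")
  write_schema(sibhudu_schema(), f)
  s2 <- read_schema(f)
  expect_equal(s2$name, sibhudu_schema()$name)
  expect_equal(s2$levels, sibhudu_schema()$levels)
  expect_equal(s2$geometry, sibhudu_schema()$geometry)
})

test_that("CSV parsing honours scales, codes and missing tokens", {
  s <- sibhudu_schema()
  hdr <- c(s$name, "group")
  row_of <- function(vals) paste(vals, collapse = ",")
  base <- c(RMA = "1", CPE = "10", LEN = "30", WID = "25", THI = "8",
            EPA = "80", SHA = "2", BUL = "3", ESC = "0", LIP = "1",
            HCO = "0", PTY = "2", PWI = "15", PTH = "5", NNU = "3",
            NOR = "1", group = "1")
  lines <- c(paste(hdr, collapse = ","),
             row_of(base),
             row_of(replace(base, "LEN", "")),
             row_of(replace(base, "RMA", "Hornfels")))
  f <- tempfile(fileext = ".csv")
  writeLines(lines, f)
  tab <- read_flake_table(f, s)
  expect_equal(nrow(tab), 3)
  expect_equal(sum(is.na(tab[, s$name])), 1)     # only the blank LEN
  expect_true(is.na(tab$LEN[2]))
  expect_equal(as.character(tab$RMA), c("Dolerite", "Dolerite", "Hornfels"))
  expect_true(is.ordered(tab$BUL))
  # value outside the declared levels is a validation error with row index
  bad <- c(lines[1], row_of(replace(base, "PTY", "7")))
  writeLines(bad, f)
  expect_error(read_flake_table(f, s), "PTY.*row")
  # missing required column
  expect_error(flake_table(data.frame(LEN = 1), s), "missing required")
})

test_that("missingness cap is the floor of the proportional threshold", {
  expect_identical(max_missing_count(16, 0.20), 3L)
  expect_identical(max_missing_count(16, 0), 0L)
  expect_identical(max_missing_count(10, 0.25), 2L)
  expect_identical(max_missing_count(15, 0.20), 3L)
})

test_that("filtering applies the cap, keeps labelled records, idempotent", {
  s <- mini_schema()
  df <- data.frame(EPA = c(80, NA, NA, NA), LEN = c(30, 30, NA, NA),
                   WID = c(25, 25, NA, NA), BUL = c("Absent", NA, NA, NA),
                   PTY = c("Plain", "Plain", "Plain", NA),
                   group = c("1", "1", "2", NA))
  tab <- flake_table(df, s)
  # missing counts 0, 2, 4, 5 over 5 vars; cap at 40% -> 2
  f1 <- filter_flakes(tab, 0.40, quiet = TRUE)
  expect_equal(nrow(f1), 2)
  f2 <- filter_flakes(f1, 0.40, quiet = TRUE)
  expect_equal(as.data.frame(f2), as.data.frame(f1))
  # zero tolerance keeps only complete labelled records
  expect_equal(nrow(filter_flakes(tab, 0, quiet = TRUE)), 1)
  expect_warning(filter_flakes(flake_table(df[3:4, ], s), 0, quiet = TRUE),
                 "every record")
})

test_that("shape conversion divides by the per-record geometric mean", {
  s <- variable_schema(paste0("G", 1:5), rep("continuous", 5),
                       geometry = rep(TRUE, 5))
  df <- data.frame(G1 = c(10, 2), G2 = c(10, 4), G3 = c(10, 8),
                   G4 = c(10, 16), G5 = c(10, 32), group = "1")
  tab <- to_shape_variables(flake_table(df, s))
  expect_equal(unlist(tab[1, 1:5], use.names = FALSE), rep(1, 5))
  expect_equal(unlist(tab[2, 1:5], use.names = FALSE),
               c(0.25, 0.5, 1, 2, 4))
  # scale invariance: multiplying a record by c > 0 changes nothing
  df2 <- df
  df2[2, 1:5] <- df2[2, 1:5] * 7.3
  tab2 <- to_shape_variables(flake_table(df2, s))
  expect_equal(as.data.frame(tab2), as.data.frame(tab))
  # product of shape values is 1 per record
  expect_equal(unname(apply(as.matrix(tab[, 1:5]), 1, prod)), c(1, 1))
  expect_error(to_shape_variables(flake_table(
    data.frame(G1 = -1, G2 = 1, G3 = 1, G4 = 1, G5 = 1, group = "1"), s)),
    "non-positive")
})

test_that("partial geometry records use the observed-subset geometric mean", {
  s <- variable_schema(paste0("G", 1:5), rep("continuous", 5),
                       geometry = rep(TRUE, 5))
  df <- data.frame(G1 = 2, G2 = 8, G3 = NA, G4 = NA, G5 = NA, group = "1")
  tab <- to_shape_variables(flake_table(df, s))          # gm(2, 8) = 4
  expect_equal(unlist(tab[1, 1:2], use.names = FALSE), c(0.5, 2))
  expect_true(all(is.na(tab[1, 3:5])))
  strict <- to_shape_variables(flake_table(df, s), partial = FALSE)
  expect_equal(unlist(strict[1, 1:2], use.names = FALSE), c(2, 8))
})

test_that("summaries partition every variable into level counts plus NA", {
  tab <- mini_table(40, seed = 2, missing_rate = 0.2)
  sm <- summarize_flakes(tab)
  for (v in unique(sm$levels$variable)) {
    expect_equal(sum(sm$levels$count[sm$levels$variable == v]), nrow(tab))
  }
  expect_equal(sm$continuous$n_missing,
               sapply(sm$continuous$variable,
                      function(v) sum(is.na(tab[[v]])), USE.NAMES = FALSE))
  # constant column
  s <- cont_schema(1)
  ctab <- flake_table(data.frame(V1 = rep(5, 4), group = "g"), s)
  cs <- summarize_flakes(ctab)$continuous
  expect_equal(c(cs$min, cs$mean, cs$max), c(5, 5, 5))
  # fully missing column is flagged with undefined statistics
  mtab <- flake_table(data.frame(V1 = rep(NA_real_, 4), group = "g"), s)
  ms <- summarize_flakes(mtab)$continuous
  expect_equal(ms$n_missing, 4)
  expect_true(is.na(ms$mean))
})

test_that("packaged schema and demo table load through the readers", {
  sy <- read_schema(system.file("extdata", "sibhudu_schema.yaml",
                                package = "morphodist"))
  expect_equal(sy$name, sibhudu_schema()$name)
  demo <- read_flake_table(
    system.file("extdata", "synthetic_flakes_demo.csv",
                package = "morphodist"), sy)
  expect_equal(nrow(demo), 46)
  expect_s3_class(demo$RMA, "factor")
  expect_true(all(levels(demo$group) == as.character(1:4)))
  kept <- filter_flakes(demo, quiet = TRUE)
  expect_true(all(missing_counts(kept) <= 3))
})
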