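test_that("a well-formed CSV reads into a validated panel", {
  df <- tiny_panel_df(c("a", "b", "c"), c(4, 17.5, 42))
  df[["Der p 23"]] <- c(0.5, 0, 12.3456)
  f <- withr::local_tempfile(fileext = ".csv")
  write_csv_lines(df, f)
  p <- read_panel(f)
  expect_s3_class(p, "hdm_panel")
  expect_equal(nrow(p), 3)
  expect_equal(p$id, c("a", "b", "c"))
  expect_equal(p[["Der p 23"]], c(0.5, 0, 12.3456))
})

test_that("header matching is case/space/underscore-insensitive and extras warn", {
  df <- tiny_panel_df("x", 10)
  names(df) <- c("ID", "Age", "tige", gsub(" ", "_", tolower(hdm_components())))
  df$extra_col <- 99
  f <- withr::local_tempfile(fileext = ".csv")
  write_csv_lines(df, f)
  expect_warning(p <- read_panel(f), "extra_col")
  expect_equal(names(p)[1:3], c("id", "age", "tIgE"))
  expect_false("extra_col" %in% names(p))
})

test_that("validation failures are fatal and name the offender", {
  df <- tiny_panel_df(c("a", "b"), c(5, 6))
  f <- withr::local_tempfile(fileext = ".csv")

  write_csv_lines(df[, setdiff(names(df), "Der p 23")], f)
  expect_error(read_panel(f), "Der p 23")

  df2 <- df
  df2[["Der f 2"]][2] <- -0.4
  write_csv_lines(df2, f)
  expect_error(read_panel(f), "b")

  df3 <- df
  df3$id <- c("dup", "dup")
  write_csv_lines(df3, f)
  expect_error(read_panel(f), "dup")

  df4 <- df
  df4[["Der p 5"]] <- c("0.5", "oops")
  write_csv_lines(df4, f)
  expect_error(read_panel(f), "Der p 5")

  # missing tIgE is tolerated, missing sIgE is not
  df5 <- df
  df5$tIgE <- c("", "250")
  write_csv_lines(df5, f)
  expect_identical(read_panel(f)$tIgE, c(NA, 250))
  df6 <- df
  df6[["Der p 21"]] <- c("", "0.2")
  write_csv_lines(df6, f)
  expect_error(read_panel(f), "Der p 21")
})

test_that("write_panel emits canonical header-only / 2-line files", {
  f <- withr::local_tempfile(fileext = ".csv")
  write_panel(hdm_panel(tiny_panel_df(character(0), numeric(0))), f)
  expect_length(readLines(f), 1)
  expect_equal(readLines(f)[1],
               paste(c("id", "age", "tIgE", hdm_components()), collapse = ","))
  write_panel(hdm_panel(tiny_panel_df("p1", 3)), f)
  expect_length(readLines(f), 2)
})

test_that("read/write round-trip is lossless at 4 decimals", {
  set.seed(31)
  p <- generate_cohort(cohort_config(1000, seed = 31))
  f1 <- withr::local_tempfile(fileext = ".csv")
  f2 <- withr::local_tempfile(fileext = ".csv")
  write_panel(p, f1)
  p2 <- read_panel(f1)
  write_panel(p2, f2)
  expect_identical(readBin(f1, "raw", file.size(f1) + 10),
                   readBin(f2, "raw", file.size(f2) + 10))
  expect_equal(as.data.frame(p2), as.data.frame(p), tolerance = 1e-12)

  # canonicalization is idempotent for a hand-written variant header file
  df <- tiny_panel_df(c("r1", "r2"), c(0.25, 60), sige = 0.31)
  names(df) <- c("id", "age", "tIgE", gsub(" ", "_", hdm_components()))
  f3 <- withr::local_tempfile(fileext = ".csv")
  write_csv_lines(df, f3)
  write_panel(read_panel(f3), f1)
  write_panel(read_panel(f1), f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("DOT export is canonical and deterministic", {
  f <- withr::local_tempfile(fileext = ".dot")
  dag <- bn_dag(hdm_components())
  export_dag_dot(dag, f)
  lines <- readLines(f)
  expect_length(grep("->", lines), 0)
  expect_length(grep("\"Der", lines), 11)

  dag <- add_edge(dag, "Der p 1", "Der f 1")
  export_dag_dot(dag, f)
  expect_true(any(grepl("\"Der p 1\" -> \"Der f 1\";", readLines(f),
                        fixed = TRUE)))

  f2 <- withr::local_tempfile(fileext = ".dot")
  export_dag_dot(dag, f2)
  expect_identical(readLines(f), readLines(f2))
})

test_that("network JSON round-trips DAGs and fitted networks", {
  net <- make_truth_net("strong5")
  f <- withr::local_tempfile(fileext = ".json")
  write_net_json(net, f)
  back <- read_net_json(f)
  expect_identical(dag_edges(back$dag), dag_edges(net$dag))
  for (v in net$dag$nodes) {
    expect_equal(back$cpts[[v]]$p1, net$cpts[[v]]$p1)
  }
  write_net_json(net$dag, f)
  expect_s3_class(read_net_json(f), "bn_dag")
})
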