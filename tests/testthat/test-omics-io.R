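test_that("multi-omic TSV round-trip preserves values and labels", {
  ds <- toy_dataset()
  mp <- withr::local_tempfile(fileext = ".tsv")
  ap <- withr::local_tempfile(fileext = ".tsv")
  write_multiomic(ds, mp, ap)
  back <- read_multiomic(mp, ap)
  expect_equal(dim(back$values), dim(ds$values))
  expect_lt(max(abs(back$values - ds$values)), 1e-12)
  expect_identical(back$feature_omic, ds$feature_omic)
  expect_identical(back$sample_phenotype, ds$sample_phenotype)
  expect_identical(back$target_genes, ds$target_genes)
})

test_that("dataset construction rejects malformed input, naming offenders", {
  vals <- matrix(1:6, 3, 2,
                 dimnames = list(c("f1", "f1", "f2"), c("s1", "s2")))
  expect_error(
    multiomic_dataset(vals, rep("transcript", 3), c("A", "A"),
                      character(0)),
    "f1")
  vals2 <- matrix(rnorm(4), 2, 2,
                  dimnames = list(c("f1", "f2"), c("s1", "s2")))
  expect_error(
    multiomic_dataset(vals2, c("transcript", "mirna"), c("A", "A"),
                      target_genes = "missing_gene"),
    "missing_gene")
  # single omic violates the >=2 omics invariant
  expect_error(
    multiomic_dataset(vals2, c("transcript", "transcript"), c("A", "A"),
                      character(0)),
    "at least 2 omics")
  # NA rejected unless imputation requested at load
  ds <- toy_dataset()
  ds$values[2, 3] <- NA
  mp <- withr::local_tempfile(); ap <- withr::local_tempfile()
  suppressWarnings(write_multiomic(ds, mp, ap))
  expect_error(read_multiomic(mp, ap), "missing values")
  imp <- read_multiomic(mp, ap, impute_median = TRUE)
  expect_equal(imp$values[2, 3],
               median(ds$values[2, -3], na.rm = TRUE))
})

test_that("feature without an omic label is rejected", {
  ds <- toy_dataset()
  mp <- withr::local_tempfile(); ap <- withr::local_tempfile()
  write_multiomic(ds, mp, ap)
  ann <- read.delim(ap)
  ann <- ann[!(ann$kind == "feature_omic" & ann$id == "tx_a"), ]
  write.table(ann, ap, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(read_multiomic(mp, ap), "tx_a")
})

test_that("GMT parsing handles dedup, empty sets, short lines, round-trip", {
  p <- withr::local_tempfile(fileext = ".gmt")
  writeLines(c("S1\tdesc\ta\tb", "S2\tdesc\ta\ta\tc"), p)
  sets <- read_gmt(p)
  expect_equal(sets$S1, c("a", "b"))
  expect_equal(sets$S2, c("a", "c"))   # duplicate member deduplicated

  writeLines(c("S1\tdesc\ta", "EMPTY\tdesc\t\t"), p)
  expect_warning(sets <- read_gmt(p), "EMPTY")
  expect_named(sets, "S1")

  writeLines(c("S1\tdesc\ta", "BAD_ONLY_TWO\tfields"), p)
  expect_error(read_gmt(p), "line 2")

  two <- list(alpha = c("x", "y", "z"), beta = c("p", "q"))
  write_gmt(two, p)
  expect_equal(read_gmt(p)[c("alpha", "beta")], two)
})

test_that("known-link table rejects duplicates and bad evidence", {
  expect_error(known_link_db(c("r1", "r1"), c("t1", "t1")),
               "duplicate")
  expect_error(known_link_db("r1", "t1", evidence = "guessed"),
               "guessed")
  db <- known_link_db(c("r1", "r1"), c("t1", "t2"),
                      evidence = c("predicted", "validated"))
  p <- withr::local_tempfile(fileext = ".tsv")
  write_known_links(db, p)
  expect_equal(read_known_links(p), db)
})

test_that("edge list write/read preserves coefficients and degrees", {
  ds <- toy_dataset()
  m <- manual_model(ds, "g1", "T",
                    beta = c(cpg_a = 0.123456789, tx_a = -1.5,
                             mir_a = 2e-7),
                    train = paste0("s0", 1:4), test = paste0("s0", 5:8))
  nw <- build_network(structure(list(m), class = "GeneModelList"), "T")
  p <- withr::local_tempfile(fileext = ".tsv")
  write_edge_list(nw, p)
  lines <- readLines(p)
  expect_length(lines, 1 + 3)          # header + one row per edge
  back <- read_edge_list(p)
  expect_equal(sort(back$edges$coefficient), sort(nw$edges$coefficient),
               tolerance = 1e-10)      # no rounding below 6 sig digits
  expect_equal(back$outdegree[order(names(back$outdegree))],
               nw$outdegree[order(names(nw$outdegree))])
  expect_equal(back$indegree, nw$indegree)
})

test_that("run config validates, serializes, and profiles differ", {
  expect_error(run_config(alpha = 1.2), "alpha")
  expect_error(run_config(train_fraction = 1), "train_fraction")
  expect_error(run_config(lambda_min = 10, lambda_max = 1), "lambda_min")
  expect_error(run_config(k_small = 1), "fold counts")
  cfg <- run_config(profile = "test")
  expect_equal(cfg$cv_repeats, 20L)
  expect_equal(cfg$lambda_grid_size, 50L)
  expect_equal(run_config()$cv_repeats, 100L)
  p <- withr::local_tempfile(fileext = ".json")
  write_run_config(cfg, p)
  back <- read_run_config(p)
  expect_equal(unclass(back), unclass(cfg))
  grid <- lambda_grid(cfg)
  expect_equal(range(grid), c(0.001, 1000))
  expect_true(all(diff(grid) < 0))
})
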