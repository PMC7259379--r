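test_that("same seed and config give bit-identical datasets", {
  a <- simulate_dataset(tiny_sim_config(seed = 5))
  b <- simulate_dataset(tiny_sim_config(seed = 5))
  expect_identical(a$dataset$values, b$dataset$values)
  expect_identical(a$truth$planted_coefficients,
                   b$truth$planted_coefficients)
  c <- simulate_dataset(tiny_sim_config(seed = 6))
  expect_false(identical(a$dataset$values, c$dataset$values))
})

test_that("noiseless limit reproduces the planted linear combination", {
  cfg <- tiny_sim_config(seed = 11, r2 = 1 - 1e-9, hub_scale = 0)
  sim <- simulate_dataset(cfg)
  ds <- sim$dataset
  for (ph in c("TumorA", "Normal")) {
    cols <- names(ds$sample_phenotype)[ds$sample_phenotype == ph]
    for (g in ds$target_genes) {
      pl <- sim$truth$planted_coefficients[[ph]][[g]]
      recon <- drop(crossprod(ds$values[pl$feature_id, cols, drop = FALSE],
                              pl$coefficient))
      expect_lt(max(abs(ds$values[g, cols] - recon)), 1e-3)
    }
  }
})

test_that("generator calibration: empirical R^2 matches config at large n", {
  cfg <- tiny_sim_config(seed = 3, r2 = 0.7, hub_scale = 0)
  cfg$n_samples <- c(TumorA = 2000, Normal = 50)
  sim <- simulate_dataset(cfg)
  ds <- sim$dataset
  cols <- names(ds$sample_phenotype)[ds$sample_phenotype == "TumorA"]
  for (g in ds$target_genes) {
    pl <- sim$truth$planted_coefficients[["TumorA"]][[g]]
    signal <- drop(crossprod(ds$values[pl$feature_id, cols, drop = FALSE],
                             pl$coefficient))
    y <- ds$values[g, cols]
    r2 <- 1 - var(y - signal) / var(y)
    expect_lt(abs(r2 - 0.7), 0.05)
    # standardized planted features imply E[y] = beta0 = 0
    expect_lt(abs(mean(y)), 5 * sd(y) / sqrt(length(y)))
  }
})

test_that("single planted predictor at rho=0, high R^2 is recoverable", {
  cfg <- sim_config(n_samples = c(T = 500, Normal = 20),
                    m_cpg = 30, m_tx = 30, m_mirna = 20,
                    n_target_genes = 2,
                    k_planted = c(methylation = 0, transcript = 1,
                                  mirna = 0),
                    rho = 0, block_size = 5, r2 = 0.99, hub_scale = 0,
                    seed = 21)
  sim <- simulate_dataset(cfg)
  ds <- sim$dataset
  cols <- names(ds$sample_phenotype)[ds$sample_phenotype == "T"]
  g <- ds$target_genes[1]
  pl <- sim$truth$planted_coefficients[["T"]][[g]]
  expect_equal(nrow(pl), 1L)
  expect_gt(abs(cor(ds$values[g, cols], ds$values[pl$feature_id, cols])),
            0.9)
})

test_that("planted structure honors exclusivity and hub invariants", {
  sim <- simulate_dataset(tiny_sim_config(seed = 8))
  tr <- sim$truth
  ds <- sim$dataset
  phs <- names(tr$planted_coefficients)
  for (g in ds$target_genes) {
    sets <- lapply(phs, function(ph)
      tr$planted_coefficients[[ph]][[g]]$feature_id)
    # sharing fraction 0: a gene's sets are disjoint across phenotypes
    expect_equal(length(unlist(sets)), length(unique(unlist(sets))))
    # a gene's own transcript is never among its planted predictors
    expect_false(g %in% unlist(sets))
  }
  for (ph in phs) {
    per_gene <- lapply(ds$target_genes, function(g)
      tr$planted_coefficients[[ph]][[g]]$feature_id)
    # within a phenotype, genes never share planted features
    expect_equal(length(unlist(per_gene)),
                 length(unique(unlist(per_gene))))
    # every planted feature exists in the dataset
    expect_true(all(unlist(per_gene) %in% rownames(ds$values)))
  }
  expect_equal(unname(ds$feature_omic[c(tr$tumor_hub_id,
                                        tr$normal_hub_id)]),
               c("mirna", "mirna"))
})

test_that("partial sharing plants the configured common subset", {
  cfg <- sim_config(n_samples = c(A = 30, B = 30, Normal = 20),
                    m_cpg = 100, m_tx = 100, m_mirna = 80,
                    n_target_genes = 2, k_planted = 4,
                    sharing_fraction = 0.5, block_size = 5,
                    seed = 4)
  tr <- simulate_dataset(cfg)$truth
  for (g in c("gene_001", "gene_002")) {
    sa <- tr$planted_coefficients[["A"]][[g]]$feature_id
    sb <- tr$planted_coefficients[["B"]][[g]]$feature_id
    expect_equal(length(intersect(sa, sb)), 3 * 2)  # 2 shared per omic
  }
})

test_that("simulated known links respect the true-positive fraction", {
  sim <- simulate_dataset(tiny_sim_config(seed = 9))
  planted <- do.call(rbind, lapply(sim$truth$planted_coefficients,
    function(ph) do.call(rbind, lapply(names(ph), function(g)
      data.frame(r = ph[[g]]$feature_id, t = g)))))
  planted_keys <- unique(paste(planted$r, planted$t))

  cfg1 <- tiny_sim_config(seed = 9, db_true_positive_fraction = 1,
                          db_decoy_links = 0)
  db1 <- simulate_known_links(sim$truth, cfg1)
  expect_setequal(paste(db1$regulator_id, db1$target_id), planted_keys)

  cfg0 <- tiny_sim_config(seed = 9, db_true_positive_fraction = 0,
                          db_decoy_links = 40)
  db0 <- simulate_known_links(sim$truth, cfg0)
  expect_equal(nrow(db0), 40L)
  expect_length(intersect(paste(db0$regulator_id, db0$target_id),
                          planted_keys), 0)

  cfg5 <- tiny_sim_config(seed = 9, db_true_positive_fraction = 0.5,
                          db_decoy_links = 20)
  db5 <- simulate_known_links(sim$truth, cfg5)
  n_true <- sum(paste(db5$regulator_id, db5$target_id) %in% planted_keys)
  expect_equal(n_true, round(0.5 * length(planted_keys)))
  expect_setequal(unique(db5$evidence), c("predicted", "validated"))
})

test_that("function sets contain planted transcript predictors and pass GMT", {
  cfg <- tiny_sim_config(seed = 10)
  sim <- simulate_dataset(cfg)
  sets <- simulate_function_sets(sim$truth, cfg)
  on_target <- attr(sets, "on_target")
  for (g in sim$dataset$target_genes) {
    pl_tx <- unique(unlist(lapply(sim$truth$planted_coefficients,
      function(ph) grep("^tx_", ph[[g]]$feature_id, value = TRUE))))
    ov <- length(intersect(pl_tx, sets[[on_target[[g]]]]))
    expect_gte(ov / length(pl_tx), 0.8)
  }
  p <- withr::local_tempfile(fileext = ".gmt")
  write_gmt(sets, p)
  back <- read_gmt(p)
  expect_equal(back[names(sets)], sets[names(sets)],
               ignore_attr = TRUE)
})

test_that("ground truth JSON round-trips", {
  sim <- simulate_dataset(tiny_sim_config(seed = 12))
  p <- withr::local_tempfile(fileext = ".json")
  write_ground_truth(sim$truth, p)
  back <- read_ground_truth(p)
  expect_equal(back$noise_sd, sim$truth$noise_sd, tolerance = 1e-12)
  expect_equal(back$tumor_hub_id, sim$truth$tumor_hub_id)
  expect_equal(back$planted_coefficients$TumorA$gene_001,
               sim$truth$planted_coefficients$TumorA$gene_001,
               tolerance = 1e-12)
})

test_that("infeasible planted configuration is rejected", {
  expect_error(sim_config(n_samples = c(A = 10, Normal = 10),
                          m_cpg = 50, m_tx = 50, m_mirna = 10,
                          n_target_genes = 5, k_planted = 5,
                          block_size = 5),
               "mirna")
})
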