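# Shared fixtures: all built in code at test time.

tiny_sim_config <- function(seed = 42, ...) {
  args <- list(
    n_samples = c(TumorA = 60, TumorB = 50, Normal = 40),
    m_cpg = 80, m_tx = 80, m_mirna = 40, n_target_genes = 3,
    k_planted = 2, block_size = 5, rho = 0.6, r2 = 0.8,
    db_decoy_links = 50, n_background_sets = 10,
    normal_phenotype = "Normal", seed = seed)
  do.call(sim_config, utils::modifyList(args, list(...)))
}

tiny_run_config <- function(seed = 42, ...) {
  args <- list(profile = "test", lambda_grid_size = 30, cv_repeats = 5,
               small_cohort_threshold = 100, seed = seed)
  do.call(run_config, utils::modifyList(args, list(...)))
}

# 6-feature hand-built dataset for I/O and masking tests
toy_dataset <- function(n = 8, seed = 7) {
  set.seed(seed)
  vals <- matrix(rnorm(6 * n), 6, n,
                 dimnames = list(c("cpg_a", "cpg_b", "tx_a", "tx_b",
                                   "mir_a", "g1"),
                                 sprintf("s%02d", seq_len(n))))
  multiomic_dataset(
    vals,
    feature_omic = c("methylation", "methylation", "transcript",
                     "transcript", "mirna", "transcript"),
    sample_phenotype = rep(c("T", "N"), length.out = n),
    target_genes = "g1")
}

# memoized small fitted pipeline shared across test files
.fixture_cache <- new.env(parent = emptyenv())

tiny_fit <- function(key = "default", sim_args = list(),
                     run_args = list()) {
  if (!is.null(.fixture_cache[[key]])) return(.fixture_cache[[key]])
  scfg <- do.call(tiny_sim_config, sim_args)
  rcfg <- do.call(tiny_run_config, run_args)
  sim <- simulate_dataset(scfg)
  split <- make_split(sim$dataset, rcfg)
  models <- fit_all(sim$dataset, split, rcfg)
  out <- list(scfg = scfg, rcfg = rcfg, dataset = sim$dataset,
              truth = sim$truth, split = split, models = models)
  .fixture_cache[[key]] <- out
  out
}

# deterministic hand-made GeneModel for unit tests that need one
manual_model <- function(dataset, gene, phenotype, beta,
                         train, test) {
  nm <- if (length(beta)) names(beta) else character(0)
  beta <- setNames(as.numeric(beta), nm)
  tr <- dataset$values[nm, train, drop = FALSE]
  mu <- rowMeans(tr)
  sdv <- sqrt(rowMeans((tr - mu)^2))
  y <- dataset$values[gene, train]
  m <- structure(list(
    gene = gene, phenotype = phenotype, alpha = 0.5,
    intercept = 0, beta = beta, lambda_selected = 1,
    cv_curve = NULL, k_folds = 3,
    selected_by_omic = split(nm,
                             factor(dataset$feature_omic[nm],
                                    c("methylation", "transcript",
                                      "mirna"))),
    scaling = list(feature = data.frame(feature = nm, mean = mu,
                                        sd = sdv,
                                        dropped = rep(FALSE, length(nm))),
                   y_mean = mean(y),
                   y_sd = sqrt(mean((y - mean(y))^2))),
    train_samples = train, test_samples = test,
    rmse_test = NA_real_, rmse_intercept_only = NA_real_),
    class = "GeneModel")
  m$rmse_test <- masked_rmse(m, dataset, "all")
  m$rmse_intercept_only <- masked_rmse(m, dataset, "none")
  m
}
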