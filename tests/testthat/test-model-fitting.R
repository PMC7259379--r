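test_that("standardize uses population sd and is idempotent", {
  tr <- matrix(c(1, 2, 3), 1, 3, dimnames = list("f", NULL))
  out <- standardize(tr)
  expect_equal(drop(out$train), c(-1.2247449, 0, 1.2247449),
               tolerance = 1e-6)   # n-denominator sd
  expect_equal(out$scaling$sd, sqrt(2 / 3))
  again <- standardize(out$train)
  expect_lt(max(abs(again$train - out$train)), 1e-12)

  const <- rbind(f1 = c(1, 2, 3), f2 = c(5, 5, 5))
  out2 <- standardize(const, test = const[, 1:2])
  expect_true(out2$scaling$dropped[2])
  expect_equal(rownames(out2$train), "f1")
  expect_equal(rownames(out2$test), "f1")
})

test_that("make_split stratifies at the configured fraction", {
  # 45 samples -> 36 train / 9 test; 125 -> 100/25
  cfg <- tiny_run_config(seed = 1)
  n <- c(A = 45, B = 125)
  vals <- matrix(rnorm(2 * sum(n)), 2, sum(n),
                 dimnames = list(c("tx_x", "mir_x"),
                                 sprintf("s%03d", seq_len(sum(n)))))
  ds <- multiomic_dataset(vals, c("transcript", "mirna"),
                          rep(names(n), n), character(0))
  sp <- make_split(ds, cfg)
  expect_length(sp$plan$A$train, 36)
  expect_length(sp$plan$A$test, 9)
  expect_length(sp$plan$B$train, 100)
  expect_length(sp$plan$B$test, 25)
  expect_length(intersect(sp$plan$A$train, sp$plan$A$test), 0)
  expect_setequal(c(sp$plan$A$train, sp$plan$A$test),
                  names(ds$sample_phenotype)[ds$sample_phenotype == "A"])
  expect_identical(make_split(ds, cfg), sp)   # deterministic given seed
})

test_that("solver matches univariate closed form and KKT zero condition", {
  set.seed(1)
  n <- 60
  x <- rnorm(n); x <- (x - mean(x)) / sqrt(mean((x - mean(x))^2))
  y <- x   # (1/n) x'y = 1 exactly
  X <- matrix(x, ncol = 1, dimnames = list(NULL, "x1"))
  for (lam in c(0.1, 0.4, 0.9)) {
    fit <- elastic_net_solve(X, y, 0.5, lam)
    expect_equal(unname(fit$beta),
                 max(1 - lam * 0.5, 0) / (1 + lam * 0.5),
                 tolerance = 1e-8)
  }
  lam_max <- max(abs(crossprod(x, y)) / n) / 0.5
  expect_identical(unname(elastic_net_solve(X, y, 0.5,
                                            lam_max * 1.000001)$beta), 0)
  expect_error(elastic_net_solve(matrix(c(1, NA), 2, 1), c(1, 2),
                                 0.5, 1), "non-finite")
})

test_that("lambda = 0 on a well-conditioned design matches least squares", {
  set.seed(2)
  n <- 80; p <- 5
  X <- matrix(rnorm(n * p), n, p)
  y <- rnorm(n)
  fit <- elastic_net_solve(X, y, 0.5, 0)
  ls <- coef(lm(y ~ X))
  expect_lt(max(abs(fit$beta - ls[-1])), 1e-6)
  expect_lt(abs(fit$b0 - ls[1]), 1e-6)
})

test_that("KKT subgradient residual < 1e-6 on random instances", {
  set.seed(3)
  for (i in 1:20) {
    n <- 50; p <- 200
    X <- scale(matrix(rnorm(n * p), n, p)) * sqrt(n / (n - 1))
    y <- rnorm(n)
    lam <- 10^runif(1, -2, 0)
    fit <- elastic_net_solve(X, y, 0.5, lam, tol = 1e-10)
    expect_lt(kkt_residual(X, y, 0.5, lam, fit$b0, fit$beta), 1e-6)
  }
})

test_that("grouping property: identical predictors share weight equally", {
  set.seed(4)
  n <- 100
  x <- rnorm(n); x <- (x - mean(x)) / sqrt(mean((x - mean(x))^2))
  X <- cbind(a = x, b = x)
  y <- 2 * x + rnorm(n, sd = 0.3)
  fit <- elastic_net_solve(X, y, 0.5, 0.2, tol = 1e-12)
  expect_gt(abs(fit$beta[["a"]]), 0)
  expect_lt(abs(fit$beta[["a"]] - fit$beta[["b"]]), 1e-6)
})

test_that("solver agrees with glmnet on its own objective", {
  skip_if_not_installed("glmnet")
  set.seed(5)
  n <- 70; p <- 150
  X <- scale(matrix(rnorm(n * p), n, p)) * sqrt(n / (n - 1))
  y <- rnorm(n); y <- (y - mean(y)) / sqrt(mean((y - mean(y))^2))
  for (lam in c(0.3, 0.05)) {
    mine <- elastic_net_solve(X, y, 0.5, lam, tol = 1e-11)
    ref <- glmnet::glmnet(X, y, alpha = 0.5, lambda = lam,
                          standardize = FALSE, thresh = 1e-14)
    expect_lt(max(abs(mine$beta - as.numeric(coef(ref))[-1])), 1e-5)
  }
})

test_that("training MSE is non-decreasing and support shrinks univariately", {
  set.seed(6)
  n <- 50
  x <- rnorm(n); x <- (x - mean(x)) / sqrt(mean((x - mean(x))^2))
  X <- matrix(x, ncol = 1)
  y <- 1.3 * x + rnorm(n, sd = 0.5)
  lams <- sort(10^seq(-3, 1, length.out = 20))
  fit <- elastic_net_solve(X, y, 0.5, lams, tol = 1e-11)
  mse <- vapply(seq_along(lams), function(l)
    mean((y - fit$b0[l] - X %*% fit$beta[, l])^2), numeric(1))
  expect_true(all(diff(mse) >= -1e-10))
  nnz <- colSums(fit$beta != 0)
  expect_true(all(diff(nnz) <= 0))
})

test_that("select_lambda applies the cohort-size fold rule", {
  set.seed(7)
  p <- 12
  cfg <- tiny_run_config(cv_repeats = 2, lambda_grid_size = 8)
  X <- matrix(rnorm(36 * p), 36, p)
  y <- X[, 1] + rnorm(36, sd = 0.5)
  expect_equal(select_lambda(X, y, cfg)$k, 3)     # n_train = 36 < 100
  X2 <- matrix(rnorm(316 * p), 316, p)
  y2 <- X2[, 1] + rnorm(316, sd = 0.5)
  expect_equal(select_lambda(X2, y2, cfg)$k, 5)   # n_train = 316 >= 100
  expect_error(select_lambda(X[1:2, ], y[1:2], cfg), "fold")
})

test_that("pure-noise response selects at or near the sparsest end", {
  cfg <- tiny_run_config(cv_repeats = 3, lambda_grid_size = 15)
  grid <- lambda_grid(cfg)
  hits <- 0L
  for (s in 1:10) {
    set.seed(100 + s)
    X <- matrix(rnorm(60 * 100), 60, 100)
    y <- rnorm(60)
    sel <- select_lambda(X, y, cfg)
    Xs <- scale(X) * sqrt(60 / 59)
    fit <- elastic_net_solve(Xs, (y - mean(y)) / sd(y), 0.5, sel$lambda)
    if (sum(fit$beta != 0) <= 3) hits <- hits + 1L
  }
  expect_gte(hits, 9L)
})

test_that("fitted models recover planted structure on the tiny scenario", {
  fx <- tiny_fit()
  expect_length(fx$models, 9)   # 3 genes x 3 phenotypes
  for (m in fx$models) {
    # the gene's own transcript row is never a predictor
    expect_false(m$gene %in% names(m$beta))
    expect_true(all(m$beta != 0))
    expect_true(m$lambda_selected %in% lambda_grid(fx$rcfg))
    expect_gte(m$rmse_test, 0)
    # decomposition bookkeeping: selected features partition by omic
    expect_setequal(unlist(m$selected_by_omic), names(m$beta))
  }
  sens <- selection_sensitivity(fx$models, fx$truth)
  expect_gte(median(sens$sensitivity), 0.5)
  expect_gte(mean(vapply(fx$models, function(m)
    m$rmse_test < m$rmse_intercept_only, TRUE)), 0.7)
})

test_that("model JSON round-trip preserves the sparse representation", {
  fx <- tiny_fit()
  p <- withr::local_tempfile(fileext = ".json")
  write_models(fx$models, p)
  back <- read_models(p, fx$dataset)
  expect_length(back, length(fx$models))
  m0 <- fx$models[[1]]; m1 <- back[[1]]
  expect_equal(m1$beta, m0$beta, tolerance = 1e-12)
  expect_equal(m1$lambda_selected, m0$lambda_selected)
  expect_equal(m1$rmse_test, m0$rmse_test, tolerance = 1e-12)
  expect_equal(m1$selected_by_omic, m0$selected_by_omic)
})

test_that("subsample refits use the configured training size", {
  fx <- tiny_fit()
  cfg <- tiny_run_config(subsample_n = 30)
  sub <- fit_all(fx$dataset, fx$split, cfg,
                 genes = fx$dataset$target_genes[1])
  expect_length(sub, 3)
  for (m in sub)
    expect_length(m$train_samples, round(0.8 * 30))
})
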