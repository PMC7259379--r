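#' Row-standardize a training block and transform a test block
#'
#' Each feature row of the training block is scaled to mean 0 and standard
#' deviation 1 (population denominator, i.e. `n`), and the test block is
#' transformed with the training-derived parameters. Zero-variance training
#' rows are flagged and dropped from both blocks.
#'
#' @param train,test numeric features-by-samples matrices sharing rownames.
#' @return list with `train`, `test` (standardized, constant rows removed)
#'   and `scaling` (data.frame `feature`, `mean`, `sd`, `dropped`).
#' @export
standardize <- function(train, test = NULL) {
  stopifnot(is.matrix(train))
  n <- ncol(train)
  mu <- rowMeans(train)
  s <- sqrt(rowMeans((train - mu)^2))      # population sd
  dropped <- s < 1e-10
  scaling <- data.frame(feature = rownames(train), mean = mu, sd = s,
                        dropped = dropped, row.names = NULL,
                        stringsAsFactors = FALSE)
  keep <- !dropped
  tr <- (train[keep, , drop = FALSE] - mu[keep]) / s[keep]
  te <- if (!is.null(test))
    (test[keep, , drop = FALSE] - mu[keep]) / s[keep]
  list(train = tr, test = te, scaling = scaling)
}

#' Stratified train/test split
#'
#' Samples are split per phenotype: a `train_fraction` share (rounded to
#' the nearest sample) is drawn for training, the rest is held out for
#' testing. Deterministic given the configured seed.
#'
#' @param dataset a `MultiOmicDataset`.
#' @param config a [run_config()].
#' @return object of class `SplitPlan`: per phenotype a list with `train`
#'   and `test` sample-id vectors.
#' @export
make_split <- function(dataset, config) {
  set.seed(substream_seed(config$seed, "make_split"))
  plan <- lapply(phenotypes(dataset), function(ph) {
    ids <- names(dataset$sample_phenotype)[dataset$sample_phenotype == ph]
    n_train <- round(config$train_fraction * length(ids))
    tr <- sort(sample(ids, n_train))
    list(train = tr, test = setdiff(ids, tr))
  })
  names(plan) <- phenotypes(dataset)
  structure(list(plan = plan, seed = config$seed,
                 train_fraction = config$train_fraction),
            class = "SplitPlan")
}

#' Solve the elastic-net problem at given penalties
#'
#' Minimizes `(1/2n) * RSS + lambda * (alpha*||b||_1 + (1-alpha)/2*||b||_2^2)`
#' by cyclic coordinate descent with an ever-active set, warm-started along
#' a decreasing lambda path. The intercept is unpenalized and satisfies
#' `b0 = mean(y - X b)`.
#'
#' @param X numeric samples-by-predictors matrix (standardized columns for
#'   the usual contract, but any finite matrix is accepted).
#' @param y numeric response vector.
#' @param alpha mixing parameter in (0, 1].
#' @param lambda numeric vector of penalty values.
#' @param tol convergence tolerance on the maximum coefficient change.
#' @param max_iter sweep cap per lambda.
#' @param intercept fit an unpenalized intercept (default `TRUE`).
#' @return for scalar `lambda`, a list with `b0` and named `beta`; for a
#'   vector, a list with `b0` (vector) and `beta` (p x L matrix).
#' @export
elastic_net_solve <- function(X, y, alpha, lambda, tol = 1e-9,
                              max_iter = 100000L, intercept = TRUE) {
  stopifnot(is.matrix(X), nrow(X) == length(y), all(lambda >= 0))
  if (anyNA(X) || anyNA(y) || any(!is.finite(X)) || any(!is.finite(y)))
    stop("non-finite values in input", call. = FALSE)
  ord <- order(lambda, decreasing = TRUE)
  fit <- enet_path_dense(X, as.numeric(y), alpha,
                         as.numeric(lambda[ord]), tol,
                         as.integer(max_iter), intercept)
  inv <- order(ord)
  B <- fit$beta[, inv, drop = FALSE]
  rownames(B) <- colnames(X)
  b0 <- fit$b0[inv]
  if (length(lambda) == 1L)
    list(b0 = b0, beta = setNames(B[, 1], colnames(X)))
  else
    list(b0 = b0, beta = B)
}

#' KKT subgradient residual of an elastic-net solution
#'
#' Maximum violation of the stationarity conditions of the elastic-net
#' objective; a correct solution has residual near zero.
#'
#' @inheritParams elastic_net_solve
#' @param b0 intercept.
#' @param beta coefficient vector.
#' @return maximum absolute subgradient residual over coordinates.
#' @export
kkt_residual <- function(X, y, alpha, lambda, b0, beta) {
  n <- nrow(X)
  r <- y - b0 - drop(X %*% beta)
  g <- drop(crossprod(X, r)) / n - lambda * (1 - alpha) * beta
  active <- beta != 0
  viol <- numeric(length(beta))
  viol[active] <- abs(g[active] - lambda * alpha * sign(beta[active]))
  viol[!active] <- pmax(abs(g[!active]) - lambda * alpha, 0)
  max(viol)
}

#' Select the shrinkage penalty by repeated cross-validation
#'
#' Uses `k_small` folds when the training set is smaller than
#' `small_cohort_threshold` and `k_large` otherwise. Folds are redrawn on
#' every repeat; the CV curve is the mean held-out RMSE over all
#' repeats-by-folds; the selected lambda minimizes the curve, with ties
#' broken toward the larger (sparser) lambda. Each fold is standardized
#' internally with its own training parameters. For speed, a fold's path
#' stops once the active set exceeds 90% of the fold's training size
#' (past interpolation capacity, held-out error can only degrade) and the
#' curve is extended flat there, which cannot relocate the minimum. Uses
#' the current RNG state; callers seed per model.
#'
#' @param X raw samples-by-predictors training matrix.
#' @param y raw training response.
#' @param config a [run_config()].
#' @return list with `lambda` (selected), `cv_curve` (data.frame `lambda`,
#'   `rmse`), and `k` (folds used).
#' @export
select_lambda <- function(X, y, config) {
  n <- nrow(X)
  k <- if (n < config$small_cohort_threshold) config$k_small
       else config$k_large
  if (n < k)
    stop(sprintf("training set (%d) smaller than fold count (%d)", n, k),
         call. = FALSE)
  lam <- lambda_grid(config)
  rmse_sum <- numeric(length(lam))
  n_fits <- 0L
  for (rep in seq_len(config$cv_repeats)) {
    folds <- sample(rep_len(seq_len(k), n))
    for (f in seq_len(k)) {
      te <- folds == f
      n_in <- sum(!te)
      rmse_sum <- rmse_sum +
        enet_cv_fold(X[!te, , drop = FALSE], y[!te],
                     X[te, , drop = FALSE], y[te],
                     config$alpha, lam, 1e-4, 200L,
                     df_max = as.integer(0.9 * n_in))
      n_fits <- n_fits + 1L
    }
  }
  curve <- rmse_sum / n_fits
  best <- which(curve <= min(curve))[1]   # lam decreasing: first = largest
  list(lambda = lam[best],
       cv_curve = data.frame(lambda = lam, rmse = curve), k = k)
}

#' Fit one elastic-net gene model
#'
#' Fits the model for one (target gene, phenotype): repeated-CV lambda
#' selection on the training samples, a final warm-started fit at the
#' selected lambda on the standardized training block, and held-out RMSE
#' on the test samples. The gene's own transcript row is never among its
#' predictors.
#'
#' @param dataset a `MultiOmicDataset`.
#' @param split a [make_split()] plan.
#' @param config a [run_config()].
#' @param gene target gene id.
#' @param phenotype phenotype label.
#' @return object of class `GeneModel`, or `NULL` (with a warning) when
#'   the target is constant on the training samples.
#' @export
fit_gene_model <- function(dataset, split, config, gene, phenotype) {
  stopifnot(gene %in% dataset$target_genes,
            phenotype %in% names(split$plan))
  tr_ids <- split$plan[[phenotype]]$train
  te_ids <- split$plan[[phenotype]]$test
  feats <- setdiff(rownames(dataset$values), gene)
  ytr <- dataset$values[gene, tr_ids]
  if (sd(ytr) < 1e-12) {
    warning(sprintf("target %s constant in %s training data; skipped",
                    gene, phenotype), call. = FALSE)
    return(NULL)
  }
  set.seed(substream_seed(config$seed, paste("fit", phenotype, gene)))
  Xtr_raw <- t(dataset$values[feats, tr_ids, drop = FALSE])
  sel <- select_lambda(Xtr_raw, ytr, config)

  std <- standardize(dataset$values[feats, tr_ids, drop = FALSE])
  ysc <- standardize(matrix(ytr, nrow = 1, dimnames = list(gene, NULL)))
  lam <- lambda_grid(config)
  lam_path <- lam[lam >= sel$lambda]
  fit <- elastic_net_solve(t(std$train), drop(ysc$train), config$alpha,
                           lam_path, tol = 1e-8, max_iter = 5000L)
  beta <- if (length(lam_path) == 1L) fit$beta else fit$beta[, length(lam_path)]
  b0 <- if (length(lam_path) == 1L) fit$b0 else fit$b0[length(lam_path)]
  beta <- beta[beta != 0]
  omic_of <- dataset$feature_omic[names(beta)]
  model <- structure(list(
    gene = gene, phenotype = phenotype, alpha = config$alpha,
    intercept = b0, beta = beta,
    lambda_selected = sel$lambda, cv_curve = sel$cv_curve,
    k_folds = sel$k,
    selected_by_omic = split(names(beta), factor(omic_of, OMIC_LEVELS)),
    scaling = list(
      feature = std$scaling[match(names(beta), std$scaling$feature), ],
      y_mean = ysc$scaling$mean, y_sd = ysc$scaling$sd),
    train_samples = tr_ids, test_samples = te_ids,
    rmse_test = NA_real_, rmse_intercept_only = NA_real_),
    class = "GeneModel")
  model$rmse_test <- masked_rmse(model, dataset, "all")
  model$rmse_intercept_only <- masked_rmse(model, dataset, "none")
  model
}

#' @export
print.GeneModel <- function(x, ...) {
  cat(sprintf("GeneModel %s / %s: lambda*=%.4g, %d predictors, RMSE %.4g (test)\n",
              x$gene, x$phenotype, x$lambda_selected, length(x$beta),
              x$rmse_test))
  counts <- vapply(x$selected_by_omic, length, integer(1))
  cat("  by omic:", paste(sprintf("%s=%d", names(counts), counts),
                          collapse = ", "), "\n")
  invisible(x)
}

#' Fit all gene models
#'
#' One elastic-net model per (target gene, phenotype). Failures are logged
#' and skipped; the run continues. When `config$subsample_n` is set, each
#' phenotype's training set is first reduced to that many samples
#' (phenotypes with fewer samples are skipped), emulating the fixed-size
#' robustness refit.
#'
#' @inheritParams fit_gene_model
#' @param genes target genes to fit (default: all flagged targets).
#' @return list of `GeneModel`s (class `GeneModelList`).
#' @export
fit_all <- function(dataset, split, config,
                    genes = dataset$target_genes) {
  if (!is.null(config$subsample_n)) {
    set.seed(substream_seed(config$seed, "subsample"))
    n_sub <- round(config$train_fraction * config$subsample_n)
    split$plan <- lapply(split$plan, function(p)
      if (length(p$train) < n_sub) NULL
      else list(train = sort(sample(p$train, n_sub)), test = p$test))
    split$plan <- Filter(Negate(is.null), split$plan)
  }
  models <- list()
  for (ph in names(split$plan)) {
    for (g in genes) {
      m <- tryCatch(fit_gene_model(dataset, split, config, g, ph),
                    error = function(e) {
                      warning(sprintf("model %s/%s failed: %s", g, ph,
                                      conditionMessage(e)), call. = FALSE)
                      NULL
                    })
      if (!is.null(m)) models[[paste(ph, g, sep = ".")]] <- m
    }
  }
  structure(models, class = c("GeneModelList", "list"))
}

#' Per-phenotype selection counts by omic
#'
#' The descriptive summary of model output: per phenotype, the number of
#' training/test samples and the number of distinct selected features per
#' omic across all gene models.
#'
#' @param models a `GeneModelList`.
#' @return data.frame with one row per phenotype.
#' @export
selection_summary <- function(models) {
  phs <- unique(vapply(models, `[[`, "", "phenotype"))
  rows <- lapply(phs, function(ph) {
    ms <- models[vapply(models, function(m) m$phenotype == ph, TRUE)]
    sel <- lapply(OMIC_LEVELS, function(om)
      unique(unlist(lapply(ms, function(m) m$selected_by_omic[[om]]))))
    data.frame(phenotype = ph,
               n_models = length(ms),
               n_train = length(ms[[1]]$train_samples),
               n_test = length(ms[[1]]$test_samples),
               selected_methylation = length(sel[[1]]),
               selected_transcript = length(sel[[2]]),
               selected_mirna = length(sel[[3]]),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Serialize / deserialize fitted gene models as JSON
#'
#' Stores the sparse representation (gene, phenotype, selected lambda,
#' intercept, nonzero coefficients, scaling record, sample split, RMSEs).
#' CV curves are included so reruns can be audited.
#'
#' @param models a `GeneModelList`.
#' @param path file path.
#' @export
write_models <- function(models, path) {
  out <- lapply(unclass(models), function(m) {
    m <- unclass(m)
    m$beta <- list(feature = names(m$beta), value = unname(m$beta))
    m$selected_by_omic <- NULL
    m
  })
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' @rdname write_models
#' @param dataset the dataset the models were fitted on (restores omic
#'   partitions).
#' @export
read_models <- function(path, dataset) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE,
                             simplifyDataFrame = TRUE)
  models <- lapply(raw, function(m) {
    beta <- setNames(as.numeric(m$beta$value), m$beta$feature)
    m$beta <- beta
    m$selected_by_omic <- split(names(beta),
                                factor(dataset$feature_omic[names(beta)],
                                       OMIC_LEVELS))
    m$cv_curve <- as.data.frame(m$cv_curve)
    m$scaling$feature <- as.data.frame(m$scaling$feature)
    structure(m, class = "GeneModel")
  })
  structure(models, class = c("GeneModelList", "list"))
}
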