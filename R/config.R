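#' Pipeline run configuration
#'
#' Bundles every tunable of the modelling pipeline. The elastic-net mixing
#' parameter is held at `alpha = 0.5`; the shrinkage parameter lambda is
#' optimised over a log-spaced grid on `[lambda_min, lambda_max]`
#' (default `[0.001, 1000]`) by repeated k-fold cross-validation, with
#' `k = k_small` folds for phenotypes with fewer than
#' `small_cohort_threshold` training samples and `k = k_large` otherwise.
#'
#' Two named profiles ship: `"paper"` (100 CV repeats, 100 grid points),
#' matching the original analysis scale, and `"test"` (20 repeats, 50
#' points) for desk-scale runs. Explicit arguments override the profile.
#'
#' @param alpha elastic-net mixing parameter in (0,1).
#' @param lambda_min,lambda_max bounds of the shrinkage grid.
#' @param lambda_grid_size number of log-spaced grid points.
#' @param cv_repeats number of repeated cross-validation rounds.
#' @param train_fraction fraction of samples per phenotype used for training.
#' @param small_cohort_threshold training-set size below which `k_small`
#'   folds are used.
#' @param k_small,k_large fold counts for small and large cohorts.
#' @param fold_change_threshold minimum fold change for the moderated
#'   differential-expression test (on the natural scale; log2 internally).
#' @param fdr_alpha significance level applied to FDR-adjusted p-values.
#' @param seed integer run seed; all stage randomness derives from it.
#' @param subsample_n optional fixed per-phenotype sample size for the
#'   robustness refit (e.g. 40); `NULL` disables it.
#' @param profile `"paper"` or `"test"`; sets `cv_repeats` and
#'   `lambda_grid_size` defaults.
#' @return object of class `RunConfig`.
#' @export
run_config <- function(alpha = 0.5, lambda_min = 0.001, lambda_max = 1000,
                       lambda_grid_size = NULL, cv_repeats = NULL,
                       train_fraction = 0.8, small_cohort_threshold = 100,
                       k_small = 3, k_large = 5,
                       fold_change_threshold = 1.1, fdr_alpha = 0.05,
                       seed = 1, subsample_n = NULL,
                       profile = c("paper", "test")) {
  profile <- match.arg(profile)
  defaults <- list(paper = c(repeats = 100, grid = 100),
                   test  = c(repeats = 20,  grid = 50))[[profile]]
  cfg <- structure(list(
    alpha = alpha, lambda_min = lambda_min, lambda_max = lambda_max,
    lambda_grid_size = as.integer(lambda_grid_size %||% defaults[["grid"]]),
    cv_repeats = as.integer(cv_repeats %||% defaults[["repeats"]]),
    train_fraction = train_fraction,
    small_cohort_threshold = small_cohort_threshold,
    k_small = as.integer(k_small), k_large = as.integer(k_large),
    fold_change_threshold = fold_change_threshold, fdr_alpha = fdr_alpha,
    seed = as.integer(seed), subsample_n = subsample_n, profile = profile
  ), class = "RunConfig")
  validate_run_config(cfg)
}

validate_run_config <- function(cfg) {
  stopifnot(inherits(cfg, "RunConfig"))
  if (!(cfg$alpha > 0 && cfg$alpha < 1))
    stop("alpha must lie strictly between 0 and 1", call. = FALSE)
  if (!(cfg$lambda_min < cfg$lambda_max))
    stop("lambda_min must be smaller than lambda_max", call. = FALSE)
  if (!(cfg$train_fraction > 0 && cfg$train_fraction < 1))
    stop("train_fraction must lie strictly between 0 and 1", call. = FALSE)
  if (cfg$k_small < 2 || cfg$k_large < 2)
    stop("fold counts must be at least 2", call. = FALSE)
  if (cfg$lambda_grid_size < 2)
    stop("lambda_grid_size must be at least 2", call. = FALSE)
  if (cfg$cv_repeats < 1) stop("cv_repeats must be positive", call. = FALSE)
  if (cfg$fold_change_threshold < 1)
    stop("fold_change_threshold must be >= 1", call. = FALSE)
  cfg
}

#' Log-spaced lambda grid for a configuration
#' @param config a [run_config()] object.
#' @return decreasing numeric vector of lambda values.
#' @export
lambda_grid <- function(config) {
  exp(seq(log(config$lambda_max), log(config$lambda_min),
          length.out = config$lambda_grid_size))
}

#' Read / write a run configuration as JSON
#'
#' @param path file path.
#' @return `read_run_config` returns a `RunConfig`; `write_run_config`
#'   returns `path` invisibly.
#' @export
read_run_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  known <- names(formals(run_config))
  unknown <- setdiff(names(raw), c(known, "profile"))
  if (length(unknown))
    stop("unknown config field(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  do.call(run_config, raw)
}

#' @rdname read_run_config
#' @param config a `RunConfig`.
#' @export
write_run_config <- function(config, path) {
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' @export
print.RunConfig <- function(x, ...) {
  cat("RunConfig (profile:", x$profile, ")\n")
  cat(sprintf("  alpha=%g  lambda in [%g, %g] x %d points\n",
              x$alpha, x$lambda_min, x$lambda_max, x$lambda_grid_size))
  cat(sprintf("  CV: %d repeats, k=%d/%d (threshold %d), train %g%%\n",
              x$cv_repeats, x$k_small, x$k_large,
              as.integer(x$small_cohort_threshold),
              100 * x$train_fraction))
  cat(sprintf("  FC threshold %g, FDR alpha %g, seed %d\n",
              x$fold_change_threshold, x$fdr_alpha, x$seed))
  invisible(x)
}
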