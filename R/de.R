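#' Inverse of the trigamma function
#'
#' Newton iteration on `1/trigamma`, monotone and fast-converging; used to
#' solve for the prior degrees of freedom in [moderate_variances()].
#'
#' @param x positive value.
#' @return y such that `trigamma(y) = x`.
#' @export
trigamma_inverse <- function(x) {
  stopifnot(x > 0)
  if (x > 1e7) return(1 / sqrt(x))
  if (x < 1e-6) return(1 / x)
  y <- 0.5 + 1 / x
  for (i in 1:50) {
    tri <- trigamma(y)
    dif <- tri * (1 - tri / x) / psigamma(y, 2)
    y <- y + dif
    if (abs(dif / y) < 1e-10) break
  }
  y
}

#' Empirical-Bayes moderation of per-feature variances
#'
#' Shrinks per-feature sample variances toward a common prior:
#' `s2_post = (d0*s0^2 + d*s2) / (d0 + d)`. The prior degrees of freedom
#' `d0` and prior variance `s0^2` are estimated by the method of moments
#' on the log variances (mean and variance of `log s2` against the
#' moments of a log scaled-F distribution). When the observed log
#' variances are no more dispersed than sampling noise, `d0` is infinite
#' and every posterior variance collapses to `s0^2`.
#'
#' @param s2 per-feature sample variances.
#' @param d residual degrees of freedom (scalar).
#' @param var_floor strictly positive floor applied to zero variances.
#' @return list with `d0`, `s0_2` and `s2_post` (per feature).
#' @export
moderate_variances <- function(s2, d, var_floor = 1e-8) {
  stopifnot(d > 0, length(s2) >= 2)
  if (length(s2) < 10)
    warning("fewer than 10 features: prior estimation is unstable",
            call. = FALSE)
  if (any(s2 <= 0)) {
    osl_log("moderate_variances: %d zero variance(s) floored",
            sum(s2 <= 0))
    s2 <- pmax(s2, var_floor)
  }
  z <- log(s2)
  evar <- var(z) - trigamma(d / 2)
  if (is.finite(evar) && evar > 0) {
    d0 <- 2 * trigamma_inverse(evar)
    s0_2 <- exp(mean(z) - digamma(d / 2) + log(d / 2) +
                  digamma(d0 / 2) - log(d0 / 2))
    s2_post <- (d0 * s0_2 + d * s2) / (d0 + d)
  } else {
    # log variances no more dispersed than sampling noise: infinite prior
    # df; the prior scale is the geometric mean, so exactly equal
    # variances moderate to themselves
    d0 <- Inf
    s0_2 <- exp(mean(z))
    s2_post <- rep(s0_2, length(s2))
  }
  list(d0 = d0, s0_2 = s0_2, s2_post = s2_post)
}

#' Fold-change-thresholded moderated t-test p-value
#'
#' Tests `H0: |logFC| <= tau` against `|logFC| > tau` with a moderated
#' standard error:
#' `p = P(T >= (|logFC|-tau)/se) + P(T >= (|logFC|+tau)/se)` on `df`
#' degrees of freedom. At `tau = 0` this is the ordinary two-sided
#' moderated t-test; at `logFC = 0` the p-value is exactly 1.
#'
#' @param logfc log2 fold changes.
#' @param se moderated standard errors.
#' @param df total degrees of freedom (residual + prior).
#' @param tau non-negative log2 fold-change threshold.
#' @return vector of p-values.
#' @export
treat_test <- function(logfc, se, df, tau) {
  if (tau < 0) stop("tau must be non-negative", call. = FALSE)
  stopifnot(all(se > 0))
  af <- abs(logfc)
  pt((af - tau) / se, df, lower.tail = FALSE) +
    pt((af + tau) / se, df, lower.tail = FALSE)
}

#' Moderated two-group treat comparison of two expression blocks
#'
#' Computes per-feature log2 fold changes (group A minus group B on
#' already-log-scale data), pooled within-group variances, empirical-Bayes
#' moderation, and the fold-change-thresholded p-value, with BH
#' adjustment over the features.
#'
#' @param a,b numeric features-by-samples matrices with identical rownames.
#' @param tau log2 fold-change threshold.
#' @return data.frame with columns `feature`, `logfc`, `s2`, `s2_post`,
#'   `d0`, `s0_2`, `df_residual`, `df_total`, `se`, `tau`, `p`, `q`,
#'   `direction`.
#' @export
moderated_treat <- function(a, b, tau) {
  stopifnot(is.matrix(a), is.matrix(b),
            identical(rownames(a), rownames(b)))
  n1 <- ncol(a); n2 <- ncol(b)
  if (n1 < 2 || n2 < 2) stop("need >= 2 samples per group", call. = FALSE)
  d <- n1 + n2 - 2
  logfc <- rowMeans(a) - rowMeans(b)
  ss <- rowSums((a - rowMeans(a))^2) + rowSums((b - rowMeans(b))^2)
  s2 <- ss / d
  mod <- moderate_variances(s2, d)
  df_total <- if (is.finite(mod$d0)) d + mod$d0 else Inf
  se <- sqrt(mod$s2_post * (1 / n1 + 1 / n2))
  p <- treat_test(logfc, se, df_total, tau)
  data.frame(feature = rownames(a), logfc = logfc, s2 = s2,
             s2_post = mod$s2_post, d0 = mod$d0, s0_2 = mod$s0_2,
             df_residual = d, df_total = df_total, se = se, tau = tau,
             p = p, q = fdr_adjust(p),
             direction = ifelse(logfc > 0, "over", "under"),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Differential expression of predictors, each tumour phenotype vs normal
#'
#' For each tumour phenotype, contrasts the named features against the
#' normal-phenotype samples with the fold-change-thresholded moderated
#' test at `tau = log2(fold_change_threshold)`; BH adjustment per
#' contrast. Data are assumed already on a log2-like continuous scale.
#'
#' @param dataset a `MultiOmicDataset`.
#' @param features feature ids to test (all must be measured).
#' @param config a [run_config()] (supplies the fold-change threshold).
#' @param normal_phenotype reference phenotype label.
#' @return data.frame of per-(phenotype, feature) results with a
#'   `phenotype` column added to the [moderated_treat()] output.
#' @export
de_per_phenotype <- function(dataset, features, config,
                             normal_phenotype = "Normal") {
  missing_f <- setdiff(features, rownames(dataset$values))
  if (length(missing_f))
    stop("feature(s) not in dataset: ",
         paste(missing_f, collapse = ", "), call. = FALSE)
  if (!(normal_phenotype %in% dataset$sample_phenotype))
    stop("normal phenotype '", normal_phenotype, "' has no samples",
         call. = FALSE)
  tau <- log2(config$fold_change_threshold)
  normal_cols <- dataset$sample_phenotype == normal_phenotype
  b <- dataset$values[features, normal_cols, drop = FALSE]
  out <- list()
  for (ph in setdiff(phenotypes(dataset), normal_phenotype)) {
    a <- dataset$values[features,
                        dataset$sample_phenotype == ph, drop = FALSE]
    res <- moderated_treat(a, b, tau)
    res$phenotype <- ph
    out[[ph]] <- res
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
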