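#' Masked-prediction RMSE of a fitted model
#'
#' Prediction error on the held-out samples using only the coefficients of
#' one omic; coefficients of all other omics are zeroed in the already
#' fitted model — never refitted. The intercept is retained in every
#' masked prediction. `omic = "all"` reproduces the full-model test RMSE;
#' `omic = "none"` gives the intercept-only RMSE. RMSE is reported in
#' standardized response units (training mean/sd).
#'
#' @param model a `GeneModel`.
#' @param dataset the `MultiOmicDataset` the model was fitted on.
#' @param omic `"all"`, `"none"`, or one of `"methylation"`,
#'   `"transcript"`, `"mirna"`.
#' @param samples sample ids to evaluate on (default: the model's test
#'   samples).
#' @return the RMSE (non-negative scalar).
#' @export
masked_rmse <- function(model, dataset, omic = "all",
                        samples = model$test_samples) {
  stopifnot(inherits(model, "GeneModel"),
            omic %in% c("all", "none", OMIC_LEVELS))
  y <- (dataset$values[model$gene, samples] - model$scaling$y_mean) /
    model$scaling$y_sd
  pred <- masked_prediction(model, dataset, omic, samples)
  sqrt(mean((y - pred)^2))
}

# standardized-scale prediction restricted to one omic's coefficients
masked_prediction <- function(model, dataset, omic, samples) {
  pred <- rep(model$intercept, length(samples))
  if (omic == "none" || !length(model$beta)) return(pred)
  keep <- if (omic == "all") rep(TRUE, length(model$beta))
          else unname(dataset$feature_omic[names(model$beta)]) == omic
  sc <- model$scaling$feature
  for (j in which(keep)) {
    f <- names(model$beta)[j]
    x <- (dataset$values[f, samples] - sc$mean[j]) / sc$sd[j]
    pred <- pred + model$beta[j] * x
  }
  pred
}

#' Omic-wise RMSE decomposition for a set of models
#'
#' @param models a `GeneModelList`.
#' @param dataset the fitted dataset.
#' @return data.frame (one row per model) with columns `gene`,
#'   `phenotype`, `rmse_full` and `rmse_<omic>` for each omic.
#' @export
omic_rmse_table <- function(models, dataset) {
  rows <- lapply(models, function(m) {
    vals <- vapply(OMIC_LEVELS, function(om) masked_rmse(m, dataset, om),
                   numeric(1))
    cbind(data.frame(gene = m$gene, phenotype = m$phenotype,
                     rmse_full = m$rmse_test, stringsAsFactors = FALSE),
          as.data.frame(as.list(setNames(vals,
                                         paste0("rmse_", OMIC_LEVELS)))))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

ks_pair <- function(a, b) {
  t <- suppressWarnings(ks.test(a, b, alternative = "two.sided"))
  c(D = unname(t$statistic), p = unname(t$p.value))
}

#' Compare masked-RMSE distributions across omics and phenotypes
#'
#' Two-sample two-sided Kolmogorov-Smirnov tests: within each phenotype
#' every pair of prediction modes (full model and each omic mask), and for
#' each mode every pair of phenotypes; with `grouping = "pooled"`,
#' phenotypes are pooled first and only mode pairs are tested.
#' Benjamini-Hochberg adjustment is applied within each test family.
#'
#' @param results the data.frame from [omic_rmse_table()].
#' @param grouping `"per_phenotype"` or `"pooled"`.
#' @return data.frame with columns `family`, `group1`, `group2`,
#'   `statistic`, `p`, `q`.
#' @export
compare_rmse_distributions <- function(results,
                                       grouping = c("per_phenotype",
                                                    "pooled")) {
  grouping <- match.arg(grouping)
  modes <- c("rmse_full", paste0("rmse_", OMIC_LEVELS))
  out <- list()
  add <- function(family, g1, g2, a, b) {
    if (length(a) < 2 || length(b) < 2) {
      warning(sprintf("comparison %s vs %s skipped: <2 values", g1, g2),
              call. = FALSE)
      return(invisible(NULL))
    }
    ks <- ks_pair(a, b)
    out[[length(out) + 1L]] <<- data.frame(
      family = family, group1 = g1, group2 = g2,
      statistic = ks[["D"]], p = ks[["p"]], stringsAsFactors = FALSE)
  }
  if (grouping == "per_phenotype") {
    for (ph in unique(results$phenotype)) {
      sub <- results[results$phenotype == ph, ]
      for (i in seq_along(modes)) for (j in seq_len(i - 1L))
        add(paste0("omic_pairs.", ph), modes[j], modes[i],
            sub[[modes[j]]], sub[[modes[i]]])
    }
    phs <- unique(results$phenotype)
    for (m in modes) {
      for (i in seq_along(phs)) for (j in seq_len(i - 1L))
        add(paste0("phenotype_pairs.", m), phs[j], phs[i],
            results[[m]][results$phenotype == phs[j]],
            results[[m]][results$phenotype == phs[i]])
    }
  } else {
    for (i in seq_along(modes)) for (j in seq_len(i - 1L))
      add("pooled_omic_pairs", modes[j], modes[i],
          results[[modes[j]]], results[[modes[i]]])
  }
  res <- do.call(rbind, out)
  if (is.null(res)) return(NULL)
  res$q <- NA_real_
  for (fam in unique(res$family)) {
    idx <- res$family == fam
    res$q[idx] <- p.adjust(res$p[idx], method = "BH")
  }
  rownames(res) <- NULL
  res
}
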