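#' Enrichment of selected predictors for known regulator-target links
#'
#' Tests, per regulator class (omic) and phenotype, whether each gene's
#' model selected known regulators of that gene more often than expected.
#' The universe is the set of measured features of the class having any
#' known-target record in the link table; the `[1,1]` cell counts selected
#' features that are recorded regulators of the gene they predict (an
#' exact (regulator, that gene) record is required). Fisher alternative is
#' `greater`; p-values are FDR-adjusted across genes within each
#' (class, phenotype) family.
#'
#' @param models a `GeneModelList`.
#' @param db a `KnownLinkDB`.
#' @param dataset the fitted `MultiOmicDataset`.
#' @return data.frame with columns `phenotype`, `gene`, `class`, `a`,
#'   `b`, `c`, `d`, `universe_size`, `odds_ratio`, `p`, `q`.
#' @export
known_link_test <- function(models, db, dataset) {
  stopifnot(inherits(db, "KnownLinkDB"))
  feats <- names(dataset$feature_omic)
  by_reg <- split(db$target_id, db$regulator_id)
  out <- list()
  for (om in OMIC_LEVELS) {
    universe <- feats[dataset$feature_omic == om]
    universe <- universe[universe %in% names(by_reg)]
    if (!length(universe)) {
      osl_log("known_link_test: empty %s universe; skipped", om)
      next
    }
    known_of <- lapply(by_reg[universe], unique)
    for (m in models) {
      sel <- intersect(m$selected_by_omic[[om]], universe)
      known_g <- universe[vapply(known_of[universe],
                                 function(t) m$gene %in% t, TRUE)]
      a <- length(intersect(sel, known_g))
      b <- length(sel) - a
      c_ <- length(known_g) - a
      d <- length(universe) - a - b - c_
      ft <- fisher_exact(rbind(c(a, b), c(c_, d)), "greater")
      out[[length(out) + 1L]] <- data.frame(
        phenotype = m$phenotype, gene = m$gene, class = om,
        a = a, b = b, c = c_, d = d,
        universe_size = length(universe),
        odds_ratio = ft$odds_ratio, p = ft$p,
        stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  if (is.null(res)) return(NULL)
  res$q <- NA_real_
  for (key in unique(paste(res$class, res$phenotype))) {
    idx <- paste(res$class, res$phenotype) == key
    res$q[idx] <- fdr_adjust(res$p[idx])
  }
  rownames(res) <- NULL
  res
}

#' Omic composition of selected predictors vs the input
#'
#' Per phenotype: a chi-square goodness-of-fit test (no continuity
#' correction, df = number of omics - 1) of the distinct selected-feature
#' counts per omic against the input omic proportions, plus a per-omic
#' 2x2 Fisher test (selected/not x this-omic/other) reported with both
#' one-sided alternatives.
#'
#' @param models a `GeneModelList`.
#' @param dataset the fitted `MultiOmicDataset`.
#' @return list with `chisq` (data.frame per phenotype) and `fisher`
#'   (data.frame per phenotype x omic).
#' @export
composition_test <- function(models, dataset) {
  input_counts <- table(factor(dataset$feature_omic, OMIC_LEVELS))
  phs <- unique(vapply(models, `[[`, "", "phenotype"))
  chisq_rows <- list(); fisher_rows <- list()
  for (ph in phs) {
    ms <- models[vapply(models, function(m) m$phenotype == ph, TRUE)]
    sel <- lapply(OMIC_LEVELS, function(om)
      unique(unlist(lapply(ms, function(m) m$selected_by_omic[[om]]))))
    names(sel) <- OMIC_LEVELS
    sel_counts <- vapply(sel, length, integer(1))
    if (sum(sel_counts) == 0) {
      osl_log("composition_test: no selections for %s; skipped", ph)
      next
    }
    gof <- chisq_gof(as.numeric(sel_counts), as.numeric(input_counts))
    chisq_rows[[ph]] <- data.frame(
      phenotype = ph, statistic = gof$statistic, df = gof$df, p = gof$p,
      stringsAsFactors = FALSE)
    for (om in OMIC_LEVELS) {
      a <- sel_counts[[om]]
      b <- sum(sel_counts) - a
      c_ <- input_counts[[om]] - a
      d <- sum(input_counts) - input_counts[[om]] - b
      tab <- rbind(c(a, b), c(c_, d))
      fisher_rows[[paste(ph, om)]] <- data.frame(
        phenotype = ph, omic = om, a = a, b = b, c = c_, d = d,
        odds_ratio = fisher_exact(tab, "greater")$odds_ratio,
        p_over = fisher_exact(tab, "greater")$p,
        p_under = fisher_exact(tab, "less")$p,
        stringsAsFactors = FALSE)
    }
  }
  list(chisq = do.call(rbind, c(chisq_rows, make.row.names = FALSE)),
       fisher = do.call(rbind, c(fisher_rows, make.row.names = FALSE)))
}
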