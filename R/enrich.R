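#' Transcript universe for functional enrichment
#'
#' The enrichment universe is the set of measured transcript features,
#' optionally excluding the target genes themselves (they are responses,
#' not candidate predictors of their own models).
#'
#' @param dataset a `MultiOmicDataset`.
#' @param exclude_targets drop the target genes from the universe
#'   (default `TRUE`).
#' @return character vector of transcript feature ids.
#' @export
transcript_universe <- function(dataset, exclude_targets = TRUE) {
  u <- names(dataset$feature_omic)[dataset$feature_omic == "transcript"]
  if (exclude_targets) u <- setdiff(u, dataset$target_genes)
  u
}

#' Hypergeometric over-representation of a selection in gene sets
#'
#' Upper-tail hypergeometric test of the overlap between a selection and
#' each gene set, both intersected with the universe first; sets smaller
#' than `min_set_size` (after intersection) are skipped. One-sided
#' over-representation only; BH adjustment across the tested sets.
#'
#' @param selection character vector of selected ids (subset of
#'   `universe`).
#' @param sets named list of character vectors (e.g. from [read_gmt()]).
#' @param universe character vector of candidate ids.
#' @param min_set_size minimum in-universe set size to test (default 2,
#'   so two-member sets are admissible).
#' @return data.frame `set`, `universe_size`, `set_size`,
#'   `selection_size`, `overlap`, `p`, `q`, ordered by `p`.
#' @export
hypergeom_enrich <- function(selection, sets, universe,
                             min_set_size = 2) {
  selection <- unique(selection)
  outside <- setdiff(selection, universe)
  if (length(outside))
    stop("selection id(s) outside universe: ",
         paste(head(outside, 5), collapse = ", "), call. = FALSE)
  if (!length(selection)) {
    osl_log("hypergeom_enrich: empty selection; no results")
    return(data.frame(set = character(0), universe_size = integer(0),
                      set_size = integer(0), selection_size = integer(0),
                      overlap = integer(0), p = numeric(0),
                      q = numeric(0), stringsAsFactors = FALSE))
  }
  N <- length(universe)
  rows <- lapply(names(sets), function(nm) {
    s <- intersect(sets[[nm]], universe)
    if (length(s) < min_set_size) return(NULL)
    ov <- length(intersect(s, selection))
    data.frame(set = nm, universe_size = N, set_size = length(s),
               selection_size = length(selection), overlap = ov,
               p = hypergeom_upper(ov, length(s), N, length(selection)),
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  if (is.null(res))
    return(data.frame(set = character(0), universe_size = integer(0),
                      set_size = integer(0), selection_size = integer(0),
                      overlap = integer(0), p = numeric(0),
                      q = numeric(0), stringsAsFactors = FALSE))
  res$q <- fdr_adjust(res$p)
  res <- res[order(res$p, res$set), ]
  rownames(res) <- NULL
  res
}

#' Functional enrichment of selected transcript predictors, per model
#'
#' For every (gene, phenotype) model, tests the model's selected
#' transcript predictors against the gene-set collection over the
#' transcript universe. Models with no transcript selections yield no
#' rows.
#'
#' @param models a `GeneModelList`.
#' @param sets named list of gene sets.
#' @param dataset the fitted `MultiOmicDataset`.
#' @param min_set_size passed to [hypergeom_enrich()].
#' @return data.frame of per-(gene, phenotype, set) results.
#' @export
functional_enrichment <- function(models, sets, dataset,
                                  min_set_size = 2) {
  universe <- transcript_universe(dataset)
  rows <- lapply(models, function(m) {
    sel <- intersect(m$selected_by_omic$transcript, universe)
    if (!length(sel)) return(NULL)
    res <- hypergeom_enrich(sel, sets, universe, min_set_size)
    if (!nrow(res)) return(NULL)
    cbind(data.frame(gene = m$gene, phenotype = m$phenotype,
                     stringsAsFactors = FALSE), res)
  })
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res
}

#' Cross-phenotype selection-exclusivity test
#'
#' Tests whether two selections drawn from a shared candidate universe
#' overlap less than independence predicts (Fisher's exact test,
#' alternative `less` on the joint cell): evidence that selection in one
#' phenotype is exclusive of selection in the other.
#'
#' @param selection_a,selection_b character vectors (subsets of
#'   `universe`).
#' @param universe shared candidate universe.
#' @return the [fisher_exact()] result plus `overlap`, `n_a`, `n_b`,
#'   `universe_size`.
#' @export
exclusivity_test <- function(selection_a, selection_b, universe) {
  selection_a <- unique(selection_a); selection_b <- unique(selection_b)
  out <- setdiff(c(selection_a, selection_b), universe)
  if (length(out))
    stop("selection id(s) outside universe: ",
         paste(head(out, 5), collapse = ", "), call. = FALSE)
  a <- length(intersect(selection_a, selection_b))
  b <- length(selection_a) - a
  c_ <- length(selection_b) - a
  d <- length(universe) - a - b - c_
  ft <- fisher_exact(rbind(c(a, b), c(c_, d)), "less")
  c(ft, list(overlap = a, n_a = length(selection_a),
             n_b = length(selection_b),
             universe_size = length(universe)))
}
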