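new_predictor_network <- function(edges, phenotype) {
  stopifnot(is.data.frame(edges),
            all(c("source", "target", "coefficient", "omic") %in%
                  names(edges)))
  outdeg <- table(edges$source)
  indeg <- table(edges$target)
  structure(list(phenotype = phenotype, edges = edges,
                 outdegree = setNames(as.integer(outdeg), names(outdeg)),
                 indegree = setNames(as.integer(indeg), names(indeg))),
            class = "PredictorNetwork")
}

#' Build the directed predictor-to-gene network for one phenotype
#'
#' One edge per nonzero coefficient in the phenotype's gene models;
#' predictors are sources, target genes are sinks, so a predictor's
#' outdegree is the number of genes it predicts and a gene's indegree is
#' its model size.
#'
#' @param models a `GeneModelList` (models of other phenotypes are
#'   ignored).
#' @param phenotype phenotype label.
#' @return object of class `PredictorNetwork`.
#' @export
build_network <- function(models, phenotype) {
  ms <- models[vapply(models, function(m) m$phenotype == phenotype, TRUE)]
  if (!length(ms)) stop("no models for phenotype ", phenotype,
                        call. = FALSE)
  edges <- do.call(rbind, lapply(ms, function(m) {
    if (!length(m$beta)) return(NULL)
    omic <- unlist(lapply(names(m$selected_by_omic), function(om)
      setNames(rep(om, length(m$selected_by_omic[[om]])),
               m$selected_by_omic[[om]])))
    data.frame(source = names(m$beta), target = m$gene,
               coefficient = unname(m$beta),
               omic = unname(omic[names(m$beta)]),
               stringsAsFactors = FALSE)
  }))
  if (is.null(edges))
    edges <- data.frame(source = character(0), target = character(0),
                        coefficient = numeric(0), omic = character(0))
  rownames(edges) <- NULL
  new_predictor_network(edges, phenotype)
}

#' @export
print.PredictorNetwork <- function(x, ...) {
  cat(sprintf("PredictorNetwork (%s): %d edges, %d predictors, %d genes\n",
              x$phenotype, nrow(x$edges), length(x$outdegree),
              length(x$indegree)))
  invisible(x)
}

#' Predictor sharing and exclusivity across genes and phenotypes
#'
#' Computes, per omic, the fraction of selected predictors that predict
#' exactly one gene (pooled over the given networks); the per
#' (gene, predictor) association its set of phenotypes; and the
#' "universal" associations selected for the same gene in every tumour
#' phenotype.
#'
#' @param networks list of `PredictorNetwork`s (one per phenotype).
#' @param tumor_phenotypes phenotype labels counted as tumour for the
#'   universal set (default: all phenotypes in `networks` except
#'   `normal_phenotype`).
#' @param normal_phenotype the non-tumour label.
#' @return list with `exclusive_fraction` (named per omic),
#'   `association_phenotypes` (data.frame `source`, `target`,
#'   `phenotypes`, `n_phenotypes`), and `universal` (data.frame of
#'   predictor-gene pairs present in all tumour phenotypes).
#' @export
sharing_stats <- function(networks, tumor_phenotypes = NULL,
                          normal_phenotype = "Normal") {
  all_edges <- do.call(rbind, lapply(networks, function(nw)
    cbind(nw$edges, phenotype = nw$phenotype)))
  phs <- vapply(networks, `[[`, "", "phenotype")
  tumor_phenotypes <- tumor_phenotypes %||% setdiff(phs, normal_phenotype)

  # exclusivity: predictors selected for exactly one gene, per omic
  pg <- unique(all_edges[c("source", "target", "omic")])
  genes_per_pred <- table(pg$source)
  exclusive_fraction <- vapply(OMIC_LEVELS, function(om) {
    preds <- unique(pg$source[pg$omic == om])
    if (!length(preds)) return(NA_real_)
    mean(genes_per_pred[preds] == 1)
  }, numeric(1))

  key <- paste(all_edges$source, all_edges$target)
  assoc <- do.call(rbind, lapply(split(all_edges, key), function(e)
    data.frame(source = e$source[1], target = e$target[1],
               phenotypes = paste(sort(unique(e$phenotype)),
                                  collapse = ","),
               n_phenotypes = length(unique(e$phenotype)),
               stringsAsFactors = FALSE)))
  rownames(assoc) <- NULL

  tum <- all_edges[all_edges$phenotype %in% tumor_phenotypes, ]
  tkey <- paste(tum$source, tum$target)
  cover <- tapply(tum$phenotype, tkey, function(x) length(unique(x)))
  universal_keys <- names(cover)[cover == length(tumor_phenotypes)]
  universal <- unique(tum[tkey %in% universal_keys,
                          c("source", "target", "omic")])
  rownames(universal) <- NULL
  list(exclusive_fraction = exclusive_fraction,
       association_phenotypes = assoc, universal = universal)
}

#' Rank predictor hubs and test their coefficient distributions
#'
#' Ranks predictors of one class (miRNAs by default, as in the signature
#' hub analysis) by outdegree within each network, and compares the top
#' hub's coefficient values against the pooled coefficients of all other
#' predictors of that class by a two-sample two-sided KS test.
#'
#' @param networks list of `PredictorNetwork`s.
#' @param dataset the fitted `MultiOmicDataset` (for omic labels).
#' @param class omic class to rank within, or `"any"` for class-agnostic
#'   ranking.
#' @param n_top number of ranked hubs to report per phenotype.
#' @return data.frame with one row per (phenotype, rank): `phenotype`,
#'   `rank`, `hub`, `outdegree`, and for the top hub the KS `statistic`
#'   and `p` vs the rest of the class.
#' @export
hub_analysis <- function(networks, dataset, class = "mirna", n_top = 5) {
  rows <- list()
  for (nw in networks) {
    e <- nw$edges
    if (class != "any") e <- e[e$omic == class, , drop = FALSE]
    if (!nrow(e)) next
    deg <- sort(table(e$source), decreasing = TRUE)
    top <- names(deg)[seq_len(min(n_top, length(deg)))]
    hub_coefs <- e$coefficient[e$source == top[1]]
    rest_coefs <- e$coefficient[e$source != top[1]]
    ks <- if (length(hub_coefs) >= 2 && length(rest_coefs) >= 2)
      ks_pair(hub_coefs, rest_coefs) else c(D = NA_real_, p = NA_real_)
    for (i in seq_along(top)) {
      rows[[length(rows) + 1L]] <- data.frame(
        phenotype = nw$phenotype, rank = i, hub = top[i],
        outdegree = as.integer(deg[[top[i]]]),
        ks_statistic = if (i == 1) ks[["D"]] else NA_real_,
        ks_p = if (i == 1) ks[["p"]] else NA_real_,
        stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res
}

# greedy set cover: largest remaining coverage first, lexicographic ties
greedy_set_cover <- function(sets, universe) {
  uncovered <- universe
  chosen <- character(0)
  sets <- sets[order(names(sets))]
  while (length(uncovered)) {
    gain <- vapply(sets, function(s) length(intersect(s, uncovered)),
                   integer(1))
    if (max(gain) == 0L) return(NULL)   # cover infeasible
    pick <- names(sets)[which.max(gain)]  # first index = lexicographic tie
    chosen <- c(chosen, pick)
    uncovered <- setdiff(uncovered, sets[[pick]])
  }
  chosen
}

# exact minimum cover by exhaustive search (small instances only)
exact_set_cover_size <- function(sets, universe) {
  nm <- names(sets)
  if (length(nm) > 20) stop("exact cover limited to <=20 sets")
  for (k in seq_along(nm)) {
    combos <- utils::combn(nm, k, simplify = FALSE)
    for (cmb in combos) {
      if (all(universe %in% unlist(sets[cmb]))) return(k)
    }
  }
  NA_integer_
}

#' Connectivity and bridging after predictor knockout
#'
#' Removes named predictor nodes from the bipartite predictor-gene graph,
#' reports the connected-component sizes of its undirected projection, and
#' estimates (greedily: largest remaining coverage first, lexicographic
#' tie-break) the minimum number of remaining predictors whose gene sets
#' jointly cover all genes.
#'
#' @param network a `PredictorNetwork`.
#' @param remove character vector of predictor ids to knock out (may be
#'   empty); non-existent ids produce a warning and are ignored.
#' @return list with `component_sizes` (decreasing integer vector),
#'   `n_components`, `bridging_set` (greedy cover, `NULL` when no cover
#'   exists), `bridging_set_size` (`NA` when undefined), and `genes`
#'   (genes remaining in the graph).
#' @export
knockout_connectivity <- function(network, remove = character(0)) {
  stopifnot(inherits(network, "PredictorNetwork"))
  e <- network$edges
  if (!nrow(e))
    return(list(component_sizes = integer(0), n_components = 0L,
                bridging_set = NULL, bridging_set_size = NA_integer_,
                genes = character(0)))
  missing <- setdiff(remove, unique(e$source))
  if (length(missing))
    warning("knockout of absent predictor(s): ",
            paste(missing, collapse = ", "), call. = FALSE)
  e <- e[!(e$source %in% remove), , drop = FALSE]
  genes <- unique(network$edges$target)
  if (!nrow(e))
    return(list(component_sizes = rep(1L, length(genes)),
                n_components = length(genes), bridging_set = NULL,
                bridging_set_size = NA_integer_, genes = genes))
  g <- igraph::graph_from_data_frame(
    e[c("source", "target")], directed = FALSE,
    vertices = unique(c(e$source, genes)))
  comp <- igraph::components(g)
  gene_sets <- lapply(split(e$target, e$source), unique)
  cover <- greedy_set_cover(gene_sets, genes)
  list(component_sizes = sort(as.integer(comp$csize), decreasing = TRUE),
       n_components = comp$no,
       bridging_set = cover,
       bridging_set_size = if (is.null(cover)) NA_integer_
                           else length(cover),
       genes = genes)
}

#' Genes with models larger than the phenotype average
#'
#' Flags genes whose model size (indegree) exceeds the mean indegree of
#' their phenotype's network.
#'
#' @param network a `PredictorNetwork`.
#' @return data.frame `gene`, `indegree`, `above_average`.
#' @export
large_model_genes <- function(network) {
  ind <- network$indegree
  data.frame(gene = names(ind), indegree = as.integer(ind),
             above_average = ind > mean(ind), row.names = NULL,
             stringsAsFactors = FALSE)
}
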