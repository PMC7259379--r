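#' Construct a multi-omic dataset
#'
#' The central data container: a numeric features-by-samples matrix with a
#' per-feature omic label (`methylation`, `transcript` or `mirna`), a
#' per-sample phenotype label, and a flagged subset of transcript rows that
#' are the modelling targets (the signature genes).
#'
#' @param values numeric matrix, features in rows, samples in columns, with
#'   unique `rownames` (feature ids) and `colnames` (sample ids).
#' @param feature_omic character vector (one per feature) of omic labels.
#' @param sample_phenotype character vector (one per sample) of phenotype
#'   labels.
#' @param target_genes character vector of transcript feature ids to model.
#' @return object of class `MultiOmicDataset`.
#' @export
multiomic_dataset <- function(values, feature_omic, sample_phenotype,
                              target_genes) {
  stopifnot(is.matrix(values), is.numeric(values))
  fid <- rownames(values); sid <- colnames(values)
  if (is.null(fid) || is.null(sid))
    stop("values must carry feature rownames and sample colnames",
         call. = FALSE)
  dup <- fid[duplicated(fid)]
  if (length(dup))
    stop("duplicate feature id(s): ", paste(unique(dup), collapse = ", "),
         call. = FALSE)
  dup <- sid[duplicated(sid)]
  if (length(dup))
    stop("duplicate sample id(s): ", paste(unique(dup), collapse = ", "),
         call. = FALSE)
  if (length(feature_omic) != nrow(values))
    stop("feature_omic must have one entry per feature", call. = FALSE)
  if (length(sample_phenotype) != ncol(values))
    stop("sample_phenotype must have one entry per sample", call. = FALSE)
  feature_omic <- as.character(feature_omic)
  bad <- setdiff(unique(feature_omic), OMIC_LEVELS)
  if (length(bad))
    stop("unknown omic label(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  if (length(unique(feature_omic)) < 2)
    stop("at least 2 omics must be present", call. = FALSE)
  if (anyNA(values))
    stop("missing values in matrix; impute or filter before construction",
         call. = FALSE)
  target_genes <- as.character(target_genes)
  missing_t <- setdiff(target_genes, fid)
  if (length(missing_t))
    stop("target gene(s) absent from matrix: ",
         paste(missing_t, collapse = ", "), call. = FALSE)
  not_tx <- target_genes[feature_omic[match(target_genes, fid)] != "transcript"]
  if (length(not_tx))
    stop("target gene(s) not transcript features: ",
         paste(not_tx, collapse = ", "), call. = FALSE)
  structure(list(values = values,
                 feature_omic = setNames(feature_omic, fid),
                 sample_phenotype = setNames(as.character(sample_phenotype),
                                             sid),
                 target_genes = target_genes),
            class = "MultiOmicDataset")
}

#' @export
print.MultiOmicDataset <- function(x, ...) {
  cat(sprintf("MultiOmicDataset: %d features x %d samples\n",
              nrow(x$values), ncol(x$values)))
  cat("  omics:     ",
      paste(sprintf("%s=%d", names(table(x$feature_omic)),
                    table(x$feature_omic)), collapse = ", "), "\n")
  cat("  phenotypes:",
      paste(sprintf("%s=%d", names(table(x$sample_phenotype)),
                    table(x$sample_phenotype)), collapse = ", "), "\n")
  cat("  target genes:", length(x$target_genes), "\n")
  invisible(x)
}

#' Phenotype labels present in a dataset
#' @param dataset a `MultiOmicDataset`.
#' @return character vector of unique phenotype labels, in column order.
#' @export
phenotypes <- function(dataset) unique(unname(dataset$sample_phenotype))

#' Read / write a multi-omic dataset as TSV
#'
#' The matrix file is TSV with a `feature_id` first column and sample ids
#' in the header. The annotation file is a long-format TSV with columns
#' `id`, `kind`, `value`, where `kind` is one of `feature_omic` (value =
#' omic label), `sample_phenotype` (value = phenotype) or `target_gene`
#' (value ignored). Readers reject malformed input rather than coerce.
#'
#' @param matrix_path path to the matrix TSV.
#' @param annotation_path path to the annotation TSV.
#' @param impute_median if `TRUE`, missing values are replaced by the
#'   per-feature median; by default missing values are rejected.
#' @return a `MultiOmicDataset`.
#' @export
read_multiomic <- function(matrix_path, annotation_path,
                           impute_median = FALSE) {
  tab <- read.delim(matrix_path, check.names = FALSE,
                    stringsAsFactors = FALSE)
  if (ncol(tab) < 2) stop("matrix file needs id column plus samples",
                          call. = FALSE)
  fid <- as.character(tab[[1]])
  dup <- unique(fid[duplicated(fid)])
  if (length(dup))
    stop("duplicate feature id(s) in matrix: ",
         paste(dup, collapse = ", "), call. = FALSE)
  vals <- as.matrix(tab[, -1, drop = FALSE])
  if (!is.numeric(vals)) stop("non-numeric entries in matrix",
                              call. = FALSE)
  rownames(vals) <- fid
  ann <- read.delim(annotation_path, stringsAsFactors = FALSE)
  need <- c("id", "kind", "value")
  if (!all(need %in% names(ann)))
    stop("annotation must have columns id, kind, value", call. = FALSE)
  fo <- ann[ann$kind == "feature_omic", ]
  sp <- ann[ann$kind == "sample_phenotype", ]
  tg <- ann$id[ann$kind == "target_gene"]
  unlabelled <- setdiff(fid, fo$id)
  if (length(unlabelled))
    stop("feature(s) without omic label: ",
         paste(head(unlabelled, 5), collapse = ", "), call. = FALSE)
  unlabelled <- setdiff(colnames(vals), sp$id)
  if (length(unlabelled))
    stop("sample(s) without phenotype label: ",
         paste(head(unlabelled, 5), collapse = ", "), call. = FALSE)
  if (anyNA(vals)) {
    if (!impute_median)
      stop("missing values in matrix (set impute_median = TRUE to impute)",
           call. = FALSE)
    for (i in which(rowSums(is.na(vals)) > 0)) {
      v <- vals[i, ]
      v[is.na(v)] <- median(v, na.rm = TRUE)
      vals[i, ] <- v
    }
  }
  multiomic_dataset(vals,
                    feature_omic = fo$value[match(fid, fo$id)],
                    sample_phenotype = sp$value[match(colnames(vals), sp$id)],
                    target_genes = tg)
}

#' @rdname read_multiomic
#' @param dataset a `MultiOmicDataset`.
#' @return `write_multiomic` returns the two paths invisibly.
#' @export
write_multiomic <- function(dataset, matrix_path, annotation_path) {
  df <- data.frame(feature_id = rownames(dataset$values),
                   dataset$values, check.names = FALSE)
  write.table(df, matrix_path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  ann <- rbind(
    data.frame(id = names(dataset$feature_omic), kind = "feature_omic",
               value = unname(dataset$feature_omic)),
    data.frame(id = names(dataset$sample_phenotype),
               kind = "sample_phenotype",
               value = unname(dataset$sample_phenotype)),
    if (length(dataset$target_genes))
      data.frame(id = dataset$target_genes, kind = "target_gene",
                 value = "yes")
  )
  write.table(ann, annotation_path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(c(matrix_path, annotation_path))
}

#' Read / write gene-set collections in GMT format
#'
#' Standard GMT: one set per line, tab-separated fields
#' `name<TAB>description<TAB>member...`. Empty sets are dropped with a
#' warning; duplicate members within a line are deduplicated.
#'
#' @param path file path.
#' @return named list of character vectors (member ids), with the set
#'   descriptions in `attr(, "description")`.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  sets <- list(); descs <- character(0)
  for (i in seq_along(lines)) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) < 3)
      stop(sprintf("GMT line %d has %d field(s); at least 3 required",
                   i, length(f)), call. = FALSE)
    members <- unique(f[-(1:2)])
    members <- members[nzchar(members)]
    if (!length(members)) {
      warning(sprintf("GMT set '%s' (line %d) is empty; dropped",
                      f[1], i), call. = FALSE)
      next
    }
    sets[[f[1]]] <- members
    descs[f[1]] <- f[2]
  }
  attr(sets, "description") <- descs
  sets
}

#' @rdname read_gmt
#' @param sets named list of character vectors.
#' @param description optional named character vector of set descriptions.
#' @export
write_gmt <- function(sets, path, description = NULL) {
  description <- description %||% attr(sets, "description")
  lines <- vapply(names(sets), function(nm) {
    d <- if (!is.null(description) && nm %in% names(description))
      description[[nm]] else "na"
    paste(c(nm, d, sets[[nm]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Construct a known regulator-target link table
#'
#' @param regulator_id,target_id character vectors of equal length.
#' @param evidence `"predicted"` or `"validated"`, recycled.
#' @param source free-text provenance label, recycled.
#' @return data.frame of class `KnownLinkDB`.
#' @export
known_link_db <- function(regulator_id, target_id,
                          evidence = "predicted", source = "unspecified") {
  db <- data.frame(regulator_id = as.character(regulator_id),
                   target_id = as.character(target_id),
                   evidence = as.character(evidence),
                   source = as.character(source),
                   stringsAsFactors = FALSE)
  bad <- setdiff(unique(db$evidence), c("predicted", "validated"))
  if (length(bad))
    stop("evidence must be 'predicted' or 'validated', got: ",
         paste(bad, collapse = ", "), call. = FALSE)
  if (anyDuplicated(db[c("regulator_id", "target_id", "source")]))
    stop("duplicate (regulator, target, source) triple(s)", call. = FALSE)
  class(db) <- c("KnownLinkDB", "data.frame")
  db
}

#' Read / write known-link tables as TSV
#'
#' Header columns: `regulator_id`, `target_id`, `evidence`, `source`.
#' @param path file path.
#' @return a `KnownLinkDB`.
#' @export
read_known_links <- function(path) {
  tab <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("regulator_id", "target_id", "evidence", "source")
  if (!all(need %in% names(tab)))
    stop("link table must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  known_link_db(tab$regulator_id, tab$target_id, tab$evidence, tab$source)
}

#' @rdname read_known_links
#' @param db a `KnownLinkDB`.
#' @export
write_known_links <- function(db, path) {
  write.table(as.data.frame(db), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' Write / read a predictor-gene network as an edge-list TSV
#'
#' Columns: `source` (predictor), `target` (gene), `coefficient`, `omic`,
#' `phenotype`. The file is importable as a directed edge list by standard
#' graph tools; coefficients are written in full precision.
#'
#' @param network a `PredictorNetwork` (see [build_network()]).
#' @param path file path.
#' @export
write_edge_list <- function(network, path) {
  stopifnot(inherits(network, "PredictorNetwork"))
  e <- network$edges
  out <- data.frame(source = e$source, target = e$target,
                    coefficient = sprintf("%.15g", e$coefficient),
                    omic = e$omic, phenotype = network$phenotype)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_edge_list
#' @return `read_edge_list` returns a `PredictorNetwork`.
#' @export
read_edge_list <- function(path) {
  tab <- read.delim(path, stringsAsFactors = FALSE,
                    colClasses = c(source = "character",
                                   target = "character"))
  need <- c("source", "target", "coefficient", "omic", "phenotype")
  if (!all(need %in% names(tab)))
    stop("edge list must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  phen <- unique(tab$phenotype)
  if (length(phen) > 1)
    stop("edge list mixes phenotypes: ", paste(phen, collapse = ", "),
         call. = FALSE)
  new_predictor_network(
    data.frame(source = tab$source, target = tab$target,
               coefficient = as.numeric(tab$coefficient), omic = tab$omic,
               stringsAsFactors = FALSE),
    phenotype = if (length(phen)) phen else NA_character_)
}
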