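stage_files <- list(
  simulate = c("dataset_matrix.tsv", "dataset_annotation.tsv",
               "ground_truth.json", "known_links.tsv",
               "function_sets.gmt"),
  fit = c("models.json", "selection_summary.tsv"),
  decompose = c("omic_rmse.tsv", "rmse_comparisons.tsv",
                "rmse_comparisons_pooled.tsv"),
  links = c("link_enrichment.tsv", "composition_chisq.tsv",
            "composition_fisher.tsv"),
  network = c("sharing_exclusivity.tsv", "universal_predictors.tsv",
              "hub_report.json", "knockout.json"),
  de = c("de_results.tsv"),
  funcenrich = c("functional_enrichment.tsv", "exclusivity_tests.tsv"))

write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

load_stage_dataset <- function(dir) {
  read_multiomic(file.path(dir, "dataset_matrix.tsv"),
                 file.path(dir, "dataset_annotation.tsv"))
}

#' Individual pipeline stages
#'
#' Each stage reads the files written by its upstream stages from `dir`
#' and writes its own outputs there, so stages can be run standalone or
#' chained; [run_all()] calls exactly these functions.
#'
#' @param sim_cfg a [sim_config()].
#' @param run_cfg a [run_config()].
#' @param dir working directory holding stage inputs/outputs.
#' @return invisibly, the paths written.
#' @name pipeline_stages
NULL

#' @rdname pipeline_stages
#' @export
stage_simulate <- function(sim_cfg, dir) {
  sim <- simulate_dataset(sim_cfg)
  write_multiomic(sim$dataset, file.path(dir, "dataset_matrix.tsv"),
                  file.path(dir, "dataset_annotation.tsv"))
  write_ground_truth(sim$truth, file.path(dir, "ground_truth.json"))
  write_known_links(simulate_known_links(sim$truth, sim_cfg),
                    file.path(dir, "known_links.tsv"))
  write_gmt(simulate_function_sets(sim$truth, sim_cfg),
            file.path(dir, "function_sets.gmt"))
  invisible(file.path(dir, stage_files$simulate))
}

#' @rdname pipeline_stages
#' @export
stage_fit <- function(run_cfg, dir) {
  dataset <- load_stage_dataset(dir)
  split <- make_split(dataset, run_cfg)
  models <- fit_all(dataset, split, run_cfg)
  write_models(models, file.path(dir, "models.json"))
  write_tsv(selection_summary(models),
            file.path(dir, "selection_summary.tsv"))
  invisible(file.path(dir, stage_files$fit))
}

#' @rdname pipeline_stages
#' @export
stage_decompose <- function(run_cfg, dir) {
  dataset <- load_stage_dataset(dir)
  models <- read_models(file.path(dir, "models.json"), dataset)
  tab <- omic_rmse_table(models, dataset)
  write_tsv(tab, file.path(dir, "omic_rmse.tsv"))
  write_tsv(compare_rmse_distributions(tab, "per_phenotype"),
            file.path(dir, "rmse_comparisons.tsv"))
  write_tsv(compare_rmse_distributions(tab, "pooled"),
            file.path(dir, "rmse_comparisons_pooled.tsv"))
  invisible(file.path(dir, stage_files$decompose))
}

#' @rdname pipeline_stages
#' @export
stage_links <- function(run_cfg, dir) {
  dataset <- load_stage_dataset(dir)
  models <- read_models(file.path(dir, "models.json"), dataset)
  db <- read_known_links(file.path(dir, "known_links.tsv"))
  write_tsv(known_link_test(models, db, dataset),
            file.path(dir, "link_enrichment.tsv"))
  comp <- composition_test(models, dataset)
  write_tsv(comp$chisq, file.path(dir, "composition_chisq.tsv"))
  write_tsv(comp$fisher, file.path(dir, "composition_fisher.tsv"))
  invisible(file.path(dir, stage_files$links))
}

#' @rdname pipeline_stages
#' @param normal_phenotype non-tumour phenotype label.
#' @export
stage_network <- function(run_cfg, dir, normal_phenotype = "Normal") {
  dataset <- load_stage_dataset(dir)
  models <- read_models(file.path(dir, "models.json"), dataset)
  phs <- unique(vapply(models, `[[`, "", "phenotype"))
  networks <- lapply(phs, function(ph) build_network(models, ph))
  names(networks) <- phs
  for (ph in phs)
    write_edge_list(networks[[ph]],
                    file.path(dir, sprintf("network_%s.tsv", ph)))
  sh <- sharing_stats(networks, normal_phenotype = normal_phenotype)
  write_tsv(data.frame(omic = names(sh$exclusive_fraction),
                       exclusive_fraction = sh$exclusive_fraction),
            file.path(dir, "sharing_exclusivity.tsv"))
  write_tsv(sh$universal, file.path(dir, "universal_predictors.tsv"))
  hubs <- hub_analysis(networks, dataset)
  jsonlite::write_json(hubs, file.path(dir, "hub_report.json"),
                       auto_unbox = TRUE, digits = NA)
  top_hubs <- unique(hubs$hub[hubs$rank == 1])
  ko <- lapply(networks, function(nw) {
    before <- knockout_connectivity(nw, character(0))
    after <- suppressWarnings(knockout_connectivity(nw, top_hubs))
    list(phenotype = nw$phenotype,
         bridging_before = before$bridging_set_size,
         bridging_after = after$bridging_set_size,
         components_before = before$n_components,
         components_after = after$n_components)
  })
  jsonlite::write_json(unname(ko), file.path(dir, "knockout.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(file.path(dir, stage_files$network))
}

#' @rdname pipeline_stages
#' @export
stage_de <- function(run_cfg, dir, normal_phenotype = "Normal") {
  dataset <- load_stage_dataset(dir)
  hubs <- jsonlite::read_json(file.path(dir, "hub_report.json"),
                              simplifyVector = TRUE)
  features <- unique(hubs$hub)
  res <- de_per_phenotype(dataset, features, run_cfg,
                          normal_phenotype = normal_phenotype)
  write_tsv(res, file.path(dir, "de_results.tsv"))
  invisible(file.path(dir, stage_files$de))
}

#' @rdname pipeline_stages
#' @export
stage_funcenrich <- function(run_cfg, dir) {
  dataset <- load_stage_dataset(dir)
  models <- read_models(file.path(dir, "models.json"), dataset)
  sets <- read_gmt(file.path(dir, "function_sets.gmt"))
  fe <- functional_enrichment(models, sets, dataset)
  write_tsv(fe, file.path(dir, "functional_enrichment.tsv"))
  # cross-phenotype exclusivity of transcript selections, per gene
  universe <- transcript_universe(dataset)
  genes <- unique(vapply(models, `[[`, "", "gene"))
  phs <- unique(vapply(models, `[[`, "", "phenotype"))
  rows <- list()
  for (g in genes) {
    sel <- lapply(phs, function(ph) {
      m <- models[[paste(ph, g, sep = ".")]]
      if (is.null(m)) character(0)
      else intersect(m$selected_by_omic$transcript, universe)
    })
    names(sel) <- phs
    for (i in seq_along(phs)) for (j in seq_len(i - 1L)) {
      if (!length(sel[[i]]) || !length(sel[[j]])) next
      et <- exclusivity_test(sel[[j]], sel[[i]], universe)
      rows[[length(rows) + 1L]] <- data.frame(
        gene = g, phenotype_a = phs[j], phenotype_b = phs[i],
        overlap = et$overlap, n_a = et$n_a, n_b = et$n_b,
        universe_size = et$universe_size, odds_ratio = et$odds_ratio,
        p = et$p, stringsAsFactors = FALSE)
    }
  }
  ex <- do.call(rbind, rows)
  if (!is.null(ex)) ex$q <- fdr_adjust(ex$p)
  write_tsv(ex %||% data.frame(), file.path(dir, "exclusivity_tests.tsv"))
  invisible(file.path(dir, stage_files$funcenrich))
}

jaccard <- function(a, b) {
  u <- length(union(a, b))
  if (u == 0) return(NA_real_)
  length(intersect(a, b)) / u
}

#' Robustness refit on a fixed per-phenotype sample size
#'
#' Refits every model using `subsample_n` samples per phenotype (the
#' stated-size robustness probe) and compares selected predictor sets to
#' the full-size models by Jaccard index.
#'
#' @param run_cfg a [run_config()] with `subsample_n` set.
#' @param dir working directory with `models.json` and the dataset files.
#' @return invisibly, the path of `subsample_jaccard.tsv`.
#' @export
stage_subsample <- function(run_cfg, dir) {
  stopifnot(!is.null(run_cfg$subsample_n))
  dataset <- load_stage_dataset(dir)
  full <- read_models(file.path(dir, "models.json"), dataset)
  split <- make_split(dataset, run_cfg)
  sub <- fit_all(dataset, split, run_cfg)
  rows <- lapply(names(sub), function(key) {
    if (is.null(full[[key]])) return(NULL)
    data.frame(gene = sub[[key]]$gene, phenotype = sub[[key]]$phenotype,
               n_selected_full = length(full[[key]]$beta),
               n_selected_sub = length(sub[[key]]$beta),
               jaccard = jaccard(names(full[[key]]$beta),
                                 names(sub[[key]]$beta)),
               stringsAsFactors = FALSE)
  })
  write_models(sub, file.path(dir, "models_subsample.json"))
  write_tsv(do.call(rbind, rows), file.path(dir, "subsample_jaccard.tsv"))
  invisible(file.path(dir, "subsample_jaccard.tsv"))
}

#' Run the full pipeline from one configuration
#'
#' Executes simulate, fit, decompose, links, network, de and funcenrich in
#' dependency order (plus the fixed-size robustness refit when
#' `subsample_n` is set), recording per-stage status, timing and output
#' digests in a run manifest. A stage failure halts downstream stages but
#' preserves completed outputs.
#'
#' @param sim_cfg a [sim_config()].
#' @param run_cfg a [run_config()].
#' @param dir output directory (created if needed).
#' @return the manifest, invisibly; also written to `manifest.json`.
#' @export
run_all <- function(sim_cfg, run_cfg, dir) {
  validate_sim_config(sim_cfg)
  validate_run_config(run_cfg)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  normal <- sim_cfg$normal_phenotype
  stages <- list(
    simulate = function() stage_simulate(sim_cfg, dir),
    fit = function() stage_fit(run_cfg, dir),
    decompose = function() stage_decompose(run_cfg, dir),
    links = function() stage_links(run_cfg, dir),
    network = function() stage_network(run_cfg, dir,
                                       normal_phenotype = normal),
    de = function() stage_de(run_cfg, dir, normal_phenotype = normal),
    funcenrich = function() stage_funcenrich(run_cfg, dir))
  if (!is.null(run_cfg$subsample_n))
    stages$subsample <- function() stage_subsample(run_cfg, dir)
  manifest <- list(
    package_version = as.character(utils::packageVersion("omicselect")),
    seed = run_cfg$seed,
    config = list(simulation = unclass(sim_cfg), run = unclass(run_cfg)),
    stages = list())
  for (nm in names(stages)) {
    t0 <- proc.time()[["elapsed"]]
    status <- tryCatch({
      paths <- stages[[nm]]()
      list(status = "ok",
           outputs = as.list(tools::md5sum(paths)))
    }, error = function(e) list(status = "failed",
                                error = conditionMessage(e)))
    status$seconds <- round(proc.time()[["elapsed"]] - t0, 3)
    manifest$stages[[nm]] <- status
    if (status$status == "failed") {
      warning(sprintf("stage %s failed: %s; downstream stages skipped",
                      nm, status$error), call. = FALSE)
      break
    }
  }
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(manifest)
}

parse_cli_flags <- function(args) {
  flags <- list()
  i <- 1L
  while (i <= length(args)) {
    a <- args[i]
    if (!startsWith(a, "--"))
      stop("unexpected argument: ", a, call. = FALSE)
    if (i == length(args)) stop("flag ", a, " needs a value",
                                call. = FALSE)
    flags[[substring(a, 3)]] <- args[i + 1L]
    i <- i + 2L
  }
  flags
}

#' Read a pipeline configuration file (JSON)
#'
#' Expects an object with optional `simulation` and `run` sections whose
#' fields are passed to [sim_config()] and [run_config()].
#'
#' @param path file path.
#' @return list with `simulation` and `run` configs.
#' @export
read_pipeline_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  sim <- raw$simulation %||% list()
  if (!is.null(sim$n_samples)) sim$n_samples <- unlist(sim$n_samples)
  list(simulation = do.call(sim_config, sim),
       run = do.call(run_config, raw$run %||% list()))
}

#' Command-line entry point
#'
#' Subcommands: `run` (full pipeline) and the standalone stages
#' `simulate`, `fit`, `decompose`, `links`, `network`, `de`,
#' `funcenrich`, `subsample`. Flags: `--config <json>` and
#' `--dir <workdir>`; `--seed <int>` overrides both config seeds. Exit
#' status: 0 success, 2 configuration/usage error, 3 data error. The
#' installed launcher in `inst/bin/omicselect` wraps this function.
#'
#' @param args character vector of command-line arguments.
#' @return integer exit status, invisibly.
#' @export
cli_main <- function(args = commandArgs(trailingOnly = TRUE)) {
  usage <- paste(
    "usage: omicselect <run|simulate|fit|decompose|links|network|de|",
    "funcenrich|subsample> --config cfg.json --dir workdir",
    "[--seed N]", sep = "")
  if (!length(args)) { message(usage); return(invisible(2L)) }
  cmd <- args[1]
  known <- c("run", "simulate", "fit", "decompose", "links", "network",
             "de", "funcenrich", "subsample")
  if (!cmd %in% known) {
    message("unknown subcommand: ", cmd, "\n", usage)
    return(invisible(2L))
  }
  cfgs <- tryCatch({
    flags <- parse_cli_flags(args[-1])
    if (is.null(flags$config) || is.null(flags$dir))
      stop("--config and --dir are required", call. = FALSE)
    cfgs <- read_pipeline_config(flags$config)
    if (!is.null(flags$seed)) {
      cfgs$simulation$seed <- as.integer(flags$seed)
      cfgs$run$seed <- as.integer(flags$seed)
    }
    cfgs$dir <- flags$dir
    cfgs
  }, error = function(e) {
    message("configuration error: ", conditionMessage(e))
    NULL
  })
  if (is.null(cfgs)) return(invisible(2L))
  dir.create(cfgs$dir, recursive = TRUE, showWarnings = FALSE)
  normal <- cfgs$simulation$normal_phenotype
  res <- tryCatch({
    switch(cmd,
      run = {
        m <- run_all(cfgs$simulation, cfgs$run, cfgs$dir)
        if (any(vapply(m$stages, `[[`, "", "status") == "failed"))
          stop("one or more stages failed", call. = FALSE)
      },
      simulate = stage_simulate(cfgs$simulation, cfgs$dir),
      fit = stage_fit(cfgs$run, cfgs$dir),
      decompose = stage_decompose(cfgs$run, cfgs$dir),
      links = stage_links(cfgs$run, cfgs$dir),
      network = stage_network(cfgs$run, cfgs$dir,
                              normal_phenotype = normal),
      de = stage_de(cfgs$run, cfgs$dir, normal_phenotype = normal),
      funcenrich = stage_funcenrich(cfgs$run, cfgs$dir),
      subsample = stage_subsample(cfgs$run, cfgs$dir))
    0L
  }, error = function(e) {
    message("error: ", conditionMessage(e))
    3L
  })
  invisible(res)
}
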