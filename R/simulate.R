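#' Simulation configuration for the synthetic multi-omic generator
#'
#' The generator emulates the structure of a preprocessed multi-omic cohort:
#' standardized continuous features drawn from equicorrelated Gaussian
#' blocks, signature genes generated as sparse linear combinations of a few
#' planted features per omic plus noise, phenotype-specific (by default
#' fully exclusive) active sets, and two weak hub miRNAs — one linked to
#' every target gene in the tumour phenotypes, one in the normal phenotype.
#'
#' Default sample sizes `(Basal=125, Her2=45, LumA=395, LumB=128,
#' Normal=75)` exercise both cross-validation branches (k=3 below 100
#' training samples, k=5 above).
#'
#' @param n_samples named integer vector: samples per phenotype.
#' @param m_cpg,m_tx,m_mirna number of methylation / transcript / miRNA
#'   predictor features (targets are emitted as additional transcript rows).
#' @param n_target_genes number of signature genes to synthesize.
#' @param k_planted planted predictors per omic per gene per phenotype;
#'   a scalar, or a vector named by omic (0 disables an omic). The
#'   planted features of one (gene, omic) are drawn from a single
#'   correlated block with sign-aligned coefficients, emulating a
#'   co-regulated module.
#' @param coef_range magnitude range of planted coefficients (one sign
#'   per (gene, omic, phenotype) module, drawn at random).
#' @param rho within-block equicorrelation of features, in `[0, 1)`.
#' @param block_size features per correlated block (blocks never span omics).
#' @param r2 target population R-squared of the planted (non-hub) part of
#'   each gene model, in (0, 1).
#' @param hub_scale hub coefficient on the standardized-response scale:
#'   the hub's marginal R-squared contribution is about `hub_scale^2`
#'   (default 0.25, i.e. ~6% of variance — an order of magnitude below
#'   the planted modules' share), reproducing a universally selected but
#'   weak predictor.
#' @param hub_logfc log2 mean shift of the hub miRNAs in tumour vs normal
#'   samples (tumour hub up, normal hub down in tumours).
#' @param sharing_fraction fraction of each planted set shared across
#'   phenotypes (0 = fully exclusive sets).
#' @param db_true_positive_fraction fraction of planted (regulator, gene)
#'   pairs emitted into the simulated known-link table.
#' @param db_decoy_links number of random decoy links in the table.
#' @param n_background_sets number of random background gene sets emitted
#'   by [simulate_function_sets()].
#' @param normal_phenotype name of the non-tumour phenotype.
#' @param logit_normal_methylation if `TRUE`, methylation rows are passed
#'   through the inverse-logit (bounded beta-value-like scale) after
#'   response generation; default keeps all omics Gaussian.
#' @param seed integer seed.
#' @return object of class `SimulationConfig`.
#' @export
sim_config <- function(n_samples = c(Basal = 125, Her2 = 45, LumA = 395,
                                     LumB = 128, Normal = 75),
                       m_cpg = 1200, m_tx = 650, m_mirna = 140,
                       n_target_genes = 10, k_planted = 5,
                       coef_range = c(0.3, 0.9), rho = 0.6,
                       block_size = 10, r2 = 0.7, hub_scale = 0.25,
                       hub_logfc = 1, sharing_fraction = 0,
                       db_true_positive_fraction = 0.5,
                       db_decoy_links = 1000, n_background_sets = 50,
                       normal_phenotype = "Normal",
                       logit_normal_methylation = FALSE, seed = 1) {
  if (length(k_planted) == 1L && is.null(names(k_planted)))
    k_planted <- setNames(rep(as.integer(k_planted), 3), OMIC_LEVELS)
  else if (!all(sort(names(k_planted)) == sort(OMIC_LEVELS)))
    stop("k_planted must be a scalar or named by omic", call. = FALSE)
  cfg <- structure(list(
    n_samples = n_samples, m_cpg = as.integer(m_cpg),
    m_tx = as.integer(m_tx), m_mirna = as.integer(m_mirna),
    n_target_genes = as.integer(n_target_genes),
    k_planted = setNames(as.integer(k_planted[OMIC_LEVELS]), OMIC_LEVELS),
    coef_range = coef_range, rho = rho,
    block_size = as.integer(block_size), r2 = r2, hub_scale = hub_scale,
    hub_logfc = hub_logfc, sharing_fraction = sharing_fraction,
    db_true_positive_fraction = db_true_positive_fraction,
    db_decoy_links = as.integer(db_decoy_links),
    n_background_sets = as.integer(n_background_sets),
    normal_phenotype = normal_phenotype,
    logit_normal_methylation = isTRUE(logit_normal_methylation),
    seed = as.integer(seed)), class = "SimulationConfig")
  validate_sim_config(cfg)
}

validate_sim_config <- function(cfg) {
  if (is.null(names(cfg$n_samples)) || any(!nzchar(names(cfg$n_samples))))
    stop("n_samples must be a named vector of phenotype sizes",
         call. = FALSE)
  if (!(cfg$normal_phenotype %in% names(cfg$n_samples)))
    stop("normal_phenotype not among n_samples names", call. = FALSE)
  if (!(cfg$rho >= 0 && cfg$rho < 1))
    stop("rho must lie in [0, 1)", call. = FALSE)
  if (!(cfg$r2 > 0 && cfg$r2 < 1))
    stop("r2 must lie strictly between 0 and 1", call. = FALSE)
  if (!(cfg$sharing_fraction >= 0 && cfg$sharing_fraction <= 1))
    stop("sharing_fraction must lie in [0, 1]", call. = FALSE)
  n_phen <- length(cfg$n_samples)
  sizes <- c(methylation = cfg$m_cpg, transcript = cfg$m_tx,
             mirna = cfg$m_mirna)
  for (om in OMIC_LEVELS) {
    k <- cfg$k_planted[[om]]
    if (k == 0L) next
    n_shared <- round(cfg$sharing_fraction * k)
    # block capacity: two miRNAs are reserved as hubs (worst case both in
    # one block); each planted module occupies one block
    margin <- if (om == "mirna") 2L else 0L
    bs <- cfg$block_size
    m <- sizes[[om]]
    n_blocks <- (m %/% bs) - (if (k + margin > bs) 1L else 0L) +
      (if (m %% bs >= k + margin) 1L else 0L)
    avail <- n_blocks - (if (n_shared > 0) cfg$n_target_genes else 0L)
    if (k > bs || avail < max(cfg$n_target_genes, n_phen))
      stop(sprintf(
        "k_planted infeasible for %s: %d usable blocks for %d genes x %d phenotypes",
        om, n_blocks, cfg$n_target_genes, n_phen), call. = FALSE)
  }
  cfg
}

# exact variance of sum(beta * x) under unit-variance equicorrelated blocks
planted_signal_variance <- function(beta, blocks, rho) {
  v <- sum(beta^2)
  if (rho > 0) {
    for (b in unique(blocks)) {
      bb <- beta[blocks == b]
      v <- v + rho * (sum(bb)^2 - sum(bb^2))
    }
  }
  v
}

#' Simulate a multi-omic dataset with planted regulatory ground truth
#'
#' For each phenotype, predictor features are drawn from equicorrelated
#' Gaussian blocks; each target gene is a sparse linear combination of its
#' planted features plus a weak hub-miRNA term (the tumour hub in tumour
#' phenotypes, the normal hub in the normal phenotype) plus Gaussian noise
#' scaled so the population R-squared matches the configuration. Target
#' genes are emitted as transcript rows of the matrix; hub miRNA rows carry
#' a phenotype mean shift so that differential-expression recovery can be
#' tested.
#'
#' @param config a [sim_config()] object.
#' @return list with elements `dataset` (a `MultiOmicDataset`) and `truth`
#'   (a `GroundTruth`: planted coefficients, hub identities, noise sds,
#'   block assignments).
#' @export
simulate_dataset <- function(config) {
  config <- validate_sim_config(config)
  set.seed(substream_seed(config$seed, "simulate_dataset"))
  phen <- names(config$n_samples)
  normal <- config$normal_phenotype
  tumor_phen <- setdiff(phen, normal)

  f_cpg <- sprintf("cpg_%05d", seq_len(config$m_cpg))
  f_tx  <- sprintf("tx_%05d", seq_len(config$m_tx))
  f_mir <- sprintf("mir_%04d", seq_len(config$m_mirna))
  genes <- sprintf("gene_%03d", seq_len(config$n_target_genes))
  feat <- c(f_cpg, f_tx, f_mir)
  omic <- c(rep("methylation", config$m_cpg),
            rep("transcript", config$m_tx),
            rep("mirna", config$m_mirna))
  hubs <- sample(f_mir, 2)
  tumor_hub <- hubs[1]; normal_hub <- hubs[2]

  # block structure per omic
  blocks <- integer(length(feat))
  off <- 0L
  for (om in OMIC_LEVELS) {
    idx <- which(omic == om)
    blocks[idx] <- off + ((seq_along(idx) - 1L) %/% config$block_size) + 1L
    off <- max(blocks[idx])
  }
  names(blocks) <- feat

  # Planted modules. Each (gene, omic, phenotype) plants its features in
  # ONE correlated block with a common coefficient sign — a co-regulated
  # module, the structure the elastic net's grouping property targets.
  # Exclusivity: a gene's modules are disjoint across phenotypes (up to
  # the configured shared fraction) and, within one phenotype, different
  # genes never share a planted block; both are enforced by a cyclic
  # (Latin-rectangle) block assignment over shuffled usable blocks.
  n_phen <- length(phen)
  n_genes <- length(genes)
  planted <- setNames(vector("list", n_phen), phen)
  for (ph in phen) planted[[ph]] <-
    setNames(vector("list", n_genes), genes)
  shared_feats <- list()   # per (gene, omic)
  block_feats <- list()    # per (gene, omic, phenotype)
  for (om in OMIC_LEVELS) {
    k <- config$k_planted[[om]]
    if (k == 0L) next
    n_shared <- round(config$sharing_fraction * k)
    idx <- which(omic == om)
    usable <- setdiff(feat[idx], hubs)
    by_block <- split(usable, blocks[usable])
    by_block <- by_block[vapply(by_block, length, 1L) >= k]
    bl <- sample(names(by_block))            # shuffled usable blocks
    off <- 0L
    if (n_shared > 0) {
      for (j in seq_len(n_genes))
        shared_feats[[paste(genes[j], om)]] <-
          sample(by_block[[bl[j]]], n_shared)
      off <- n_genes
    }
    mfree <- length(bl) - off
    for (i in seq_len(n_phen)) for (j in seq_len(n_genes)) {
      b <- bl[off + ((i - 1L + (j - 1L)) %% mfree) + 1L]
      block_feats[[paste(phen[i], genes[j], om)]] <-
        sample(by_block[[b]], k - n_shared)
    }
  }
  for (ph in phen) for (g in genes) {
    ids <- character(0); coefs <- numeric(0)
    for (om in OMIC_LEVELS) {
      if (config$k_planted[[om]] == 0L) next
      mod_ids <- c(shared_feats[[paste(g, om)]],
                   block_feats[[paste(ph, g, om)]])
      sgn <- sample(c(-1, 1), 1)
      ids <- c(ids, mod_ids)
      coefs <- c(coefs, sgn * runif(length(mod_ids),
                                    config$coef_range[1],
                                    config$coef_range[2]))
    }
    planted[[ph]][[g]] <- data.frame(feature_id = ids,
                                     coefficient = coefs,
                                     stringsAsFactors = FALSE)
  }

  # draw features and responses phenotype by phenotype
  n_tot <- sum(config$n_samples)
  vals <- matrix(NA_real_, nrow = length(feat) + length(genes),
                 ncol = n_tot,
                 dimnames = list(c(feat, genes), NULL))
  sample_phen <- character(n_tot)
  sample_ids <- character(n_tot)
  noise_sd <- matrix(NA_real_, length(phen), length(genes),
                     dimnames = list(phen, genes))
  col0 <- 0L
  for (ph in phen) {
    n <- config$n_samples[[ph]]
    cols <- col0 + seq_len(n)
    # equicorrelated blocks: x = sqrt(rho) z_block + sqrt(1-rho) e
    z <- matrix(rnorm(max(blocks) * n), max(blocks), n)
    e <- matrix(rnorm(length(feat) * n), length(feat), n)
    x <- sqrt(config$rho) * z[blocks, , drop = FALSE] +
      sqrt(1 - config$rho) * e
    rownames(x) <- feat
    hub_id <- if (ph == normal) normal_hub else tumor_hub
    hub_sign <- sample(c(-1, 1), length(genes), replace = TRUE)
    for (gi in seq_along(genes)) {
      g <- genes[gi]
      pl <- planted[[ph]][[g]]
      vsig <- planted_signal_variance(pl$coefficient,
                                      blocks[pl$feature_id], config$rho)
      sdg <- sqrt(vsig * (1 - config$r2) / config$r2)
      noise_sd[ph, g] <- sdg
      # hub term on the standardized-response scale: raw coefficient
      # hub_scale * sd(planted signal + noise); its marginal R^2 share is
      # ~hub_scale^2 -- an order of magnitude below the planted modules
      gam <- hub_sign[gi] * config$hub_scale * sqrt(vsig + sdg^2)
      beta <- c(pl$coefficient, gam)
      bfeat <- c(pl$feature_id, hub_id)
      vals[g, cols] <- drop(crossprod(x[bfeat, , drop = FALSE], beta)) +
        rnorm(n, sd = sdg)
    }
    vals[feat, cols] <- x
    sample_phen[cols] <- ph
    sample_ids[cols] <- sprintf("%s_s%03d", ph, seq_len(n))
    col0 <- col0 + n
  }
  # hub expression shift: tumour hub up / normal hub down in tumours
  tumor_cols <- sample_phen %in% tumor_phen
  vals[tumor_hub, tumor_cols] <- vals[tumor_hub, tumor_cols] +
    config$hub_logfc
  vals[normal_hub, tumor_cols] <- vals[normal_hub, tumor_cols] -
    config$hub_logfc
  if (config$logit_normal_methylation) {
    midx <- which(omic == "methylation")
    vals[midx, ] <- stats::plogis(vals[midx, ])
  }
  colnames(vals) <- sample_ids

  dataset <- multiomic_dataset(
    vals,
    feature_omic = c(omic, rep("transcript", length(genes))),
    sample_phenotype = sample_phen,
    target_genes = genes)
  truth <- structure(list(
    planted_coefficients = planted,
    tumor_hub_id = tumor_hub, normal_hub_id = normal_hub,
    hub_coefficient_scale = config$hub_scale,
    noise_sd = noise_sd,
    correlated_block_assignments = blocks,
    planted_function_sets = NULL,
    db_true_positive_fraction = config$db_true_positive_fraction,
    normal_phenotype = normal), class = "GroundTruth")
  list(dataset = dataset, truth = truth)
}

# unique planted (regulator, target-gene) pairs across phenotypes
planted_pairs <- function(truth) {
  out <- do.call(rbind, lapply(names(truth$planted_coefficients),
    function(ph) {
      pls <- truth$planted_coefficients[[ph]]
      do.call(rbind, lapply(names(pls), function(g)
        data.frame(regulator_id = pls[[g]]$feature_id, target_id = g,
                   stringsAsFactors = FALSE)))
    }))
  unique(out)
}

#' Simulate a known-link table from planted ground truth
#'
#' A fraction `db_true_positive_fraction` of the planted (regulator, gene)
#' pairs are emitted as links, padded with random decoy links among measured
#' non-planted pairs so the table size is configuration-controlled. The
#' evidence field alternates between `predicted` and `validated`.
#'
#' @param truth a `GroundTruth` from [simulate_dataset()].
#' @param config the matching [sim_config()].
#' @param exclude_planted_decoys if `TRUE` (default) decoy links never
#'   coincide with planted pairs, so `db_true_positive_fraction = 0`
#'   yields a table fully disjoint from the truth. Set to `FALSE` for
#'   calibration studies: a decoy table drawn independently of the truth
#'   is what makes the known-link Fisher p-values exactly conditionally
#'   hypergeometric under the null (deliberate exclusion induces negative
#'   dependence and conservative p-values).
#' @return a `KnownLinkDB`.
#' @export
simulate_known_links <- function(truth, config,
                                 exclude_planted_decoys = TRUE) {
  set.seed(substream_seed(config$seed, "simulate_known_links"))
  pp <- planted_pairs(truth)
  n_true <- round(config$db_true_positive_fraction * nrow(pp))
  true_links <- pp[sample(nrow(pp), n_true), , drop = FALSE]
  feats <- names(truth$correlated_block_assignments)
  genes <- colnames(truth$noise_sd)
  n_decoy <- config$db_decoy_links
  decoys <- NULL
  if (n_decoy > 0) {
    planted_key <- paste(pp$regulator_id, pp$target_id)
    # oversample, then drop planted and duplicate pairs
    cand <- data.frame(
      regulator_id = sample(feats, 4 * n_decoy, replace = TRUE),
      target_id = sample(genes, 4 * n_decoy, replace = TRUE),
      stringsAsFactors = FALSE)
    key <- paste(cand$regulator_id, cand$target_id)
    keep <- !duplicated(key)
    if (exclude_planted_decoys) keep <- keep & !(key %in% planted_key)
    keep <- keep & !(key %in% paste(true_links$regulator_id,
                                    true_links$target_id))
    cand <- cand[keep, , drop = FALSE]
    if (nrow(cand) < n_decoy)
      stop("could not draw enough decoy links; increase feature space",
           call. = FALSE)
    decoys <- cand[seq_len(n_decoy), , drop = FALSE]
  }
  links <- rbind(true_links, decoys)
  known_link_db(links$regulator_id, links$target_id,
                evidence = rep_len(c("predicted", "validated"),
                                   nrow(links)),
                source = "synthetic")
}

#' Simulate a gene-set collection with planted on-target sets
#'
#' Emits one on-target set per target gene containing at least 80% of that
#' gene's planted transcript predictors (union across phenotypes) plus
#' random filler transcripts, and `n_background_sets` size-matched sets
#' drawn randomly from the measured transcripts.
#'
#' @param truth a `GroundTruth` from [simulate_dataset()].
#' @param config the matching [sim_config()].
#' @return named list of character vectors (GMT-compatible); the attribute
#'   `"on_target"` maps each gene to its planted set name.
#' @export
simulate_function_sets <- function(truth, config) {
  set.seed(substream_seed(config$seed, "simulate_function_sets"))
  blocks <- truth$correlated_block_assignments
  feats <- names(blocks)
  tx_feats <- grep("^tx_", feats, value = TRUE)
  genes <- colnames(truth$noise_sd)
  sets <- list()
  on_target <- character(0)
  set_size <- 0L
  for (g in genes) {
    pl_tx <- unique(unlist(lapply(truth$planted_coefficients, function(ph)
      ph[[g]]$feature_id[grepl("^tx_", ph[[g]]$feature_id)])))
    n_in <- ceiling(0.85 * length(pl_tx))
    members <- sample(pl_tx, n_in)
    fillers <- sample(setdiff(tx_feats, pl_tx),
                      max(2, round(0.4 * n_in)))
    nm <- paste0("target_set_", g)
    sets[[nm]] <- c(members, fillers)
    on_target[g] <- nm
    set_size <- max(set_size, length(sets[[nm]]))
  }
  for (b in seq_len(config$n_background_sets)) {
    sets[[sprintf("background_%03d", b)]] <- sample(tx_feats, set_size)
  }
  attr(sets, "description") <- setNames(rep("synthetic", length(sets)),
                                        names(sets))
  attr(sets, "on_target") <- on_target
  sets
}

#' Sensitivity of model selection against planted ground truth
#'
#' For each (gene, phenotype) model, the fraction of planted predictors
#' recovered in the selected set (hub terms excluded).
#'
#' @param models list of `GeneModel`s (see [fit_all()]).
#' @param truth a `GroundTruth`.
#' @return data.frame with columns `gene`, `phenotype`, `n_planted`,
#'   `n_recovered`, `sensitivity`.
#' @export
selection_sensitivity <- function(models, truth) {
  rows <- lapply(models, function(m) {
    pl <- truth$planted_coefficients[[m$phenotype]][[m$gene]]
    if (is.null(pl)) return(NULL)
    sel <- names(m$beta)
    data.frame(gene = m$gene, phenotype = m$phenotype,
               n_planted = nrow(pl),
               n_recovered = sum(pl$feature_id %in% sel),
               sensitivity = mean(pl$feature_id %in% sel),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Serialize / deserialize a ground-truth record as JSON
#' @param truth a `GroundTruth`.
#' @param path file path.
#' @export
write_ground_truth <- function(truth, path) {
  x <- unclass(truth)
  x$noise_sd <- list(phenotypes = rownames(truth$noise_sd),
                     genes = colnames(truth$noise_sd),
                     values = unname(truth$noise_sd))
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' @rdname write_ground_truth
#' @export
read_ground_truth <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  ns <- x$noise_sd
  m <- as.matrix(ns$values)
  dimnames(m) <- list(ns$phenotypes, ns$genes)
  x$noise_sd <- m
  x$correlated_block_assignments <- unlist(x$correlated_block_assignments)
  x$planted_coefficients <- lapply(x$planted_coefficients, function(ph)
    lapply(ph, function(g) as.data.frame(g, stringsAsFactors = FALSE)))
  structure(x, class = "GroundTruth")
}
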