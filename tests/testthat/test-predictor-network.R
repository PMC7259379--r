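make_models <- function(ds, spec_list, phenotype = "T") {
  ms <- lapply(names(spec_list), function(g)
    manual_model(ds, g, phenotype, spec_list[[g]],
                 train = sprintf("s%02d", 1:6),
                 test = sprintf("s%02d", 7:10)))
  names(ms) <- paste(phenotype, names(spec_list), sep = ".")
  structure(ms, class = c("GeneModelList", "list"))
}

two_gene_ds <- function() {
  set.seed(3)
  vals <- matrix(rnorm(70), 7, 10,
                 dimnames = list(c("cpg_a", "tx_a", "tx_b", "mir_a",
                                   "mir_b", "g1", "g2"),
                                 sprintf("s%02d", 1:10)))
  multiomic_dataset(vals,
                    c("methylation", "transcript", "transcript", "mirna",
                      "mirna", "transcript", "transcript"),
                    rep("T", 10), c("g1", "g2"))
}

test_that("network edges, degrees and counts follow the models", {
  ds <- two_gene_ds()
  ms <- make_models(ds, list(g1 = c(mir_a = 0.5, tx_a = -0.2),
                             g2 = c(mir_a = 0.1, cpg_a = 0.3,
                                    tx_b = 0.2)))
  nw <- build_network(ms, "T")
  expect_equal(nrow(nw$edges),
               sum(vapply(ms, function(m) length(m$beta), 1L)))
  expect_equal(nw$outdegree[["mir_a"]], 2)   # shared predictor
  expect_equal(nw$indegree[["g1"]], 2)
  expect_equal(nw$indegree[["g2"]], 3)
  expect_equal(sum(nw$outdegree), sum(nw$indegree))
  expect_equal(sum(nw$outdegree), nrow(nw$edges))
})

test_that("sharing stats compute exclusivity and universal associations", {
  ds <- two_gene_ds()
  nts <- lapply(c("A", "B"), function(ph)
    build_network(make_models(ds, list(
      g1 = c(mir_a = 0.5, tx_a = 0.3),
      g2 = c(mir_a = 0.2, cpg_a = 0.1)), ph), ph))
  sh <- sharing_stats(nts, tumor_phenotypes = c("A", "B"))
  # mir_a predicts two genes -> excluded from the exclusive count
  expect_equal(unname(sh$exclusive_fraction[["mirna"]]), 0)
  expect_equal(unname(sh$exclusive_fraction[["transcript"]]), 1)
  expect_equal(unname(sh$exclusive_fraction[["methylation"]]), 1)
  # all associations appear in both phenotypes -> all universal
  expect_equal(nrow(sh$universal), 4)
  expect_true(all(sh$association_phenotypes$n_phenotypes == 2))

  # replication idempotence: one network's fractions equal the pair's
  sh1 <- sharing_stats(nts[1], tumor_phenotypes = "A")
  expect_equal(sh1$exclusive_fraction, sh$exclusive_fraction)
})

test_that("hub analysis ranks outdegree and KS handles identical coefs", {
  ds <- two_gene_ds()
  ms <- make_models(ds, list(g1 = c(mir_a = 0.2, mir_b = 0.4),
                             g2 = c(mir_a = 0.2, mir_b = 0.1)))
  nw <- build_network(ms, "T")
  hub <- hub_analysis(list(nw), ds, class = "mirna", n_top = 2)
  expect_equal(hub$hub[hub$rank == 1], "mir_a")  # lexicographic tie
  expect_equal(hub$outdegree, c(2L, 2L))
  # hub coefficients identical to the rest -> KS p near 1
  expect_gt(hub$ks_p[hub$rank == 1], 0.5)
})

test_that("knockout connectivity and greedy covers behave", {
  ds <- two_gene_ds()
  ms <- make_models(ds, list(g1 = c(mir_a = 0.5, tx_a = 0.2),
                             g2 = c(mir_a = 0.3, tx_b = 0.1)))
  nw <- build_network(ms, "T")
  before <- knockout_connectivity(nw)
  expect_equal(before$bridging_set, "mir_a")     # hub covers all genes
  expect_equal(before$n_components, 1)
  after <- knockout_connectivity(nw, "mir_a")
  expect_gt(after$bridging_set_size, 1)          # cover strictly grows
  expect_equal(after$n_components, 2)
  expect_warning(knockout_connectivity(nw, "absent_node"), "absent")
  # empty network: cover undefined
  empty <- build_network(make_models(ds, list(g1 = numeric(0))), "T")
  res <- knockout_connectivity(empty)
  expect_true(is.na(res$bridging_set_size))
})

test_that("greedy cover is never smaller than the exact minimum", {
  set.seed(9)
  for (i in 1:25) {
    n_pred <- sample(4:10, 1)
    genes <- paste0("g", 1:6)
    sets <- lapply(seq_len(n_pred), function(j)
      sample(genes, sample(1:4, 1)))
    names(sets) <- paste0("p", seq_len(n_pred))
    if (!all(genes %in% unlist(sets))) next
    greedy <- omicselect:::greedy_set_cover(sets, genes)
    exact <- omicselect:::exact_set_cover_size(sets, genes)
    expect_gte(length(greedy), exact)
    expect_true(all(genes %in% unlist(sets[greedy])))
  }
})

test_that("genes above mean indegree are flagged", {
  ds <- two_gene_ds()
  ms <- make_models(ds, list(g1 = c(mir_a = 0.5),
                             g2 = c(mir_a = 0.3, tx_b = 0.1,
                                    cpg_a = 0.2)))
  lm_genes <- large_model_genes(build_network(ms, "T"))
  expect_true(lm_genes$above_average[lm_genes$gene == "g2"])
  expect_false(lm_genes$above_average[lm_genes$gene == "g1"])
})
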