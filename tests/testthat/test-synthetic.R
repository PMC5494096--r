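# Synthetic-study generator: determinism, planting guarantees, truth
# consistency, recovery power.

small_cfg <- function(...) {
  defaults <- list(n_mirnas = 30, n_genes = 200, n_tfs = 40,
                   n_case_mirna = 5, n_control_mirna = 5,
                   n_case_mrna = 5, n_control_mrna = 5,
                   n_planted_biomarkers = 3,
                   n_gene_sets = 10, gene_set_size = 15)
  do.call(synthetic_config, utils::modifyList(defaults, list(...)))
}

test_that("identical configs give identical artifacts", {
  cfg <- small_cfg(seed = 99)
  a <- generate_synthetic_study(cfg)
  b <- generate_synthetic_study(small_cfg(seed = 99))
  expect_identical(a$network$edges, b$network$edges)
  expect_identical(a$network$tf_genes, b$network$tf_genes)
  expect_identical(a$mirna$data$values, b$mirna$data$values)
  expect_identical(a$mrna$data$values, b$mrna$data$values)
  expect_identical(a$gene_sets$sets, b$gene_sets$sets)
  # different seed changes the data
  c <- generate_reference_network(small_cfg(seed = 100))
  expect_false(identical(a$network$edges, c$edges))
})

test_that("planted biomarkers carry the promised unique, TF-rich target sets", {
  cfg <- small_cfg(seed = 7, n_planted_biomarkers = 3,
                   planted_unique_targets = 5, planted_tf_frac = 0.6)
  net <- generate_reference_network(cfg)
  planted <- attr(net, "planted_biomarkers")
  expect_length(planted, 3L)
  indeg <- table(net$edges$gene_id)
  for (m in planted) {
    targets <- net$edges$gene_id[net$edges$mirna_id == m]
    # >= 5 targets of in-degree exactly 1, by exhaustive tally
    expect_gte(sum(indeg[targets] == 1L), 5L)
    expect_gte(mean(targets %in% net$tf_genes), 0.6)
  }
  # unique targets recorded on the network are truly in-degree 1
  for (u in unlist(attr(net, "planted_unique")))
    expect_equal(unname(indeg[u]), 1L)
})

test_that("network sanity: edge count equals summed out-degree, TF count exact", {
  cfg <- small_cfg(seed = 15)
  net <- generate_reference_network(cfg)
  expect_equal(nrow(net$edges),
               sum(table(net$edges$mirna_id)))
  expect_equal(length(net$tf_genes), 40L)
  expect_true(all(net$tf_genes %in% sprintf("GENE%04d", 1:200)))
  expect_false(any(duplicated(net$edges)))
})

test_that("no-planting and infeasible configurations behave as specified", {
  cfg0 <- small_cfg(seed = 3, n_planted_biomarkers = 0)
  net0 <- generate_reference_network(cfg0)
  expect_length(attr(net0, "planted_biomarkers"), 0L)
  expect_error(small_cfg(n_planted_biomarkers = 10,
                         planted_unique_targets = 25),
               "infeasible")
  expect_error(generate_reference_network(
    small_cfg(seed = 1, n_tfs = 2, n_planted_biomarkers = 3,
              planted_unique_targets = 5, planted_tf_frac = 1)),
    "infeasible")
  expect_error(small_cfg(frac_de_mirna = 1.5), "fractions")
  expect_error(small_cfg(n_tfs = 300), "n_tfs")
})

test_that("ground truth is internally consistent", {
  study <- generate_synthetic_study(small_cfg(seed = 23))
  truth <- study$truth
  expect_true(all(truth$planted_biomarkers %in% truth$de_mirnas))
  expect_true(all(truth$tf_genes %in% sprintf("GENE%04d", 1:200)))
  # every planted target is a differential gene (survives gene restriction)
  planted_targets <- study$network$edges$gene_id[
    study$network$edges$mirna_id %in% truth$planted_biomarkers]
  expect_true(all(planted_targets %in% truth$de_genes))
  # without planting and with frac 0, the differential miRNA set is empty
  e <- generate_expression_dataset(
    small_cfg(seed = 2, n_planted_biomarkers = 0, frac_de_mirna = 0), "mirna")
  expect_length(e$de_features, 0L)
})

test_that("null effect sizes give near-alpha downstream hit rates", {
  cfg <- small_cfg(seed = 44, effect_size = 0, n_mirnas = 500,
                   n_case_mirna = 10, n_control_mirna = 10)
  e <- generate_expression_dataset(cfg, "mirna")
  res <- moderated_t_test(e$data)
  expect_lt(mean(res$p_raw < 0.05), 0.10)
  # BH keeps false discoveries rare under the global null
  expect_lte(sum(res$is_significant), 2L)
})

test_that("planted differential features are recoverable at high power", {
  # effect 2, noise 0.5, 30/30 samples: >= 95% recovery over 20 seeds
  recovered <- 0L; planted_total <- 0L
  for (s in 1:20) {
    cfg <- synthetic_config(n_mirnas = 300, n_genes = 200, n_tfs = 40,
                            n_case_mirna = 30, n_control_mirna = 30,
                            effect_size = 2, noise_sd = 0.5, seed = 500 + s)
    e <- generate_expression_dataset(cfg, "mirna")
    res <- moderated_t_test(e$data)
    hits <- select_differential(res, 0.05)
    recovered <- recovered + length(intersect(hits, e$de_features))
    planted_total <- planted_total + length(e$de_features)
  }
  expect_gte(recovered / planted_total, 0.95)
})

test_that("the loaded gene set is maximally enriched for planted targets", {
  cfg <- small_cfg(seed = 67)
  study <- generate_synthetic_study(cfg)
  coll <- study$gene_sets
  expect_length(coll$sets, 10L)
  expect_true(all(lengths(coll$sets) == 15L))
  expect_gt(attr(coll, "loaded_overlap"), 0)
  planted_targets <- unique(study$network$edges$gene_id[
    study$network$edges$mirna_id %in% study$truth$planted_biomarkers])
  res <- suppressMessages(enrich_gene_sets(planted_targets, coll))
  expect_equal(res$set_name[1], attr(coll, "loaded_set"))
  expect_error(generate_gene_sets(small_cfg(gene_set_size = 5000),
                                  study$network),
               "universe")
})

test_that("the file bundle round-trips through the standard formats", {
  dir <- withr::local_tempdir()
  cfg <- small_cfg(seed = 12)
  paths <- write_synthetic_bundle(cfg, dir)
  expect_true(all(file.exists(paths)))
  study <- generate_synthetic_study(cfg)
  back <- read_expression_tsv(paths["mirna_expr"], paths["mirna_design"])
  expect_equal(back$values, study$mirna$data$values, tolerance = 1e-6)
  expect_identical(as.character(back$group),
                   as.character(study$mirna$data$group))
  net <- load_reference_network(paths["edges"], paths["tf"])
  expect_setequal(net$tf_genes, study$network$tf_genes)
  expect_equal(nrow(net$edges), nrow(study$network$edges))
  truth <- jsonlite::read_json(paths["truth"], simplifyVector = TRUE)
  expect_setequal(truth$de_mirnas, study$truth$de_mirnas)
})
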