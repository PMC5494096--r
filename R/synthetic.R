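# Synthetic study generator with planted ground truth.
#
# Emulates the shapes of a two-assay case/control microarray study (a
# miRNA assay and an mRNA assay), a reference miRNA->gene interaction
# network with heterogeneous out-degree, a TF annotation, and GMT gene-set
# collections. "Planted" biomarker miRNAs are endowed by construction with
# many uniquely-targeted genes and a TF-rich target set, so downstream
# recovery is exactly checkable. One RNG stream per artifact (network,
# miRNA matrix, mRNA matrix, gene sets) is derived from the master seed.

#' Synthetic study configuration
#'
#' Defaults mirror a tissue miRNA assay of 47 tumor / 47 control samples
#' and an mRNA assay of 33 tumor / 32 control samples, with feature counts
#' and differential fractions sized so that the differential sets are in
#' the ~90 miRNA / ~340 gene range typical of such studies.
#'
#' @param n_mirnas,n_genes,n_tfs feature universe sizes.
#' @param n_case_mirna,n_control_mirna,n_case_mrna,n_control_mrna sample
#'   counts per assay.
#' @param frac_de_mirna,frac_de_gene fractions of differential features.
#' @param effect_size mean |log2 shift| of differential features in cases.
#' @param noise_sd residual SD of log2 expression.
#' @param baseline baseline log2 expression level.
#' @param mean_out_degree expected background targets per miRNA (Poisson).
#' @param n_planted_biomarkers number of planted biomarker miRNAs (the
#'   first miRNA ids).
#' @param planted_unique_targets uniquely-targeted genes given to each
#'   planted biomarker.
#' @param planted_tf_frac minimum TF fraction of a planted biomarker's
#'   target set.
#' @param n_gene_sets,gene_set_size gene-set collection shape.
#' @param seed master RNG seed; fully determines all artifacts.
#' @return list of class `synthetic_config`.
#' @export
synthetic_config <- function(n_mirnas = 150, n_genes = 2000, n_tfs = 300,
                             n_case_mirna = 47, n_control_mirna = 47,
                             n_case_mrna = 33, n_control_mrna = 32,
                             frac_de_mirna = 0.6, frac_de_gene = 0.17,
                             effect_size = 2, noise_sd = 0.5, baseline = 8,
                             mean_out_degree = 8,
                             n_planted_biomarkers = 5,
                             planted_unique_targets = 5,
                             planted_tf_frac = 0.6,
                             n_gene_sets = 50, gene_set_size = 40,
                             seed = 1) {
  cfg <- list(n_mirnas = n_mirnas, n_genes = n_genes, n_tfs = n_tfs,
              n_case_mirna = n_case_mirna, n_control_mirna = n_control_mirna,
              n_case_mrna = n_case_mrna, n_control_mrna = n_control_mrna,
              frac_de_mirna = frac_de_mirna, frac_de_gene = frac_de_gene,
              effect_size = effect_size, noise_sd = noise_sd,
              baseline = baseline, mean_out_degree = mean_out_degree,
              n_planted_biomarkers = n_planted_biomarkers,
              planted_unique_targets = planted_unique_targets,
              planted_tf_frac = planted_tf_frac,
              n_gene_sets = n_gene_sets, gene_set_size = gene_set_size,
              seed = seed)
  fracs <- c(frac_de_mirna, frac_de_gene, planted_tf_frac)
  if (any(fracs < 0 | fracs > 1)) stop("fractions must lie in [0, 1]")
  if (n_tfs > n_genes) stop("n_tfs must not exceed n_genes")
  if (min(n_case_mirna, n_control_mirna, n_case_mrna, n_control_mrna) < 2)
    stop("need >= 2 samples per group in each assay")
  if (n_planted_biomarkers > n_mirnas)
    stop("more planted biomarkers than miRNAs")
  if (n_planted_biomarkers * planted_unique_targets > n_genes)
    stop("infeasible: not enough genes to plant unique targets")
  structure(cfg, class = "synthetic_config")
}

syn_mirna_ids <- function(cfg) sprintf("miR-s%03d", seq_len(cfg$n_mirnas))
syn_gene_ids  <- function(cfg) sprintf("GENE%04d", seq_len(cfg$n_genes))
syn_planted   <- function(cfg) syn_mirna_ids(cfg)[seq_len(cfg$n_planted_biomarkers)]

#' Generate the synthetic reference network
#'
#' Each miRNA draws a Poisson(`mean_out_degree`) number of background
#' targets without replacement from the non-reserved gene pool; each
#' planted biomarker additionally receives `planted_unique_targets` genes
#' no other miRNA targets, and enough of its targets are flagged TF to make
#' its target TF fraction at least `planted_tf_frac`. Exactly `n_tfs` genes
#' carry the TF flag. Deterministic given `config$seed`.
#'
#' @param config a [synthetic_config()].
#' @return a [regulatory_network()] with attributes `planted_biomarkers`
#'   (ids) and `planted_unique` (named list of each planted miRNA's unique
#'   target genes).
#' @export
generate_reference_network <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  set.seed(substream_seed(config$seed, 1L))
  mirnas <- syn_mirna_ids(config)
  genes <- syn_gene_ids(config)
  planted <- syn_planted(config)
  n_p <- length(planted)
  u <- config$planted_unique_targets

  reserved <- if (n_p * u > 0) sample(genes, n_p * u) else character()
  pool <- setdiff(genes, reserved)
  planted_unique <- if (n_p > 0)
    split(reserved, rep(seq_len(n_p), each = u))[as.character(seq_len(n_p))]
  else list()
  names(planted_unique) <- planted

  edges_m <- character(); edges_g <- character()
  forced_tf <- character()
  for (i in seq_along(mirnas)) {
    deg <- min(stats::rpois(1L, config$mean_out_degree), length(pool))
    bg <- if (deg > 0) sample(pool, deg) else character()
    targets <- bg
    if (mirnas[i] %in% planted) {
      uniq <- planted_unique[[mirnas[i]]]
      targets <- c(uniq, bg)
      need_tf <- ceiling(config$planted_tf_frac * length(targets))
      # flag unique targets first so the TF-rich core stays unshared
      forced_tf <- c(forced_tf, utils::head(c(uniq, bg), need_tf))
    }
    edges_m <- c(edges_m, rep(mirnas[i], length(targets)))
    edges_g <- c(edges_g, targets)
  }
  forced_tf <- unique(forced_tf)
  if (length(forced_tf) > config$n_tfs)
    stop("infeasible: planted TF requirements exceed n_tfs")
  extra_tf <- sample(setdiff(genes, forced_tf),
                     config$n_tfs - length(forced_tf))
  net <- regulatory_network(
    data.frame(mirna_id = edges_m, gene_id = edges_g,
               stringsAsFactors = FALSE),
    tf_genes = c(forced_tf, extra_tf),
    mirnas = mirnas)
  attr(net, "planted_biomarkers") <- planted
  attr(net, "planted_unique") <- planted_unique
  net
}

#' Generate a synthetic two-group expression dataset
#'
#' Null features are i.i.d. Normal(`baseline`, `noise_sd`) across samples;
#' differential features are shifted by `+-effect_size` in case samples
#' (sign random, recorded). For the miRNA assay, the differential set
#' always contains the planted biomarkers; for the mRNA assay it always
#' contains every target of a planted biomarker, so the planted structure
#' survives the condition-network restriction.
#'
#' @param config a [synthetic_config()].
#' @param truth_role `"mirna"` or `"mrna"`.
#' @return list with elements `data` (an [expression_dataset()]),
#'   `de_features` (ids of the shifted features) and `signs` (named +-1
#'   vector of shift directions).
#' @export
generate_expression_dataset <- function(config,
                                        truth_role = c("mirna", "mrna")) {
  stopifnot(inherits(config, "synthetic_config"))
  truth_role <- match.arg(truth_role)
  if (truth_role == "mirna") {
    set.seed(substream_seed(config$seed, 2L))
    features <- syn_mirna_ids(config)
    n1 <- config$n_case_mirna; n2 <- config$n_control_mirna
    must <- syn_planted(config)
    n_de <- round(config$frac_de_mirna * length(features))
  } else {
    set.seed(substream_seed(config$seed, 3L))
    features <- syn_gene_ids(config)
    n1 <- config$n_case_mrna; n2 <- config$n_control_mrna
    net <- generate_reference_network(config)
    # restore this stream: network generation reseeded the RNG
    set.seed(substream_seed(config$seed, 3L))
    must <- unique(net$edges$gene_id[net$edges$mirna_id %in%
                                       attr(net, "planted_biomarkers")])
    n_de <- round(config$frac_de_gene * length(features))
  }
  n_de <- max(n_de, length(must))
  de <- c(must, sample(setdiff(features, must), n_de - length(must)))
  signs <- stats::setNames(sample(c(-1, 1), length(de), replace = TRUE), de)

  n <- n1 + n2
  mat <- matrix(stats::rnorm(length(features) * n, mean = config$baseline,
                             sd = config$noise_sd),
                nrow = length(features),
                dimnames = list(features,
                                sprintf("%s_S%03d", truth_role, seq_len(n))))
  group <- rep(c("case", "control"), c(n1, n2))
  mat[de, group == "case"] <- mat[de, group == "case"] +
    signs[de] * config$effect_size
  list(data = expression_dataset(mat, group),
       de_features = de, signs = signs)
}

#' Generate synthetic gene-set collections
#'
#' Draws `n_gene_sets` sets of `gene_set_size` genes from the network's
#' gene universe. The first set is deliberately loaded with targets of the
#' planted biomarkers (the achieved overlap fraction is recorded in the
#' attribute `loaded_overlap`), so enrichment recovery is testable.
#'
#' @param config a [synthetic_config()].
#' @param network the synthetic reference network (from
#'   [generate_reference_network()]).
#' @param planted_targets genes targeted by planted biomarkers; defaults to
#'   those recorded on `network`.
#' @return a [gene_set_collection()] with attributes `loaded_set` (name)
#'   and `loaded_overlap` (fraction of the loaded set that is planted
#'   targets).
#' @export
generate_gene_sets <- function(config, network, planted_targets = NULL) {
  stopifnot(inherits(config, "synthetic_config"),
            inherits(network, "regulatory_network"))
  set.seed(substream_seed(config$seed, 4L))
  universe <- network$gene_ids
  if (config$gene_set_size > length(universe))
    stop("gene_set_size exceeds the gene universe")
  if (is.null(planted_targets)) {
    planted <- attr(network, "planted_biomarkers")
    planted_targets <- unique(
      network$edges$gene_id[network$edges$mirna_id %in% planted])
  }
  nm <- sprintf("SET%03d", seq_len(config$n_gene_sets))
  sets <- vector("list", config$n_gene_sets)
  loaded <- utils::head(intersect(planted_targets, universe),
                        config$gene_set_size)
  filler <- sample(setdiff(universe, loaded),
                   config$gene_set_size - length(loaded))
  sets[[1L]] <- c(loaded, filler)
  for (i in seq_len(config$n_gene_sets)[-1L])
    sets[[i]] <- sample(universe, config$gene_set_size)
  names(sets) <- nm
  coll <- gene_set_collection(sets, universe)
  attr(coll, "loaded_set") <- nm[1L]
  attr(coll, "loaded_overlap") <- length(loaded) / config$gene_set_size
  coll
}

#' Generate a complete synthetic study
#'
#' Runs all three generators and assembles the combined ground truth.
#'
#' @param config a [synthetic_config()].
#' @return list with `network`, `mirna` and `mrna` (each the list returned
#'   by [generate_expression_dataset()]), `gene_sets`, and `truth` (list
#'   with `de_mirnas`, `de_genes`, `planted_biomarkers`, `tf_genes`).
#' @export
generate_synthetic_study <- function(config = synthetic_config()) {
  network <- generate_reference_network(config)
  mirna <- generate_expression_dataset(config, "mirna")
  mrna <- generate_expression_dataset(config, "mrna")
  gene_sets <- generate_gene_sets(config, network)
  list(network = network, mirna = mirna, mrna = mrna, gene_sets = gene_sets,
       truth = list(de_mirnas = mirna$de_features,
                    de_genes = mrna$de_features,
                    planted_biomarkers = attr(network, "planted_biomarkers"),
                    tf_genes = network$tf_genes))
}

#' Write a synthetic study to a directory of standard-format files
#'
#' Emits the expression/design TSVs for both assays, the edge-list TSV,
#' the TF list, the GMT collection, and a ground-truth JSON.
#'
#' @param config a [synthetic_config()].
#' @param dir output directory (created if needed).
#' @return invisibly, a named character vector of the written paths.
#' @export
write_synthetic_bundle <- function(config, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  study <- generate_synthetic_study(config)
  paths <- c(mirna_expr = file.path(dir, "mirna_expression.tsv"),
             mirna_design = file.path(dir, "mirna_design.tsv"),
             mrna_expr = file.path(dir, "mrna_expression.tsv"),
             mrna_design = file.path(dir, "mrna_design.tsv"),
             edges = file.path(dir, "reference_edges.tsv"),
             tf = file.path(dir, "tf_genes.txt"),
             gmt = file.path(dir, "gene_sets.gmt"),
             truth = file.path(dir, "truth.json"))
  write_expression_tsv(study$mirna$data, paths["mirna_expr"], paths["mirna_design"])
  write_expression_tsv(study$mrna$data, paths["mrna_expr"], paths["mrna_design"])
  write_network_tsv(study$network, paths["edges"], paths["tf"])
  write_gmt(study$gene_sets, paths["gmt"])
  jsonlite::write_json(study$truth, paths["truth"], auto_unbox = FALSE)
  invisible(paths)
}
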