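# End-to-end orchestration: expression -> differential calls -> condition
# network -> structural scores -> signed-rank screen -> enrichment, with
# every intermediate table written to disk and a JSON run manifest.

#' Pipeline configuration
#'
#' @param mirna_expr,mirna_design,mrna_expr,mrna_design expression and
#'   design TSV paths for the two assays.
#' @param reference_edges edge-list TSV path.
#' @param tf_list TF gene list path (optional).
#' @param gene_sets GMT path (optional; enrichment skipped without it).
#' @param known_biomarkers known-miRNA list path (optional).
#' @param out_dir output directory.
#' @param alpha_de,alpha_screen,alpha_enrich significance levels (default
#'   0.05 each).
#' @param restrict_genes restrict condition-network edges to differentially
#'   expressed genes (default `TRUE`).
#' @param paired use a paired contrast in the expression stage.
#' @param normalization `"quantile"` or `"none"`.
#' @param top_k enrichment records kept in the top-k report.
#' @param seed RNG seed echoed into the manifest.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(mirna_expr = NULL, mirna_design = NULL,
                            mrna_expr = NULL, mrna_design = NULL,
                            reference_edges = NULL, tf_list = NULL,
                            gene_sets = NULL, known_biomarkers = NULL,
                            out_dir = "netmark_out",
                            alpha_de = 0.05, alpha_screen = 0.05,
                            alpha_enrich = 0.05,
                            restrict_genes = TRUE, paired = FALSE,
                            normalization = c("quantile", "none"),
                            top_k = 10, seed = 1) {
  alphas <- c(alpha_de, alpha_screen, alpha_enrich)
  if (any(alphas <= 0 | alphas >= 1)) stop("alphas must lie in (0, 1)")
  structure(list(mirna_expr = mirna_expr, mirna_design = mirna_design,
                 mrna_expr = mrna_expr, mrna_design = mrna_design,
                 reference_edges = reference_edges, tf_list = tf_list,
                 gene_sets = gene_sets, known_biomarkers = known_biomarkers,
                 out_dir = out_dir, alpha_de = alpha_de,
                 alpha_screen = alpha_screen, alpha_enrich = alpha_enrich,
                 restrict_genes = isTRUE(restrict_genes),
                 paired = isTRUE(paired),
                 normalization = match.arg(normalization),
                 top_k = top_k, seed = seed),
            class = "pipeline_config")
}

#' Load a pipeline configuration from a YAML file
#'
#' Keys mirror the arguments of [pipeline_config()]; `overrides` (a named
#' list, e.g. from command-line flags) win over file values.
#'
#' @param path YAML file path.
#' @param overrides named list of overriding values.
#' @return a [pipeline_config()].
#' @export
load_pipeline_config <- function(path, overrides = list()) {
  vals <- yaml::read_yaml(path)
  vals[names(overrides)] <- overrides
  do.call(pipeline_config, vals)
}

stage_log <- function(stage, fmt, ...) {
  message(sprintf("[netmark:%s] %s", stage, sprintf(fmt, ...)))
}

# shared tail of the pipeline: condition network -> scores -> screen ->
# annotate -> enrich; writes tables into out_dir and returns the pieces
run_scoring_stages <- function(config, de_mirnas, de_genes) {
  out <- config$out_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  reference <- load_reference_network(config$reference_edges, config$tf_list)
  stage_log("network", "reference: %d miRNAs, %d genes, %d edges",
            length(reference$mirna_ids), length(reference$gene_ids),
            nrow(reference$edges))
  missing_m <- setdiff(normalize_mirna_id(de_mirnas), reference$mirna_ids)
  if (length(missing_m))
    stage_log("network", "%d differential miRNA(s) absent from the reference",
              length(missing_m))
  condition <- build_condition_network(reference, de_mirnas, de_genes,
                                       restrict_genes = config$restrict_genes)
  if (length(condition$mirna_ids) == 0L)
    stop("pipeline aborted at stage 'network': condition network is empty")
  scores <- score_all(condition)
  calls <- screen_biomarkers(scores, screen_config(alpha = config$alpha_screen))
  calls <- annotate_known(calls, known_file = config$known_biomarkers)
  write_candidate_tsv(calls, file.path(out, "candidates.tsv"))
  stage_log("screen", "%d candidates (%d known)",
            sum(calls$is_candidate), sum(calls$is_candidate & calls$is_known))

  enrichment <- NULL
  cand_targets <- unique(unlist(strsplit(
    calls$targets[calls$is_candidate], ";", fixed = TRUE)))
  cand_targets <- cand_targets[nzchar(cand_targets)]
  if (!is.null(config$gene_sets) && length(cand_targets)) {
    collection <- read_gmt(config$gene_sets, universe = reference$gene_ids)
    enrichment <- enrich_gene_sets(cand_targets, collection,
                                   alpha = config$alpha_enrich)
    write_tsv(enrichment, file.path(out, "enrichment.tsv"))
    write_tsv(top_k_report(enrichment, config$top_k),
              file.path(out, "enrichment_topk.tsv"))
    stage_log("enrich", "%d/%d sets significant at adjusted p < %g",
              sum(enrichment$is_significant), nrow(enrichment),
              config$alpha_enrich)
  } else if (!is.null(config$gene_sets)) {
    stage_log("enrich", "no candidate targets: enrichment skipped")
  }
  list(reference = reference, condition = condition, scores = scores,
       calls = calls, enrichment = enrichment, missing_mirnas = missing_m)
}

make_manifest <- function(config, counts) {
  list(config = unclass(config),
       counts = counts,
       version = as.character(utils::packageVersion("netmark")),
       timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
}

#' Run the full biomarker-screening pipeline
#'
#' Executes normalization and moderated-t differential expression on both
#' assays, builds the condition-specific network, scores and screens every
#' miRNA, annotates literature-known candidates, and (if a GMT is
#' configured) runs gene-set enrichment on the pooled candidate targets.
#' All intermediate tables plus a JSON manifest are written to
#' `config$out_dir`. Rerunning with identical config and inputs reproduces
#' identical tables.
#'
#' @param config a [pipeline_config()] with all expression/network paths set.
#' @return invisibly, the manifest list (also written to `manifest.json`).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  for (p in c("mirna_expr", "mirna_design", "mrna_expr", "mrna_design",
              "reference_edges")) {
    if (is.null(config[[p]]) || !file.exists(config[[p]]))
      stop("pipeline aborted at stage 'input': missing file for '", p, "'")
  }
  out <- config$out_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  set.seed(config$seed)

  de <- list()
  for (assay in c("mirna", "mrna")) {
    data <- read_expression_tsv(config[[paste0(assay, "_expr")]],
                                config[[paste0(assay, "_design")]])
    res <- differential_expression(data, alpha = config$alpha_de,
                                   normalize = config$normalization,
                                   paired = config$paired)
    write_tsv(res, file.path(out, paste0("diffexpr_", assay, ".tsv")))
    de[[assay]] <- select_differential(res, config$alpha_de)
    stage_log("diffexpr", "%s: %d/%d differential at adjusted p < %g",
              assay, length(de[[assay]]), nrow(res), config$alpha_de)
    if (length(de[[assay]]) == 0L)
      stop("pipeline aborted at stage 'diffexpr': no differential ", assay,
           " features at alpha = ", config$alpha_de)
  }

  stages <- run_scoring_stages(config, de$mirna, de$mrna)
  counts <- list(de_mirnas = length(de$mirna),
                 de_genes = length(de$mrna),
                 network_edges = nrow(stages$condition$edges),
                 scored_mirnas = nrow(stages$scores),
                 candidates = sum(stages$calls$is_candidate),
                 novel_candidates = sum(stages$calls$is_candidate &
                                          !stages$calls$is_known),
                 significant_sets = if (is.null(stages$enrichment)) 0L
                                    else sum(stages$enrichment$is_significant))
  manifest <- make_manifest(config, counts)
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, null = "null", pretty = TRUE)
  invisible(manifest)
}

#' Run the scoring stages only, from precomputed differential lists
#'
#' Entry point for users who bring their own differential-expression calls:
#' skips the expression stages and runs network scoring, the signed-rank
#' screen, known-biomarker annotation and enrichment.
#'
#' @param config a [pipeline_config()] with at least `reference_edges` set.
#' @param de_mirna_file,de_gene_file one-id-per-line files of differential
#'   miRNAs / genes (`de_gene_file` optional when
#'   `config$restrict_genes = FALSE`).
#' @return invisibly, a list with `calls` (annotated candidate table),
#'   `scores`, `enrichment` and `manifest`.
#' @export
scoring_only <- function(config, de_mirna_file, de_gene_file = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  de_mirnas <- read_id_list(de_mirna_file)
  if (length(de_mirnas) == 0L)
    stop("pipeline aborted at stage 'input': empty differential miRNA list")
  de_genes <- if (!is.null(de_gene_file)) read_id_list(de_gene_file) else NULL
  stages <- run_scoring_stages(config, de_mirnas, de_genes)
  counts <- list(de_mirnas = length(de_mirnas),
                 de_genes = length(de_genes),
                 missing_mirnas = length(stages$missing_mirnas),
                 network_edges = nrow(stages$condition$edges),
                 scored_mirnas = nrow(stages$scores),
                 candidates = sum(stages$calls$is_candidate),
                 novel_candidates = sum(stages$calls$is_candidate &
                                          !stages$calls$is_known),
                 significant_sets = if (is.null(stages$enrichment)) 0L
                                    else sum(stages$enrichment$is_significant))
  manifest <- make_manifest(config, counts)
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, null = "null", pretty = TRUE)
  invisible(list(calls = stages$calls, scores = stages$scores,
                 enrichment = stages$enrichment, manifest = manifest))
}
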