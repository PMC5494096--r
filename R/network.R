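# Bipartite miRNA -> gene regulatory network and the two structural
# biomarker indices:
#   NOG -- number of a miRNA's targets that no other miRNA in the same
#          network targets (targets of in-degree exactly 1);
#   TFP -- fraction of a miRNA's targets annotated as transcription factors.
# Both are computed within whichever network they are asked on; for the
# biomarker screen that is the condition-specific (disease) network.

#' Construct a bipartite miRNA-gene regulatory network
#'
#' @param edges data.frame with character columns `mirna_id` and `gene_id`;
#'   duplicate edges are collapsed.
#' @param tf_genes character vector of gene symbols flagged as transcription
#'   factors; symbols absent from the network are retained (harmless).
#' @param mirnas optional extra miRNA ids kept in the network even with no
#'   edges (they score NOG = 0, TFP = 0).
#' @return object of class `regulatory_network`: list with `edges`
#'   (deduplicated data.frame), `mirna_ids`, `gene_ids`, `tf_genes`.
#' @export
regulatory_network <- function(edges, tf_genes = character(), mirnas = NULL) {
  edges <- data.frame(mirna_id = as.character(edges$mirna_id),
                      gene_id = as.character(edges$gene_id),
                      stringsAsFactors = FALSE)
  edges <- unique(edges)
  structure(list(
    edges = edges,
    mirna_ids = sort(unique(c(edges$mirna_id, as.character(mirnas)))),
    gene_ids = sort(unique(edges$gene_id)),
    tf_genes = sort(unique(as.character(tf_genes)))
  ), class = "regulatory_network")
}

#' @export
print.regulatory_network <- function(x, ...) {
  cat(sprintf("regulatory_network: %d miRNAs, %d genes, %d edges, %d TF flags\n",
              length(x$mirna_ids), length(x$gene_ids),
              nrow(x$edges), length(x$tf_genes)))
  invisible(x)
}

#' Load a reference miRNA-mRNA interaction network from files
#'
#' Reads a two-column tab-separated edge list (`mirna_id`, `gene_id`, header
#' optional) and an optional transcription-factor list (one symbol per
#' line). Gene and TF symbols are upper-cased; miRNA ids are normalized with
#' [normalize_mirna_id()] (arm suffixes preserved). Duplicate edges are
#' dropped.
#'
#' @param edge_file path to the edge-list TSV.
#' @param tf_file optional path to the TF gene list.
#' @return a [regulatory_network()].
#' @export
load_reference_network <- function(edge_file, tf_file = NULL) {
  lines <- readLines(edge_file, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(parts) != 2L)
  if (length(bad))
    stop(sprintf("malformed edge line %d in '%s': expected 2 tab-separated fields",
                 bad[1L], edge_file))
  m <- vapply(parts, `[[`, "", 1L)
  g <- vapply(parts, `[[`, "", 2L)
  if (length(m) && tolower(m[1L]) %in% c("mirna_id", "mirna", "mir")) {  # header row
    m <- m[-1L]; g <- g[-1L]
  }
  tf <- if (!is.null(tf_file) && file.exists(tf_file))
    toupper(read_id_list(tf_file)) else character()
  regulatory_network(
    data.frame(mirna_id = normalize_mirna_id(m), gene_id = toupper(g),
               stringsAsFactors = FALSE),
    tf_genes = tf)
}

#' Write a network's edge list to TSV
#'
#' @param network a [regulatory_network()].
#' @param edge_file output path.
#' @param tf_file optional path for the TF list (one symbol per line).
#' @return invisibly, `edge_file`.
#' @export
write_network_tsv <- function(network, edge_file, tf_file = NULL) {
  write_tsv(network$edges, edge_file)
  if (!is.null(tf_file))
    writeLines(network$tf_genes, tf_file)
  invisible(edge_file)
}

#' Build the condition-specific network
#'
#' Restricts the reference network to edges whose miRNA is differentially
#' expressed; with `restrict_genes = TRUE` (default) the gene must also be
#' differentially expressed. Differentially expressed miRNAs present in the
#' reference are retained even if all their edges are dropped -- they score
#' NOG = 0 and TFP = 0 downstream.
#'
#' @param reference a [regulatory_network()].
#' @param de_mirnas character vector of differentially expressed miRNA ids.
#' @param de_genes character vector of differentially expressed gene
#'   symbols; required when `restrict_genes = TRUE`.
#' @param restrict_genes logical (default `TRUE`).
#' @return a [regulatory_network()] (the condition-specific subnetwork).
#' @export
build_condition_network <- function(reference, de_mirnas, de_genes = NULL,
                                    restrict_genes = TRUE) {
  stopifnot(inherits(reference, "regulatory_network"))
  de_mirnas <- normalize_mirna_id(de_mirnas)
  if (length(de_mirnas) == 0L)
    warning("empty differentially-expressed miRNA set: condition network has no edges")
  keep <- reference$edges$mirna_id %in% de_mirnas
  if (restrict_genes) {
    if (is.null(de_genes))
      stop("`de_genes` is required when restrict_genes = TRUE")
    keep <- keep & reference$edges$gene_id %in% toupper(de_genes)
  }
  regulatory_network(reference$edges[keep, , drop = FALSE],
                     tf_genes = reference$tf_genes,
                     mirnas = intersect(de_mirnas, reference$mirna_ids))
}

# per-gene in-degree (named integer vector) of the network
gene_in_degree <- function(network) {
  table(network$edges$gene_id)
}

# target set of one miRNA
mirna_targets <- function(network, mirna_id) {
  if (!mirna_id %in% network$mirna_ids)
    stop("unknown miRNA: ", mirna_id)
  network$edges$gene_id[network$edges$mirna_id == mirna_id]
}

#' Number of uniquely targeted genes (NOG)
#'
#' Counts the targets of `mirna_id` whose in-degree in `network` is exactly
#' 1, i.e. genes no other miRNA of the same network targets. A miRNA with no
#' targets scores 0.
#'
#' @param network a [regulatory_network()] (normally the condition network).
#' @param mirna_id a miRNA id present in the network.
#' @return integer count.
#' @export
compute_nog <- function(network, mirna_id) {
  targets <- mirna_targets(network, mirna_id)
  if (length(targets) == 0L) return(0L)
  indeg <- gene_in_degree(network)
  sum(indeg[targets] == 1L)
}

#' Transcription-factor percentage of targets (TFP)
#'
#' Fraction of `mirna_id`'s targets annotated as transcription factors; 0
#' for a miRNA with no targets. The exact fraction is returned; candidate
#' tables report it to 2 decimals with [round_half_away()].
#'
#' @inheritParams compute_nog
#' @return numeric fraction in \[0, 1\].
#' @export
compute_tfp <- function(network, mirna_id) {
  targets <- mirna_targets(network, mirna_id)
  if (length(targets) == 0L) return(0)
  sum(targets %in% network$tf_genes) / length(targets)
}

#' Score every miRNA of a network
#'
#' Computes NOG and TFP for each miRNA, ordered by descending NOG, then
#' descending TFP, then id. The screening p-value columns are `NA` until
#' filled by [screen_biomarkers()].
#'
#' @param network a [regulatory_network()].
#' @return data.frame with columns `mirna_id`, `nog`, `tfp`, `p_nog`,
#'   `p_tfp`, `targets` (";"-joined gene list).
#' @export
score_all <- function(network) {
  stopifnot(inherits(network, "regulatory_network"))
  ids <- network$mirna_ids
  if (length(ids) == 0L)
    return(data.frame(mirna_id = character(), nog = integer(), tfp = numeric(),
                      p_nog = numeric(), p_tfp = numeric(),
                      targets = character(), stringsAsFactors = FALSE))
  indeg <- gene_in_degree(network)
  tgt <- split(network$edges$gene_id, network$edges$mirna_id)
  nog <- integer(length(ids)); tfp <- numeric(length(ids))
  tstr <- character(length(ids))
  for (i in seq_along(ids)) {
    targets <- tgt[[ids[i]]]
    if (is.null(targets)) targets <- character()
    nog[i] <- sum(indeg[targets] == 1L)
    tfp[i] <- if (length(targets)) sum(targets %in% network$tf_genes) / length(targets) else 0
    tstr[i] <- paste(sort(targets), collapse = ";")
  }
  out <- data.frame(mirna_id = ids, nog = nog, tfp = tfp,
                    p_nog = NA_real_, p_tfp = NA_real_, targets = tstr,
                    stringsAsFactors = FALSE)
  out[order(-out$nog, -out$tfp, out$mirna_id), , drop = FALSE]
}
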