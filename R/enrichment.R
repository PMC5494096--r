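# Hypergeometric over-representation analysis of candidate-miRNA target
# genes against GMT gene-set collections, with BH-FDR control across sets.

#' Construct a gene-set collection
#'
#' @param sets named list of character vectors (gene symbols); names must
#'   be unique.
#' @param universe character vector: the background gene universe (by
#'   convention, all genes of the reference network).
#' @param descriptions optional character vector parallel to `sets`.
#' @return object of class `gene_set_collection`.
#' @export
gene_set_collection <- function(sets, universe, descriptions = NULL) {
  if (is.null(names(sets)) || anyDuplicated(names(sets)))
    stop("`sets` must be a uniquely named list")
  universe <- unique(toupper(universe))
  sets <- lapply(sets, function(s) unique(toupper(s)))
  if (is.null(descriptions)) descriptions <- rep("", length(sets))
  structure(list(sets = sets, universe = universe,
                 descriptions = stats::setNames(descriptions, names(sets))),
            class = "gene_set_collection")
}

#' @export
print.gene_set_collection <- function(x, ...) {
  cat(sprintf("gene_set_collection: %d sets over a universe of %d genes\n",
              length(x$sets), length(x$universe)))
  invisible(x)
}

#' Read a GMT gene-set file
#'
#' Standard GMT: one set per line, tab-separated fields name, description,
#' then member symbols.
#'
#' @param path GMT file path.
#' @param universe background universe; defaults to the union of all set
#'   members.
#' @return a [gene_set_collection()].
#' @export
read_gmt <- function(path, universe = NULL) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(parts) < 3L)
  if (length(bad))
    stop(sprintf("malformed GMT line %d in '%s': need name, description, members",
                 bad[1L], path))
  nm <- vapply(parts, `[[`, "", 1L)
  desc <- vapply(parts, `[[`, "", 2L)
  sets <- lapply(parts, function(p) p[-(1:2)])
  names(sets) <- nm
  if (is.null(universe)) universe <- unique(unlist(sets))
  gene_set_collection(sets, universe, desc)
}

#' Write a gene-set collection to GMT
#'
#' @param collection a [gene_set_collection()].
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_gmt <- function(collection, path) {
  lines <- vapply(names(collection$sets), function(nm) {
    paste(c(nm, collection$descriptions[[nm]], collection$sets[[nm]]),
          collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' Hypergeometric upper-tail probability
#'
#' P(X >= k) for X ~ Hypergeometric(N, K, n): the probability of drawing at
#' least `k` annotated genes when `n` genes are drawn without replacement
#' from a universe of `N` genes of which `K` are annotated. Computed in
#' log-space for numerical stability.
#'
#' @param N universe size.
#' @param K number of annotated genes in the universe (set size).
#' @param n query size.
#' @param k observed overlap.
#' @return p-value in (0, 1].
#' @export
hypergeometric_tail <- function(N, K, n, k) {
  if (any(c(N, K, n, k) < 0) || K > N || n > N || k > min(K, n))
    stop("require 0 <= k <= min(K, n) <= N")
  if (k == 0) return(1)
  stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' Gene-set over-representation analysis
#'
#' Tests each set of the collection for over-representation of the query
#' genes by [hypergeometric_tail()], adjusts across all sets with
#' [bh_adjust()], and sorts by ascending adjusted p then set name. Query
#' genes outside the universe are dropped with a message.
#'
#' @param query character vector of gene symbols (e.g. pooled candidate
#'   targets).
#' @param collection a [gene_set_collection()].
#' @param alpha significance level for the `is_significant` flag (adjusted
#'   p strictly below `alpha`).
#' @return data.frame with columns `set_name`, `N`, `K`, `n`, `k`, `p_raw`,
#'   `p_adj`, `is_significant`, `overlap_genes` (";"-joined).
#' @export
enrich_gene_sets <- function(query, collection, alpha = 0.05) {
  stopifnot(inherits(collection, "gene_set_collection"))
  query <- unique(toupper(query))
  dropped <- setdiff(query, collection$universe)
  query_u <- intersect(query, collection$universe)
  if (length(dropped))
    message(length(dropped), " query gene(s) outside the universe dropped")
  if (length(query_u) == 0L)
    stop("no query genes in the universe; dropped: ",
         paste(dropped, collapse = ", "))
  N <- length(collection$universe)
  n <- length(query_u)
  rows <- lapply(names(collection$sets), function(nm) {
    set_u <- intersect(collection$sets[[nm]], collection$universe)
    ov <- intersect(query_u, set_u)
    data.frame(set_name = nm, N = N, K = length(set_u), n = n,
               k = length(ov),
               p_raw = hypergeometric_tail(N, length(set_u), n, length(ov)),
               overlap_genes = paste(sort(ov), collapse = ";"),
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  res$p_adj <- bh_adjust(res$p_raw)
  res$is_significant <- res$p_adj < alpha
  res <- res[order(res$p_adj, res$set_name), ,
             drop = FALSE]
  rownames(res) <- NULL
  res[, c("set_name", "N", "K", "n", "k", "p_raw", "p_adj",
          "is_significant", "overlap_genes")]
}

#' Top-k enrichment report
#'
#' First `k` records of a sorted enrichment table (ties at the cut are
#' already ordered deterministically by `p_adj` then `set_name`).
#'
#' @param records data.frame from [enrich_gene_sets()].
#' @param k number of records to keep (default 10).
#' @return the first `min(k, nrow)` records.
#' @export
top_k_report <- function(records, k = 10) {
  utils::head(records, k)
}
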