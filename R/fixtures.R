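# Curated NSCLC adenocarcinoma fixture: a published nine-miRNA candidate
# biomarker panel with its printed target lists, the TF annotation that
# reproduces the reported TFP values, and the literature-reported biomarker
# list used for known/novel bookkeeping.

#' Paths to the bundled NSCLC adenocarcinoma fixture files
#'
#' The fixture is a curated nine-miRNA candidate biomarker panel for NSCLC
#' adenocarcinoma with the published target lists (56 edges over 47 genes),
#' the transcription-factor annotation consistent with the reported TFP
#' values, the list of literature-reported adenocarcinoma biomarker miRNAs,
#' and the nine candidate ids as a differential-miRNA list for scoring-only
#' runs.
#'
#' @return named character vector with elements `edges`, `tf`, `known`,
#'   `de_mirnas`.
#' @export
nsclc_fixture_files <- function() {
  f <- function(x) system.file("extdata", x, package = "netmark",
                               mustWork = TRUE)
  c(edges = f("nsclc_candidate_edges.tsv"),
    tf = f("nsclc_tf_genes.txt"),
    known = f("nsclc_known_mirnas.txt"),
    de_mirnas = f("nsclc_de_mirnas.txt"))
}

#' Load the bundled NSCLC candidate-panel network
#'
#' @return a [regulatory_network()] built from the fixture edge list and TF
#'   annotation.
#' @export
nsclc_fixture_network <- function() {
  f <- nsclc_fixture_files()
  load_reference_network(f[["edges"]], f[["tf"]])
}
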