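# Wilcoxon signed-rank screen of the structural indices.
#
# Each miRNA's index value (NOG or TFP) is compared against the background
# distribution of the same index over the other miRNAs of the condition
# network: a one-sample signed-rank test of the differences
# (candidate - background_i) with alternative "candidate greater". Because
# the statistic depends only on the candidate value and the fixed
# background, miRNAs with equal index values receive equal p-values.

#' Screen configuration
#'
#' @param alpha significance level for candidate calls (default 0.05,
#'   strict `<`).
#' @param background `"loo"` (default): each miRNA is tested against the
#'   other miRNAs' values; `"all"`: against all values including its own.
#' @param zero_policy `"wilcoxon"` (default): zero differences are dropped
#'   before ranking; `"pratt"`: zeros are ranked with the rest but excluded
#'   from the test statistic.
#' @return list of class `screen_config`.
#' @export
screen_config <- function(alpha = 0.05, background = c("loo", "all"),
                          zero_policy = c("wilcoxon", "pratt")) {
  stopifnot(alpha > 0, alpha < 1)
  structure(list(alpha = alpha,
                 background = match.arg(background),
                 zero_policy = match.arg(zero_policy)),
            class = "screen_config")
}

#' One-sample signed-rank p-value of a candidate against a background
#'
#' Tests whether `candidate_value` is large relative to `background` via a
#' Wilcoxon signed-rank test on the differences `candidate - background_i`.
#' Zero differences are handled per `zero_policy`; ties in the absolute
#' differences receive average ranks. The p-value is exact (enumeration of
#' all 2^n sign assignments) when n <= 12 with no ties after zero handling,
#' and otherwise uses the normal approximation with tie correction and a
#' continuity correction.
#'
#' @param background numeric vector of background index values.
#' @param candidate_value the candidate's index value.
#' @param alternative only `"greater"` is supported: small p-values mean
#'   the candidate exceeds the background.
#' @param zero_policy `"wilcoxon"` (drop zeros, default) or `"pratt"`.
#' @return p-value in (0, 1].
#' @export
wilcoxon_signed_rank_p <- function(background, candidate_value,
                                   alternative = "greater",
                                   zero_policy = c("wilcoxon", "pratt")) {
  alternative <- match.arg(alternative, "greater")
  zero_policy <- match.arg(zero_policy)
  d <- candidate_value - background
  if (all(d == 0)) {
    warning("all differences are zero: degenerate signed-rank test, p = 1")
    return(1)
  }
  if (zero_policy == "wilcoxon") {
    d <- d[d != 0]
    r <- rank(abs(d))
    W <- sum(r[d > 0])
    n <- length(d)
    ranks_used <- r
  } else {  # pratt: rank zeros with the rest, drop them from W and the null
    r <- rank(abs(d))
    nonzero <- d != 0
    W <- sum(r[d > 0])
    n <- sum(nonzero)
    ranks_used <- r[nonzero]
  }
  ties <- anyDuplicated(ranks_used) > 0L
  if (n <= 12L && !ties && zero_policy == "wilcoxon") {
    # exact: enumerate all 2^n sign assignments of the ranks
    p_exact_signed_rank(ranks_used, W)
  } else {
    mu <- sum(ranks_used) / 2
    # variance of the sum of positively-signed ranks with average-rank ties
    sigma2 <- sum(ranks_used^2) / 4
    z <- (W - mu - 0.5) / sqrt(sigma2)
    stats::pnorm(z, lower.tail = FALSE)
  }
}

# exact P(W* >= W) over all sign assignments of `ranks`
p_exact_signed_rank <- function(ranks, W) {
  n <- length(ranks)
  total <- 2^n
  # distribution of W* by dynamic programming over achievable sums
  counts <- numeric(sum(ranks) + 1)  # index s+1 = count of assignments with W* = s
  counts[1] <- 1
  for (r in ranks) {
    shifted <- c(numeric(r), counts[seq_len(length(counts) - r)])
    counts <- counts + shifted
  }
  sum(counts[seq.int(floor(W) + 1L, length(counts))]) / total
}

#' Screen all scored miRNAs for candidate biomarkers
#'
#' For each miRNA, computes `p_nog` and `p_tfp` by [wilcoxon_signed_rank_p()]
#' against the background of the other miRNAs' NOG and TFP values (or all
#' values, per `config$background`). A miRNA is a candidate when both
#' p-values are strictly below `config$alpha`. Output rows keep the input
#' order of `scores`.
#'
#' @param scores data.frame from [score_all()] (>= 6 rows).
#' @param config a [screen_config()].
#' @return data.frame with columns `mirna_id`, `nog`, `p_nog`, `tfp`,
#'   `p_tfp`, `targets`, `is_candidate`.
#' @export
screen_biomarkers <- function(scores, config = screen_config()) {
  if (nrow(scores) < 6L)
    stop("need at least 6 scored miRNAs for the signed-rank screen")
  n <- nrow(scores)
  p_nog <- p_tfp <- numeric(n)
  for (i in seq_len(n)) {
    bg <- if (config$background == "loo") -i else seq_len(n)
    p_nog[i] <- suppressWarnings(
      wilcoxon_signed_rank_p(scores$nog[bg], scores$nog[i],
                             zero_policy = config$zero_policy))
    p_tfp[i] <- suppressWarnings(
      wilcoxon_signed_rank_p(scores$tfp[bg], scores$tfp[i],
                             zero_policy = config$zero_policy))
  }
  data.frame(mirna_id = scores$mirna_id,
             nog = scores$nog, p_nog = p_nog,
             tfp = scores$tfp, p_tfp = p_tfp,
             targets = scores$targets,
             is_candidate = p_nog < config$alpha & p_tfp < config$alpha,
             stringsAsFactors = FALSE)
}

#' Flag candidates already reported in the literature
#'
#' Matches candidate miRNA ids against a curated list of known biomarkers.
#' With `arm_insensitive = TRUE` (default) a known entry without a -3p/-5p
#' arm suffix matches any arm of that miRNA (so a reported "miR-145"
#' matches a candidate "miR-145-5p"); entries carrying an arm suffix match
#' exactly.
#'
#' @param calls data.frame from [screen_biomarkers()].
#' @param known_file path to a one-id-per-line file of reported biomarker
#'   miRNAs; missing or `NULL` leaves all calls unknown.
#' @param known_ids character vector used instead of `known_file` if given.
#' @param arm_insensitive logical (default `TRUE`).
#' @return `calls` with an added logical column `is_known`.
#' @export
annotate_known <- function(calls, known_file = NULL, known_ids = NULL,
                           arm_insensitive = TRUE) {
  if (is.null(known_ids)) {
    known_ids <- if (!is.null(known_file) && file.exists(known_file))
      read_id_list(known_file) else character()
  }
  known_ids <- normalize_mirna_id(known_ids)
  ids <- normalize_mirna_id(calls$mirna_id)
  is_known <- ids %in% known_ids
  if (arm_insensitive && length(known_ids)) {
    armless <- known_ids[!has_arm(known_ids)]
    is_known <- is_known | strip_arm(ids) %in% armless
  }
  calls$is_known <- is_known
  calls
}

#' Write a candidate table to TSV
#'
#' Serializes a screened (optionally annotated) candidate table; TFP is
#' reported to 2 decimals (half away from zero), p-values with 6
#' significant digits.
#'
#' @param calls data.frame from [screen_biomarkers()] / [annotate_known()].
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_candidate_tsv <- function(calls, path) {
  out <- calls
  out$tfp <- sprintf("%.2f", round_half_away(calls$tfp, 2))
  for (col in intersect(c("p_nog", "p_tfp"), names(out)))
    out[[col]] <- signif(out[[col]], 6)
  write_tsv(out, path)
  invisible(path)
}
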