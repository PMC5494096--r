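#' Round half away from zero
#'
#' Rounding convention used when reporting TFP values: exact halves are
#' rounded away from zero (so 0.125 reported to 2 decimals is 0.13), unlike
#' [round()]'s round-half-even. This is the convention the candidate tables
#' are printed with.
#'
#' @param x numeric vector.
#' @param digits number of decimal places (default 2).
#' @return numeric vector rounded half away from zero.
#' @examples
#' round_half_away(0.125, 2)  # 0.13
#' round(0.125, 2)            # 0.12 (round-half-even)
#' @export
round_half_away <- function(x, digits = 2) {
  scale <- 10^digits
  # nudge by an epsilon proportional to x to defeat binary representation
  # of values like 0.115 that are stored slightly below the true half
  sign(x) * floor(abs(x) * scale + 0.5 + 1e-9) / scale
}

#' Normalize miRNA identifiers
#'
#' Puts identifiers into lower-case "miR-" style: strips a species prefix
#' such as "hsa-", fixes capitalisation of the "miR" stem, and preserves
#' -3p/-5p arm suffixes untouched.
#'
#' @param x character vector of miRNA ids.
#' @return normalized character vector.
#' @examples
#' normalize_mirna_id(c("hsa-miR-145-5p", "MIR-650", "mir-139-5p"))
#' @export
normalize_mirna_id <- function(x) {
  x <- trimws(x)
  x <- sub("^hsa-", "", x, ignore.case = TRUE)
  x <- sub("^mir-?", "miR-", x, ignore.case = TRUE)
  x
}

# strip a trailing -3p/-5p arm suffix (for arm-insensitive matching)
strip_arm <- function(x) sub("-[35]p$", "", x)

# has an explicit arm suffix?
has_arm <- function(x) grepl("-[35]p$", x)

# derive independent sub-seeds from a master seed, kept within 32-bit range
substream_seed <- function(seed, k) {
  (as.integer(seed) %% 1000003L) * 2017L + 97L * as.integer(k)
}

# read a one-id-per-line text file, ignoring blanks and '#' comments
read_id_list <- function(path) {
  x <- readLines(path, warn = FALSE)
  x <- trimws(x)
  x[nzchar(x) & !startsWith(x, "#")]
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

read_tsv <- function(path, ...) {
  utils::read.delim(path, sep = "\t", header = TRUE,
                    stringsAsFactors = FALSE, check.names = FALSE, ...)
}
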