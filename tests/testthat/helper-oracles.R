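# Independent oracles (brute force / enumeration) and small generators
# used across the suite. These deliberately avoid the package's own code
# paths for the quantities they check.

# NOG by double loop: for each target, count how many miRNAs target it
oracle_nog <- function(network, mirna_id) {
  e <- network$edges
  targets <- e$gene_id[e$mirna_id == mirna_id]
  sum(vapply(targets, function(g) sum(e$gene_id == g) == 1L, logical(1)))
}

oracle_tfp <- function(network, mirna_id) {
  e <- network$edges
  targets <- e$gene_id[e$mirna_id == mirna_id]
  if (!length(targets)) return(0)
  mean(targets %in% network$tf_genes)
}

# exact one-sample signed-rank P(W* >= W) by enumerating all 2^n sign
# vectors of the absolute-difference ranks (zeros dropped)
oracle_signed_rank_p <- function(background, candidate) {
  d <- candidate - background
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  W <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  w_all <- as.vector(signs %*% r)
  mean(w_all >= W)
}

# hypergeometric upper tail by direct pmf summation via log-binomials
oracle_hyper_tail <- function(N, K, n, k) {
  kk <- k:min(K, n)
  sum(exp(lchoose(K, kk) + lchoose(N - K, n - kk) - lchoose(N, n)))
}

# small random bipartite network with a given edge probability
random_test_network <- function(n_mirnas, n_genes, p_edge = 0.15,
                                tf_frac = 0.3) {
  ms <- sprintf("miR-t%02d", seq_len(n_mirnas))
  gs <- sprintf("G%03d", seq_len(n_genes))
  pairs <- expand.grid(mirna_id = ms, gene_id = gs,
                       stringsAsFactors = FALSE)
  keep <- stats::runif(nrow(pairs)) < p_edge
  regulatory_network(pairs[keep, , drop = FALSE],
                     tf_genes = sample(gs, ceiling(tf_frac * n_genes)),
                     mirnas = ms)
}

# tiny two-group dataset with given per-feature shifts in cases
make_dataset <- function(n_features, n1, n2, shift = 0, sd = 1,
                         baseline = 8) {
  mat <- matrix(stats::rnorm(n_features * (n1 + n2), baseline, sd),
                nrow = n_features,
                dimnames = list(sprintf("f%04d", seq_len(n_features)),
                                sprintf("s%03d", seq_len(n1 + n2))))
  grp <- rep(c("case", "control"), c(n1, n2))
  if (length(shift) == 1L) shift <- rep(shift, n_features)
  mat[, grp == "case"] <- mat[, grp == "case"] + shift
  expression_dataset(mat, grp)
}
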