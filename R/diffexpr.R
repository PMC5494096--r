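# Empirical-Bayes moderated two-sample testing.
#
# The per-feature pooled variance s_g^2 (residual df d_g) is shrunk toward a
# prior variance s0^2 with prior df d0, both estimated by method of moments
# on z_g = log(s_g^2), whose mean/variance under the scaled-chisquare model
# involve digamma/trigamma terms. The moderated statistic
#   t_g = logFC_g / sqrt(s~_g^2 * (1/n1 + 1/n2)),
#   s~_g^2 = (d0*s0^2 + d_g*s_g^2) / (d0 + d_g)
# is referred to a t distribution with d0 + d_g df (normal when d0 = Inf).

# variance floor applied before taking log-variance moments so that
# zero-variance features keep the trigamma inversion finite
.VAR_FLOOR <- 1e-12

# Invert trigamma(x) = y by Newton iteration on a log scale-stable update.
trigamma_inverse <- function(y, tol = 1e-8, maxit = 50L) {
  if (!is.finite(y)) return(if (y > 0) 0 else Inf)
  if (y <= 0) return(Inf)
  if (y > 1e7) return(1 / sqrt(y))
  if (y < 1e-6) return(1 / y)
  x <- 0.5 + 1 / y
  for (i in seq_len(maxit)) {
    tri <- trigamma(x)
    dif <- tri * (1 - tri / y) / psigamma(x, deriv = 2L)
    x <- x + dif
    if (abs(dif) < tol * x) break
  }
  x
}

#' Estimate empirical-Bayes variance hyperparameters
#'
#' Method-of-moments fit of the prior df `d0` and prior variance `s0_sq`
#' from per-feature sample variances, assuming s_g^2 ~ s0^2 * chisq(d_g)/d_g
#' scaled by a feature-level inverse-chisquare prior. Solves
#' `trigamma(d0/2) = var(z) - trigamma(d_g/2)` for `d0` with `z = log(s_g^2)`
#' (numeric inversion by Newton iteration); `s0_sq` follows from the mean of
#' `z` corrected by the digamma terms. When the observed log-variance spread
#' is no larger than expected under equal true variances, `d0 = Inf` and
#' `s0_sq` is the (geometric-mean-based) common variance.
#'
#' @param sample_vars numeric vector of per-feature pooled variances (>= 0;
#'   values below `1e-12` are floored).
#' @param df_resid residual degrees of freedom of each variance (scalar).
#' @return list with elements `d0` (prior df, possibly `Inf`) and `s0_sq`
#'   (prior variance, > 0).
#' @export
estimate_eb_hyperparameters <- function(sample_vars, df_resid) {
  if (length(sample_vars) < 2L) stop("need >= 2 sample variances")
  if (df_resid <= 0) stop("df_resid must be positive")
  v <- pmax(sample_vars, .VAR_FLOOR)
  if (all(v == v[1L])) return(list(d0 = Inf, s0_sq = v[1L]))
  z <- log(v)
  # centre z so its expectation is log(s0^2) + digamma(d0/2) - log(d0/2)
  e <- z - digamma(df_resid / 2) + log(df_resid / 2)
  evar <- stats::var(e)
  excess <- evar - trigamma(df_resid / 2)
  if (!is.finite(excess) || excess <= 0) {
    return(list(d0 = Inf, s0_sq = exp(mean(e))))
  }
  d0 <- 2 * trigamma_inverse(excess)
  if (d0 > 1e6) return(list(d0 = Inf, s0_sq = exp(mean(e))))
  s0_sq <- exp(mean(e) + digamma(d0 / 2) - log(d0 / 2))
  list(d0 = d0, s0_sq = s0_sq)
}

#' Moderated t-test for a two-group expression dataset
#'
#' Computes, per feature, the case-minus-control log fold change, pooled
#' variance, empirical-Bayes shrunken variance, moderated t-statistic with
#' augmented degrees of freedom, two-sided p-value and BH-adjusted p-value.
#' With `d0 = 0` the statistic reduces to the ordinary pooled-variance
#' two-sample t; with `d0 = Inf` all variances are replaced by `s0_sq` and
#' the reference distribution is normal.
#'
#' @param data an [expression_dataset()] (normally quantile-normalized).
#' @param d0,s0_sq variance-prior hyperparameters, usually from
#'   [estimate_eb_hyperparameters()]; if both `NULL` they are estimated from
#'   `data`.
#' @param alpha significance level for the `is_significant` flag
#'   (BH-adjusted p strictly below `alpha`).
#' @param paired logical; if `TRUE`, samples are treated as pairs matched by
#'   order within the case and control groups (requires equal group sizes)
#'   and a one-sample moderated t on within-pair differences is used.
#' @return data.frame with columns `feature_id`, `log_fc`, `sample_var`,
#'   `moderated_var`, `t_mod`, `df_total`, `p_raw`, `p_adj`,
#'   `is_significant`.
#' @export
moderated_t_test <- function(data, d0 = NULL, s0_sq = NULL, alpha = 0.05,
                             paired = FALSE) {
  stopifnot(inherits(data, "expression_dataset"))
  x <- data$values
  case <- x[, data$group == "case", drop = FALSE]
  ctrl <- x[, data$group == "control", drop = FALSE]
  n1 <- ncol(case); n2 <- ncol(ctrl)
  if (n1 < 2L || n2 < 2L) stop("each group needs >= 2 samples")

  if (paired) {
    if (n1 != n2) stop("paired analysis requires equal group sizes")
    d <- case - ctrl
    log_fc <- rowMeans(d)
    df_resid <- n1 - 1L
    s2 <- apply(d, 1L, stats::var)
    stderr_scale <- 1 / n1
  } else {
    log_fc <- rowMeans(case) - rowMeans(ctrl)
    df_resid <- n1 + n2 - 2L
    s2 <- ((n1 - 1L) * apply(case, 1L, stats::var) +
           (n2 - 1L) * apply(ctrl, 1L, stats::var)) / df_resid
    stderr_scale <- 1 / n1 + 1 / n2
  }
  s2 <- pmax(s2, 0)

  if (is.null(d0) || is.null(s0_sq)) {
    hyp <- estimate_eb_hyperparameters(s2, df_resid)
    d0 <- hyp$d0; s0_sq <- hyp$s0_sq
  }

  if (is.infinite(d0)) {
    s2_mod <- rep(s0_sq, length(s2))
  } else if (d0 == 0) {
    s2_mod <- s2
  } else {
    s2_mod <- (d0 * s0_sq + df_resid * s2) / (d0 + df_resid)
  }
  df_total <- d0 + df_resid
  t_mod <- log_fc / sqrt(s2_mod * stderr_scale)
  t_mod[!is.finite(t_mod)] <- 0
  p_raw <- 2 * stats::pt(-abs(t_mod), df = df_total)
  p_adj <- bh_adjust(p_raw)
  data.frame(feature_id = rownames(x),
             log_fc = log_fc,
             sample_var = s2,
             moderated_var = s2_mod,
             t_mod = t_mod,
             df_total = df_total,
             p_raw = p_raw,
             p_adj = p_adj,
             is_significant = p_adj < alpha,
             row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Adjusts a vector of p-values to control the false discovery rate; the
#' output is in the input order, elementwise >= the input, capped at 1, and
#' idempotent on its own output.
#'
#' @param p_values numeric vector of p-values in \[0, 1\].
#' @return adjusted p-values, same length and order.
#' @export
bh_adjust <- function(p_values) {
  if (length(p_values) == 0L) return(numeric(0))
  if (any(p_values < 0 | p_values > 1, na.rm = TRUE))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(p_values, method = "BH")
}

#' Select significant features
#'
#' Features whose BH-adjusted p-value is strictly below `alpha`.
#'
#' @param results data.frame from [moderated_t_test()].
#' @param alpha significance level (default 0.05).
#' @return character vector of feature ids.
#' @export
select_differential <- function(results, alpha = 0.05) {
  stopifnot(alpha > 0, alpha < 1)
  results$feature_id[results$p_adj < alpha]
}

#' One-step differential expression
#'
#' Convenience wrapper: optional quantile normalization, empirical-Bayes
#' hyperparameter estimation and moderated t-testing.
#'
#' @param data an [expression_dataset()].
#' @param alpha significance level.
#' @param normalize `"quantile"` (default) or `"none"`.
#' @param paired passed to [moderated_t_test()].
#' @return data.frame as returned by [moderated_t_test()].
#' @export
differential_expression <- function(data, alpha = 0.05,
                                    normalize = c("quantile", "none"),
                                    paired = FALSE) {
  normalize <- match.arg(normalize)
  if (normalize == "quantile") data <- quantile_normalize(data)
  moderated_t_test(data, alpha = alpha, paired = paired)
}
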