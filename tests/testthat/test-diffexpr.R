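# Differential-expression stage: quantile normalization, empirical-Bayes
# hyperparameters, moderated t, BH adjustment.

test_that("quantile normalization matches its closed-form post-conditions", {
  # 2 features x 2 samples: both columns become the rank-wise means
  m <- matrix(c(1, 5, 3, 7), nrow = 2,
              dimnames = list(c("a", "b"), c("s1", "s2")))
  norm <- quantile_normalize(m)
  expect_equal(unname(norm[, 1]), c(2, 6))
  expect_equal(unname(norm[, 2]), c(2, 6))

  # identical columns are a fixed point
  m2 <- matrix(rep(c(4, 1, 9), 3), nrow = 3,
               dimnames = list(letters[1:3], paste0("s", 1:3)))
  expect_equal(quantile_normalize(m2), m2)

  # random matrix: all column-wise sorted vectors identical afterwards
  set.seed(11)
  m3 <- matrix(rnorm(500), nrow = 50,
               dimnames = list(paste0("f", 1:50), paste0("s", 1:10)))
  n3 <- quantile_normalize(m3)
  sorted <- apply(n3, 2, sort)
  expect_true(all(abs(sorted - sorted[, 1]) < 1e-12))
  # feature/sample order preserved
  expect_identical(dimnames(n3), dimnames(m3))
})

test_that("single-sample quantile normalization warns and is the identity", {
  m <- matrix(1:5, ncol = 1, dimnames = list(paste0("f", 1:5), "s1"))
  expect_warning(out <- quantile_normalize(m), "single-sample")
  expect_equal(out, m)
})

test_that("EB hyperparameters: degenerate and root-finder cases", {
  # identical variances: infinite prior df, prior variance = that variance
  hyp <- estimate_eb_hyperparameters(rep(2.5, 20), df_resid = 10)
  expect_identical(hyp$d0, Inf)
  expect_equal(hyp$s0_sq, 2.5, tolerance = 1e-10)

  # two variances {1, e}: the trigamma moment equation is solved to 1e-8
  hyp2 <- estimate_eb_hyperparameters(c(1, exp(1)), df_resid = 10)
  if (is.finite(hyp2$d0)) {
    z <- log(c(1, exp(1)))
    residual <- trigamma(hyp2$d0 / 2) - (var(z) - trigamma(10 / 2))
    expect_lt(abs(residual), 1e-8)
  } else {
    # var(z) below the sampling floor: infinite d0 is the correct root
    expect_lte(var(log(c(1, exp(1)))), trigamma(10 / 2))
  }
})

test_that("EB hyperparameters recover a known scale mixture", {
  # s_g^2 ~ s0^2 * chisq_d0/d0 prior, then chisq_{df}/df sampling noise
  set.seed(42)
  d0 <- 4; s0 <- 1; df_resid <- 10; n <- 5000
  true_var <- s0 * d0 / rchisq(n, d0)
  s2 <- true_var * rchisq(n, df_resid) / df_resid
  hyp <- estimate_eb_hyperparameters(s2, df_resid)
  expect_gt(hyp$d0, 3); expect_lt(hyp$d0, 5)
  expect_gt(hyp$s0_sq, 0.8); expect_lt(hyp$s0_sq, 1.25)
})

test_that("moderated t with d0 = 0 is the ordinary pooled two-sample t", {
  set.seed(3)
  data <- make_dataset(50, 6, 8)
  res <- moderated_t_test(data, d0 = 0, s0_sq = 1)
  x <- data$values
  for (i in c(1, 17, 50)) {
    tt <- t.test(x[i, data$group == "case"], x[i, data$group == "control"],
                 var.equal = TRUE)
    expect_equal(res$t_mod[i], unname(tt$statistic), tolerance = 1e-10)
    expect_equal(res$p_raw[i], tt$p.value, tolerance = 1e-10)
  }
})

test_that("zero log fold change gives t = 0 and p = 1", {
  m <- rbind(f1 = c(1, 2, 2, 1), f2 = c(5, 3, 1, 4))
  colnames(m) <- paste0("s", 1:4)
  data <- expression_dataset(m, c("case", "case", "control", "control"))
  res <- moderated_t_test(data, d0 = 0, s0_sq = 1)
  expect_equal(res$t_mod[1], 0)
  expect_equal(res$p_raw[1], 1)
})

test_that("moderated variance interpolates monotonically between s_g^2 and s0^2", {
  set.seed(5)
  data <- make_dataset(30, 5, 5)
  r0 <- moderated_t_test(data, d0 = 1e-9, s0_sq = 0.7)
  prev <- r0$moderated_var
  for (d0 in c(1, 10, 1000, 1e5)) {
    r <- moderated_t_test(data, d0 = d0, s0_sq = 0.7)
    lo <- pmin(r$sample_var, 0.7); hi <- pmax(r$sample_var, 0.7)
    expect_true(all(r$moderated_var >= lo - 1e-12 &
                    r$moderated_var <= hi + 1e-12))
    # each step moves every feature's variance toward s0^2
    expect_true(all(abs(r$moderated_var - 0.7) <= abs(prev - 0.7) + 1e-12))
    prev <- r$moderated_var
  }
  rinf <- moderated_t_test(data, d0 = Inf, s0_sq = 0.7)
  expect_true(all(rinf$moderated_var == 0.7))
})

test_that("moderated t agrees with limma's eBayes on random data", {
  set.seed(8)
  # heterogeneous true variances so the prior df estimate is finite and
  # both implementations take the shrinkage branch
  sds <- sqrt(4 / rchisq(200, 4))
  mat <- matrix(rnorm(200 * 16, 8, sds), nrow = 200,
                dimnames = list(sprintf("f%03d", 1:200), sprintf("s%02d", 1:16)))
  data <- expression_dataset(mat, rep(c("case", "control"), each = 8))
  res <- moderated_t_test(data)
  expect_true(is.finite(res$df_total[1]))
  design <- cbind(1, as.integer(data$group == "case"))
  fit <- limma::eBayes(limma::lmFit(data$values, design))
  expect_equal(res$t_mod, unname(fit$t[, 2]), tolerance = 1e-6)
  expect_equal(res$p_raw, unname(fit$p.value[, 2]), tolerance = 1e-6)
  expect_equal(unique(res$df_total), unname(fit$df.total[1]), tolerance = 1e-6)
})

test_that("paired moderated t with d0 = 0 matches the paired t-test", {
  set.seed(13)
  data <- make_dataset(20, 7, 7)
  res <- moderated_t_test(data, d0 = 0, s0_sq = 1, paired = TRUE)
  x <- data$values
  tt <- t.test(x[4, data$group == "case"], x[4, data$group == "control"],
               paired = TRUE)
  expect_equal(res$t_mod[4], unname(tt$statistic), tolerance = 1e-10)
  expect_equal(res$p_raw[4], tt$p.value, tolerance = 1e-10)
})

test_that("BH adjustment: worked example, dominance, order preservation, equivariance", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(0.03), 0.03)
  expect_identical(bh_adjust(numeric(0)), numeric(0))

  set.seed(21)
  p <- runif(200)^2
  q <- bh_adjust(p)
  expect_true(all(q >= p) && all(q <= 1))
  # order-preserving: adjusted values sorted like the raw ones
  expect_true(all(diff(q[order(p)]) >= -1e-15))
  perm <- sample(200)
  expect_equal(bh_adjust(p[perm]), q[perm])           # permutation-equivariant
})

test_that("selection is strict at the threshold", {
  res <- data.frame(feature_id = c("a", "b", "c"),
                    p_adj = c(0.049, 0.05, 0.051))
  expect_identical(select_differential(res, 0.05), "a")
})

test_that("type-I error of the moderated test is near nominal under the global null", {
  # 2000 null features x 10+10 samples, pooled over 20 seeds
  hits <- 0L; total <- 0L
  for (s in 1:20) {
    set.seed(1000 + s)
    data <- make_dataset(2000, 10, 10, shift = 0, sd = 1)
    res <- moderated_t_test(data)
    hits <- hits + sum(res$p_raw < 0.05)
    total <- total + nrow(res)
  }
  rate <- hits / total
  expect_gte(rate, 0.04)
  expect_lte(rate, 0.06)
})
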