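test_that("two-group fits reproduce hand-computed means, pooled variances and df", {
  ## resistant {2,2,2} vs sensitive {1,1,1}
  mat <- toy_intensity(matrix(c(1, 1, 1, 2, 2, 2), 1, 6,
                              dimnames = list("F1", NULL)), n_bio = 3)
  fit <- fit_two_group(mat)
  expect_equal(fit$logFC, 1)
  expect_equal(fit$s2, 0)
  expect_equal(fit$df, 4)
  expect_equal(fit$v, 2 / 3)

  ## resistant {3,1} vs sensitive {1,1}: var_r = 2, var_s = 0, s2 = 1, df = 2
  mat <- toy_intensity(matrix(c(1, 1, 3, 1), 1, 4, dimnames = list("F1", NULL)),
                       n_bio = 2)
  fit <- fit_two_group(mat)
  expect_equal(fit$logFC, 1)
  expect_equal(fit$s2, 1)
  expect_equal(fit$df, 2)

  ## equal groups -> logFC 0; feature with < 2 per group -> flagged NA
  vals <- matrix(c(5, 6, 5, 6, NA, 2, 3, 4), 2, 4, byrow = TRUE,
                 dimnames = list(c("F1", "F2"), NULL))
  fit <- fit_two_group(toy_intensity(vals, n_bio = 2))
  expect_equal(fit$logFC[1], 0)
  expect_true(is.na(fit$logFC[2]))
  expect_true(is.na(fit$df[2]))
})

test_that("one-sample ratio fits orient dye swaps and use n - 1 df", {
  vals <- matrix(c(1.2, -0.8, 1.0), 1, 3, dimnames = list("F1", NULL))
  mat <- toy_ratio(vals, bio_rep = 1:3, tech_rep = c(1, 1, 1),
                   dye = c("Cy5", "Cy3", "Cy5"))
  fit <- fit_two_group(mat)
  expect_equal(fit$logFC, 1)
  expect_equal(fit$df, 2)
  expect_equal(fit$v, 1 / 3)
  expect_equal(fit$s2, var(c(1.2, 0.8, 1.0)))
})

test_that("the variance prior recovers simulated hyperparameters and matches limma", {
  set.seed(21)
  d0_true <- 8; s0_true <- 0.05; df_res <- 4
  s2 <- s0_true * d0_true / rchisq(5000, d0_true) * rchisq(5000, df_res) / df_res
  pr <- estimate_prior(s2, df_res)
  lf <- limma::fitFDist(s2, df1 = df_res)
  expect_equal(pr$d0, lf$df2, tolerance = 1e-6)
  expect_equal(pr$s0_sq, lf$scale, tolerance = 1e-6)
  expect_lt(abs(pr$d0 - d0_true) / d0_true, 0.35)
  expect_lt(abs(pr$s0_sq - s0_true) / s0_true, 0.1)

  ## pure chi-square variances (no prior spread beyond sampling noise)
  s2 <- rchisq(5000, df_res) / df_res
  pr <- estimate_prior(s2, df_res)
  expect_lt(abs(pr$s0_sq - 1), 0.1)

  expect_equal(estimate_prior(rep(2, 100), 4)$d0, Inf)
  expect_error(estimate_prior(rep(0, 100), 4), "zero")
  expect_error(estimate_prior(c(1, 2), c(4, 4)), "10 features")
})

test_that("two interleaved variance populations give a finite positive prior df", {
  set.seed(22)
  s2 <- c(0.5 * rchisq(500, 4) / 4, 2 * rchisq(500, 4) / 4)
  pr <- estimate_prior(s2, 4)
  expect_true(is.finite(pr$d0) && pr$d0 > 0)
})

test_that("moderated t reproduces the worked shrinkage case and its limits", {
  fit <- data.frame(feature_id = "F1", logFC = 1, avg_expr = 1, s2 = 2,
                    df = 4, v = 2 / 3)
  out <- moderated_t(fit, list(d0 = 4, s0_sq = 1))
  expect_equal(out$s_tilde2, 1.5)
  expect_equal(out$t_mod, 1)
  expect_equal(out$p, 2 * pt(-1, df = 8))

  ## d0 = 0: ordinary pooled t on random fixtures
  set.seed(23)
  fits <- data.frame(feature_id = sprintf("F%d", 1:100),
                     logFC = rnorm(100), avg_expr = 0,
                     s2 = rchisq(100, 4) / 4, df = 4, v = 2 / 3)
  out0 <- moderated_t(fits, list(d0 = 0, s0_sq = 1))
  expect_equal(out0$t_mod, fits$logFC / sqrt(fits$s2 * fits$v), tolerance = 1e-12)

  ## identical s2 = s0^2: moderation is a fixed point for any d0
  fits$s2 <- 0.7
  for (d0 in c(0.5, 4, 100)) {
    out <- moderated_t(fits, list(d0 = d0, s0_sq = 0.7))
    expect_equal(out$t_mod, fits$logFC / sqrt(0.7 * fits$v), tolerance = 1e-12)
  }

  ## d0 -> Inf: prior variance with a normal reference
  outI <- moderated_t(fits, list(d0 = Inf, s0_sq = 0.5))
  expect_equal(outI$t_mod, fits$logFC / sqrt(0.5 * fits$v))
  expect_equal(outI$p, 2 * pnorm(-abs(outI$t_mod)))
  outL <- moderated_t(fits, list(d0 = 1e8, s0_sq = 0.5))
  expect_equal(outL$t_mod, outI$t_mod, tolerance = 1e-6)
})

test_that("moderated t grows with |logFC| at fixed variances", {
  fit <- data.frame(feature_id = sprintf("F%d", 1:5),
                    logFC = c(0.1, 0.5, 1, 2, 4), avg_expr = 0,
                    s2 = 1, df = 4, v = 2 / 3)
  out <- moderated_t(fit, list(d0 = 4, s0_sq = 1))
  expect_true(all(diff(out$t_mod) > 0))
})

test_that("BH adjustment equals brute-force step-up enumeration", {
  expect_equal(bh_fdr(rep(0.03, 10)), rep(0.03, 10))
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_fdr(c(0.005, 0.1)), c(0.01, 0.1))

  set.seed(24)
  for (i in 1:300) {
    p <- sample(seq(0, 1, by = 0.01), sample(1:6, 1), replace = TRUE)
    expect_equal(bh_fdr(p), bh_bruteforce(p))
  }
  expect_error(bh_fdr(c(0.2, 1.3)), "0, 1")
})

test_that("BH output is monotone in sorted order and permutation invariant", {
  set.seed(25)
  p <- runif(50)
  q <- bh_fdr(p)
  expect_true(all(diff(q[order(p)]) >= -1e-15))
  perm <- sample(50)
  expect_equal(bh_fdr(p[perm]), q[perm])
})

test_that("status calls follow the layer thresholds with inclusive boundaries", {
  res <- data.frame(feature_id = c("a", "b", "c", "d"),
                    logFC = c(1.2, 0.8, -0.3, -2),
                    fdr = c(0.009, 0.009, 0.10, 0.011))
  mrna <- select_differential(res, de_thresholds("mRNA"))
  expect_equal(mrna$status, c("up", "ns", "ns", "ns"))
  mirna <- select_differential(res, de_thresholds("miRNA"))
  expect_equal(mirna$status, c("up", "up", "down", "down"))
  expect_error(select_differential(res, list(fdr_max = 0, min_abs_logfc = 0)),
               "fdr_max")
})

test_that("delta-delta-Ct folds are exact and antisymmetric", {
  expect_equal(ddct_fold_change(20, 18, 20, 18), 1)
  expect_equal(ddct_fold_change(20, 18, 22, 18), 4)
  f <- ddct_fold_change(21.3, 17.2, 24.8, 18.1)
  expect_equal(ddct_fold_change(24.8, 18.1, 21.3, 17.2), 1 / f)
})
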