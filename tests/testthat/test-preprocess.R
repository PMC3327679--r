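test_that("normexp correction matches numerical integration of the convolution model", {
  pars <- normexp_params(mu = 100, sigma = 20, alpha = 500, offset = 0)
  for (x in c(150, 90, 300, 1000)) {
    got <- normexp_correct(x, 0, pars)
    want <- normexp_conditional_mean_quad(x, 100, 20, 500)
    expect_equal(got, want, tolerance = 1e-6)
  }
})

test_that("normexp is strictly positive and reduces to fg + offset in the no-background limit", {
  fg <- c(0, 1, 50, 120, 5000)
  pars <- normexp_params(mu = 0, sigma = 1e-8, alpha = 500, offset = 16)
  expect_equal(normexp_correct(fg, rep(0, 5), pars), fg + 16, tolerance = 1e-6)

  set.seed(1)
  fg <- rexp(500, 1 / 300) + rnorm(500, 100, 20)
  bg <- rnorm(500, 100, 20)
  out <- normexp_correct(pmax(fg, 0), pmax(bg, 0), "estimate")
  expect_true(all(out > 0))

  expect_error(normexp_params(100, -1, 500), "sigma")
  expect_error(normexp_params(100, 20, 0), "alpha")
})

test_that("lowess normalization removes constant and smooth intensity-dependent trends", {
  set.seed(11)
  A <- runif(400, 6, 14)

  expect_equal(lowess_normalize(rep(0, 400), A), rep(0, 400))
  expect_true(all(abs(lowess_normalize(rep(0.5, 400), A)) < 1e-6))

  M <- 0.3 * A + rnorm(400, 0, 0.01)
  out <- lowess_normalize(M, A)
  dec <- cut(A, quantile(A, 0:10 / 10), include.lowest = TRUE)
  expect_true(all(abs(tapply(out, dec, median)) < 0.02))

  expect_error(lowess_normalize(c(1, 2, NA), c(1, NA, 3)), "10 finite")
  M2 <- M; M2[5] <- NA
  out2 <- lowess_normalize(M2, A)
  expect_true(is.na(out2[5]))
  expect_equal(length(out2), 400L)
})

test_that("lowess and rank-invariant normalization are shift/scale equivariant", {
  set.seed(2)
  A <- runif(200, 6, 14)
  M <- rnorm(200, 0, 0.3)
  expect_equal(lowess_normalize(M + 2, A), lowess_normalize(M, A),
               tolerance = 1e-6)

  ch1 <- 2^runif(200, 6, 14)
  ch2 <- ch1 * 2^rnorm(200, 0, 0.2)
  expect_equal(rank_invariant_normalize(3 * ch1, 3 * ch2),
               rank_invariant_normalize(ch1, ch2), tolerance = 1e-6)
})

test_that("rank-invariant normalization nulls identical and globally scaled channels", {
  set.seed(3)
  ch1 <- 2^runif(300, 6, 14)
  expect_true(all(abs(rank_invariant_normalize(ch1, ch1)) < 1e-8))
  expect_true(all(abs(rank_invariant_normalize(ch1, 2 * ch1)) < 1e-8))
  expect_error(rank_invariant_normalize(ch1[1:10], ch1[1:10]), "20")
})

test_that("rank-invariant normalization removes an intensity-dependent bias despite spiked features", {
  set.seed(4)
  n <- 1000
  ch1 <- 2^runif(n, 6, 14)
  A0 <- log2(ch1)
  bias <- 0.4 * (A0 - 10) / 4
  ch2 <- ch1 * exp(bias * log(2)) * 2^rnorm(n, 0, 0.05)
  spiked <- sample(n, 50)
  ch2[spiked] <- ch2[spiked] * 2^1.5
  out <- rank_invariant_normalize(ch1, ch2)
  expect_lt(median(abs(out[-spiked])), 0.05)
})

test_that("the variance-stabilizing transform approaches log2 and equalizes replicate variance", {
  set.seed(5)
  mu <- 2^runif(600, 13.5, 17)
  vals <- cbind(mu, mu)
  mat <- toy_intensity(vals, layer = "miRNA", n_bio = 1, n_tech = 1)
  out <- vsn_like_normalize(mat)
  shift <- median(out$values[, 1] - log2(vals[, 1]))
  expect_true(all(abs(out$values[, 1] - (log2(vals[, 1]) + shift)) /
                    abs(log2(vals[, 1])) < 0.01))
  expect_identical(out$values[, 1], out$values[, 2])

  ## additive + multiplicative noise model: y = mu * exp(eta) + eps,
  ## eta ~ N(0, 0.15^2), eps ~ N(0, 60^2); 4 technical replicates
  mu <- 2^runif(2000, 4, 14)
  reps <- sapply(1:4, function(i) mu * exp(rnorm(2000, 0, 0.15)) + rnorm(2000, 0, 60))
  reps <- pmax(reps, 1)
  mat <- toy_intensity(cbind(reps, reps), layer = "miRNA", n_bio = 1, n_tech = 4)
  mat$values <- mat$values[, 1:4, drop = FALSE]
  mat$samples <- mat$samples[1:4, , drop = FALSE]
  out <- vsn_like_normalize(mat)
  qs <- cut(rowMeans(out$values), quantile(rowMeans(out$values), 0:4 / 4),
            include.lowest = TRUE)
  sd_by_q <- function(x) tapply(apply(x, 1, sd), qs, median)
  s_vsn <- sd_by_q(out$values)
  s_log <- sd_by_q(log2(pmax(reps, 1)))
  expect_lt(max(s_vsn) / min(s_vsn) - 1, 0.25)
  expect_gt(max(s_log) / min(s_log) - 1, 2)

  mat$values[, 2] <- 0
  expect_error(vsn_like_normalize(mat), "all-zero")
})

test_that("low-signal filtering keeps the 60% boundary and removes strictly above it", {
  fg <- matrix(10, 3, 5, dimnames = list(c("F1", "F2", "F3"), NULL))
  bg <- matrix(5, 3, 5)
  bg[1, 1:3] <- 20   # below background in 3 of 5 arrays: fraction 0.6 -> kept
  bg[2, 1:4] <- 20   # 0.8 -> removed
  rep <- filter_low_signal(fg, bg)
  expect_true("F1" %in% rep$kept)
  expect_true("F2" %in% rep$removed)
  expect_equal(rep$removed, "F2")
  expect_equal(unname(rep$fraction), c(0.6, 0.8, 0))

  all_above <- filter_low_signal(fg, matrix(5, 3, 5))
  expect_equal(length(all_above$removed), 0L)
  expect_error(filter_low_signal(fg, bg, max_fraction = 1.2), "0, 1")
})

test_that("lowering the filter threshold never rescues a removed feature", {
  set.seed(6)
  fg <- matrix(runif(200, 5, 15), 20, 10,
               dimnames = list(sprintf("F%02d", 1:20), NULL))
  bg <- matrix(runif(200, 5, 15), 20, 10)
  fracs <- seq(0, 1, by = 0.1)
  removed_sets <- lapply(fracs, function(f) filter_low_signal(fg, bg, f)$removed)
  for (i in seq_along(fracs)[-1])
    expect_true(all(removed_sets[[i]] %in% removed_sets[[i - 1]]))
})

test_that("replicate collapse reorients dye swaps, averages, and honours missing values", {
  vals <- matrix(c(1, -1), 1, 2, dimnames = list("F1", NULL))
  mat <- toy_ratio(vals, bio_rep = c(1, 1), tech_rep = c(1, 2),
                   dye = c("Cy5", "Cy3"))
  out <- collapse_replicates(mat)
  expect_equal(unname(out$values[1, 1]), 1)

  vals <- matrix(0.5, 1, 4, dimnames = list("F1", NULL))
  mat <- toy_ratio(vals, bio_rep = rep(1, 4), tech_rep = 1:4, dye = rep("Cy5", 4))
  expect_equal(unname(collapse_replicates(mat)$values[1, 1]), 0.5)

  vals <- matrix(c(1, 2, 3, NA), 1, 4, dimnames = list("F1", NULL))
  mat <- toy_ratio(vals, bio_rep = rep(1, 4), tech_rep = 1:4, dye = rep("Cy5", 4))
  expect_equal(unname(collapse_replicates(mat)$values[1, 1]), 2)

  mat$samples$dye[2] <- NA
  expect_error(collapse_replicates(mat), "dye")
})

test_that("replicate collapse commutes with feature reordering", {
  set.seed(8)
  vals <- matrix(rnorm(24), 6, 4,
                 dimnames = list(sprintf("F%d", 1:6), NULL))
  mat <- toy_ratio(vals, bio_rep = c(1, 1, 2, 2), tech_rep = c(1, 2, 1, 2),
                   dye = c("Cy5", "Cy3", "Cy5", "Cy3"))
  out1 <- collapse_replicates(mat)
  perm <- c(4, 2, 6, 1, 3, 5)
  mat2 <- mat
  mat2$values <- mat$values[perm, ]
  out2 <- collapse_replicates(mat2)
  expect_identical(out2$values[rownames(out1$values), ], out1$values)
})
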