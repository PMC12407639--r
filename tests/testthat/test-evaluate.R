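test_that("masked MSE evaluates directly and symmetrically", {
  a <- matrix(0, 2, 2)
  b <- matrix(c(1, 0, 0, 3), 2, 2)
  expect_equal(masked_mse(a, a), 0)
  expect_equal(masked_mse(a, a + 1), 1)
  mask <- matrix_mask(c(1, 2), c(1, 2), shape = c(2, 2))
  expect_equal(masked_mse(a, b, mask), 5) # (1 + 9) / 2
  expect_equal(masked_mse(b, a, mask), masked_mse(a, b, mask))
  empty <- matrix_mask(integer(0), integer(0), shape = c(2, 2))
  expect_error(masked_mse(a, b, empty), "empty")
  expect_error(masked_mse(a, matrix(0, 3, 2)), "shape")
})

test_that("per-taxon correlation honours affine and monotone maps", {
  set.seed(12)
  a <- matrix(runif(60, 1, 4), 12, 5)
  affine <- per_taxon_correlation(a, 2 * a + 3, "pearson")
  expect_true(all(abs(affine$per_taxon - 1) < 1e-12))
  neg <- per_taxon_correlation(a, -a, "pearson")
  expect_true(all(abs(neg$per_taxon + 1) < 1e-12))
  # non-affine monotone map: Spearman stays 1, Pearson drops below it
  cubed <- a^3
  expect_true(all(per_taxon_correlation(a, cubed, "spearman")$per_taxon == 1))
  expect_true(all(per_taxon_correlation(a, cubed, "pearson")$per_taxon < 1))
  # symmetry in the two arguments
  b <- matrix(runif(60), 12, 5)
  expect_equal(per_taxon_correlation(a, b)$per_taxon,
               per_taxon_correlation(b, a)$per_taxon)
  # constant columns are flagged and excluded, not zeroed
  b2 <- b; b2[, 3] <- 7
  pc <- per_taxon_correlation(a, b2)
  expect_true(is.na(pc$per_taxon[3]))
  expect_equal(pc$n_excluded, 1L)
  expect_equal(pc$mean, mean(pc$per_taxon[-3]))
})

test_that("identification rate counts restored injected zeros", {
  mk <- function(imputed, input) {
    structure(list(imputed_logged = imputed, input_logged = input),
              class = "mbsparse_result")
  }
  input <- matrix(0, 2, 5)
  mask <- matrix_mask(rep(1:2, 5), rep(1:5, each = 2), shape = c(2, 5))
  expect_equal(identification_rate(mk(input + 1, input), mask), 1)
  expect_equal(identification_rate(mk(input, input), mask), 0)
  nine <- input; nine[1:9] <- 2
  expect_equal(identification_rate(mk(nine, input), mask), 0.9)
  # mask coordinates must have been zeros in the input
  expect_error(identification_rate(mk(nine, nine), mask), "not zero")
  empty <- matrix_mask(integer(0), integer(0), shape = c(2, 5))
  expect_error(identification_rate(mk(input, input), empty), "empty")
})

test_that("SMA regression matches its closed form and symmetry", {
  f <- sma_fit(c(1, 2, 3), c(2, 4, 6))
  expect_equal(f$slope, 2)
  expect_equal(f$intercept, 0)
  expect_equal(f$pearson_r, 1)
  g <- sma_fit(c(1, 2, 3), c(6, 4, 2))
  expect_equal(g$slope, -2)
  expect_equal(g$intercept, 8)
  expect_equal(g$pearson_r, -1)
  # swapping x and y inverts the slope on collinear data
  h <- sma_fit(c(2, 4, 6), c(1, 2, 3))
  expect_equal(h$slope, 1 / f$slope)
  expect_error(sma_fit(c(1, 1, 1), c(1, 2, 3)), "constant")
})

test_that("SMA agrees with an eigen-decomposition oracle", {
  set.seed(77)
  for (case in 1:100) {
    n <- sample(5:40, 1)
    x <- rnorm(n)
    y <- 0.5 * sample(c(-1, 1), 1) * x + rnorm(n, sd = runif(1, 0.1, 2))
    f <- sma_fit(x, y)
    # oracle: major axis of the standardized covariance, rescaled back;
    # sign-align the eigenvector with the correlation
    r <- cor(x, y)
    ev <- eigen(cov(cbind(scale(x), scale(y))))$vectors[, 1]
    slope_std <- ev[2] / ev[1]
    if (sign(slope_std) != sign(r)) slope_std <- -slope_std # tie of axes
    expect_equal(f$slope, slope_std * sd(y) / sd(x), tolerance = 1e-8)
  }
})

test_that("recovery report scores perfect and no-op imputations correctly", {
  mat <- rand_counts(12, 8, seed = 23, lambda = 8)
  ex <- inject_dropout(mat, 0.3, seed = 1)
  tm <- transform_counts(ex$corrupted)
  complete_logged <- transform_counts(ex$complete)$logged
  mk <- function(imputed) {
    structure(list(imputed_logged = imputed,
                   imputed_normalized = inverse_transform(imputed),
                   input_logged = tm$logged, transform = tm),
              class = "mbsparse_result")
  }
  perfect <- recovery_report(ex, mk(complete_logged))
  expect_equal(perfect$mse, 0)
  expect_equal(perfect$identification_rate, 1)
  expect_true(all(abs(na.omit(perfect$pearson_per_taxon) - 1) < 1e-12))
  noop <- recovery_report(ex, mk(tm$logged))
  expect_equal(noop$identification_rate, 0)
  expect_equal(noop$mse, noop$baseline_mse)
  expect_equal(noop$mean_pearson, noop$baseline_mean_pearson)
})

test_that("recovery report is equivariant under taxon permutation", {
  mat <- rand_counts(12, 8, seed = 29, lambda = 8)
  ex <- inject_dropout(mat, 0.3, seed = 2)
  res <- run_mbsparse(ex$corrupted, small_config(seed = 3))
  rep1 <- recovery_report(ex, res)
  perm <- sample(8)
  ex_p <- ex
  ex_p$complete <- count_matrix(ex$complete[, perm])
  ex_p$corrupted <- count_matrix(ex$corrupted[, perm])
  ij <- unclass(ex$injected_mask)
  ex_p$injected_mask <- matrix_mask(ij[, "sample"], order(perm)[ij[, "taxon"]],
                                    dim(ex$complete))
  res_p <- res
  res_p$imputed_logged <- res$imputed_logged[, perm]
  res_p$imputed_normalized <- res$imputed_normalized[, perm]
  res_p$input_logged <- res$input_logged[, perm]
  res_p$transform <- transform_counts(ex_p$corrupted)
  rep2 <- recovery_report(ex_p, res_p)
  for (f in c("mse", "baseline_mse", "identification_rate",
              "mean_pearson", "mean_spearman")) {
    expect_equal(rep1[[f]], rep2[[f]], tolerance = 1e-12)
  }
})

test_that("provenance mismatches are rejected", {
  mat <- rand_counts(10, 8, seed = 31, lambda = 8)
  ex <- inject_dropout(mat, 0.3, seed = 1)
  other <- run_mbsparse(rand_counts(10, 8, seed = 99, lambda = 8),
                        small_config(seed = 1))
  expect_error(recovery_report(ex, other), "not produced")
})
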