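test_that("the generator is seed-reproducible and hits its sparsity regime", {
  spec <- synthetic_spec(n_samples = 40, n_taxa = 60, seed = 5)
  m1 <- synthesize_count_matrix(spec)
  m2 <- synthesize_count_matrix(spec)
  expect_identical(m1, m2)
  # zero_inflation = 0: with the default large means, sampling zeros are rare
  dense <- synthesize_count_matrix(synthetic_spec(n_samples = 40, n_taxa = 60,
                                                  zero_inflation = 0, seed = 5))
  expect_lt(mean(dense == 0), 0.01)
  # zero_inflation = 0.9: the observed fraction is at least the injected one,
  # up to 3 binomial standard errors
  sparse <- synthesize_count_matrix(synthetic_spec(n_samples = 40, n_taxa = 60,
                                                   zero_inflation = 0.9, seed = 5))
  se <- sqrt(0.9 * 0.1 / length(sparse))
  expect_gte(mean(sparse == 0), 0.9 - 3 * se)
})

test_that("group effects shift the designated taxa", {
  spec <- synthetic_spec(n_samples = 60, n_taxa = 40, n_groups = 2,
                         effect_size = 2, zero_inflation = 0, seed = 9)
  mat <- synthesize_count_matrix(spec)
  grp <- attr(mat, "group")
  da <- attr(mat, "da_taxa")
  expect_equal(length(da), 10L) # a quarter of the taxa by default
  da_ratio <- colMeans(mat[grp == 2, da]) / colMeans(mat[grp == 1, da])
  other_ratio <- colMeans(mat[grp == 2, -da]) / colMeans(mat[grp == 1, -da])
  expect_gt(median(da_ratio), 2 * median(other_ratio))
})

test_that("extraction scheme returns the zero-free dense block", {
  set.seed(21)
  mat <- matrix(0, 30, 25)
  mat[1:10, 1:20] <- rpois(200, 20) + 1 # dense block
  mat[11:30, ] <- rpois(500, 0.3) # sparse remainder
  mat[, 21:25] <- rbinom(150, 1, 0.2) * rpois(150, 5)
  mat <- count_matrix(mat)
  sub <- make_complete_scheme1(mat, proportion = 20 / 25)
  expect_equal(sum(sub == 0), 0L)
  expect_true(all(paste0("S", 1:10) %in% rownames(sub)))
  expect_equal(ncol(sub), 20L)
  # proportion 1 on an already zero-free matrix is the identity
  dense <- count_matrix(matrix(rpois(20, 9) + 1, 4, 5))
  expect_identical(make_complete_scheme1(dense, 1), dense)
  # no zero-free submatrix -> rejection
  sparse <- count_matrix(diag(4) * 3)
  expect_error(make_complete_scheme1(sparse, 1), "no zero-free submatrix")
})

test_that("extraction-plus-sampling rows sum to the depth and converge", {
  set.seed(3)
  mat <- count_matrix(matrix(rpois(300, 50) + 1, 15, 20))
  s2 <- make_complete_scheme2(mat, proportion = 0.5, depth = 2000, seed = 8)
  expect_true(all(rowSums(s2) == 2000))
  expect_identical(s2, make_complete_scheme2(mat, 0.5, 2000, seed = 8))
  # law of large numbers: at depth 1e6 the relative abundances match the
  # extracted matrix within 5% per entry
  extracted <- make_complete_scheme1(mat, 0.5)
  deep <- make_complete_scheme2(mat, 0.5, depth = 1e6, seed = 8)
  rel_ext <- extracted / rowSums(extracted)
  rel_deep <- deep / 1e6
  expect_lt(max(abs(rel_deep - rel_ext) / rel_ext), 0.05)
})

test_that("dropout injection removes the exact count and is invertible", {
  set.seed(13)
  mat <- count_matrix(matrix(rpois(50, 5) + 1, 5, 10)) # 50 non-zero entries
  ex <- inject_dropout(mat, 0.1, seed = 2)
  expect_equal(nrow(ex$injected_mask), 5L) # floor(0.1 * 50)
  idx <- mbsparse:::mask_linear_index(ex$injected_mask)
  expect_true(all(ex$corrupted[idx] == 0))
  expect_true(all(ex$complete[idx] > 0))
  # outside the mask the matrices agree
  expect_identical(ex$corrupted[-idx], ex$complete[-idx])
  # mask is sufficient to undo the corruption
  expect_identical(restore_from_mask(ex), unclass(ex$complete))
  # rate 0: nothing changes
  ex0 <- inject_dropout(mat, 0, seed = 2)
  expect_identical(ex0$corrupted, ex0$complete)
  expect_equal(nrow(ex0$injected_mask), 0L)
  expect_error(inject_dropout(mat, 1), "rate")
})

test_that("depth downsampling conserves totals and tracks depth", {
  mat <- rand_counts(10, 30, seed = 17, lambda = 200)
  ds <- downsample_depth(mat, 500, seed = 4)
  expect_true(all(rowSums(ds) == 500))
  expect_identical(ds, downsample_depth(mat, 500, seed = 4))
  # deeper sequencing leaves fewer zeros (mean over 30 seeds)
  zf <- function(depth) {
    mean(vapply(1:30, function(s) mean(downsample_depth(mat, depth, seed = s) == 0),
                numeric(1)))
  }
  expect_lte(zf(10000), zf(1000))
  # depth_experiment masks exactly the newly created zeros
  de <- depth_experiment(mat, 100, seed = 1)
  lg <- mask_to_logical(de$injected_mask)
  expect_identical(lg, unname(mat > 0 & de$corrupted == 0))
})

test_that("outlier construction respects eligibility and value pools", {
  set.seed(55)
  mat <- matrix(rpois(40 * 30, 40), 40, 30)
  mat[, 1:10] <- rpois(400, 2) # low-abundance taxa, mostly >= 10 non-zeros
  mat[, 11] <- c(rpois(5, 2) + 1, rep(0, 35)) # only 5 non-zero entries
  mat <- count_matrix(mat)
  out <- make_outlier(mat, sample_index = 3, seed = 6)
  row <- out[3, ]
  chosen <- which(row > 0)
  eligible <- which(colMeans(mat) < median(colMeans(mat)) &
                      colSums(mat > 0) >= 10)
  # the target row is non-zero exactly on chosen eligible taxa
  expect_true(all(chosen %in% eligible))
  expect_equal(length(chosen), length(eligible)) # "auto" uses all of them
  # the thin taxon (5 non-zeros) is never chosen
  expect_equal(row[11], c(T11 = 0))
  # each injected value comes from that taxon's top-100 observed pool
  for (j in chosen) {
    vals <- mat[, j][mat[, j] > 0]
    pool <- sort(vals, decreasing = TRUE)[seq_len(min(100, length(vals)))]
    expect_true(row[j] %in% pool)
  }
  expect_identical(out, make_outlier(mat, 3, seed = 6))
  expect_error(make_outlier(mat, 3, n_outlier_taxa = 1e4), "eligible")
})
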