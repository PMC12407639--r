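#' Specification for the synthetic count generator
#'
#' The generator emulates the sparsity regime of WGS species profiles: a
#' low-rank log-normal mean structure (samples and taxa share latent
#' factors, inducing the between-sample correlation the KNN graph exploits),
#' negative-binomial count noise, and independent entry-wise zero inflation.
#' Defaults reflect the benchmark conditions used throughout the test suite:
#' 100 samples, 300 taxa, 30% zero inflation.
#'
#' @param n_samples,n_taxa Matrix dimensions (defaults 100 x 300).
#' @param latent_rank Rank of the log-mean structure (default 5);
#'   must not exceed min(n_samples, n_taxa).
#' @param zero_inflation Probability an entry is zeroed on top of sampling
#'   zeros (default 0.3).
#' @param dispersion Negative-binomial dispersion; the NB size parameter is
#'   1/dispersion (default 0.5).
#' @param mean_log_abundance Intercept of the log-mean (natural log scale,
#'   default log(100)), setting the typical per-entry count.
#' @param n_groups Number of sample groups (default 1). With more than one
#'   group a fixed set of taxa is differentially abundant between groups.
#' @param effect_size Log-scale shift applied to differential taxa in
#'   non-reference groups (default 0).
#' @param n_da_taxa Number of differentially abundant taxa when
#'   `n_groups > 1` (default: a quarter of the taxa).
#' @param seed RNG seed.
#' @return A list of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_samples = 100L, n_taxa = 300L, latent_rank = 5L,
                           zero_inflation = 0.3, dispersion = 0.5,
                           mean_log_abundance = log(100),
                           n_groups = 1L, effect_size = 0,
                           n_da_taxa = NULL, seed = 1L) {
  stopifnot(n_samples >= 2, n_taxa >= 2, latent_rank >= 1,
            zero_inflation >= 0, zero_inflation <= 1,
            dispersion > 0, n_groups >= 1, effect_size >= 0)
  if (latent_rank > min(n_samples, n_taxa)) {
    abort("latent_rank (%d) exceeds min(n_samples, n_taxa)", latent_rank)
  }
  if (is.null(n_da_taxa)) {
    n_da_taxa <- if (n_groups > 1L) ceiling(n_taxa / 4) else 0L
  }
  structure(list(n_samples = as.integer(n_samples),
                 n_taxa = as.integer(n_taxa),
                 latent_rank = as.integer(latent_rank),
                 zero_inflation = zero_inflation,
                 dispersion = dispersion,
                 mean_log_abundance = mean_log_abundance,
                 n_groups = as.integer(n_groups),
                 effect_size = effect_size,
                 n_da_taxa = as.integer(n_da_taxa),
                 seed = as.integer(seed)),
            class = "synthetic_spec")
}

#' Draw a zero-inflated low-rank count matrix
#'
#' Log-means are `mean_log_abundance + (U V') / sqrt(latent_rank)` with
#' standard-normal factors U (n x r) and V (m x r); counts are negative
#' binomial with those means; entries are then zeroed independently with
#' probability `zero_inflation`. Sample group labels (when `n_groups > 1`)
#' are attached as the `group` attribute and the spiked taxa as `da_taxa`.
#'
#' @param spec A [synthetic_spec()].
#' @return A samples-x-taxa count matrix.
#' @export
synthesize_count_matrix <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  n <- spec$n_samples
  m <- spec$n_taxa
  r <- spec$latent_rank
  with_seed(spec$seed, {
    U <- matrix(stats::rnorm(n * r), n, r)
    V <- matrix(stats::rnorm(m * r), m, r)
    logmu <- spec$mean_log_abundance + tcrossprod(U, V) / sqrt(r)
    group <- rep(seq_len(spec$n_groups), length.out = n)
    da_taxa <- integer(0)
    if (spec$n_groups > 1L && spec$n_da_taxa > 0L) {
      da_taxa <- seq_len(min(spec$n_da_taxa, m))
      shift <- outer(group - 1L, rep(spec$effect_size, length(da_taxa)))
      logmu[, da_taxa] <- logmu[, da_taxa] + shift
    }
    mu <- exp(logmu)
    counts <- matrix(stats::rnbinom(n * m, mu = mu, size = 1 / spec$dispersion), n, m)
    if (spec$zero_inflation > 0) {
      drop <- matrix(stats::runif(n * m) < spec$zero_inflation, n, m)
      counts[drop] <- 0L
    }
    out <- count_matrix(counts * 1.0,
                        sample_ids = paste0("S", seq_len(n)),
                        taxon_ids = paste0("T", seq_len(m)))
    attr(out, "group") <- group
    attr(out, "da_taxa") <- da_taxa
    out
  })
}

#' Extract a zero-free complete submatrix (extraction scheme)
#'
#' Selects the `ceiling(proportion * m)` taxa with the fewest zeros, then
#' keeps every sample in which all selected taxa are non-zero (the largest
#' such sample subset). The result contains no zeros by construction and
#' serves as "complete" ground truth for corruption experiments.
#'
#' @param matrix Count matrix.
#' @param proportion Fraction of taxa to extract, in (0, 1].
#' @return A zero-free count submatrix.
#' @export
make_complete_scheme1 <- function(matrix, proportion) {
  validate_count_matrix(matrix)
  stopifnot(proportion > 0, proportion <= 1)
  m <- ncol(matrix)
  n_keep <- ceiling(proportion * m)
  zero_per_taxon <- colSums(matrix == 0)
  taxa <- order(zero_per_taxon, seq_len(m))[seq_len(n_keep)]
  taxa <- sort(taxa)
  rows <- which(rowSums(matrix[, taxa, drop = FALSE] == 0) == 0)
  if (length(rows) < 2L || length(taxa) < 2L) {
    abort("no zero-free submatrix of at least 2 x 2 exists at proportion %g (%d samples x %d taxa found)",
          proportion, length(rows), length(taxa))
  }
  matrix[rows, taxa, drop = FALSE]
}

#' Extraction followed by multinomial resampling (sampling scheme)
#'
#' Applies [make_complete_scheme1()], then resamples each retained sample
#' multinomially at the given depth from its relative abundances, so every
#' row sums exactly to `depth`. Note the resampling can introduce sampling
#' zeros at low depth.
#'
#' @param matrix Count matrix.
#' @param proportion Fraction of taxa to extract.
#' @param depth Reads per sample after resampling.
#' @param seed RNG seed.
#' @return A count matrix whose rows each sum to `depth`.
#' @export
make_complete_scheme2 <- function(matrix, proportion, depth, seed = 1L) {
  extracted <- make_complete_scheme1(matrix, proportion)
  downsample_depth(extracted, depth, seed)
}

#' Inject dropout zeros into a matrix
#'
#' Picks `floor(rate * #nonzero)` non-zero coordinates uniformly without
#' replacement and sets them to zero, recording the mask — the ground-truth
#' construction used for recovery scoring.
#'
#' @param complete Count matrix with at least one non-zero entry.
#' @param rate Fraction of non-zero entries to remove, in [0, 1).
#' @param seed RNG seed.
#' @return A `corruption_experiment`: list with `complete`, `corrupted`,
#'   `injected_mask`, `rate`, `seed` and `kind = "dropout"`.
#' @export
inject_dropout <- function(complete, rate, seed = 1L) {
  validate_count_matrix(complete)
  if (rate < 0 || rate >= 1) abort("rate must lie in [0, 1)")
  nz <- which(complete > 0)
  if (!length(nz)) abort("matrix has no non-zero entries to remove")
  n_drop <- floor(rate * length(nz))
  with_seed(seed, {
    chosen <- if (n_drop > 0) sort(nz[sample.int(length(nz), n_drop)]) else integer(0)
    corrupted <- complete
    corrupted[chosen] <- 0
    ij <- arrayInd(chosen, dim(complete))
    structure(list(complete = complete, corrupted = corrupted,
                   injected_mask = matrix_mask(ij[, 1], ij[, 2], dim(complete)),
                   rate = rate, seed = as.integer(seed), kind = "dropout"),
              class = "corruption_experiment")
  })
}

#' Undo a dropout corruption from its mask
#'
#' @param experiment A dropout `corruption_experiment`.
#' @return The complete matrix, reconstructed from `corrupted` plus the
#'   masked values of `complete`.
#' @export
restore_from_mask <- function(experiment) {
  stopifnot(inherits(experiment, "corruption_experiment"))
  if (experiment$kind != "dropout") abort("only dropout corruptions are restorable")
  out <- experiment$corrupted
  idx <- mask_linear_index(experiment$injected_mask)
  out[idx] <- experiment$complete[idx]
  out
}

#' Multinomial downsampling to a fixed sequencing depth
#'
#' Resamples each sample's counts multinomially at `depth` reads from its
#' relative abundances; every output row sums exactly to `depth`. Lower
#' depths produce more sampling zeros.
#'
#' @param matrix Count matrix (every row sum positive).
#' @param depth Reads per sample.
#' @param seed RNG seed.
#' @return A count matrix of the same shape.
#' @export
downsample_depth <- function(matrix, depth, seed = 1L) {
  validate_count_matrix(matrix)
  stopifnot(depth >= 1)
  if (any(rowSums(matrix) == 0)) abort("every row sum must be positive")
  with_seed(seed, {
    out <- t(apply(matrix, 1L, function(row) {
      stats::rmultinom(1L, size = depth, prob = row / sum(row))[, 1L]
    }))
    dimnames(out) <- dimnames(matrix)
    out * 1.0
  })
}

#' Depth-downsampling corruption experiment
#'
#' Downsamples to `depth` and records as the mask the coordinates that were
#' non-zero in the input but became sampling zeros. Unlike dropout, entries
#' outside the mask also change (all counts are resampled), so this kind is
#' evaluated against the complete matrix on the mask only.
#'
#' @inheritParams downsample_depth
#' @return A `corruption_experiment` with `kind = "depth"`.
#' @export
depth_experiment <- function(matrix, depth, seed = 1L) {
  corrupted <- downsample_depth(matrix, depth, seed)
  mask <- mask_from_logical(matrix > 0 & corrupted == 0)
  structure(list(complete = matrix, corrupted = corrupted,
                 injected_mask = mask, rate = NA_real_, depth = depth,
                 seed = as.integer(seed), kind = "depth"),
            class = "corruption_experiment")
}

#' Turn one sample into an outlier
#'
#' Eligible taxa are those with mean abundance below the across-taxa median
#' of means and at least 10 non-zero entries. The chosen taxa (all eligible
#' ones under `"auto"`) get a value drawn uniformly from that taxon's top-100
#' observed abundances (or all its non-zero values when fewer than 100
#' exist); every other taxon in the target sample is set to zero.
#'
#' @param matrix Count matrix.
#' @param sample_index Row to transform.
#' @param n_outlier_taxa Number of eligible taxa to use, or `"auto"` for all.
#' @param seed RNG seed.
#' @return The matrix with the target row replaced.
#' @export
make_outlier <- function(matrix, sample_index, n_outlier_taxa = "auto", seed = 1L) {
  validate_count_matrix(matrix)
  stopifnot(sample_index >= 1, sample_index <= nrow(matrix))
  eligible <- which(colMeans(matrix) < stats::median(colMeans(matrix)) &
                      colSums(matrix > 0) >= 10L)
  if (identical(n_outlier_taxa, "auto")) {
    n_outlier_taxa <- length(eligible)
    if (!n_outlier_taxa) abort("no eligible low-abundance taxa")
  }
  n_outlier_taxa <- as.integer(n_outlier_taxa)
  if (length(eligible) < n_outlier_taxa) {
    abort("only %d eligible taxa but %d requested", length(eligible), n_outlier_taxa)
  }
  with_seed(seed, {
    chosen <- sort(eligible[sample.int(length(eligible), n_outlier_taxa)])
    new_row <- numeric(ncol(matrix))
    for (j in chosen) {
      vals <- matrix[, j]
      vals <- vals[vals > 0]
      pool <- sort(vals, decreasing = TRUE)[seq_len(min(100L, length(vals)))]
      new_row[j] <- pool[sample.int(length(pool), 1L)]
    }
    matrix[sample_index, ] <- new_row
    matrix
  })
}

#' @export
print.corruption_experiment <- function(x, ...) {
  cat(sprintf("corruption_experiment (%s): %d x %d, %d masked entries%s\n",
              x$kind, nrow(x$complete), ncol(x$complete), nrow(x$injected_mask),
              if (x$kind == "dropout") sprintf(", rate %g", x$rate)
              else sprintf(", depth %d", x$depth)))
  invisible(x)
}
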