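#' Mean squared error over a mask
#'
#' Mean of `(a - b)^2` over the mask coordinates (or all entries with
#' `mask = "all"`). Symmetric in its two arguments.
#'
#' @param a,b Numeric matrices of equal shape.
#' @param mask A [matrix_mask()] or `"all"`.
#' @return Non-negative scalar.
#' @export
masked_mse <- function(a, b, mask = "all") {
  stopifnot(is.matrix(a), is.matrix(b))
  if (!all(dim(a) == dim(b))) abort("matrices differ in shape")
  if (identical(mask, "all")) return(mean((a - b)^2))
  stopifnot(inherits(mask, "matrix_mask"))
  if (!nrow(mask)) abort("mask is empty")
  if (!all(attr(mask, "shape") == dim(a))) abort("mask shape does not match the matrices")
  idx <- mask_linear_index(mask)
  mean((a[idx] - b[idx])^2)
}

#' Column-wise (per-taxon) correlation between two matrices
#'
#' Correlates each taxon's values across samples between the two matrices.
#' Columns that are constant in either matrix have undefined correlation;
#' they are flagged NA, excluded from the mean, and counted.
#'
#' @param a,b Numeric matrices of equal shape (samples x taxa), n >= 3.
#' @param method `"pearson"` or `"spearman"`.
#' @return List with `per_taxon` (length-m vector, NA where undefined),
#'   `mean` (unweighted mean over defined columns) and `n_excluded`.
#' @export
per_taxon_correlation <- function(a, b, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  stopifnot(is.matrix(a), is.matrix(b))
  if (!all(dim(a) == dim(b))) abort("matrices differ in shape")
  if (nrow(a) < 3L) abort("need at least 3 samples for a meaningful correlation")
  m <- ncol(a)
  per <- vapply(seq_len(m), function(j) {
    x <- a[, j]
    y <- b[, j]
    if (stats::sd(x) == 0 || stats::sd(y) == 0) return(NA_real_)
    stats::cor(x, y, method = method)
  }, numeric(1))
  names(per) <- colnames(a)
  list(per_taxon = per,
       mean = mean(per, na.rm = TRUE),
       n_excluded = sum(is.na(per)))
}

#' Fraction of injected zeros restored to non-zero
#'
#' @param result An `mbsparse_result`.
#' @param mask The injected-zero mask; must be a subset of the input zeros.
#' @return Scalar in [0, 1].
#' @export
identification_rate <- function(result, mask) {
  stopifnot(inherits(result, "mbsparse_result"), inherits(mask, "matrix_mask"))
  if (!nrow(mask)) abort("mask is empty")
  if (!all(attr(mask, "shape") == dim(result$imputed_logged))) {
    abort("mask shape does not match the result")
  }
  idx <- mask_linear_index(mask)
  if (any(result$input_logged[idx] != 0)) {
    abort("mask contains coordinates that were not zero in the imputation input")
  }
  mean(result$imputed_logged[idx] > 0)
}

#' Standard major axis (SMA) regression
#'
#' Symmetric line fit used to compare taxon-taxon abundance relationships:
#' `slope = sign(r) * sd(y) / sd(x)`, `intercept = mean(y) - slope * mean(x)`,
#' with r the Pearson correlation. Unlike ordinary least squares the fit
#' treats x and y interchangeably (swapping them inverts the slope).
#'
#' @param x,y Numeric vectors of equal length >= 3, both non-constant.
#' @return List with `slope`, `intercept` and `pearson_r`.
#' @export
#' @examples
#' sma_fit(c(1, 2, 3), c(2, 4, 6)) # slope 2, intercept 0
sma_fit <- function(x, y) {
  stopifnot(is.numeric(x), is.numeric(y), length(x) == length(y))
  if (length(x) < 3L) abort("need at least 3 points")
  sx <- stats::sd(x)
  sy <- stats::sd(y)
  if (sx == 0 || sy == 0) abort("constant input: SMA slope is undefined")
  r <- stats::cor(x, y)
  s <- sign(r)
  if (s == 0) s <- 1
  slope <- s * sy / sx
  list(slope = slope, intercept = mean(y) - slope * mean(x), pearson_r = r)
}

#' Recovery report for a corruption experiment
#'
#' Scores an imputation of the corrupted matrix against the complete matrix:
#' masked MSE of the imputed and of the non-imputed (corrupted) baseline,
#' per-taxon Pearson and Spearman correlation for both, and the
#' identification rate of injected zeros. Comparisons default to the logged
#' scale. The result must derive from the experiment's corrupted matrix
#' (checked against the stored input).
#'
#' @param experiment A `corruption_experiment`.
#' @param result The `mbsparse_result` from imputing `experiment$corrupted`.
#' @param space `"logged"` (default) or `"normalized"`.
#' @param exclude_samples Sample indices whose mask coordinates are dropped
#'   from scoring (used when those rows were deliberately corrupted into
#'   outliers and carry no recoverable signal).
#' @return An `evaluation_report` list; see Details for fields.
#' @details Fields: `mse`, `baseline_mse` (masked coordinates only),
#'   `mse_all`, `baseline_mse_all` (whole matrix — the relevant comparison
#'   for depth downsampling, where every entry changes, not only the masked
#'   ones), `identification_rate`,
#'   `mean_pearson`, `baseline_mean_pearson`, `mean_spearman`,
#'   `baseline_mean_spearman`, `pearson_per_taxon`, `spearman_per_taxon`,
#'   `n_excluded_taxa`, `n_masked`, `space`.
#' @export
recovery_report <- function(experiment, result,
                            space = c("logged", "normalized"),
                            exclude_samples = integer(0)) {
  stopifnot(inherits(experiment, "corruption_experiment"),
            inherits(result, "mbsparse_result"))
  space <- match.arg(space)
  tm <- result$transform
  if (is.null(tm)) abort("result carries no transform; run it through run_mbsparse()")
  if (!all(dim(experiment$corrupted) == dim(result$input_logged))) {
    abort("experiment and result shapes differ")
  }
  corrupted_tm <- transform_counts(experiment$corrupted,
                                   target = tm$target_library_size,
                                   method = tm$method)
  if (max(abs(corrupted_tm$logged - result$input_logged)) > 1e-8) {
    abort("result was not produced from this experiment's corrupted matrix")
  }
  complete_tm <- transform_counts(experiment$complete,
                                  target = tm$target_library_size,
                                  method = tm$method)
  pick <- function(t) if (space == "logged") t$logged else t$normalized
  complete <- pick(complete_tm)
  corrupted <- pick(corrupted_tm)
  imputed <- if (space == "logged") result$imputed_logged else result$imputed_normalized

  mask <- experiment$injected_mask
  if (length(exclude_samples)) {
    keep <- !(unclass(mask)[, "sample"] %in% exclude_samples)
    if (!any(keep)) abort("all mask coordinates excluded")
    mask <- matrix_mask(unclass(mask)[keep, "sample"], unclass(mask)[keep, "taxon"],
                        attr(mask, "shape"))
  }

  pear <- per_taxon_correlation(imputed, complete, "pearson")
  pear0 <- per_taxon_correlation(corrupted, complete, "pearson")
  spear <- per_taxon_correlation(imputed, complete, "spearman")
  spear0 <- per_taxon_correlation(corrupted, complete, "spearman")

  structure(list(
    mse = masked_mse(imputed, complete, mask),
    baseline_mse = masked_mse(corrupted, complete, mask),
    mse_all = masked_mse(imputed, complete, "all"),
    baseline_mse_all = masked_mse(corrupted, complete, "all"),
    identification_rate = identification_rate(result, mask),
    mean_pearson = pear$mean,
    baseline_mean_pearson = pear0$mean,
    mean_spearman = spear$mean,
    baseline_mean_spearman = spear0$mean,
    pearson_per_taxon = pear$per_taxon,
    spearman_per_taxon = spear$per_taxon,
    n_excluded_taxa = pear$n_excluded,
    n_masked = nrow(mask),
    space = space
  ), class = "evaluation_report")
}

#' One-row tibble view of an evaluation report
#'
#' @param report An `evaluation_report`.
#' @return Tibble with the scalar report fields.
#' @export
report_to_tibble <- function(report) {
  stopifnot(inherits(report, "evaluation_report"))
  tibble::tibble(
    mse = report$mse,
    baseline_mse = report$baseline_mse,
    mse_all = report$mse_all,
    baseline_mse_all = report$baseline_mse_all,
    identification_rate = report$identification_rate,
    mean_pearson = report$mean_pearson,
    baseline_mean_pearson = report$baseline_mean_pearson,
    mean_spearman = report$mean_spearman,
    baseline_mean_spearman = report$baseline_mean_spearman,
    n_excluded_taxa = report$n_excluded_taxa,
    n_masked = report$n_masked,
    space = report$space
  )
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf(paste0(
    "evaluation_report (%s scale, %d masked entries):\n",
    "  masked MSE        %.4f (non-imputed %.4f)\n",
    "  identification    %.2f%%\n",
    "  mean Pearson      %.4f (non-imputed %.4f)\n",
    "  mean Spearman     %.4f (non-imputed %.4f; %d taxa excluded)\n"),
    x$space, x$n_masked, x$mse, x$baseline_mse,
    100 * x$identification_rate, x$mean_pearson, x$baseline_mean_pearson,
    x$mean_spearman, x$baseline_mean_spearman, x$n_excluded_taxa))
  invisible(x)
}
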