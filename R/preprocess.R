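#' Library-size (total-sum) normalization
#'
#' Rescales every sample (row) to a common total, by default 10^6, the
#' standard total-sum scaling used before log transformation:
#' `M'_ij = target * M_ij / sum_j' M_ij'`.
#'
#' @param matrix Samples-x-taxa count matrix.
#' @param target Positive target library size (default 1e6).
#' @return Matrix of the same shape whose rows each sum to `target`.
#' @export
#' @examples
#' normalize_library_size(count_matrix(rbind(c(1, 1, 2), c(5, 5, 10))))[1, ]
normalize_library_size <- function(matrix, target = 1e6) {
  stopifnot(is_count_like(matrix), target > 0)
  if (any(matrix < 0)) abort("negative entries cannot be normalized")
  rs <- rowSums(matrix)
  zero <- which(rs == 0)
  if (length(zero)) {
    abort("sample %d ('%s') has zero total count and cannot be normalized",
          zero[1L], rownames(matrix)[zero[1L]] %||% "?")
  }
  matrix * (target / rs)
}

#' Log10 transform of normalized counts
#'
#' `X_ij = log10(M'_ij + 1)`: zeros map to zeros and all outputs are
#' non-negative, so zero remains the missing-value sentinel after
#' transformation.
#'
#' @param normalized Non-negative matrix (normalized counts).
#' @return Matrix of `log10(x + 1)` values.
#' @export
log_transform <- function(normalized) {
  stopifnot(is.numeric(normalized))
  if (any(normalized < 0)) abort("log transform requires non-negative input")
  log10(normalized + 1)
}

#' Invert the log10 transform
#'
#' Returns `10^X - 1`, the algebraic inverse of [log_transform()], mapping
#' logged values back to the normalized-count scale.
#'
#' @param logged Non-negative matrix on the logged scale.
#' @return Matrix on the normalized-count scale.
#' @export
inverse_transform <- function(logged) {
  stopifnot(is.numeric(logged))
  if (any(logged < 0)) abort("inverse transform requires non-negative input")
  10^logged - 1
}

#' Full preprocessing: normalization plus log transform
#'
#' Produces the working representation used by all model stages: the
#' normalized matrix M' (rows summing to the target library size), the logged
#' matrix X = log10(M' + 1), and the mask of input zeros. With
#' `method = "none"` the input is passed through untouched (for matrices the
#' user has already normalized and transformed).
#'
#' @param matrix Samples-x-taxa count matrix.
#' @param target Target library size (default 1e6).
#' @param method `"log_tss"` (default) or `"none"`.
#' @return An object of class `mbsparse_transform`: list with elements
#'   `normalized`, `logged`, `target_library_size`, `zero_mask`, `method`.
#' @export
transform_counts <- function(matrix, target = 1e6,
                             method = c("log_tss", "none")) {
  method <- match.arg(method)
  validate_count_matrix(matrix)
  if (method == "log_tss") {
    normalized <- normalize_library_size(matrix, target)
    logged <- log_transform(normalized)
  } else {
    normalized <- matrix
    logged <- matrix
  }
  structure(
    list(normalized = normalized,
         logged = logged,
         target_library_size = target,
         zero_mask = mask_from_logical(matrix == 0),
         method = method),
    class = "mbsparse_transform"
  )
}

#' @export
print.mbsparse_transform <- function(x, ...) {
  cat(sprintf("mbsparse_transform: %d x %d, target library size %g, %d zeros (%.1f%%)\n",
              nrow(x$logged), ncol(x$logged), x$target_library_size,
              nrow(x$zero_mask), 100 * nrow(x$zero_mask) / length(x$logged)))
  invisible(x)
}
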