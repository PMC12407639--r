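#' Construct and validate a count matrix
#'
#' The package-wide data model is a plain numeric matrix with samples as rows
#' and taxa as columns; row names are sample identifiers and column names are
#' taxon identifiers. Entries are non-negative reals (relative abundances are
#' accepted, integer-ness is never assumed). Zeros are the missing-value
#' sentinel: there are no NA entries.
#'
#' @param values Numeric matrix, samples x taxa.
#' @param sample_ids Character vector of unique sample identifiers
#'   (default: existing row names, or S1..Sn).
#' @param taxon_ids Character vector of unique taxon identifiers
#'   (default: existing column names, or T1..Tm).
#' @return A validated numeric matrix with dimnames set.
#' @export
#' @examples
#' count_matrix(matrix(0:5, 2, 3))
count_matrix <- function(values, sample_ids = NULL, taxon_ids = NULL) {
  if (!is_count_like(values)) abort("`values` must be a numeric matrix")
  n <- nrow(values)
  m <- ncol(values)
  if (is.null(sample_ids)) {
    sample_ids <- rownames(values)
    if (is.null(sample_ids)) sample_ids <- paste0("S", seq_len(n))
  }
  if (is.null(taxon_ids)) {
    taxon_ids <- colnames(values)
    if (is.null(taxon_ids)) taxon_ids <- paste0("T", seq_len(m))
  }
  rownames(values) <- sample_ids
  colnames(values) <- taxon_ids
  validate_count_matrix(values)
  values
}

#' Validate the count-matrix invariants
#'
#' Checks non-negativity, absence of missing values, minimum size
#' (at least 2 samples and 2 taxa: the method needs neighbours and multiple
#' taxa) and uniqueness of labels. The offending coordinate is named on
#' failure.
#'
#' @param x Numeric matrix with dimnames.
#' @return Invisibly, `x`.
#' @export
validate_count_matrix <- function(x) {
  if (!is_count_like(x)) abort("count matrix must be a numeric matrix")
  if (nrow(x) < 2L || ncol(x) < 2L) {
    abort("count matrix must have at least 2 samples and 2 taxa (got %d x %d)",
          nrow(x), ncol(x))
  }
  bad <- which(!is.finite(x) | x < 0)
  if (length(bad)) {
    ij <- arrayInd(bad[1L], dim(x))
    abort("invalid entry at sample %d ('%s'), taxon %d ('%s'): %s",
          ij[1], rownames(x)[ij[1]] %||% "?", ij[2], colnames(x)[ij[2]] %||% "?",
          format(x[bad[1L]]))
  }
  if (anyDuplicated(rownames(x))) abort("duplicate sample identifiers")
  if (anyDuplicated(colnames(x))) abort("duplicate taxon identifiers")
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read a count matrix from delimited text or BIOM
#'
#' Delimited files must have one header row and one leading label column.
#' The delimiter is taken from the extension (.csv = comma, otherwise tab)
#' unless `delim` is given. BIOM files (.biom, JSON or HDF5 via the
#' biomformat package) store taxa as rows, so they are read with
#' `orientation = "taxa_as_rows"` by default.
#'
#' @param path File path.
#' @param orientation Whether on-disk rows are samples (`"samples_as_rows"`,
#'   the default for text) or taxa (`"taxa_as_rows"`). The returned matrix is
#'   always samples x taxa.
#' @param delim Field delimiter override for text files.
#' @return A samples-x-taxa count matrix (see [count_matrix()]).
#' @export
read_count_matrix <- function(path,
                              orientation = c("samples_as_rows", "taxa_as_rows"),
                              delim = NULL) {
  if (!file.exists(path)) abort("file not found: %s", path)
  is_biom <- grepl("\\.biom$", path, ignore.case = TRUE)
  if (is_biom && missing(orientation)) orientation <- "taxa_as_rows"
  orientation <- match.arg(orientation)
  if (is_biom) {
    if (!requireNamespace("biomformat", quietly = TRUE)) {
      abort("reading BIOM requires the biomformat package")
    }
    b <- biomformat::read_biom(path)
    vals <- as(biomformat::biom_data(b), "matrix")
  } else {
    if (is.null(delim)) delim <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
    df <- utils::read.table(path, header = TRUE, sep = delim, check.names = FALSE,
                            stringsAsFactors = FALSE, comment.char = "",
                            quote = "\"")
    if (ncol(df) < 2L) abort("expected a label column plus at least one data column in %s", path)
    labels <- as.character(df[[1L]])
    numcols <- df[-1L]
    nonnum <- !vapply(numcols, is.numeric, logical(1))
    if (any(nonnum)) {
      j <- which(nonnum)[1L]
      i <- which(is.na(suppressWarnings(as.numeric(numcols[[j]]))))[1L]
      abort("non-numeric cell at row %s, column '%s' in %s",
            if (is.na(i)) "?" else format(i), names(numcols)[j], path)
    }
    vals <- as.matrix(numcols)
    rownames(vals) <- labels
  }
  neg <- which(vals < 0)
  if (length(neg)) {
    ij <- arrayInd(neg[1L], dim(vals))
    abort("negative entry %s at row %d ('%s'), column %d ('%s') in %s",
          format(vals[neg[1L]]), ij[1], rownames(vals)[ij[1]] %||% "?",
          ij[2], colnames(vals)[ij[2]] %||% "?", path)
  }
  if (orientation == "taxa_as_rows") vals <- t(vals)
  if (anyDuplicated(rownames(vals))) abort("duplicate sample identifiers in %s", path)
  if (anyDuplicated(colnames(vals))) abort("duplicate taxon identifiers in %s", path)
  count_matrix(vals)
}

#' Write a count matrix as delimited text
#'
#' Writes rows = samples, first column = sample identifier, header = taxon
#' identifiers. A read-back with [read_count_matrix()] recovers the values to
#' within `10^-precision` and the labels exactly.
#'
#' @param matrix Samples-x-taxa count matrix.
#' @param path Output path; `.csv` selects comma, anything else tab.
#' @param precision Decimal places kept (default 6).
#' @export
write_count_matrix <- function(matrix, path, precision = 6L) {
  validate_count_matrix(matrix)
  delim <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  vals <- round(matrix, precision)
  df <- data.frame(sample_id = rownames(matrix), vals,
                   check.names = FALSE, stringsAsFactors = FALSE)
  ok <- tryCatch({
    utils::write.table(df, path, sep = delim, row.names = FALSE,
                       col.names = TRUE, quote = FALSE)
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok)) abort("failed to write %s: %s", path, conditionMessage(ok))
  invisible(path)
}

#' Build a matrix mask from coordinates
#'
#' A mask is a two-column integer matrix of (sample, taxon) coordinates
#' (1-based, R convention) with the host matrix shape kept as an attribute.
#' Masks record which entries a corruption protocol set to zero and which
#' entries an imputation filled.
#'
#' @param sample,taxon Equal-length integer vectors of coordinates.
#' @param shape Integer vector c(n, m) of the host matrix.
#' @return A `matrix_mask` object.
#' @export
matrix_mask <- function(sample, taxon, shape) {
  sample <- as.integer(sample)
  taxon <- as.integer(taxon)
  if (length(sample) != length(taxon)) abort("coordinate vectors differ in length")
  shape <- as.integer(shape)
  if (length(shape) != 2L) abort("`shape` must be c(n, m)")
  if (length(sample) && (min(sample) < 1L || max(sample) > shape[1] ||
                         min(taxon) < 1L || max(taxon) > shape[2])) {
    abort("mask coordinate outside the %d x %d shape", shape[1], shape[2])
  }
  if (anyDuplicated(cbind(sample, taxon))) abort("duplicate mask coordinates")
  # canonical column-major order so equal coordinate sets compare identical
  ord <- order(taxon, sample)
  sample <- sample[ord]
  taxon <- taxon[ord]
  structure(cbind(sample = sample, taxon = taxon),
            shape = shape, class = c("matrix_mask", "matrix", "array"))
}

#' @rdname matrix_mask
#' @param x Logical matrix; TRUE entries become mask coordinates.
#' @export
mask_from_logical <- function(x) {
  idx <- which(x, arr.ind = TRUE)
  matrix_mask(idx[, 1L], idx[, 2L], dim(x))
}

#' @rdname matrix_mask
#' @param mask A `matrix_mask`.
#' @export
mask_to_logical <- function(mask) {
  shape <- attr(mask, "shape")
  out <- matrix(FALSE, shape[1], shape[2])
  if (nrow(mask)) out[unclass(mask)[, 1:2, drop = FALSE]] <- TRUE
  out
}

# linear (column-major) indices of mask coordinates in its host matrix
mask_linear_index <- function(mask) {
  shape <- attr(mask, "shape")
  unclass(mask)[, 1L] + (unclass(mask)[, 2L] - 1L) * shape[1L]
}

#' @export
print.matrix_mask <- function(x, ...) {
  shape <- attr(x, "shape")
  cat(sprintf("matrix_mask: %d coordinates in a %d x %d matrix\n",
              nrow(x), shape[1], shape[2]))
  invisible(x)
}

# TRUE when two masks share no coordinate
masks_disjoint <- function(a, b) {
  !any(mask_linear_index(a) %in% mask_linear_index(b))
}
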