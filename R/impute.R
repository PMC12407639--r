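#' Pipeline configuration
#'
#' Bundles every stage's knobs. Stage seeds are derived deterministically
#' from the global `seed` and the stage name via [derive_seed()], so the full
#' run is reproducible and stages have independent random streams.
#'
#' @param k Neighbours per sample in the KNN graph (default 5).
#' @param seed Global seed.
#' @param variant `"full"` (feature autoencoder + CVAE), `"no_fae"` (KNN on
#'   the raw logged rows), `"no_cvae"` (zero filling from real neighbours
#'   only) or `"neither"` (both substitutions) — the three ablation modes.
#' @param target_library_size Normalization target (default 1e6).
#' @param normalize_method `"log_tss"` or `"none"` (see [transform_counts()]).
#' @param fae A [fae_config()] (its seed is overridden by the derived seed).
#' @param cvae A [cvae_config()] (likewise).
#' @return A list of class `mbsparse_config`.
#' @export
mbsparse_config <- function(k = 5L, seed = 1L,
                            variant = c("full", "no_fae", "no_cvae", "neither"),
                            target_library_size = 1e6,
                            normalize_method = c("log_tss", "none"),
                            fae = fae_config(),
                            cvae = cvae_config()) {
  variant <- match.arg(variant)
  normalize_method <- match.arg(normalize_method)
  structure(list(k = as.integer(k), seed = as.integer(seed), variant = variant,
                 target_library_size = target_library_size,
                 normalize_method = normalize_method,
                 fae = fae, cvae = cvae),
            class = "mbsparse_config")
}

#' Fill zeros from real and conditional neighbours
#'
#' For every zero entry `X[i, j]` the imputed value is the average of that
#' taxon over sample i's k graph neighbours and their conditional samples:
#' `(1 / 2K) * sum_{k in N_i} (X[k, j] + X_cond[k, j])`. With
#' `X_cond = NULL` (the no-CVAE ablation) the rule degenerates to the plain
#' neighbour mean `(1 / K) * sum X[k, j]`. Non-zero entries are returned
#' bit-exact; a zero whose neighbours are all zero stays zero, which is how
#' putative biological zeros are left alone.
#'
#' @param X Logged matrix (samples x taxa).
#' @param graph [build_knn_graph()] result on the same samples.
#' @param X_cond Conditional matrix X^c of the same shape, or NULL.
#' @param transform Optional `mbsparse_transform` providing the
#'   normalized-scale view of the output.
#' @return An object of class `mbsparse_result`: list with `imputed_logged`,
#'   `imputed_normalized` (via [inverse_transform()]), `filled_mask`
#'   (injected non-zeros), `input_logged`, `graph`, plus `config_snapshot`
#'   and `seed` when run through [run_mbsparse()].
#' @export
#' @examples
#' X <- rbind(c(0, 4), c(4, 2), c(2, 2))
#' g <- build_knn_graph(matrix(c(0, 1, 2), 3, 1), k = 1)
#' fill_zeros(X, g)$imputed_logged[1, 1] # neighbour mean
fill_zeros <- function(X, graph, X_cond = NULL, transform = NULL) {
  stopifnot(is.matrix(X), inherits(graph, "sample_graph"))
  if (graph$n != nrow(X)) abort("graph has %d nodes but X has %d rows", graph$n, nrow(X))
  if (!is.null(X_cond)) {
    if (!all(dim(X_cond) == dim(X))) abort("X_cond must match X in shape")
    if (any(X_cond < 0)) abort("conditional samples must be non-negative")
  }
  K <- graph$k
  if (K < 1L) abort("every node needs at least one neighbour")
  A <- graph$adjacency
  fill <- if (is.null(X_cond)) {
    (A %*% X) / K
  } else {
    (A %*% (X + X_cond)) / (2 * K)
  }
  zeros <- X == 0
  imputed <- X
  imputed[zeros] <- fill[zeros]
  filled <- mask_from_logical(zeros & imputed > 0)
  structure(list(
    imputed_logged = imputed,
    imputed_normalized = inverse_transform(imputed),
    filled_mask = filled,
    input_logged = X,
    graph = graph,
    config_snapshot = NULL,
    seed = NULL
  ), class = "mbsparse_result")
}

#' Run the full imputation pipeline
#'
#' Executes normalize -> log -> feature autoencoder -> embeddings -> KNN
#' graph -> training pairs -> CVAE -> conditional samples -> zero filling.
#' The `no_fae` variant builds the graph directly on the logged rows; the
#' `no_cvae` variant fills from real neighbours only; `neither` does both.
#' Imputation is attempted at every zero (no pre-classification of
#' biological versus non-biological zeros) and non-zero entries pass through
#' bit-exact on the logged scale. Output rows are not re-normalized after
#' filling.
#'
#' @param matrix Samples-x-taxa count matrix (every row sum positive).
#' @param config A [mbsparse_config()].
#' @param verbose Print per-stage summaries (default FALSE).
#' @return An `mbsparse_result` (see [fill_zeros()]) with `config_snapshot`,
#'   `seed`, `transform`, and the trained `fae`/`cvae` models attached.
#' @export
run_mbsparse <- function(matrix, config = mbsparse_config(), verbose = FALSE) {
  stopifnot(inherits(config, "mbsparse_config"))
  validate_count_matrix(matrix)
  say <- function(fmt, ...) if (verbose) message(sprintf(fmt, ...))

  tm <- transform_counts(matrix, target = config$target_library_size,
                         method = config$normalize_method)
  X <- tm$logged
  say("preprocess: %d x %d, %.1f%% zeros", nrow(X), ncol(X),
      100 * nrow(tm$zero_mask) / length(X))

  use_fae <- config$variant %in% c("full", "no_cvae")
  use_cvae <- config$variant %in% c("full", "no_fae")

  fae_model <- NULL
  if (use_fae) {
    fc <- config$fae
    fc$seed <- derive_seed(config$seed, "fae")
    fae_model <- tryCatch(train_fae(X, fc),
                          error = function(e) abort("stage fae: %s", conditionMessage(e)))
    Z <- embed_samples(fae_model, X)
    say("fae: final reconstruction MSE %.4g", fae_model$loss_trace[fc$epochs])
  } else {
    Z <- X
  }

  graph <- tryCatch(build_knn_graph(Z, config$k),
                    error = function(e) abort("stage graph: %s", conditionMessage(e)))
  say("graph: %d nodes, k = %d", graph$n, graph$k)

  cvae_model <- NULL
  X_cond <- NULL
  if (use_cvae) {
    pairs <- make_training_pairs(graph)
    cc <- config$cvae
    cc$seed <- derive_seed(config$seed, "cvae")
    cvae_model <- tryCatch(train_cvae(X, pairs, cc),
                           error = function(e) abort("stage cvae: %s", conditionMessage(e)))
    X_cond <- generate_conditional_samples(cvae_model, X,
                                           seed = derive_seed(config$seed, "generate"))
    say("cvae: final mean ELBO %.4g", cvae_model$elbo_trace[cc$epochs])
  }

  result <- fill_zeros(X, graph, X_cond, transform = tm)
  result$config_snapshot <- config
  result$seed <- config$seed
  result$transform <- tm
  result$fae <- fae_model
  result$cvae <- cvae_model
  say("impute: filled %d of %d zeros", nrow(result$filled_mask), nrow(tm$zero_mask))
  result
}

#' @export
print.mbsparse_result <- function(x, ...) {
  nz <- sum(x$input_logged == 0)
  cat(sprintf("mbsparse_result: %d x %d; %d of %d zeros filled (%.1f%%)\n",
              nrow(x$imputed_logged), ncol(x$imputed_logged),
              nrow(x$filled_mask), nz,
              if (nz) 100 * nrow(x$filled_mask) / nz else 0))
  if (!is.null(x$config_snapshot)) {
    cat(sprintf("  variant: %s, k = %d, seed = %d\n",
                x$config_snapshot$variant, x$config_snapshot$k, x$seed))
  }
  invisible(x)
}
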