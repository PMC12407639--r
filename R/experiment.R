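#' Dropout-recovery benchmark over replicate seeds
#'
#' For each seed: draw a synthetic matrix, inject dropout zeros, impute the
#' corrupted matrix, and score recovery against the complete matrix. Stage
#' seeds are derived from the replicate seed with [derive_seed()], so
#' replicates are independent and each is fully reproducible. Optionally a
#' number of samples are corrupted into outliers after dropout; their mask
#' coordinates are excluded from scoring.
#'
#' @param spec A [synthetic_spec()] (its own seed is overridden per replicate).
#' @param rate Dropout rate over non-zero entries (default 0.2).
#' @param config A [mbsparse_config()] (seed overridden per replicate).
#' @param seeds Integer vector of replicate seeds.
#' @param n_outliers Number of outlier samples to inject (default 0).
#' @param space Evaluation scale, `"logged"` (default) or `"normalized"`.
#' @return Tibble with one row per replicate: the scalar fields of
#'   [recovery_report()] plus `seed` and `variant`.
#' @export
benchmark_recovery <- function(spec = synthetic_spec(), rate = 0.2,
                               config = mbsparse_config(), seeds = 1:10,
                               n_outliers = 0L, space = "logged") {
  rows <- lapply(seeds, function(s) {
    spec$seed <- derive_seed(s, "simulate")
    complete <- synthesize_count_matrix(spec)
    exper <- inject_dropout(complete, rate, seed = derive_seed(s, "dropout"))
    excl <- integer(0)
    if (n_outliers > 0L) {
      out_rows <- with_seed(derive_seed(s, "outlier_rows"),
                            sample.int(nrow(complete), n_outliers))
      for (i in seq_along(out_rows)) {
        exper$corrupted <- make_outlier(exper$corrupted, out_rows[i],
                                        seed = derive_seed(s, "outlier", i))
      }
      excl <- out_rows
    }
    config$seed <- derive_seed(s, "impute")
    result <- run_mbsparse(exper$corrupted, config)
    rep <- recovery_report(exper, result, space = space, exclude_samples = excl)
    cbind(tibble::tibble(seed = s, variant = config$variant),
          report_to_tibble(rep))
  })
  do.call(rbind, rows)
}

#' Depth-robustness benchmark
#'
#' For each (depth, seed): draw a dense (zero-inflation-free) synthetic
#' matrix, downsample it multinomially to the depth, impute, and score
#' against the original on the coordinates turned into sampling zeros.
#'
#' @param spec A [synthetic_spec()]; its `zero_inflation` is forced to 0 so
#'   the pre-downsampling matrix is dense.
#' @param depths Integer vector of sequencing depths.
#' @param config A [mbsparse_config()].
#' @param seeds Integer vector of replicate seeds.
#' @return Tibble with one row per (depth, seed).
#' @export
benchmark_depth <- function(spec = synthetic_spec(), depths = c(1000L, 2000L, 5000L, 10000L),
                            config = mbsparse_config(), seeds = 1:10) {
  spec$zero_inflation <- 0
  rows <- list()
  for (depth in depths) {
    for (s in seeds) {
      spec$seed <- derive_seed(s, "simulate")
      complete <- synthesize_count_matrix(spec)
      exper <- depth_experiment(complete, depth, seed = derive_seed(s, "depth"))
      config$seed <- derive_seed(s, "impute")
      result <- run_mbsparse(exper$corrupted, config)
      rep <- recovery_report(exper, result, space = "logged")
      rows[[length(rows) + 1L]] <-
        cbind(tibble::tibble(depth = depth, seed = s), report_to_tibble(rep))
    }
  }
  do.call(rbind, rows)
}

#' Run a replicated experiment and write its artifacts
#'
#' Executes the dropout-recovery protocol for `replicates` replicates with
#' seeds derived from the global seed, writes one TSV report per replicate,
#' a mean +/- standard deviation summary TSV, and a JSON snapshot of the
#' configuration, into `output_dir`. Reruns with an identical configuration
#' reproduce the artifacts byte for byte.
#'
#' @param spec A [synthetic_spec()].
#' @param config A [mbsparse_config()].
#' @param output_dir Directory to create/populate.
#' @param replicates Number of replicates (default 10).
#' @param rate Dropout rate (default 0.2).
#' @param seed Global seed; replicate r uses `derive_seed(seed, "replicate", r)`.
#' @param space Evaluation scale.
#' @return Invisibly, a list with `replicates` (tibble) and `summary` (tibble).
#' @export
run_experiment <- function(spec = synthetic_spec(), config = mbsparse_config(),
                           output_dir, replicates = 10L, rate = 0.2,
                           seed = 1L, space = "logged") {
  stopifnot(replicates >= 1)
  dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
  rep_seeds <- vapply(seq_len(replicates), function(r) derive_seed(seed, "replicate", r),
                      integer(1))
  tbl <- benchmark_recovery(spec, rate = rate, config = config,
                            seeds = rep_seeds, space = space)
  tbl$replicate <- seq_len(replicates)
  for (r in seq_len(replicates)) {
    utils::write.table(tbl[tbl$replicate == r, , drop = FALSE],
                       file.path(output_dir, sprintf("replicate_%03d.tsv", r)),
                       sep = "\t", row.names = FALSE, quote = FALSE)
  }
  num <- vapply(tbl, is.numeric, logical(1)) & !(names(tbl) %in% c("seed", "replicate"))
  summary_tbl <- tibble::tibble(
    metric = names(tbl)[num],
    mean = vapply(tbl[num], mean, numeric(1)),
    sd = vapply(tbl[num], stats::sd, numeric(1))
  )
  utils::write.table(summary_tbl, file.path(output_dir, "summary.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  snapshot <- list(spec = unclass(spec), config = config_to_list(config),
                   replicates = replicates, rate = rate, seed = seed,
                   space = space)
  jsonlite::write_json(snapshot, file.path(output_dir, "config.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(list(replicates = tbl, summary = summary_tbl))
}

# plain-list view of a pipeline config for serialization
config_to_list <- function(config) {
  out <- unclass(config)
  out$fae <- unclass(out$fae)
  out$cvae <- unclass(out$cvae)
  out
}
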