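#' Evaluate code with a temporary RNG seed
#'
#' Runs `code` with the global RNG seeded to `seed` and restores the previous
#' RNG state afterwards, so seeded operations do not perturb the caller's
#' random stream.
#'
#' @param seed Integer seed.
#' @param code Expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' Derive a stage-specific seed from a global seed
#'
#' Deterministic 31-bit hash (djb2 over the stage name folded with the global
#' seed and replicate index) so every stochastic stage gets an independent,
#' reproducible stream and adding stages never perturbs existing ones.
#'
#' @param seed Integer global seed.
#' @param stage Character stage name (e.g. "fae", "cvae", "simulate").
#' @param replicate Integer replicate index (default 1).
#' @return A positive integer seed below 2^31.
#' @export
#' @examples
#' derive_seed(1, "fae")
#' derive_seed(1, "fae", replicate = 2)
derive_seed <- function(seed, stage, replicate = 1L) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(stage))
  mod <- 2147483647
  h <- 5381
  bytes <- c(
    utf8ToInt(stage),
    abs(as.numeric(seed)) %% 256,
    (abs(as.numeric(seed)) %/% 256) %% 256,
    (abs(as.numeric(seed)) %/% 65536) %% 256,
    abs(as.numeric(replicate)) %% 65536
  )
  for (b in bytes) h <- (h * 33 + b) %% mod
  as.integer(max(1, h))
}

# stop() with a call-free, sprintf-style message
abort <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

is_count_like <- function(x) {
  is.matrix(x) && is.numeric(x)
}
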