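#' Feature autoencoder configuration
#'
#' The feature autoencoder maps each logged taxonomic profile (length m)
#' through a two-layer dense encoder m -> hidden_dim -> embedding_dim and a
#' mirrored decoder embedding_dim -> hidden_dim -> m. The inner widths
#' default to 512 and 128; the outer widths adapt to the number of taxa.
#' Hidden layers use ReLU; the embedding layer uses ReLU (embeddings are
#' non-negative) and the reconstruction layer uses softplus (reconstructions
#' are non-negative, matching the logged input scale).
#'
#' @param hidden_dim Width of the hidden layers (default 512).
#' @param embedding_dim Embedding size d (default 128); must be below the
#'   number of taxa and at most `hidden_dim`.
#' @param epochs Training epochs (default 200).
#' @param learning_rate Adam learning rate (default 1e-3).
#' @param batch_size Mini-batch size; clamped to the sample count (default 64).
#' @param seed RNG seed controlling initialization and batch order.
#' @return A list of class `fae_config`.
#' @export
fae_config <- function(hidden_dim = 512L, embedding_dim = 128L,
                       epochs = 200L, learning_rate = 1e-3,
                       batch_size = 64L, seed = 1L) {
  stopifnot(hidden_dim >= 1, embedding_dim >= 1, epochs >= 1,
            learning_rate > 0, batch_size >= 1)
  if (hidden_dim < embedding_dim) {
    abort("hidden_dim (%d) must be at least embedding_dim (%d)",
          hidden_dim, embedding_dim)
  }
  structure(list(hidden_dim = as.integer(hidden_dim),
                 embedding_dim = as.integer(embedding_dim),
                 epochs = as.integer(epochs),
                 learning_rate = learning_rate,
                 batch_size = as.integer(batch_size),
                 seed = as.integer(seed)),
            class = "fae_config")
}

#' Train the feature autoencoder
#'
#' Minimizes the reconstruction mean squared error between the logged matrix
#' X and its reconstruction through the bottleneck. Training is full batch
#' gradient descent with Adam over shuffled mini-batches; with a fixed seed
#' two runs produce identical parameters and loss traces.
#'
#' @param X Logged matrix (samples x taxa), all entries finite and >= 0.
#' @param config A [fae_config()].
#' @return An object of class `fae_model` with elements `encoder`, `decoder`,
#'   `loss_trace` (per-epoch mean squared reconstruction error per entry),
#'   `config` and `m`.
#' @export
train_fae <- function(X, config = fae_config()) {
  stopifnot(is.matrix(X), is.numeric(X))
  if (!all(is.finite(X))) abort("X must be finite")
  n <- nrow(X)
  m <- ncol(X)
  if (n < 2L) abort("need at least 2 samples to train")
  if (config$embedding_dim >= m) {
    abort("embedding_dim (%d) must be smaller than the number of taxa (%d)",
          config$embedding_dim, m)
  }
  bs <- min(config$batch_size, n)
  with_seed(config$seed, {
    enc <- mlp_init(c(m, config$hidden_dim, config$embedding_dim),
                    c("relu", "relu"))
    dec <- mlp_init(c(config$embedding_dim, config$hidden_dim, m),
                    c("relu", "softplus"))
    enc_state <- adam_init(enc)
    dec_state <- adam_init(dec)
    trace <- numeric(config$epochs)
    t <- 0L
    for (epoch in seq_len(config$epochs)) {
      batches <- make_batches(n, bs)
      batch_loss <- numeric(length(batches))
      for (bi in seq_along(batches)) {
        idx <- batches[[bi]]
        Xb <- X[idx, , drop = FALSE]
        ef <- mlp_forward(enc, Xb)
        df <- mlp_forward(dec, ef$out)
        resid <- df$out - Xb
        loss <- mean(resid^2)
        if (!is.finite(loss)) abort("non-finite training loss at epoch %d", epoch)
        batch_loss[bi] <- loss
        dout <- 2 * resid / length(resid)
        db <- mlp_backward(dec, df$caches, dout)
        eb <- mlp_backward(enc, ef$caches, db$dinput)
        t <- t + 1L
        up <- adam_step(dec, db$grads, dec_state, config$learning_rate, t)
        dec <- up$net; dec_state <- up$state
        up <- adam_step(enc, eb$grads, enc_state, config$learning_rate, t)
        enc <- up$net; enc_state <- up$state
      }
      trace[epoch] <- mean(batch_loss)
    }
    structure(list(encoder = enc, decoder = dec, loss_trace = trace,
                   config = config, m = m),
              class = "fae_model")
  })
}

#' Extract per-sample embeddings
#'
#' Applies the trained encoder row-wise: each sample's embedding depends only
#' on its own profile, so duplicate rows receive identical embeddings and the
#' map is equivariant under sample permutation.
#'
#' @param model A trained [train_fae()] model.
#' @param X Logged matrix with the same number of taxa the model was trained on.
#' @return Embedding matrix Z (samples x embedding_dim), non-negative.
#' @export
embed_samples <- function(model, X) {
  stopifnot(inherits(model, "fae_model"), is.matrix(X))
  if (ncol(X) != model$m) {
    abort("X has %d taxa but the model was trained on %d", ncol(X), model$m)
  }
  mlp_forward(model$encoder, X)$out
}

# decoder applied to embeddings (used in tests and diagnostics)
reconstruct_samples <- function(model, Z) {
  stopifnot(inherits(model, "fae_model"))
  mlp_forward(model$decoder, Z)$out
}

#' @export
print.fae_model <- function(x, ...) {
  cat(sprintf("fae_model: %d taxa -> %d -> %d embedding; %d epochs, final MSE %.4g\n",
              x$m, x$config$hidden_dim, x$config$embedding_dim,
              length(x$loss_trace), x$loss_trace[length(x$loss_trace)]))
  invisible(x)
}

#' Training trace as a tibble
#'
#' @param model A `fae_model` or `cvae_model`.
#' @return Tibble with columns `epoch` and `value` (`mse` for the feature
#'   autoencoder, `elbo` for the CVAE) plus a `metric` column.
#' @export
loss_trace <- function(model) {
  if (inherits(model, "fae_model")) {
    tibble::tibble(epoch = seq_along(model$loss_trace),
                   metric = "mse", value = model$loss_trace)
  } else if (inherits(model, "cvae_model")) {
    tibble::tibble(epoch = seq_along(model$elbo_trace),
                   metric = "elbo", value = model$elbo_trace)
  } else {
    abort("no training trace for objects of class '%s'", class(model)[1])
  }
}
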