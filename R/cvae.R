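#' Conditional VAE configuration
#'
#' The CVAE learns p(X_u | X_v) over directed graph edges: the recognition
#' network q(z | X_u, X_v) maps the concatenated target and condition
#' profiles through one hidden layer to a diagonal-Gaussian posterior; the
#' generative network concatenates a latent draw z with a learned linear
#' projection of the condition and decodes through one hidden layer back to a
#' non-negative profile. Inner widths default to 256 x 10 (encoder) and
#' 20 x 256 (decoder), i.e. latent_dim + condition_proj_dim = decoder input.
#'
#' @param latent_dim Latent dimension (default 10).
#' @param hidden_dim Hidden width of encoder and decoder (default 256).
#' @param condition_proj_dim Width of the linear condition projection
#'   (default 10).
#' @param epochs Training epochs (default 200).
#' @param learning_rate Adam learning rate (default 1e-3).
#' @param batch_size Mini-batch size over training pairs (default 64).
#' @param seed RNG seed for initialization, batch order and latent draws.
#' @param n_mc_samples Monte-Carlo draws per pair for the reconstruction term
#'   (default 1, the standard single-draw reparameterized estimator).
#' @return A list of class `cvae_config`.
#' @export
cvae_config <- function(latent_dim = 10L, hidden_dim = 256L,
                        condition_proj_dim = 10L, epochs = 200L,
                        learning_rate = 1e-3, batch_size = 64L,
                        seed = 1L, n_mc_samples = 1L) {
  stopifnot(latent_dim >= 1, hidden_dim >= 1, condition_proj_dim >= 1,
            epochs >= 1, learning_rate > 0, batch_size >= 1, n_mc_samples >= 1)
  structure(list(latent_dim = as.integer(latent_dim),
                 hidden_dim = as.integer(hidden_dim),
                 condition_proj_dim = as.integer(condition_proj_dim),
                 epochs = as.integer(epochs),
                 learning_rate = learning_rate,
                 batch_size = as.integer(batch_size),
                 seed = as.integer(seed),
                 n_mc_samples = as.integer(n_mc_samples)),
            class = "cvae_config")
}

#' Training pairs from the sample graph
#'
#' One (condition v, target u) pair per directed edge, u in N_v, so every
#' node contributes exactly k pairs and no pair is a self-loop.
#'
#' @param graph A [build_knn_graph()] result.
#' @return Integer matrix with columns `v` (condition) and `u` (target),
#'   n*k rows.
#' @export
make_training_pairs <- function(graph) {
  stopifnot(inherits(graph, "sample_graph"))
  cbind(v = rep(seq_len(graph$n), each = graph$k),
        u = unlist(graph$neighborhoods))
}

#' KL divergence of a diagonal Gaussian from the standard normal
#'
#' Closed form `0.5 * sum(exp(logvar) + mu^2 - 1 - logvar)` for
#' KL(N(mu, diag(exp(logvar))) || N(0, I)). Non-negative, zero iff mu = 0 and
#' logvar = 0. For matrix inputs the KL is computed row-wise.
#'
#' @param mu Mean vector (or matrix, rows = cases).
#' @param logvar Log-variance vector (or matrix) of the same shape.
#' @return Scalar (or vector of row-wise) KL divergence.
#' @export
#' @examples
#' kl_gaussian(c(2), c(0)) # == 2
kl_gaussian <- function(mu, logvar) {
  stopifnot(length(mu) == length(logvar))
  if (!all(is.finite(mu)) || !all(is.finite(logvar))) abort("inputs must be finite")
  term <- exp(logvar) + mu^2 - 1 - logvar
  if (is.matrix(mu)) 0.5 * rowSums(term) else 0.5 * sum(term)
}

# internal model assembly ---------------------------------------------------

cvae_new <- function(m, config) {
  structure(list(
    trunk = mlp_init(c(2L * m, config$hidden_dim), "relu"),
    mu_head = mlp_init(c(config$hidden_dim, config$latent_dim), "linear"),
    logvar_head = mlp_init(c(config$hidden_dim, config$latent_dim), "linear"),
    cond_proj = mlp_init(c(m, config$condition_proj_dim), "linear"),
    decoder = mlp_init(c(config$latent_dim + config$condition_proj_dim,
                         config$hidden_dim, m),
                       c("relu", "softplus")),
    config = config, m = m, elbo_trace = numeric(0)
  ), class = "cvae_model")
}

# recognition pass; Xu, Xv: batch x m
cvae_encode <- function(model, Xu, Xv) {
  tf <- mlp_forward(model$trunk, cbind(Xu, Xv))
  muf <- mlp_forward(model$mu_head, tf$out)
  lvf <- mlp_forward(model$logvar_head, tf$out)
  list(mu = muf$out, logvar = lvf$out, trunk = tf, mu_f = muf, logvar_f = lvf)
}

# generative pass; z: batch x latent, Xv: batch x m
cvae_decode_full <- function(model, z, Xv) {
  pf <- mlp_forward(model$cond_proj, Xv)
  df <- mlp_forward(model$decoder, cbind(z, pf$out))
  list(out = df$out, proj = pf, dec = df)
}

#' Decode latent draws under a condition
#'
#' @param model A trained `cvae_model`.
#' @param z Latent matrix (cases x latent_dim).
#' @param Xv Condition matrix (cases x m).
#' @return Non-negative decoded matrix (cases x m).
#' @export
cvae_decode <- function(model, z, Xv) {
  stopifnot(inherits(model, "cvae_model"))
  if (is.vector(z)) z <- matrix(z, nrow = 1L)
  if (is.vector(Xv)) Xv <- matrix(Xv, nrow = 1L)
  cvae_decode_full(model, z, Xv)$out
}

#' Evidence lower bound for (target, condition) pairs
#'
#' Computes `-KL(q(z | X_u, X_v) || N(0, I)) + (1/L) sum_l log p(X_u | X_v,
#' z_l)` with reparameterized draws `z_l = mu + sigma * e_l`, `e_l ~ N(0, I)`,
#' and a fixed-unit-variance Gaussian likelihood in logged space, so the
#' reconstruction term is `-0.5 * ||X_u - decode(z_l, X_v)||^2 -
#' (m/2) log(2 pi)`. Deterministic given `seed`.
#'
#' @param model A `cvae_model`.
#' @param X_u Target profile(s): vector of length m or matrix (pairs x m).
#' @param X_v Condition profile(s), same shape as `X_u`.
#' @param n_mc_samples Monte-Carlo draws L (default `model$config$n_mc_samples`).
#' @param seed RNG seed for the draws.
#' @return Mean ELBO over the supplied pairs (scalar).
#' @export
elbo <- function(model, X_u, X_v, n_mc_samples = model$config$n_mc_samples,
                 seed = 1L) {
  stopifnot(inherits(model, "cvae_model"))
  if (is.vector(X_u)) X_u <- matrix(X_u, nrow = 1L)
  if (is.vector(X_v)) X_v <- matrix(X_v, nrow = 1L)
  if (ncol(X_u) != model$m || ncol(X_v) != model$m || nrow(X_u) != nrow(X_v)) {
    abort("X_u and X_v must both be pairs x %d", model$m)
  }
  m <- model$m
  with_seed(seed, {
    enc <- cvae_encode(model, X_u, X_v)
    kl <- kl_gaussian(enc$mu, enc$logvar)
    sigma <- exp(0.5 * enc$logvar)
    recon <- 0
    for (l in seq_len(n_mc_samples)) {
      eps <- matrix(stats::rnorm(length(sigma)), nrow(sigma), ncol(sigma))
      z <- enc$mu + sigma * eps
      dec <- cvae_decode_full(model, z, X_v)$out
      logp <- -0.5 * rowSums((X_u - dec)^2) - (m / 2) * log(2 * pi)
      recon <- recon + logp / n_mc_samples
    }
    val <- mean(-kl + recon)
    if (!is.finite(val)) abort("non-finite ELBO")
    val
  })
}

#' Train the conditional VAE over graph edges
#'
#' Maximizes the ELBO with Adam over shuffled mini-batches of (condition,
#' target) pairs. The per-epoch mean ELBO is recorded; with a fixed seed two
#' runs produce identical parameters and traces.
#'
#' @param X Logged matrix (samples x taxa).
#' @param pairs [make_training_pairs()] output (columns v, u).
#' @param config A [cvae_config()].
#' @return A `cvae_model` with a populated `elbo_trace`.
#' @export
train_cvae <- function(X, pairs, config = cvae_config()) {
  stopifnot(is.matrix(X), is.numeric(X), is.matrix(pairs))
  if (!all(c("v", "u") %in% colnames(pairs))) abort("pairs must have columns v and u")
  if (max(pairs) > nrow(X) || min(pairs) < 1) abort("pair index outside X")
  n_pairs <- nrow(pairs)
  m <- ncol(X)
  L <- config$n_mc_samples
  bs <- min(config$batch_size, n_pairs)
  with_seed(config$seed, {
    model <- cvae_new(m, config)
    states <- lapply(model[c("trunk", "mu_head", "logvar_head",
                             "cond_proj", "decoder")], adam_init)
    trace <- numeric(config$epochs)
    t <- 0L
    for (epoch in seq_len(config$epochs)) {
      batches <- make_batches(n_pairs, bs)
      batch_elbo <- numeric(length(batches))
      for (bi in seq_along(batches)) {
        idx <- batches[[bi]]
        Xu <- X[pairs[idx, "u"], , drop = FALSE]
        Xv <- X[pairs[idx, "v"], , drop = FALSE]
        B <- nrow(Xu)

        enc <- cvae_encode(model, Xu, Xv)
        kl <- kl_gaussian(enc$mu, enc$logvar)
        sigma <- exp(0.5 * enc$logvar)

        dmu_kl <- enc$mu / B
        dlogvar_kl <- 0.5 * (exp(enc$logvar) - 1) / B
        dmu <- dmu_kl
        dlogvar <- dlogvar_kl
        dec_gacc <- NULL
        proj_gacc <- NULL
        recon <- numeric(B)
        for (l in seq_len(L)) {
          eps <- matrix(stats::rnorm(B * config$latent_dim), B, config$latent_dim)
          z <- enc$mu + sigma * eps
          fw <- cvae_decode_full(model, z, Xv)
          resid <- fw$out - Xu
          recon <- recon - 0.5 * rowSums(resid^2) / L
          # objective is -mean(ELBO); d(-ELBO)/d(out) = resid / (B * L)
          dout <- resid / (B * L)
          bk_dec <- mlp_backward(model$decoder, fw$dec$caches, dout)
          dz <- bk_dec$dinput[, seq_len(config$latent_dim), drop = FALSE]
          dproj <- bk_dec$dinput[, -seq_len(config$latent_dim), drop = FALSE]
          bk_proj <- mlp_backward(model$cond_proj, fw$proj$caches, dproj)
          dec_gacc <- acc_grads(dec_gacc, bk_dec$grads)
          proj_gacc <- acc_grads(proj_gacc, bk_proj$grads)
          dmu <- dmu + dz
          dlogvar <- dlogvar + dz * eps * 0.5 * sigma
        }
        recon <- recon - (m / 2) * log(2 * pi)
        mean_elbo <- mean(-kl + recon)
        if (!is.finite(mean_elbo)) abort("non-finite ELBO at epoch %d", epoch)
        batch_elbo[bi] <- mean_elbo

        bk_mu <- mlp_backward(model$mu_head, enc$mu_f$caches, dmu)
        bk_lv <- mlp_backward(model$logvar_head, enc$logvar_f$caches, dlogvar)
        dtrunk <- bk_mu$dinput + bk_lv$dinput
        bk_tr <- mlp_backward(model$trunk, enc$trunk$caches, dtrunk)

        t <- t + 1L
        for (piece in list(list("decoder", dec_gacc),
                           list("cond_proj", proj_gacc),
                           list("mu_head", bk_mu$grads),
                           list("logvar_head", bk_lv$grads),
                           list("trunk", bk_tr$grads))) {
          nm <- piece[[1]]
          up <- adam_step(model[[nm]], piece[[2]], states[[nm]],
                          config$learning_rate, t)
          model[[nm]] <- up$net
          states[[nm]] <- up$state
        }
      }
      trace[epoch] <- mean(batch_elbo)
    }
    model$elbo_trace <- trace
    model
  })
}

# sum per-layer gradient lists (for multi-draw reconstruction terms)
acc_grads <- function(acc, g) {
  if (is.null(acc)) return(g)
  for (l in seq_along(g)) {
    acc[[l]]$W <- acc[[l]]$W + g[[l]]$W
    acc[[l]]$b <- acc[[l]]$b + g[[l]]$b
  }
  acc
}

#' Generate one conditional sample per node
#'
#' For every sample v, draws z ~ N(0, I) and decodes it with v's own profile
#' as the condition, yielding the conditional sample X^c_v. Because exactly
#' one conditional sample exists per node, the conditional neighbours of any
#' target are indexed by the same neighbourhood as its real neighbours, so
#' the graph structure carries over unchanged.
#'
#' @param model A trained `cvae_model`.
#' @param X Logged matrix (samples x taxa) used as conditions.
#' @param seed RNG seed for the latent draws.
#' @return Non-negative conditional matrix X^c (samples x taxa).
#' @export
generate_conditional_samples <- function(model, X, seed = 1L) {
  stopifnot(inherits(model, "cvae_model"), is.matrix(X))
  if (ncol(X) != model$m) {
    abort("X has %d taxa but the model was trained on %d", ncol(X), model$m)
  }
  n <- nrow(X)
  with_seed(seed, {
    z <- matrix(stats::rnorm(n * model$config$latent_dim),
                n, model$config$latent_dim)
    cvae_decode_full(model, z, X)$out
  })
}

#' @export
print.cvae_model <- function(x, ...) {
  cat(sprintf("cvae_model: m = %d, latent %d, hidden %d; %d epochs, final ELBO %.4g\n",
              x$m, x$config$latent_dim, x$config$hidden_dim,
              length(x$elbo_trace),
              if (length(x$elbo_trace)) x$elbo_trace[length(x$elbo_trace)] else NA))
  invisible(x)
}
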