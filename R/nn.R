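# Minimal dense-network machinery: forward/backward passes and Adam, in
# vectorized base R. All networks in this package (feature autoencoder,
# CVAE encoder/decoder and heads) are compositions of these pieces, so one
# backprop implementation serves everything. Single-threaded and pure
# double-precision: runs with the same seed are bit-identical.

# activation forward; `pre` is the pre-activation matrix
act_fwd <- function(pre, act) {
  switch(act,
    linear = pre,
    relu = pmax(pre, 0),
    # overflow-safe softplus: log(1 + exp(x))
    softplus = ifelse(pre > 0, pre + log1p(exp(-pre)), log1p(exp(pre))),
    abort("unknown activation '%s'", act)
  )
}

# d out / d pre, multiplied into the incoming gradient
act_bwd <- function(dout, pre, act) {
  switch(act,
    linear = dout,
    relu = dout * (pre > 0),
    softplus = dout * stats::plogis(pre),
    abort("unknown activation '%s'", act)
  )
}

# He-style initialization; weights drawn from the current RNG stream
mlp_init <- function(dims, acts) {
  stopifnot(length(acts) == length(dims) - 1L)
  layers <- vector("list", length(acts))
  for (l in seq_along(acts)) {
    fin <- dims[l]
    fout <- dims[l + 1L]
    layers[[l]] <- list(
      W = matrix(stats::rnorm(fin * fout, sd = sqrt(2 / fin)), fin, fout),
      b = numeric(fout),
      act = acts[l]
    )
  }
  structure(list(layers = layers, dims = dims), class = "mbsparse_mlp")
}

# X: batch x dims[1]. Returns output and the caches backward needs.
mlp_forward <- function(net, X) {
  caches <- vector("list", length(net$layers))
  H <- X
  for (l in seq_along(net$layers)) {
    ly <- net$layers[[l]]
    pre <- H %*% ly$W
    pre <- sweep(pre, 2L, ly$b, "+")
    caches[[l]] <- list(input = H, pre = pre)
    H <- act_fwd(pre, ly$act)
  }
  list(out = H, caches = caches)
}

# dout: gradient of the objective wrt the network output.
# Returns per-layer weight/bias gradients plus the gradient wrt the input.
mlp_backward <- function(net, caches, dout) {
  L <- length(net$layers)
  grads <- vector("list", L)
  g <- dout
  for (l in rev(seq_len(L))) {
    ly <- net$layers[[l]]
    cache <- caches[[l]]
    dpre <- act_bwd(g, cache$pre, ly$act)
    grads[[l]] <- list(W = crossprod(cache$input, dpre), b = colSums(dpre))
    g <- dpre %*% t(ly$W)
  }
  list(grads = grads, dinput = g)
}

adam_init <- function(net) {
  lapply(net$layers, function(ly) list(
    mW = ly$W * 0, vW = ly$W * 0,
    mb = ly$b * 0, vb = ly$b * 0
  ))
}

# One Adam update over all layers; returns list(net, state)
adam_step <- function(net, grads, state, lr, t,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  bc1 <- 1 - beta1^t
  bc2 <- 1 - beta2^t
  for (l in seq_along(net$layers)) {
    g <- grads[[l]]
    s <- state[[l]]
    s$mW <- beta1 * s$mW + (1 - beta1) * g$W
    s$vW <- beta2 * s$vW + (1 - beta2) * g$W^2
    s$mb <- beta1 * s$mb + (1 - beta1) * g$b
    s$vb <- beta2 * s$vb + (1 - beta2) * g$b^2
    net$layers[[l]]$W <- net$layers[[l]]$W -
      lr * (s$mW / bc1) / (sqrt(s$vW / bc2) + eps)
    net$layers[[l]]$b <- net$layers[[l]]$b -
      lr * (s$mb / bc1) / (sqrt(s$vb / bc2) + eps)
    state[[l]] <- s
  }
  list(net = net, state = state)
}

# split 1..n into shuffled batches of size at most `size` (assumes the
# permutation is drawn by the caller's seeded stream)
make_batches <- function(n, size) {
  perm <- sample.int(n)
  split(perm, ceiling(seq_along(perm) / size))
}
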