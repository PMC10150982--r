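# Minimal dense feedforward network with manual backprop and Adam.
# Shared by the predicted-age regressor and the Gaussian density network
# (which attaches its own negative log-likelihood head).

mlp_init <- function(sizes, activation = c("tanh", "relu", "identity"),
                     seed = 1L) {
  activation <- match.arg(activation)
  L <- length(sizes) - 1
  with_seed(seed, {
    W <- vector("list", L)
    b <- vector("list", L)
    for (i in seq_len(L)) {
      fan_in <- sizes[i]; fan_out <- sizes[i + 1]
      sdv <- if (activation == "relu") sqrt(2 / fan_in)
             else sqrt(2 / (fan_in + fan_out))
      W[[i]] <- matrix(rnorm(fan_in * fan_out, sd = sdv), fan_in, fan_out)
      b[[i]] <- numeric(fan_out)
    }
  })
  list(sizes = sizes, activation = activation, W = W, b = b)
}

mlp_n_params <- function(net)
  sum(vapply(seq_along(net$W),
             function(i) length(net$W[[i]]) + length(net$b[[i]]), 0))

act_fun <- function(z, type) switch(type,
  tanh = tanh(z), relu = (z + abs(z)) * 0.5, identity = z)

act_grad <- function(a, z, type) switch(type,
  tanh = 1 - a^2, relu = z > 0, identity = array(1, dim(z)))

# Forward pass; X is n x d. The final layer is linear. Returns the output and
# the per-layer pre-/post-activations needed for backprop.
mlp_forward <- function(net, X, keep_cache = FALSE) {
  L <- length(net$W)
  A <- X
  zs <- if (keep_cache) vector("list", L) else NULL
  as <- if (keep_cache) vector("list", L + 1) else NULL
  if (keep_cache) as[[1]] <- A
  for (i in seq_len(L)) {
    Z <- A %*% net$W[[i]]
    Z <- Z + rep(net$b[[i]], each = nrow(Z))  # column-major bias add
    A <- if (i < L) act_fun(Z, net$activation) else Z
    if (keep_cache) { zs[[i]] <- Z; as[[i + 1]] <- A }
  }
  if (keep_cache) list(out = A, zs = zs, as = as) else A
}

# Backprop of dLoss/dOut (n x out) through the cached forward pass; adds the
# gradient of an L2 weight penalty `l2 * sum(W^2)` when l2 > 0.
mlp_backward <- function(net, cache, dOut, l2 = 0) {
  L <- length(net$W)
  dW <- vector("list", L); db <- vector("list", L)
  delta <- dOut
  for (i in rev(seq_len(L))) {
    if (i < L) delta <- delta * act_grad(cache$as[[i + 1]], cache$zs[[i]],
                                         net$activation)
    dW[[i]] <- crossprod(cache$as[[i]], delta)
    if (l2 > 0) dW[[i]] <- dW[[i]] + 2 * l2 * net$W[[i]]
    db[[i]] <- colSums(delta)
    if (i > 1) delta <- delta %*% t(net$W[[i]])
  }
  list(W = dW, b = db)
}

adam_init <- function(net) {
  zero_like <- function(x) lapply(x, function(m) m * 0)
  list(mW = zero_like(net$W), vW = zero_like(net$W),
       mb = zero_like(net$b), vb = zero_like(net$b), t = 0)
}

adam_step <- function(net, state, grads, lr = 1e-3, beta1 = 0.9,
                      beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1
  c1 <- 1 - beta1^state$t; c2 <- 1 - beta2^state$t
  for (i in seq_along(net$W)) {
    state$mW[[i]] <- beta1 * state$mW[[i]] + (1 - beta1) * grads$W[[i]]
    state$vW[[i]] <- beta2 * state$vW[[i]] + (1 - beta2) * grads$W[[i]]^2
    net$W[[i]] <- net$W[[i]] -
      lr * (state$mW[[i]] / c1) / (sqrt(state$vW[[i]] / c2) + eps)
    state$mb[[i]] <- beta1 * state$mb[[i]] + (1 - beta1) * grads$b[[i]]
    state$vb[[i]] <- beta2 * state$vb[[i]] + (1 - beta2) * grads$b[[i]]^2
    net$b[[i]] <- net$b[[i]] -
      lr * (state$mb[[i]] / c1) / (sqrt(state$vb[[i]] / c2) + eps)
  }
  list(net = net, state = state)
}
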