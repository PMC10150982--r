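#' Encode production time into density-network inputs
#'
#' Production age is z-scored with constants frozen from the training side;
#' time of day enters as sine and cosine of the day angle (24 h = 2*pi), so
#' renditions at the same time of day on different days share the same
#' circadian regressor.
#'
#' @param age_dph production ages (days).
#' @param time_of_day_h times of day (hours).
#' @param norm list with `age_mean` and `age_sd`.
#' @return Matrix with columns `z_age`, `sin_t`, `cos_t`.
#' @export
encode_inputs <- function(age_dph, time_of_day_h, norm) {
  if (norm$age_sd == 0) stop("age standard deviation is zero")
  ang <- 2 * pi * time_of_day_h / 24
  cbind(z_age = (age_dph - norm$age_mean) / norm$age_sd,
        sin_t = sin(ang), cos_t = cos(ang))
}

# Hidden layout per architecture preset. At k = 6..8 the parameter counts of
# these presets are 141089-145972 ("wide", 256 units, 2 repeated blocks),
# 10721-11956 ("narrow64") and 75297-80180 ("shallow", single block).
dev_sizes <- function(architecture, k) {
  out <- 2L * k + (k * (k + 1L)) %/% 2L
  switch(architecture,
    wide = c(3, 256, 256, 256, out),
    narrow64 = c(3, 64, 64, 64, out),
    shallow = c(3, 256, 256, out))
}

# Split the network output row(s) into (mu, l, d) blocks.
split_output <- function(out, k) {
  q <- (k * (k + 1)) %/% 2
  list(mu = out[, seq_len(k), drop = FALSE],
       l = out[, k + seq_len(q), drop = FALSE],
       d = out[, k + q + seq_len(k), drop = FALSE])
}

# Assemble Sigma = L L' + diag(exp(d) + eps) from one packed output row.
assemble_sigma <- function(lrow, drow, k, eps) {
  L <- matrix(0, k, k)
  idx <- 1L
  for (i in seq_len(k)) for (j in seq_len(i)) {
    L[i, j] <- lrow[idx]; idx <- idx + 1L
  }
  Sigma <- tcrossprod(L) + diag(exp(drow) + eps, k)
  list(L = L, Sigma = Sigma)
}

#' Train a time-varying Gaussian model of a syllable's latent distribution
#'
#' Fits a feedforward network mapping (z-scored age, sin/cos time of day) to
#' the mean and covariance of a k-dimensional Gaussian, with the covariance
#' parameterised as `Sigma = L L' + diag(exp(d) + eps)` (L lower-triangular,
#' read row-wise from the network output), by minimising the negative log
#' likelihood of observed latents with Adam (lr 0.001). The training side is
#' internally subdivided 80/20; the 20% internal test part drives early
#' stopping (patience epochs, best checkpoint restored). Latents are centred
#' on the training side; the offset is stored in the model.
#'
#' @param train rendition data frame (one syllable): latent columns plus
#'   `age_dph`, `time_of_day_h`, `day_index`.
#' @param architecture `"wide"` (256 units, 2 repeated ReLU blocks),
#'   `"narrow64"` (default; 64 units) or `"shallow"` (single block).
#' @param seed RNG seed (internal split, initialisation, minibatch order).
#' @param eps diagonal jitter in the covariance construction.
#' @param lr,batch_size,max_epochs,patience optimisation controls.
#' @return Object of class `dev_model`.
#' @export
train_dev_model <- function(train, architecture = c("narrow64", "wide", "shallow"),
                            seed = 1L, eps = 1e-4, lr = 1e-3,
                            batch_size = 512, max_epochs = 300, patience = 10) {
  architecture <- match.arg(architecture)
  X <- latent_matrix(train)
  k <- ncol(X)
  n <- nrow(X)
  if (n < 50) stop("too few renditions to fit a density model (n = ", n, ")")
  idx <- with_seed(substream_seed(seed, 11), sample.int(n))
  n_tr <- floor(0.8 * n)
  tr <- idx[seq_len(n_tr)]; te <- idx[(n_tr + 1):n]
  norm <- list(age_mean = mean(train$age_dph[tr]),
               age_sd = sd(train$age_dph[tr]))
  center <- colMeans(X[tr, , drop = FALSE])
  Xc <- sweep(X, 2, center)
  U <- encode_inputs(train$age_dph, train$time_of_day_h, norm)
  net <- mlp_init(dev_sizes(architecture, k), activation = "relu",
                  seed = substream_seed(seed, 12))
  state <- adam_init(net)
  q <- (k * (k + 1)) %/% 2
  eval_nll <- function(net, rows) {
    o <- split_output(mlp_forward(net, U[rows, , drop = FALSE]), k)
    mean(gauss_nll_batch(o$mu, o$l, o$d, Xc[rows, , drop = FALSE], eps))
  }
  best <- list(net = net, nll = eval_nll(net, te), epoch = 0)
  wait <- 0
  history <- numeric(0)
  with_seed(substream_seed(seed, 13), {
    for (epoch in seq_len(max_epochs)) {
      ord <- sample(tr)
      for (start in seq(1, length(ord), by = batch_size)) {
        bi <- ord[start:min(start + batch_size - 1, length(ord))]
        cache <- mlp_forward(net, U[bi, , drop = FALSE], keep_cache = TRUE)
        o <- split_output(cache$out, k)
        g <- gauss_nll_grad(o$mu, o$l, o$d, Xc[bi, , drop = FALSE], eps)
        if (!is.finite(g$nll)) stop("training diverged (non-finite loss)")
        dOut <- cbind(g$dmu, g$dl, g$dd)
        grads <- mlp_backward(net, cache, dOut)
        upd <- adam_step(net, state, grads, lr = lr)
        net <- upd$net; state <- upd$state
      }
      te_nll <- eval_nll(net, te)
      history <- c(history, te_nll)
      if (!is.finite(te_nll)) stop("training diverged (non-finite test loss)")
      if (te_nll < best$nll - 1e-8) {
        best <- list(net = net, nll = te_nll, epoch = epoch)
        wait <- 0
      } else {
        wait <- wait + 1
        if (wait >= patience) break
      }
    }
  })
  structure(list(
    architecture = architecture, k = k, eps = eps, net = best$net,
    norm = norm, latent_center = center,
    n_params = mlp_n_params(best$net), seed = seed,
    epochs = best$epoch, test_nll = best$nll, history = history,
    bird_id = train$bird_id[1], syllable_id = train$syllable_id[1]
  ), class = "dev_model")
}

#' @export
print.dev_model <- function(x, ...) {
  cat(sprintf(
    "<dev_model> %s, k = %d (%d params), internal-test NLL %.3f nats (%s)\n",
    x$architecture, x$k, x$n_params, x$test_nll,
    x$syllable_id %||% "unlabelled"))
  invisible(x)
}

# Packed network parameters (mu, l, d rows) at arbitrary query times.
dev_forward_params <- function(model, age_dph, time_of_day_h) {
  U <- encode_inputs(age_dph, time_of_day_h, model$norm)
  o <- split_output(mlp_forward(model$net, U), model$k)
  o$mu <- sweep(o$mu, 2, model$latent_center, "+")
  o
}

#' Evaluate the model distribution at a production time
#'
#' @param model a `dev_model`.
#' @param age_dph production age (days); scalar.
#' @param time_of_day_h time of day (hours); scalar.
#' @return A `gaussian_snapshot`: list with `mu`, `L`, `d`, `eps` and the
#'   assembled covariance `Sigma = L L' + diag(exp(d) + eps)`.
#' @export
dev_forward <- function(model, age_dph, time_of_day_h) {
  stopifnot(length(age_dph) == 1, length(time_of_day_h) == 1)
  o <- dev_forward_params(model, age_dph, time_of_day_h)
  if (!all(is.finite(unlist(o)))) stop("non-finite network output")
  parts <- assemble_sigma(o$l[1, ], o$d[1, ], model$k, model$eps)
  structure(list(mu = drop(o$mu), L = parts$L, d = drop(o$d),
                 eps = model$eps, Sigma = parts$Sigma),
            class = "gaussian_snapshot")
}

#' Negative log likelihood of a latent vector under a snapshot
#'
#' @param snapshot a `gaussian_snapshot` from [dev_forward()].
#' @param latent numeric vector of length k.
#' @return `-log N(latent; mu, Sigma)` in nats.
#' @export
nll <- function(snapshot, latent) {
  k <- length(snapshot$mu)
  if (length(latent) != k) stop("latent length does not match snapshot")
  C <- chol(snapshot$Sigma)
  w <- backsolve(C, latent - snapshot$mu, transpose = TRUE)
  0.5 * (k * log(2 * pi) + 2 * sum(log(diag(C))) + sum(w^2))
}

#' Held-out log likelihood with permutation controls
#'
#' Computes the mean per-rendition log likelihood of evaluation latents under
#' the model at their true production times (`shuffle = "none"`), or the
#' distribution of that mean when production times are permuted totally or
#' only within days.
#'
#' @param model a `dev_model`.
#' @param eval_set evaluation rendition data frame.
#' @param shuffle `"none"`, `"total"` or `"within_day"`.
#' @param n_permutations number of permutations for shuffled modes.
#' @param seed RNG seed.
#' @return For `"none"`, a list with `mean_loglik` and `n`; otherwise also
#'   `perm_loglik` (per-permutation means) and their `mean_perm_loglik`.
#' @export
eval_loglik <- function(model, eval_set,
                        shuffle = c("none", "total", "within_day"),
                        n_permutations = 1000, seed = 1L) {
  shuffle <- match.arg(shuffle)
  X <- latent_matrix(eval_set, k = model$k)
  o <- dev_forward_params(model, eval_set$age_dph, eval_set$time_of_day_h)
  base <- -mean(gauss_nll_batch(o$mu, o$l, o$d, X, model$eps))
  if (shuffle == "none")
    return(list(shuffle = shuffle, mean_loglik = base, n = nrow(X)))
  groups <- if (shuffle == "within_day")
    split(seq_len(nrow(X)), eval_set$day_index) else list(seq_len(nrow(X)))
  perm_ll <- numeric(n_permutations)
  with_seed(seed, for (p in seq_len(n_permutations)) {
    pi_ <- seq_len(nrow(X))
    for (g in groups) if (length(g) > 1) pi_[g] <- g[sample.int(length(g))]
    # latents keep their identity; production times are permuted
    perm_ll[p] <- -mean(gauss_nll_batch(
      o$mu[pi_, , drop = FALSE], o$l[pi_, , drop = FALSE],
      o$d[pi_, , drop = FALSE], X, model$eps))
  })
  list(shuffle = shuffle, mean_loglik = base, perm_loglik = perm_ll,
       mean_perm_loglik = mean(perm_ll), n = nrow(X))
}
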