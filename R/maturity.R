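#' Split a syllable's renditions into training and evaluation sides
#'
#' Random, disjoint, exhaustive 80/20 (by default) partition of a rendition
#' table. The training side is later subdivided 70/15/15 internally
#' (optimisation / early-stopping / penalty-selection) by [train_age_net()].
#'
#' @param renditions a rendition data frame (one syllable).
#' @param eval_fraction fraction held out for final evaluation.
#' @param seed RNG seed.
#' @return List with elements `train` and `eval`.
#' @export
split_dataset <- function(renditions, eval_fraction = 0.2, seed = 1L) {
  n <- nrow(renditions)
  n_eval <- round(n * eval_fraction)
  if (n - n_eval < 20 || n_eval < 1)
    stop("too few renditions to split (n = ", n, ")")
  idx <- with_seed(seed, sample.int(n, n_eval))
  list(train = renditions[-idx, , drop = FALSE],
       eval = renditions[idx, , drop = FALSE])
}

# Layer widths for the maturity architectures. The pyramid gives 705
# trainable parameters at 32 input dimensions, the shallow variant 601.
maturity_sizes <- function(architecture, d) switch(architecture,
  pyramid = c(d, 16, 8, 4, 1),
  shallow = c(d, 16, 4, 1),
  linear  = c(d, 1))

#' Train a predicted-age ("maturity") regressor
#'
#' Fits a small feedforward network mapping a rendition's latent vector to
#' its production age (dph), minimising mean squared prediction error plus an
#' L2 penalty on the weights. The training side is internally partitioned
#' 70/15/15; optimisation runs on the 70% with Adam, early stopping (patience
#' `patience` epochs, best weights restored) monitors the 15% test part, and
#' the penalty weight is selected from `l2_grid` on the 15% validation part.
#' The `linear` architecture is solved in closed form (ridge regression, the
#' exact minimiser of the same objective).
#'
#' @param train a rendition data frame (the training side of
#'   [split_dataset()]) with latent columns `z1..zk` and `age_dph`.
#' @param architecture `"pyramid"` (default; tanh hidden layers narrowing
#'   16-8-4), `"shallow"` (16-4) or `"linear"`.
#' @param l2_weight fixed L2 penalty weight; `NULL` selects from `l2_grid`.
#' @param l2_grid candidate penalty weights.
#' @param seed RNG seed controlling the internal split, initialisation and
#'   minibatch order.
#' @param max_epochs,patience,batch_size,lr optimisation controls.
#' @param activation override the hidden activation (e.g. `"identity"` to
#'   disable all nonlinearity, which collapses the network to an affine map).
#' @return Object of class `maturity_model`.
#' @export
train_age_net <- function(train, architecture = c("pyramid", "shallow", "linear"),
                          l2_weight = NULL, l2_grid = c(1e-4, 1e-3, 1e-2),
                          seed = 1L, max_epochs = 200, patience = 3,
                          batch_size = 256, lr = 1e-3, activation = NULL) {
  architecture <- match.arg(architecture)
  X <- latent_matrix(train)
  y <- train$age_dph
  n <- nrow(X)
  if (n < 20) stop("too few renditions to train (n = ", n, ")")
  # internal 70/15/15 split of the training side
  parts <- with_seed(substream_seed(seed, 1), {
    idx <- sample.int(n)
    n_tr <- floor(0.70 * n); n_te <- floor(0.15 * n)
    list(tr = idx[seq_len(n_tr)],
         te = idx[n_tr + seq_len(n_te)],
         va = idx[(n_tr + n_te + 1):n])
  })
  x_center <- colMeans(X[parts$tr, , drop = FALSE])
  x_scale <- apply(X[parts$tr, , drop = FALSE], 2, sd)
  x_scale[x_scale == 0] <- 1
  y_center <- mean(y[parts$tr]); y_scale <- sd(y[parts$tr])
  if (y_scale == 0) y_scale <- 1
  Xs <- sweep(sweep(X, 2, x_center), 2, x_scale, "/")
  ys <- (y - y_center) / y_scale
  grid <- if (!is.null(l2_weight)) l2_weight else l2_grid
  fits <- lapply(grid, function(l2)
    fit_age_core(architecture, Xs, ys, parts, l2, seed, max_epochs,
                 patience, batch_size, lr, activation))
  val_mse <- vapply(fits, function(f) f$val_mse, 0)
  best <- which.min(val_mse)
  fit <- fits[[best]]
  structure(list(
    architecture = architecture, sizes = fit$sizes, net = fit$net,
    beta = fit$beta, activation = fit$activation,
    x_center = x_center, x_scale = x_scale,
    y_center = y_center, y_scale = y_scale,
    l2_weight = grid[best], l2_grid = grid,
    n_params = fit$n_params, seed = seed,
    epochs = fit$epochs,
    train_mse = fit$train_mse * y_scale^2,
    test_mse = fit$test_mse * y_scale^2,
    val_mse = fit$val_mse * y_scale^2,
    split_fractions = c(train = 0.70, test = 0.15, validation = 0.15)
  ), class = "maturity_model")
}

fit_age_core <- function(architecture, Xs, ys, parts, l2, seed, max_epochs,
                         patience, batch_size, lr, activation) {
  d <- ncol(Xs)
  if (architecture == "linear") {
    # exact ridge solution of mean((y - Xb - b0)^2) + l2 * sum(b^2)
    Xtr <- cbind(1, Xs[parts$tr, , drop = FALSE])
    ytr <- ys[parts$tr]
    n_tr <- nrow(Xtr)
    P <- diag(c(0, rep(1, d)))  # intercept unpenalised
    beta <- solve(crossprod(Xtr) / n_tr + l2 * P, crossprod(Xtr, ytr) / n_tr)
    pred <- function(idx) drop(cbind(1, Xs[idx, , drop = FALSE]) %*% beta)
    return(list(sizes = c(d, 1), net = NULL, beta = drop(beta),
                activation = "identity", n_params = d + 1, epochs = 0,
                train_mse = mean((ys[parts$tr] - pred(parts$tr))^2),
                test_mse = mean((ys[parts$te] - pred(parts$te))^2),
                val_mse = mean((ys[parts$va] - pred(parts$va))^2)))
  }
  sizes <- maturity_sizes(architecture, d)
  act <- activation %||% "tanh"
  net <- mlp_init(sizes, activation = act, seed = substream_seed(seed, 2))
  state <- adam_init(net)
  Xtr <- Xs[parts$tr, , drop = FALSE]; ytr <- ys[parts$tr]
  Xte <- Xs[parts$te, , drop = FALSE]; yte <- ys[parts$te]
  n_tr <- nrow(Xtr)
  best <- list(net = net, mse = Inf, epoch = 0)
  wait <- 0
  with_seed(substream_seed(seed, 3), {
    for (epoch in seq_len(max_epochs)) {
      ord <- sample.int(n_tr)
      for (start in seq(1, n_tr, by = batch_size)) {
        bi <- ord[start:min(start + batch_size - 1, n_tr)]
        cache <- mlp_forward(net, Xtr[bi, , drop = FALSE], keep_cache = TRUE)
        resid <- drop(cache$out) - ytr[bi]
        dOut <- matrix(2 * resid / length(bi), ncol = 1)
        grads <- mlp_backward(net, cache, dOut, l2 = l2)
        upd <- adam_step(net, state, grads, lr = lr)
        net <- upd$net; state <- upd$state
      }
      te_mse <- mean((drop(mlp_forward(net, Xte)) - yte)^2)
      if (!is.finite(te_mse)) stop("training diverged (non-finite test loss)")
      if (te_mse < best$mse - 1e-9) {
        best <- list(net = net, mse = te_mse, epoch = epoch)
        wait <- 0
      } else {
        wait <- wait + 1
        if (wait >= patience) break
      }
    }
  })
  net <- best$net
  pr <- function(idx) drop(mlp_forward(net, Xs[idx, , drop = FALSE]))
  list(sizes = sizes, net = net, beta = NULL, activation = act,
       n_params = mlp_n_params(net), epochs = best$epoch,
       train_mse = mean((ys[parts$tr] - pr(parts$tr))^2),
       test_mse = best$mse,
       val_mse = mean((ys[parts$va] - pr(parts$va))^2))
}

#' @export
print.maturity_model <- function(x, ...) {
  cat(sprintf(
    "<maturity_model> %s (%d params, l2 = %g), held-in test MSE %.3f days^2\n",
    x$architecture, x$n_params, x$l2_weight, x$test_mse))
  invisible(x)
}

#' Predict age (maturity score) for latent vectors
#'
#' @param model a `maturity_model`.
#' @param latents numeric matrix (n x k) or a rendition data frame with
#'   latent columns.
#' @return Numeric vector of predicted ages in days.
#' @export
predict_age <- function(model, latents) {
  X <- if (is.data.frame(latents)) latent_matrix(latents) else as.matrix(latents)
  if (ncol(X) != length(model$x_center))
    stop(sprintf("latent dimensionality %d does not match model input %d",
                 ncol(X), length(model$x_center)))
  Xs <- sweep(sweep(X, 2, model$x_center), 2, model$x_scale, "/")
  out <- if (model$architecture == "linear")
    drop(cbind(1, Xs) %*% model$beta)
  else drop(mlp_forward(model$net, Xs))
  out * model$y_scale + model$y_center
}

#' Permutation-control MSE for a maturity model
#'
#' Evaluates the model on an evaluation set and compares against permutation
#' nulls: `"total"` permutes production ages freely across renditions;
#' `"within_day"` permutes ages only among renditions of the same day,
#' isolating sub-circadian structure. Evaluation is restricted to ages inside
#' `age_limits` (60-95 dph by default).
#'
#' @param model a `maturity_model`.
#' @param eval_set evaluation rendition data frame.
#' @param mode `"total"` or `"within_day"`.
#' @param n_permutations number of permutations (may be 0).
#' @param seed RNG seed.
#' @param age_limits evaluation age window in dph.
#' @return Object of class `shuffle_report`: unshuffled MSE, per-permutation
#'   MSEs, their mean and the exceedance fraction (share of permutation MSEs
#'   strictly greater than the unshuffled MSE).
#' @export
shuffle_mse <- function(model, eval_set, mode = c("total", "within_day"),
                        n_permutations = 1000, seed = 1L,
                        age_limits = c(60, 95)) {
  mode <- match.arg(mode)
  keep <- eval_set$age_dph >= age_limits[1] & eval_set$age_dph <= age_limits[2]
  df <- eval_set[keep, , drop = FALSE]
  if (nrow(df) == 0) stop("no renditions inside age_limits")
  pred <- predict_age(model, df)
  y <- df$age_dph
  unshuffled <- mean((pred - y)^2)
  perm_mse <- numeric(n_permutations)
  if (n_permutations > 0) {
    groups <- if (mode == "within_day") split(seq_along(y), df$day_index)
              else list(seq_along(y))
    single <- sum(vapply(groups, length, 1L) < 2)
    if (mode == "within_day" && single > 0)
      message(single, " day(s) with a single rendition contribute no ",
              "within-day permutation variability")
    with_seed(seed, for (p in seq_len(n_permutations)) {
      yp <- y
      for (g in groups) if (length(g) > 1) yp[g] <- y[sample(g)]
      perm_mse[p] <- mean((pred - yp)^2)
    })
  }
  structure(list(mode = mode, n_permutations = n_permutations,
                 unshuffled_mse = unshuffled, perm_mse = perm_mse,
                 mean_perm_mse = if (n_permutations > 0) mean(perm_mse) else NA_real_,
                 exceedance = if (n_permutations > 0)
                   mean(perm_mse > unshuffled) else NA_real_,
                 n = nrow(df)),
            class = "shuffle_report")
}

#' @export
print.shuffle_report <- function(x, ...) {
  cat(sprintf(
    "<shuffle_report> %s: unshuffled MSE %.4f days^2; mean of %d permutations %.4f; exceedance %.3f\n",
    x$mode, x$unshuffled_mse, x$n_permutations, x$mean_perm_mse, x$exceedance))
  invisible(x)
}
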