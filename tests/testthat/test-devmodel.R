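test_that("input encoding has the documented trigonometric identities", {
  norm <- list(age_mean = 70, age_sd = 5)
  u <- encode_inputs(70, 6, norm)
  expect_equal(unname(u[1, ]), c(0, 1, 0), tolerance = 1e-12)
  expect_equal(encode_inputs(65, 0, norm)[, 2:3],
               encode_inputs(83, 24, norm)[, 2:3], tolerance = 1e-12)
  # same time of day on different days -> identical circadian regressors
  expect_equal(encode_inputs(61, 9.5, norm)[, 2:3],
               encode_inputs(88, 9.5, norm)[, 2:3], tolerance = 1e-12)
  expect_error(encode_inputs(70, 6, list(age_mean = 70, age_sd = 0)), "zero")
})

test_that("zeroed network gives Sigma = (1 + eps) I; snapshots are SPD", {
  m <- constant_dev_model(k = 4, eps = 1e-4, center = 1:4)
  s <- dev_forward(m, 70, 12)
  expect_equal(s$Sigma, diag(1 + 1e-4, 4), tolerance = 1e-12)
  expect_equal(s$mu, 1:4)
  expect_true(all(eigen(s$Sigma, symmetric = TRUE)$values > 0))
  expect_silent(chol(s$Sigma))
})

test_that("perturbing d changes only the diagonal of Sigma", {
  m <- cosine_dev_model(k = 3, gain = 0.5)
  s1 <- dev_forward(m, 70, 8)    # different cos_t -> different d
  s2 <- dev_forward(m, 70, 20)
  off1 <- s1$Sigma - diag(diag(s1$Sigma))
  off2 <- s2$Sigma - diag(diag(s2$Sigma))
  expect_equal(off1, off2, tolerance = 1e-12)
  expect_false(isTRUE(all.equal(diag(s1$Sigma), diag(s2$Sigma))))
})

test_that("nll matches closed forms and an independent density routine", {
  # standard normal at its mean in 1-D: 0.5 * log(2*pi)
  snap1 <- structure(list(mu = 0, Sigma = matrix(1, 1, 1)),
                     class = "gaussian_snapshot")
  expect_equal(nll(snap1, 0), 0.5 * log(2 * pi), tolerance = 1e-12)
  # latent at the mean: 0.5 * log(det(2*pi*Sigma))
  set.seed(3)
  S <- random_spd(3)
  snap3 <- structure(list(mu = c(1, -2, 0.5), Sigma = S),
                     class = "gaussian_snapshot")
  expect_equal(nll(snap3, c(1, -2, 0.5)),
               0.5 * as.numeric(determinant(2 * pi * S)$modulus),
               tolerance = 1e-10)
  # generic point against a determinant/solve-based density
  x <- c(0.3, 0.1, -1)
  ref <- 0.5 * (3 * log(2 * pi) + as.numeric(determinant(S)$modulus) +
                  drop(t(x - snap3$mu) %*% solve(S, x - snap3$mu)))
  expect_equal(nll(snap3, x), ref, tolerance = 1e-10)
  expect_error(nll(snap3, c(1, 2)), "length")
})

test_that("the compiled batch NLL agrees with the R snapshot NLL", {
  set.seed(9)
  k <- 5; n <- 20; q <- k * (k + 1) / 2
  mu <- matrix(rnorm(n * k), n)
  l <- matrix(rnorm(n * q, sd = 0.3), n)
  d <- matrix(rnorm(n * k, sd = 0.2), n)
  x <- matrix(rnorm(n * k), n)
  batch <- songdev:::gauss_nll_batch(mu, l, d, x, 1e-4)
  for (i in c(1, 7, 20)) {
    parts <- songdev:::assemble_sigma(l[i, ], d[i, ], k, 1e-4)
    snap <- structure(list(mu = mu[i, ], Sigma = parts$Sigma),
                      class = "gaussian_snapshot")
    expect_equal(batch[i], nll(snap, x[i, ]), tolerance = 1e-10)
  }
  g <- songdev:::gauss_nll_grad(mu, l, d, x, 1e-4)
  expect_equal(g$nll, mean(batch), tolerance = 1e-10)
})

test_that("compiled NLL gradients match finite differences", {
  set.seed(10)
  k <- 3; q <- 6
  mu <- matrix(rnorm(k), 1)
  l <- matrix(rnorm(q, sd = 0.4), 1)
  d <- matrix(rnorm(k, sd = 0.3), 1)
  x <- matrix(rnorm(k), 1)
  g <- songdev:::gauss_nll_grad(mu, l, d, x, 1e-4)
  h <- 1e-6
  fd <- function(mat, gmat, name) {
    for (j in seq_len(ncol(mat))) {
      up <- mat; up[1, j] <- up[1, j] + h
      dn <- mat; dn[1, j] <- dn[1, j] - h
      args_up <- list(mu = mu, l = l, d = d); args_up[[name]] <- up
      args_dn <- list(mu = mu, l = l, d = d); args_dn[[name]] <- dn
      num <- (songdev:::gauss_nll_batch(args_up$mu, args_up$l, args_up$d, x, 1e-4) -
                songdev:::gauss_nll_batch(args_dn$mu, args_dn$l, args_dn$d, x, 1e-4)) / (2 * h)
      expect_equal(gmat[1, j], drop(num), tolerance = 1e-5)
    }
  }
  fd(mu, g$dmu, "mu"); fd(l, g$dl, "l"); fd(d, g$dd, "d")
})

test_that("architecture presets land in the documented parameter windows", {
  count <- function(sz) sum(sz[-length(sz)] * sz[-1] + sz[-1])
  expect_equal(count(songdev:::dev_sizes("wide", 6)), 141089)
  expect_equal(count(songdev:::dev_sizes("wide", 7)), 143402)
  expect_equal(count(songdev:::dev_sizes("narrow64", 6)), 10721)
  expect_equal(count(songdev:::dev_sizes("narrow64", 8)), 11956)
  expect_equal(count(songdev:::dev_sizes("shallow", 6)), 75297)
  expect_equal(count(songdev:::dev_sizes("shallow", 8)), 80180)
})

test_that("a stationary Gaussian is fit with a near-constant mean", {
  set.seed(12)
  n <- 3000
  df <- data.frame(age_dph = runif(n, 60, 70), z1 = rnorm(n, 2, 0.5),
                   z2 = rnorm(n, -1, 0.8))
  df$time_of_day_h <- runif(n, 7, 21)
  df$day_index <- floor(df$age_dph)
  m <- train_dev_model(df, seed = 1, max_epochs = 100)
  grid <- expand.grid(age = c(61, 64, 68), tod = c(8, 13, 19))
  mus <- t(mapply(function(a, t) dev_forward(m, a, t)$mu, grid$age, grid$tod))
  target <- c(mean(df$z1), mean(df$z2))
  se <- c(sd(df$z1), sd(df$z2)) / sqrt(n)
  # max deviation small relative to the data scale (a few sample SEs)
  expect_lt(max(abs(sweep(mus, 2, target))), 30 * max(se))
  # and Sigma is SPD on the whole grid
  for (i in seq_len(nrow(grid))) {
    s <- dev_forward(m, grid$age[i], grid$tod[i])
    expect_true(all(eigen(s$Sigma, symmetric = TRUE)$values > 0))
  }
})

test_that("time-constant models make total shuffles exactly neutral", {
  m <- constant_dev_model(k = 3)
  set.seed(4)
  ev <- data.frame(age_dph = runif(100, 60, 70))
  ev$day_index <- floor(ev$age_dph)
  ev$time_of_day_h <- runif(100, 7, 21)
  ev$z1 <- rnorm(100); ev$z2 <- rnorm(100); ev$z3 <- rnorm(100)
  r <- eval_loglik(m, ev, "total", n_permutations = 25, seed = 1)
  expect_true(all(abs(r$perm_loglik - r$mean_loglik) < 1e-12))
})

test_that("within-day shuffles with day-resolution ages are neutral", {
  m <- cosine_dev_model(k = 2, gain = 0.3)
  set.seed(5)
  ev <- data.frame(day_index = rep(60:64, each = 20))
  ev$time_of_day_h <- 12        # same production time within each day
  ev$age_dph <- ev$day_index + 0.5
  ev$z1 <- rnorm(100); ev$z2 <- rnorm(100)
  r <- eval_loglik(m, ev, "within_day", n_permutations = 25, seed = 1)
  expect_true(all(abs(r$perm_loglik - r$mean_loglik) < 1e-12))
})

test_that("exact-model evaluation matches the analytic expected log-density", {
  # data at a single timestamp, model = exact generating Gaussian
  k <- 3
  m <- constant_dev_model(k = k, center = c(1, 2, 3))
  set.seed(6)
  n <- 4e4
  z <- matrix(rnorm(n * k, sd = sqrt(1 + 1e-4)), n)
  ev <- data.frame(age_dph = 65.5, time_of_day_h = 12, day_index = 65,
                   z1 = z[, 1] + 1, z2 = z[, 2] + 2, z3 = z[, 3] + 3)
  r <- eval_loglik(m, ev, "none")
  analytic <- -(k / 2) * (1 + log(2 * pi)) - 0.5 * k * log(1 + 1e-4)
  expect_equal(r$mean_loglik, analytic, tolerance = 0.02)
})

test_that("training is deterministic given the seed", {
  syl <- head(tiny_syllable(), 1200)
  m1 <- train_dev_model(syl, seed = 5, max_epochs = 15, patience = 3)
  m2 <- train_dev_model(syl, seed = 5, max_epochs = 15, patience = 3)
  expect_identical(m1$net$W, m2$net$W)
  expect_identical(m1$history, m2$history)
})
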