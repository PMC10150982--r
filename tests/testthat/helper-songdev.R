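# Shared fixtures, all built in code at test time.

# Small single-syllable synthetic dataset (one bird), cached per session.
tiny_params <- function(seed = 42, ...) {
  args <- utils::modifyList(
    list(n_birds = 1, syllables_per_bird = 1, k = 6,
         age_range = c(60, 72), renditions_per_day = 400, seed = seed),
    list(...))
  do.call(ground_truth_params, args)
}

tiny_syllable <- local({
  cache <- new.env()
  function() {
    if (is.null(cache$df)) {
      d <- generate_dataset(tiny_params())
      cache$df <- syllable_renditions(d, "bird01_syl1")
    }
    cache$df
  }
})

# Hand-constructed density model whose network has all-zero weights:
# mu = latent_center, Sigma = (1 + eps) * I at every production time.
constant_dev_model <- function(k = 3, eps = 1e-4, center = rep(0, k)) {
  net <- mlp_zeroed(dev_sizes_local("narrow64", k))
  structure(list(architecture = "narrow64", k = k, eps = eps, net = net,
                 norm = list(age_mean = 70, age_sd = 5),
                 latent_center = center, n_params = 0, seed = 0,
                 epochs = 0, test_nll = NA_real_,
                 bird_id = "birdX", syllable_id = "birdX_sylY"),
            class = "dev_model")
}

dev_sizes_local <- function(arch, k) {
  out <- 2L * k + (k * (k + 1L)) %/% 2L
  switch(arch, narrow64 = c(3, 64, 64, 64, out), wide = c(3, 256, 256, 256, out))
}

mlp_zeroed <- function(sizes) {
  L <- length(sizes) - 1
  list(sizes = sizes, activation = "relu",
       W = lapply(seq_len(L), function(i) matrix(0, sizes[i], sizes[i + 1])),
       b = lapply(seq_len(L), function(i) numeric(sizes[i + 1])))
}

# Density model whose log-variances depend on time of day: the third input
# (cos of the day angle) is passed through one hidden unit into every d
# output, so det(Sigma) varies deterministically over the day.
cosine_dev_model <- function(k = 2, gain = 1, eps = 1e-4) {
  sizes <- dev_sizes_local("narrow64", k)
  net <- mlp_zeroed(sizes)
  # hidden chain carrying relu(cos_t + 2) > 0 through the layers
  net$W[[1]][3, 1] <- 1
  net$b[[1]][1] <- 2            # keeps the unit active for all cos_t
  net$W[[2]][1, 1] <- 1
  net$W[[3]][1, 1] <- 1
  q <- (k * (k + 1)) %/% 2
  for (i in seq_len(k))
    net$W[[4]][1, k + q + i] <- gain   # d_i = gain * (cos_t + 2)
  structure(list(architecture = "narrow64", k = k, eps = eps, net = net,
                 norm = list(age_mean = 70, age_sd = 5),
                 latent_center = rep(0, k), n_params = 0, seed = 0,
                 epochs = 0, test_nll = NA_real_,
                 bird_id = "birdX", syllable_id = "birdX_sylY"),
            class = "dev_model")
}

# Random SPD matrix with log-spaced eigenvalues.
random_spd <- function(k) {
  ev <- exp(runif(k, -2, 2))
  Q <- qr.Q(qr(matrix(rnorm(k * k), k)))
  Q %*% (ev * t(Q))
}

# Shift records drawn from the mixed-effects generative model.
make_shift_records <- function(n_birds = 5, syll_per_bird = c(3, 3, 3, 2, 2),
                               n_pairs = 25,
                               levels = c(1, 5, 25, 50, 75, 95, 99),
                               intercept = -0.8, slope = 2.0,
                               sd_bird = c(0.2, 0.3), sd_syll = c(0.3, 0.5),
                               sd_noise = 1.0, seed = 1) {
  set.seed(seed)
  syll_per_bird <- rep_len(syll_per_bird, n_birds)
  rows <- list()
  for (b in seq_len(n_birds)) {
    ab <- rnorm(1, sd = sd_bird[1]); bb <- rnorm(1, sd = sd_bird[2])
    for (s in seq_len(syll_per_bird[b])) {
      as_ <- rnorm(1, sd = sd_syll[1]); bs <- rnorm(1, sd = sd_syll[2])
      g <- expand.grid(day_from = seq_len(n_pairs), level = levels)
      g$bird_id <- sprintf("b%d", b)
      g$syllable_id <- sprintf("b%d_s%d", b, s)
      g$percentile <- g$level / 100
      g$shift <- (intercept + ab + as_) + (slope + bb + bs) * g$percentile +
        rnorm(nrow(g), sd = sd_noise)
      g$day_to <- g$day_from + 1; g$gap <- 0.5; g$condition <- "real"
      rows[[length(rows) + 1]] <- g
    }
  }
  do.call(rbind, rows)
}

make_entropy_samples <- function(n_birds = 5, syll_per_bird = c(3, 3, 3, 2, 2),
                                 intercept = 3, tod_slope = -0.07,
                                 sd_bird = c(0.2, 0.01),
                                 sd_syll = c(0.4, 0.02),
                                 sd_noise = 0.1, seed = 1) {
  set.seed(seed)
  syll_per_bird <- rep_len(syll_per_bird, n_birds)
  rows <- list()
  for (b in seq_len(n_birds)) {
    ab <- rnorm(1, sd = sd_bird[1]); bb <- rnorm(1, sd = sd_bird[2])
    for (s in seq_len(syll_per_bird[b])) {
      as_ <- rnorm(1, sd = sd_syll[1]); bs <- rnorm(1, sd = sd_syll[2])
      g <- expand.grid(time_of_day_h = seq(7.5, 20.5, by = 0.25),
                       day_index = 60:74)
      g$bird_id <- sprintf("b%d", b)
      g$syllable_id <- sprintf("b%d_s%d", b, s)
      g$age_dph <- g$day_index + g$time_of_day_h / 24
      g$entropy <- (intercept + ab + as_) +
        (tod_slope + bb + bs) * g$time_of_day_h + rnorm(nrow(g), sd = sd_noise)
      rows[[length(rows) + 1]] <- g
    }
  }
  do.call(rbind, rows)
}

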