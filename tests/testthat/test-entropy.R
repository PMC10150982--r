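test_that("gaussian_entropy matches closed forms", {
  expect_equal(gaussian_entropy(matrix(1, 1, 1)), 0.5 * (1 + log(2 * pi)),
               tolerance = 1e-12)
  expect_equal(gaussian_entropy(diag(2)), 1 + log(2 * pi), tolerance = 1e-12)
  # diag(4, 1): 0.5*log(4) + 1 + log(2*pi)
  expect_equal(gaussian_entropy(diag(c(4, 1))),
               0.5 * log(4) + 1 + log(2 * pi), tolerance = 1e-12)
  expect_error(gaussian_entropy(matrix(c(1, 2, 2, 1), 2)),
               "positive definite")
})

test_that("query-time grids respect the support window and count filter", {
  empty <- data.frame(bird_id = character(), syllable_id = character(),
                      age_dph = numeric(), time_of_day_h = numeric(),
                      day_index = integer())
  expect_equal(nrow(sample_query_times(empty)), 0)
  # 40 renditions at exactly 10:00 on one day: only grid times within 15
  # minutes of 10:00 qualify (closed bounds)
  df <- data.frame(day_index = 70, time_of_day_h = rep(10, 40),
                   age_dph = 70 + 10 / 24)
  qt <- sample_query_times(df, day_window = c(7, 21))
  expect_true(all(abs(qt$time_of_day_h - 10) <= 0.25 + 1e-12))
  expect_equal(sort(qt$time_of_day_h),
               seq(9.75, 10.25, by = 5 / 60), tolerance = 1e-12)
  expect_true(all(qt$n_support == 40))
  # 29 renditions in every window: everything filtered
  df29 <- df[1:29, ]
  expect_equal(nrow(sample_query_times(df29, day_window = c(7, 21))), 0)
  # age_dph on the grid combines day and hours
  expect_equal(qt$age_dph, qt$day_index + qt$time_of_day_h / 24)
})

test_that("entropy trajectories reflect the model covariance exactly", {
  m <- constant_dev_model(k = 3)
  qt <- data.frame(day_index = c(70, 70, 71), time_of_day_h = c(8, 14, 9),
                   age_dph = c(70, 70, 71) + c(8, 14, 9) / 24,
                   n_support = 50)
  tr <- entropy_trajectory(m, qt)
  expect_equal(tr$entropy, rep(gaussian_entropy(diag(1 + 1e-4, 3)), 3),
               tolerance = 1e-12)
  # doubling Sigma raises entropy by (k/2) log 2
  s <- dev_forward(m, 70, 8)
  expect_equal(gaussian_entropy(2 * s$Sigma) - gaussian_entropy(s$Sigma),
               1.5 * log(2), tolerance = 1e-12)
})

test_that("daily_min_det takes the minimum over each day's grid", {
  m <- cosine_dev_model(k = 2, gain = 0.4)
  qt <- expand.grid(time_of_day_h = seq(7, 21, by = 0.5),
                    day_index = 70:72)
  qt$age_dph <- qt$day_index + qt$time_of_day_h / 24
  qt$n_support <- 50
  tg <- daily_min_det(m, qt)
  expect_equal(nrow(tg), 3)
  tr <- entropy_trajectory(m, qt)
  for (day in 70:72)
    expect_equal(tg$target_det[tg$day_index == day],
                 min(tr$det[tr$day_index == day]), tolerance = 1e-12)
  # constant model: the target is the constant determinant
  mc <- constant_dev_model(k = 2)
  tgc <- daily_min_det(mc, qt)
  expect_equal(tgc$target_det, rep(det(diag(1 + 1e-4, 2)), 3),
               tolerance = 1e-12)
})

test_that("fix_entropy hits the target determinant and preserves allocation", {
  # isotropic: 4I with target 1 -> I
  expect_equal(fix_entropy(diag(4, 2), 1), diag(2), tolerance = 1e-10)
  # diag(8, 2) with target 1 -> diag(2, 0.5): ratio 16, divisor 4
  expect_equal(fix_entropy(diag(c(8, 2)), 1), diag(c(2, 0.5)),
               tolerance = 1e-10)
  # identity case: target equal to det leaves Sigma unchanged
  set.seed(21)
  S <- random_spd(4)
  expect_equal(fix_entropy(S, det(S)), S, tolerance = 1e-10)
  expect_error(fix_entropy(S, -1), "target_det")
  expect_error(fix_entropy(matrix(c(1, 2, 2, 1), 2), 1), "positive definite")
})

test_that("fix_entropy invariants hold for random SPD matrices", {
  set.seed(22)
  for (k in c(2, 5, 8)) {
    S <- random_spd(k)
    tgt <- exp(runif(1, -3, 3))
    F1 <- fix_entropy(S, tgt)
    expect_equal(det(F1), tgt, tolerance = 1e-8 * tgt)
    # eigenbasis and eigenvalue ratios preserved
    e0 <- eigen(S, symmetric = TRUE); e1 <- eigen(F1, symmetric = TRUE)
    expect_equal(e1$values / e1$values[1], e0$values / e0$values[1],
                 tolerance = 1e-8)
    expect_equal(abs(diag(crossprod(e0$vectors, e1$vectors))), rep(1, k),
                 tolerance = 1e-6)
    # idempotent under repeated application
    expect_equal(fix_entropy(F1, tgt), F1, tolerance = 1e-9)
    # entropy of the result is exactly the clamped value
    expect_equal(gaussian_entropy(F1),
                 0.5 * log(tgt) + (k / 2) * (1 + log(2 * pi)),
                 tolerance = 1e-9)
  }
})

test_that("simulation draws honour the model distribution and seeding", {
  m <- constant_dev_model(k = 3, center = c(5, -2, 1))
  obs <- data.frame(bird_id = "b", syllable_id = "s",
                    age_dph = rep(70.5, 10000), time_of_day_h = 12,
                    day_index = 70)
  sim <- simulate_development(m, obs, "baseline", seed = 3)
  expect_identical(sim, simulate_development(m, obs, "baseline", seed = 3))
  # CLT: sample mean within 3 SEs of mu componentwise
  z <- as.matrix(sim[paste0("z", 1:3)])
  expect_true(all(abs(colMeans(z) - c(5, -2, 1)) < 3 * sqrt(1.0001 / 10000)))
  # subsets reproduce independently of the other rows
  sub <- simulate_development(m, obs[1:5, ], "baseline", seed = 3)
  expect_equal(sub[paste0("z", 1:3)], sim[1:5, paste0("z", 1:3)],
               tolerance = 1e-12)
})

test_that("fixed-entropy simulation flattens the within-day spread", {
  m <- cosine_dev_model(k = 2, gain = -0.6)   # morning det > evening det
  qt <- expand.grid(time_of_day_h = seq(7, 21, by = 0.25), day_index = 70)
  qt$age_dph <- qt$day_index + qt$time_of_day_h / 24
  qt$n_support <- 50
  tg <- daily_min_det(m, qt)
  obs <- data.frame(bird_id = "b", syllable_id = "s",
                    time_of_day_h = rep(c(8, 20), each = 4000))
  obs$day_index <- 70
  obs$age_dph <- 70 + obs$time_of_day_h / 24
  base <- simulate_development(m, obs, "baseline", seed = 5, targets = tg)
  fixed <- simulate_development(m, obs, "fixed_entropy", seed = 5, targets = tg)
  lds <- function(df, tod) {
    z <- as.matrix(df[df$time_of_day_h == tod, paste0("z", 1:2)])
    as.numeric(determinant(cov(z))$modulus)
  }
  # baseline keeps the generator's morning > evening determinant ordering
  expect_gt(lds(base, 8), lds(base, 20) + 0.5)
  # clamped mode equalises determinants to the daily minimum
  expect_lt(abs(lds(fixed, 8) - lds(fixed, 20)), 0.15)
  expect_equal(lds(fixed, 20), log(tg$target_det[1]), tolerance = 0.1)
  # the transform never moves the mean
  for (tod in c(8, 20)) {
    zb <- as.matrix(base[base$time_of_day_h == tod, paste0("z", 1:2)])
    zf <- as.matrix(fixed[fixed$time_of_day_h == tod, paste0("z", 1:2)])
    expect_lt(max(abs(colMeans(zb) - colMeans(zf))), 0.1)
  }
})

test_that("days without clamping targets are skipped with a warning", {
  m <- constant_dev_model(k = 2)
  obs <- data.frame(bird_id = "b", syllable_id = "s",
                    age_dph = c(70.5, 71.5), time_of_day_h = 12,
                    day_index = c(70, 71))
  tg <- data.frame(day_index = 70, target_det = 1)
  expect_warning(out <- simulate_development(m, obs, "fixed_entropy",
                                             seed = 1, targets = tg),
                 "skipped")
  expect_equal(out$day_index, 70)
})
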