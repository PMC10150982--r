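make_pred <- function(day, tod_frac, values, bird = "b1", syll = "s1",
                      condition = NULL) {
  df <- data.frame(bird_id = bird, syllable_id = syll,
                   age_dph = day + tod_frac, day_index = day,
                   time_of_day_h = tod_frac * 24,
                   predicted_age = values)
  if (!is.null(condition)) df$condition <- condition
  df
}

test_that("bins anchor at midnight, interpolate quantiles, drop small bins", {
  df <- make_pred(70, rep(0.55, 100), 1:100)   # one bin [70.5, 70.6)
  b <- bin_and_quantile(df)
  expect_equal(unique(b$bin_start), 70.5)
  expect_equal(unique(b$bin_end), 70.6)
  # brute-force type-7 order statistics on 1..100
  expect_equal(b$value[b$level == 50], 50.5)
  expect_equal(b$value[b$level == 1], 1.99)  # x1 + 0.99*(x2 - x1)
  expect_equal(b$value[b$level == 99], 99.01)
  # 29 renditions: dropped
  expect_equal(nrow(bin_and_quantile(make_pred(70, rep(0.55, 29), 1:29))), 0)
  # 30 renditions: retained
  expect_equal(nrow(bin_and_quantile(make_pred(70, rep(0.55, 30), 1:30))),
               7)
  # all values equal c: every level equals c
  bc <- bin_and_quantile(make_pred(70, rep(0.3, 40), rep(3.14, 40)))
  expect_true(all(bc$value == 3.14))
  # quantile monotonicity within a bin
  set.seed(1)
  br <- bin_and_quantile(make_pred(70, rep(0.3, 200), rnorm(200)))
  expect_true(all(diff(br$value) >= 0))
})

test_that("overnight shifts subtract last-evening from first-morning bins", {
  evening <- make_pred(70, rep(0.85, 50), 1:50)
  morning <- make_pred(71, rep(0.35, 50), 1:50 + 1)
  b <- bin_and_quantile(rbind(evening, morning))
  rec <- overnight_shifts(b)
  expect_equal(nrow(rec), 7)
  expect_true(all(abs(rec$shift - 1) < 1e-12))
  expect_equal(unique(rec$day_from), 70)
  # identical distributions: all shifts zero
  rec0 <- overnight_shifts(bin_and_quantile(rbind(
    evening, make_pred(71, rep(0.35, 50), 1:50))))
  expect_true(all(rec0$shift == 0))
  # adding a constant to all predicted ages changes no shift
  shifted_df <- rbind(evening, morning)
  shifted_df$predicted_age <- shifted_df$predicted_age + 42
  rec42 <- overnight_shifts(bin_and_quantile(shifted_df))
  expect_equal(rec42$shift, rec$shift, tolerance = 1e-12)
})

test_that("the 0.6-day gap rule fires on constructed edge cases", {
  # evening bin ends 19:12 (0.8 d), morning bin starts 07:12 next day
  # (1.3 d): gap 0.5 d -> retained
  near <- rbind(make_pred(70, rep(0.75, 40), rnorm(40)),
                make_pred(71, rep(0.35, 40), rnorm(40)))
  expect_equal(nrow(overnight_shifts(bin_and_quantile(near))), 7)
  # evening bin ends 14:24 (0.6 d); morning starts 07:12 (+1.3): gap 0.7 d
  far <- rbind(make_pred(70, rep(0.55, 40), rnorm(40)),
               make_pred(71, rep(0.35, 40), rnorm(40)))
  expect_equal(nrow(overnight_shifts(bin_and_quantile(far))), 0)
  # exactly 0.6 d is retained ("more than 0.6 days" is discarded)
  edge <- rbind(make_pred(70, rep(0.65, 40), rnorm(40)),
                make_pred(71, rep(0.35, 40), rnorm(40)))
  expect_equal(nrow(overnight_shifts(bin_and_quantile(edge))), 7)
  # missing morning bin: pair skipped
  gap2 <- rbind(make_pred(70, rep(0.85, 40), rnorm(40)),
                make_pred(72, rep(0.35, 40), rnorm(40)))
  expect_equal(nrow(overnight_shifts(bin_and_quantile(gap2))), 0)
})

test_that("noise-free records are recovered exactly by the shift LMM", {
  recs <- make_shift_records(n_birds = 3, syll_per_bird = 2, n_pairs = 5,
                             sd_bird = c(0, 0), sd_syll = c(0, 0),
                             sd_noise = 0, intercept = -0.8, slope = 2.0)
  fit <- fit_shift_lmm(recs)
  expect_equal(fit$fixed$estimate, c(-0.8, 2.0), tolerance = 1e-6)
  # 3-level binning on linear records gives the same slope
  fit3 <- fit_shift_lmm(recs[recs$level %in% c(1, 50, 99), ])
  expect_equal(fit3$fixed$estimate[2], 2.0, tolerance = 1e-6)
})

test_that("the condition contrast is null when conditions are identical", {
  base <- make_shift_records(n_birds = 3, syll_per_bird = 2, n_pairs = 10,
                             sd_noise = 0.1, seed = 4)
  base$condition <- "baseline"
  fixed <- base
  fixed$condition <- "fixed_entropy"
  fit <- fit_shift_lmm(rbind(base, fixed), with_condition = TRUE)
  est <- fit$fixed
  expect_lt(abs(est$estimate[est$term == "conditionfixed_entropy"]), 1e-6)
  expect_lt(abs(est$estimate[est$term ==
                               "percentile:conditionfixed_entropy"]), 1e-6)
  expect_error(fit_shift_lmm(base, with_condition = TRUE), "requires both")
})

test_that("level estimates follow the fitted fixed effects", {
  recs <- make_shift_records(seed = 6, sd_noise = 0.5)
  fit <- fit_shift_lmm(recs)
  le <- shift_level_estimates(fit, levels = c(1, 50, 99))
  co <- fit$fixed$estimate
  expect_equal(le$estimate, co[1] + co[2] * c(0.01, 0.5, 0.99),
               tolerance = 1e-8)
  expect_true(all(le$se > 0))
})

test_that("single-level grouping falls back to a reduced structure", {
  recs <- make_shift_records(n_birds = 1, syll_per_bird = 3, n_pairs = 10,
                             sd_noise = 0.3, seed = 7)
  fit <- fit_shift_lmm(recs)
  expect_true(fit$reduced_random_effects)
  expect_equal(nrow(fit$fixed), 2)
})

test_that("alternative binnings agree on clean linear data", {
  recs <- make_shift_records(seed = 8, sd_noise = 0.3)
  recs$predicted_age <- NULL
  # build renditions whose binned quantiles are exactly linear in percentile:
  # use a uniform sample, whose type-7 quantiles are linear in p
  df <- do.call(rbind, lapply(1:6, function(day) {
    rbind(make_pred(60 + day, rep(0.8, 101), seq(0, 1, by = 0.01)),
          make_pred(61 + day, rep(0.35, 101), seq(0, 1, by = 0.01) + 0.2))
  }))
  fits <- alternative_binnings(df)
  expect_named(fits, c("3", "7", "11"))
  for (f in fits)
    expect_equal(f$fixed$estimate, c(0.2, 0), tolerance = 1e-6)
  expect_error(alternative_binnings(df, level_sets = list()), "empty")
  expect_error(alternative_binnings(df, level_sets = list(a = numeric(0))),
               "empty")
})

test_that("noisy mixed-effects fixed effects are recovered within CIs", {
  recs <- make_shift_records(seed = 9)
  fit <- fit_shift_lmm(recs)
  est <- fit$fixed
  for (i in 1:2) {
    truth <- c(-0.8, 2.0)[i]
    expect_lt(abs(est$estimate[i] - truth), 3 * est$se[i] + 0.3)
  }
  expect_lt(est$p[est$term == "percentile"], 0.05)
})
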