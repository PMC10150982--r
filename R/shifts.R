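#' Time-binned predicted-age quantiles
#'
#' Bins renditions by production age on a grid of `bin_width`-day bins
#' anchored at midnight (integer dph), computes the empirical predicted-age
#' quantiles at each percentile level (type-7 linear interpolation by
#' default) and drops bins with fewer than `min_n` renditions.
#'
#' @param renditions data frame with `predicted_age`, `age_dph`,
#'   `day_index`, `bird_id`, `syllable_id` (and optionally `condition`).
#' @param bin_width bin width in days.
#' @param levels percentile levels (0-100).
#' @param min_n minimum renditions per retained bin.
#' @param quantile_type quantile estimator type passed to [stats::quantile()].
#' @return Long data frame: one row per retained bin x level with
#'   `bin_start`, `bin_end`, `n`, `level`, `value` (and `condition` if
#'   present).
#' @export
bin_and_quantile <- function(renditions, bin_width = 0.1,
                             levels = c(1, 5, 25, 50, 75, 95, 99),
                             min_n = 30, quantile_type = 7) {
  stopifnot(length(levels) > 0, all(levels >= 0 & levels <= 100))
  df <- renditions
  if (!"predicted_age" %in% names(df)) stop("`predicted_age` column required")
  if (!"condition" %in% names(df)) df$condition <- "real"
  bin <- floor(df$age_dph / bin_width + 1e-9)
  key <- interaction(df$bird_id, df$syllable_id, df$condition, bin, drop = TRUE)
  pieces <- split(seq_len(nrow(df)), key)
  out <- lapply(pieces, function(rows) {
    if (length(rows) < min_n) return(NULL)
    b <- bin[rows[1]]
    qs <- quantile(df$predicted_age[rows], probs = levels / 100,
                   type = quantile_type, names = FALSE)
    data.frame(bird_id = df$bird_id[rows[1]],
               syllable_id = df$syllable_id[rows[1]],
               condition = df$condition[rows[1]],
               day_index = floor(b * bin_width + 1e-9),
               bin_start = b * bin_width,
               bin_end = (b + 1) * bin_width,
               n = length(rows), level = levels, value = qs,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  if (is.null(res))
    res <- data.frame(bird_id = character(), syllable_id = character(),
                      condition = character(), day_index = integer(),
                      bin_start = numeric(), bin_end = numeric(),
                      n = integer(), level = numeric(), value = numeric())
  res <- res[order(res$bird_id, res$syllable_id, res$condition, res$bin_start,
                   res$level), ]
  rownames(res) <- NULL
  res
}

#' Percentile-wise overnight shifts in predicted age
#'
#' For each consecutive day pair (j, j+1) of a syllable, subtracts each
#' percentile of the last retained bin of day j from the same percentile of
#' the first retained bin of day j+1. Pairs whose bins are separated by more
#' than `max_gap` days (first-bin start minus last-bin end) are discarded.
#'
#' @param bins output of [bin_and_quantile()].
#' @param max_gap maximum allowed separation in days.
#' @return Data frame of shift records: one row per (syllable, day pair,
#'   level) with `shift` (days), `gap`, `percentile` (level/100) and the
#'   `condition` tag.
#' @export
overnight_shifts <- function(bins, max_gap = 0.6) {
  if (nrow(bins) == 0) return(empty_shifts())
  key <- interaction(bins$bird_id, bins$syllable_id, bins$condition,
                     drop = TRUE)
  out <- lapply(split(seq_len(nrow(bins)), key), function(rows) {
    b <- bins[rows, , drop = FALSE]
    days <- sort(unique(b$day_index))
    recs <- lapply(days[-length(days)], function(j) {
      if (!(j + 1) %in% days) return(NULL)
      dj <- b[b$day_index == j, ]
      dj1 <- b[b$day_index == j + 1, ]
      last <- dj[dj$bin_start == max(dj$bin_start), ]
      first <- dj1[dj1$bin_start == min(dj1$bin_start), ]
      gap <- first$bin_start[1] - last$bin_end[1]
      if (gap > max_gap) return(NULL)
      lv <- sort(intersect(last$level, first$level))
      data.frame(bird_id = b$bird_id[1], syllable_id = b$syllable_id[1],
                 condition = b$condition[1], day_from = j, day_to = j + 1,
                 level = lv, percentile = lv / 100,
                 shift = first$value[match(lv, first$level)] -
                   last$value[match(lv, last$level)],
                 gap = gap, stringsAsFactors = FALSE)
    })
    do.call(rbind, recs)
  })
  res <- do.call(rbind, out)
  if (is.null(res)) return(empty_shifts())
  rownames(res) <- NULL
  res
}

empty_shifts <- function()
  data.frame(bird_id = character(), syllable_id = character(),
             condition = character(), day_from = integer(),
             day_to = integer(), level = numeric(), percentile = numeric(),
             shift = numeric(), gap = numeric())

#' Mixed-effects model of overnight shifts on percentile
#'
#' Fits `shift ~ 1 + percentile` (percentile on \[0, 1\]) with correlated
#' random intercepts and slopes at the bird and syllable levels. With
#' `with_condition = TRUE` the fixed part becomes
#' `shift ~ percentile * condition` (condition: baseline vs fixed_entropy)
#' and the full interaction enters the random effects, matching the
#' simulation contrast analysis. Missing grouping levels trigger an
#' automatic fallback to a reduced random-effects structure, flagged in the
#' result.
#'
#' @param records shift records from [overnight_shifts()].
#' @param with_condition include the entropy-condition contrast.
#' @return Object of class `songdev_lmm`.
#' @export
fit_shift_lmm <- function(records, with_condition = FALSE) {
  df <- data.frame(shift = records$shift, percentile = records$percentile,
                   bird = factor(records$bird_id),
                   syllable = factor(records$syllable_id))
  if (with_condition) {
    if (length(unique(records$condition)) < 2)
      stop("with_condition requires both baseline and fixed_entropy records")
    df$condition <- factor(records$condition,
                           levels = c("baseline", "fixed_entropy"))
    fit_songdev_lmm("shift ~ percentile * condition",
                    "percentile * condition", df, response = "shift")
  } else {
    fit_songdev_lmm("shift ~ percentile", "percentile", df,
                    response = "shift")
  }
}

#' Estimated shift (with test) at given percentile levels
#'
#' Linear combinations of the fixed effects of a [fit_shift_lmm()] fit,
#' giving the model-implied mean overnight shift at each percentile level
#' (optionally within one entropy condition), with Satterthwaite-based t
#' tests against zero.
#'
#' @param lmm a `songdev_lmm` from [fit_shift_lmm()].
#' @param levels percentile levels (0-100).
#' @param condition for condition-contrast fits, `"baseline"` or
#'   `"fixed_entropy"`.
#' @param df_method `"residual"` (default) tests Wald contrasts against a t
#'   distribution with residual degrees of freedom, the convention of the
#'   coefficient tests this analysis mirrors; `"satterthwaite"` uses the
#'   Satterthwaite approximation instead.
#' @return Data frame with `level`, `estimate`, `se`, `df`, `p`.
#' @export
shift_level_estimates <- function(lmm, levels = c(1, 5, 25, 50, 75, 95, 99),
                                  condition = NULL,
                                  df_method = c("residual", "satterthwaite")) {
  stopifnot(inherits(lmm, "songdev_lmm"))
  df_method <- match.arg(df_method)
  terms <- lmm$fixed$term
  rows <- lapply(levels, function(lv) {
    q <- lv / 100
    L <- stats::setNames(numeric(length(terms)), terms)
    L["(Intercept)"] <- 1
    L["percentile"] <- q
    if (!is.null(condition) && condition == "fixed_entropy") {
      L["conditionfixed_entropy"] <- 1
      L["percentile:conditionfixed_entropy"] <- q
    }
    if (inherits(lmm$fit, "lmerModLmerTest") &&
        df_method == "satterthwaite") {
      ct <- lmerTest::contest1D(lmm$fit, L, confint = FALSE)
      data.frame(level = lv, estimate = ct$Estimate, se = ct$`Std. Error`,
                 df = ct$df, p = ct$`Pr(>|t|)`)
    } else {
      est <- sum(L * lmm$fixed$estimate)
      V <- as.matrix(vcov(lmm$fit))
      se <- sqrt(drop(t(L) %*% V %*% L))
      dfree <- if (inherits(lmm$fit, "merMod"))
        lmm$n_obs - length(terms) else lmm$fit$df.residual
      data.frame(level = lv, estimate = est, se = se, df = dfree,
                 p = 2 * stats::pt(abs(est / se), dfree, lower.tail = FALSE))
    }
  })
  do.call(rbind, rows)
}

#' Robustness of the shift analysis to percentile binning
#'
#' Recomputes quantile bins, overnight shifts and the mixed-effects fit for
#' several percentile level sets (3, 7 and 11 levels by default, the
#' standard alternatives).
#'
#' @param renditions predicted-age rendition data frame (see
#'   [bin_and_quantile()]).
#' @param level_sets named list of percentile level vectors.
#' @param with_condition passed to [fit_shift_lmm()].
#' @param ... passed to [bin_and_quantile()] / [overnight_shifts()]
#'   (`bin_width`, `min_n`, `max_gap`).
#' @return Named list of `songdev_lmm` fits, one per level set.
#' @export
alternative_binnings <- function(renditions,
                                 level_sets = list(
                                   `3` = c(1, 50, 99),
                                   `7` = c(1, 5, 25, 50, 75, 95, 99),
                                   `11` = c(1, 5, 15, 25, 40, 50, 60, 75, 85,
                                            95, 99)),
                                 with_condition = FALSE,
                                 bin_width = 0.1, min_n = 30, max_gap = 0.6) {
  if (length(level_sets) == 0) stop("empty level set")
  lapply(level_sets, function(lv) {
    if (length(lv) == 0) stop("empty level set")
    bins <- bin_and_quantile(renditions, bin_width = bin_width, levels = lv,
                             min_n = min_n)
    recs <- overnight_shifts(bins, max_gap = max_gap)
    fit_shift_lmm(recs, with_condition = with_condition)
  })
}
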