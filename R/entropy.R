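#' Differential entropy of a multivariate Gaussian
#'
#' `0.5 * log(det(Sigma)) + (k/2) * (1 + log(2*pi))` in nats.
#'
#' @param Sigma symmetric positive-definite covariance matrix.
#' @param k dimension; defaults to `nrow(Sigma)`.
#' @return Entropy in nats.
#' @export
gaussian_entropy <- function(Sigma, k = nrow(Sigma)) {
  Sigma <- as.matrix(Sigma)
  stopifnot(nrow(Sigma) == k, ncol(Sigma) == k)
  C <- tryCatch(chol(Sigma),
                error = function(e) stop("Sigma is not positive definite"))
  sum(log(diag(C))) + gauss_entropy_const(k)
}

#' Query-time grid with singing-support filter
#'
#' Generates query times at `interval_min`-minute intervals inside the
#' lights-on window of every day a syllable was recorded, and keeps only
#' times whose centred `window_min`-minute window (closed bounds) contains at
#' least `min_count` training renditions of that syllable on that day.
#'
#' @param renditions training-side rendition data frame (one syllable).
#' @param day_window lights-on/lights-off hours.
#' @param interval_min grid spacing in minutes.
#' @param window_min support window width in minutes.
#' @param min_count minimum renditions in the window.
#' @return Data frame with `day_index`, `time_of_day_h`, `age_dph` (day +
#'   hours/24) and `n_support`; zero rows when nothing qualifies.
#' @export
sample_query_times <- function(renditions, day_window = c(7, 21),
                               interval_min = 5, window_min = 30,
                               min_count = 30) {
  if (nrow(renditions) == 0)
    return(data.frame(day_index = integer(), time_of_day_h = numeric(),
                      age_dph = numeric(), n_support = integer()))
  grid_h <- seq(day_window[1], day_window[2], by = interval_min / 60)
  half <- window_min / 120  # half-window in hours
  out <- lapply(sort(unique(renditions$day_index)), function(day) {
    tod <- renditions$time_of_day_h[renditions$day_index == day]
    n_sup <- vapply(grid_h, function(t)
      sum(tod >= t - half & tod <= t + half), 0L)
    keep <- which(n_sup >= min_count)
    data.frame(day_index = rep(day, length(keep)), time_of_day_h = grid_h[keep],
               age_dph = day + grid_h[keep] / 24, n_support = n_sup[keep])
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Entropy trajectory of a fitted density model
#'
#' Evaluates the model covariance at each retained query time and summarises
#' it by its differential entropy (and determinant).
#'
#' @param model a `dev_model`.
#' @param query_times data frame from [sample_query_times()].
#' @return The query-time data frame with added `entropy` (nats), `det`
#'   columns and the model's bird/syllable identifiers.
#' @export
entropy_trajectory <- function(model, query_times) {
  qt <- query_times
  if (nrow(qt) == 0) {
    qt$entropy <- numeric(0); qt$det <- numeric(0); qt$k <- integer(0)
    qt$bird_id <- character(0); qt$syllable_id <- character(0)
    return(qt)
  }
  o <- dev_forward_params(model, qt$age_dph, qt$time_of_day_h)
  ent <- numeric(nrow(qt)); dets <- numeric(nrow(qt))
  for (i in seq_len(nrow(qt))) {
    S <- assemble_sigma(o$l[i, ], o$d[i, ], model$k, model$eps)$Sigma
    C <- chol(S)
    ld <- 2 * sum(log(diag(C)))
    ent[i] <- 0.5 * ld + gauss_entropy_const(model$k)
    dets[i] <- exp(ld)
  }
  qt$entropy <- ent
  qt$det <- dets
  qt$k <- model$k
  qt$bird_id <- model$bird_id %||% NA_character_
  qt$syllable_id <- model$syllable_id %||% NA_character_
  qt
}

#' Mixed-effects model of entropy on time of day
#'
#' Fits `entropy ~ 1 + timeOfDay` with correlated random intercepts and
#' slopes at the bird and syllable levels (`tod_only`), or adds a main effect
#' of age and an age-by-time-of-day interaction with the full random-effect
#' structure (`tod_by_age`). Time of day is in hours (slopes in nats/hour);
#' age is centred at its mean for the interaction variant.
#'
#' @param samples entropy samples (rows from [entropy_trajectory()] pooled
#'   across syllables) with columns `entropy`, `time_of_day_h`, `age_dph`,
#'   `bird_id`, `syllable_id`.
#' @param variant `"tod_only"` or `"tod_by_age"`.
#' @return Object of class `songdev_lmm`.
#' @export
fit_entropy_lmm <- function(samples, variant = c("tod_only", "tod_by_age")) {
  variant <- match.arg(variant)
  df <- data.frame(entropy = samples$entropy,
                   timeOfDay = samples$time_of_day_h,
                   age = samples$age_dph - mean(samples$age_dph),
                   bird = factor(samples$bird_id),
                   syllable = factor(samples$syllable_id))
  fixed <- if (variant == "tod_only") "entropy ~ timeOfDay"
           else "entropy ~ timeOfDay * age"
  re_term <- if (variant == "tod_only") "timeOfDay" else "timeOfDay * age"
  fit_songdev_lmm(fixed, re_term, df, response = "entropy")
}

# Shared LMM fitting with graceful degradation of the grouping structure.
fit_songdev_lmm <- function(fixed, re_term, df, response) {
  terms <- character(0)
  if (nlevels(df$bird) >= 2) terms <- c(terms, sprintf("(1 + %s | bird)", re_term))
  if (nlevels(df$syllable) >= 2)
    terms <- c(terms, sprintf("(1 + %s | syllable)", re_term))
  reduced <- length(terms) < 2
  singular <- FALSE; converged <- TRUE; messages <- character(0)
  if (length(terms) == 0) {
    fit <- stats::lm(stats::as.formula(fixed), data = df)
    cf <- withCallingHandlers(
      summary(fit)$coefficients,
      warning = function(w) {  # e.g. "essentially perfect fit"
        messages <<- c(messages, conditionMessage(w))
        invokeRestart("muffleWarning")
      })
    fe <- data.frame(term = rownames(cf), estimate = cf[, 1], se = cf[, 2],
                     df = fit$df.residual, t = cf[, 3], p = cf[, 4],
                     row.names = NULL)
    return(structure(list(formula = fixed, fixed = fe, fit = fit,
                          n_obs = nrow(df), singular = FALSE,
                          converged = TRUE, reduced_random_effects = TRUE,
                          messages = c(messages,
                            "no grouping factors; ordinary least squares")),
                     class = "songdev_lmm"))
  }
  form <- stats::as.formula(paste(fixed, "+", paste(terms, collapse = " + ")))
  fit <- withCallingHandlers(
    lmerTest::lmer(form, data = df, REML = FALSE,
                   control = lme4::lmerControl(check.conv.singular =
                     lme4::.makeCC(action = "message", tol = 1e-4))),
    message = function(m) {
      messages <<- c(messages, conditionMessage(m)); invokeRestart("muffleMessage")
    },
    warning = function(w) {
      messages <<- c(messages, conditionMessage(w))
      if (grepl("converge", conditionMessage(w), ignore.case = TRUE))
        converged <<- FALSE
      invokeRestart("muffleWarning")
    })
  singular <- lme4::isSingular(fit, tol = 1e-4)
  cf <- summary(fit)$coefficients
  fe <- data.frame(term = rownames(cf), estimate = cf[, "Estimate"],
                   se = cf[, "Std. Error"], df = cf[, "df"],
                   t = cf[, "t value"], p = cf[, "Pr(>|t|)"],
                   row.names = NULL)
  structure(list(formula = deparse1(form), fixed = fe, fit = fit,
                 n_obs = nrow(df),
                 ranef_vcov = lme4::VarCorr(fit),
                 singular = singular, converged = converged,
                 reduced_random_effects = reduced, messages = messages),
            class = "songdev_lmm")
}

#' @export
print.songdev_lmm <- function(x, digits = 4, ...) {
  cat("<songdev_lmm> ", x$formula, "\n", sep = "")
  cat(sprintf("  n = %d%s%s\n", x$n_obs,
              if (x$singular) ", singular fit" else "",
              if (!x$converged) ", DID NOT CONVERGE" else ""))
  print(format(x$fixed, digits = digits), row.names = FALSE)
  invisible(x)
}

#' Daily minimum covariance determinant (entropy-clamping target)
#'
#' For each day, the minimum `det(Sigma)` of the model over that day's
#' retained query times. Used as the per-day target determinant for the
#' fixed-entropy counterfactual.
#'
#' @param model a `dev_model`.
#' @param query_times data frame from [sample_query_times()].
#' @return Data frame with `day_index` and `target_det`.
#' @export
daily_min_det <- function(model, query_times) {
  if (nrow(query_times) == 0)
    return(data.frame(day_index = integer(), target_det = numeric()))
  traj <- entropy_trajectory(model, query_times)
  agg <- stats::aggregate(det ~ day_index, data = traj, FUN = min)
  names(agg)[2] <- "target_det"
  agg
}

#' Clamp a covariance to a target determinant, preserving allocation
#'
#' Eigendecomposes `Sigma = Q Lambda Q'` and divides every eigenvalue by
#' `(det(Sigma)/target_det)^(1/k)`, so the result has determinant exactly
#' `target_det` while keeping the eigenvectors and the eigenvalue ratios
#' (the allocation of variation) unchanged. The entropy of the result is
#' `0.5*log(target_det) + (k/2)*(1+log(2*pi))`.
#'
#' @param Sigma symmetric positive-definite matrix.
#' @param target_det positive target determinant.
#' @return The rescaled covariance matrix.
#' @export
fix_entropy <- function(Sigma, target_det) {
  stopifnot(is.numeric(target_det), length(target_det) == 1, target_det > 0)
  e <- eigen(Sigma, symmetric = TRUE)
  if (any(e$values <= 0)) stop("Sigma is not positive definite")
  k <- length(e$values)
  ratio <- exp(sum(log(e$values)) - log(target_det))
  scaled <- e$values / ratio^(1 / k)
  e$vectors %*% (scaled * t(e$vectors))
}

#' Simulate development by sampling the fitted model
#'
#' Draws one latent sample per observation time: at each held-out production
#' time the model covariance is evaluated (and, in `"fixed_entropy"` mode,
#' first clamped with [fix_entropy()] to that day's minimum determinant from
#' [daily_min_det()]), then a single rendition is sampled. Simulated
#' renditions carry the original timestamps. Draws use per-observation seed
#' substreams, so any subset reproduces independently.
#'
#' @param model a `dev_model`.
#' @param observations held-out rendition data frame supplying the
#'   production times (`age_dph`, `time_of_day_h`, `day_index`, ids).
#' @param mode `"baseline"` or `"fixed_entropy"`.
#' @param seed RNG seed.
#' @param targets per-day target determinants (from [daily_min_det()]);
#'   required for `"fixed_entropy"` unless `query_times` is given.
#' @param query_times alternative to `targets`: training-side query times
#'   from which targets are computed.
#' @return Data frame like `observations` but with simulated latent columns
#'   and a `condition` column; observations on days without a clamping
#'   target are dropped with a warning.
#' @export
simulate_development <- function(model, observations,
                                 mode = c("baseline", "fixed_entropy"),
                                 seed = 1L, targets = NULL,
                                 query_times = NULL) {
  mode <- match.arg(mode)
  obs <- observations
  if (mode == "fixed_entropy") {
    if (is.null(targets)) {
      if (is.null(query_times))
        stop("fixed_entropy mode needs `targets` or `query_times`")
      targets <- daily_min_det(model, query_times)
    }
    keep <- obs$day_index %in% targets$day_index
    if (any(!keep)) {
      warning(sum(!keep), " observation(s) on days without a clamping ",
              "target were skipped")
      obs <- obs[keep, , drop = FALSE]
    }
    tmap <- stats::setNames(targets$target_det, targets$day_index)
  }
  o <- dev_forward_params(model, obs$age_dph, obs$time_of_day_h)
  k <- model$k
  Z <- matrix(NA_real_, nrow(obs), k)
  for (i in seq_len(nrow(obs))) {
    S <- assemble_sigma(o$l[i, ], o$d[i, ], k, model$eps)$Sigma
    if (mode == "fixed_entropy")
      S <- fix_entropy(S, tmap[[as.character(obs$day_index[i])]])
    u <- with_seed(substream_seed(seed, i), rnorm(k))
    Z[i, ] <- o$mu[i, ] + drop(crossprod(chol(S), u))
  }
  keep <- c("bird_id", "syllable_id", "age_dph", "time_of_day_h", "day_index")
  keep <- intersect(keep, names(obs))
  out <- cbind(obs[keep], as.data.frame(Z))
  names(out)[-seq_along(keep)] <- paste0("z", seq_len(k))
  out$condition <- mode
  rownames(out) <- NULL
  out
}
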