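#' Ground-truth parameters for the synthetic development generator
#'
#' Defines a population of juvenile birds whose syllable renditions live in a
#' per-syllable k-dimensional latent space. Each syllable is a Gaussian
#' cluster whose mean drifts smoothly along a developmental trajectory and
#' whose covariance follows a deterministic entropy schedule: a linear
#' within-day decline (morning variability higher than evening) plus a linear
#' trend across development, realised by isotropic scaling of a fixed-shape,
#' slowly rotating eigenvalue spectrum. The mean advances with cumulative
#' *daytime* (singing) hours and is flat overnight, so the generator encodes
#' developmental consolidation with no net overnight regression of the mean.
#'
#' @param n_birds number of birds.
#' @param syllables_per_bird integer vector (recycled over birds) of syllable
#'   counts; the default gives 13 syllables across 5 birds.
#' @param k latent dimensionalities, recycled across syllables in order.
#' @param age_range two ages in days post hatch (dph); renditions are
#'   produced on days `floor(age_range[1]) .. floor(age_range[2]) - 1`.
#' @param day_window lights-on and lights-off hours; renditions are produced
#'   uniformly inside this window.
#' @param mean_displacement total latent-space displacement of the syllable
#'   mean over the full age range (latent units).
#' @param mean_curvature amplitude (latent units) of a transverse sinusoidal
#'   bulge making the developmental trajectory non-linear; 0 gives a straight
#'   line.
#' @param entropy_base differential entropy (nats) at the reference time
#'   (mid-age, mid-day). `NULL` derives it per syllable from `sigma_drift`.
#' @param sigma_drift when `entropy_base` is `NULL`, the rendition standard
#'   deviation (latent units) along the drift direction at the reference
#'   time; sets the overall noise scale.
#' @param entropy_day_amplitude total within-day linear entropy decline, in
#'   nats from lights-on to lights-off.
#' @param entropy_dev_slope entropy trend across development, nats per day.
#' @param eigen_decay ratio between consecutive eigenvalues of the
#'   covariance spectrum (allocation shape).
#' @param rotation_deg_per_day rotation rate of the eigenbasis in the plane
#'   of its two leading directions, degrees per day.
#' @param renditions_per_day renditions produced per syllable per day.
#' @param syllable_heterogeneity log-scale standard deviation of
#'   per-syllable multipliers applied to the within-day entropy amplitude,
#'   the noise scale and the mean displacement. Real syllable types differ
#'   substantially in how variable they are and how fast they change; this
#'   spread is what the bird- and syllable-level random effects in the
#'   downstream mixed models are there to absorb. 0 gives identical
#'   schedules for every syllable.
#' @param seed master seed; per-(bird, syllable) substreams are derived from
#'   it so subsets regenerate independently.
#'
#' @return An object of class `gt_params`.
#' @export
ground_truth_params <- function(n_birds = 5,
                                syllables_per_bird = c(3, 3, 3, 2, 2),
                                k = 6:8,
                                age_range = c(60, 95),
                                day_window = c(7, 21),
                                mean_displacement = 5,
                                mean_curvature = 0.5,
                                entropy_base = NULL,
                                sigma_drift = 0.55,
                                entropy_day_amplitude = 1.0,
                                entropy_dev_slope = -0.033,
                                eigen_decay = 0.75,
                                rotation_deg_per_day = 2,
                                renditions_per_day = 1000,
                                syllable_heterogeneity = 0.3,
                                seed = 1L) {
  stopifnot(n_birds >= 1, all(k >= 1), length(age_range) == 2,
            age_range[1] < age_range[2], length(day_window) == 2,
            day_window[1] < day_window[2], renditions_per_day >= 1,
            eigen_decay > 0, sigma_drift > 0, syllable_heterogeneity >= 0)
  p <- list(
    n_birds = as.integer(n_birds),
    syllables_per_bird = as.integer(rep_len(syllables_per_bird, n_birds)),
    k = as.integer(k),
    age_range = as.numeric(age_range),
    day_window = as.numeric(day_window),
    mean_displacement = mean_displacement,
    mean_curvature = mean_curvature,
    entropy_base = entropy_base,
    sigma_drift = sigma_drift,
    entropy_day_amplitude = entropy_day_amplitude,
    entropy_dev_slope = entropy_dev_slope,
    eigen_decay = eigen_decay,
    rotation_deg_per_day = rotation_deg_per_day,
    renditions_per_day = as.integer(renditions_per_day),
    syllable_heterogeneity = syllable_heterogeneity,
    seed = as.integer(seed)
  )
  class(p) <- "gt_params"
  validate_gt_params(p)
  p
}

# Reject parameter sets whose implied covariances degenerate numerically at
# any corner of the generated (age, time-of-day) range.
validate_gt_params <- function(p) {
  corners <- expand.grid(age = p$age_range, tod = p$day_window)
  for (b in seq_len(p$n_birds)) {
    for (s in seq_len(p$syllables_per_bird[b])) {
      spec <- syllable_spec(p, b, s)
      for (i in seq_len(nrow(corners))) {
        ev <- true_eigenvalues_at(p, spec, corners$age[i], corners$tod[i])
        if (any(ev <= 1e-12)) {
          stop(sprintf(
            "implied covariance not positive definite for %s at age %.1f dph, %.1f h (min eigenvalue %.3g); raise entropy_base",
            spec$syllable_id, corners$age[i], corners$tod[i], min(ev)))
        }
      }
    }
  }
  invisible(p)
}

# Global (across birds) syllable index, used to cycle k and derive seeds.
syllable_index <- function(p, bird, syllable) {
  prior <- if (bird > 1) sum(p$syllables_per_bird[seq_len(bird - 1)]) else 0L
  prior + syllable
}

#' @export
print.gt_params <- function(x, ...) {
  cat(sprintf(
    "<gt_params> %d birds, %d syllables, ages %.0f-%.0f dph, lights %g-%g h\n",
    x$n_birds, sum(x$syllables_per_bird), x$age_range[1], x$age_range[2],
    x$day_window[1], x$day_window[2]))
  cat(sprintf(
    "  entropy: day amplitude %.2f nats, dev slope %+.3f nats/day; %d renditions/day, seed %d\n",
    x$entropy_day_amplitude, x$entropy_dev_slope, x$renditions_per_day, x$seed))
  invisible(x)
}

# Deterministic per-syllable structure: dimensionality, base orientation,
# normalised spectrum (det = 1), cluster offset and entropy offset.
syllable_spec <- function(p, bird, syllable) {
  idx <- syllable_index(p, bird, syllable)
  k <- p$k[((idx - 1) %% length(p$k)) + 1]
  spectrum <- p$eigen_decay^(seq_len(k) - 1)
  spectrum <- spectrum / exp(mean(log(spectrum)))  # det = 1
  h <- p$syllable_heterogeneity %||% 0
  with_seed(substream_seed(p$seed, idx), {
    Q0 <- random_orthogonal(k)
    mu0 <- rnorm(k, sd = 4)
    mult <- exp(rnorm(3, sd = h))  # amplitude, noise scale, displacement
  })
  sigma_drift <- p$sigma_drift * mult[2]
  base <- p$entropy_base %||%
    (gauss_entropy_const(k) + (k / 2) * log(sigma_drift^2 / spectrum[1]))
  list(
    bird_id = sprintf("bird%02d", bird),
    syllable_id = sprintf("bird%02d_syl%d", bird, syllable),
    index = idx, k = k, Q0 = Q0, mu0 = mu0,
    spectrum = spectrum, entropy_base = base,
    day_amplitude = p$entropy_day_amplitude * mult[1],
    displacement = p$mean_displacement * mult[3]
  )
}

# Table of all syllables implied by a parameter set.
syllable_table <- function(p) {
  rows <- list()
  for (b in seq_len(p$n_birds)) {
    for (s in seq_len(p$syllables_per_bird[b])) {
      spec <- syllable_spec(p, b, s)
      rows[[length(rows) + 1]] <- data.frame(
        bird_id = spec$bird_id, syllable_id = spec$syllable_id,
        bird = b, syllable = s, k = spec$k,
        entropy_base = spec$entropy_base,
        day_amplitude = spec$day_amplitude,
        displacement = spec$displacement, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

# Developmental progress in [0, 1]: cumulative practice. Each lights-on day
# contributes one unit, accrued along a quintic smootherstep profile of the
# day fraction (learning rate ~0 right after lights-on and before
# lights-off, peaking midday, flat overnight), so the mean neither
# regresses nor advances between evening song and next-morning song.
dev_progress <- function(p, age) {
  day0 <- floor(p$age_range[1])
  n_days <- floor(p$age_range[2]) - day0
  day <- floor(age)
  tod <- (age - day) * 24
  u <- pmin(pmax((tod - p$day_window[1]) /
                   (p$day_window[2] - p$day_window[1]), 0), 1)
  frac <- u^3 * (6 * u^2 - 15 * u + 10)
  pmin(pmax(((day - day0) + frac) / n_days, 0), 1)
}

# True syllable mean at a production age.
true_mean_at <- function(p, spec, age) {
  u <- dev_progress(p, age)
  drift <- spec$Q0[, 1]
  curve <- if (spec$k >= 2) spec$Q0[, 2] else spec$Q0[, 1] * 0
  spec$mu0 + spec$displacement * u * drift +
    p$mean_curvature * sin(pi * u) * curve
}

# Deterministic entropy schedule (nats): linear in time of day within the
# lights-on window plus linear in age across development, both centred.
entropy_schedule <- function(p, spec, age, tod) {
  mid_age <- mean(p$age_range)
  day_frac <- (tod - p$day_window[1]) / (p$day_window[2] - p$day_window[1])
  spec$entropy_base +
    p$entropy_dev_slope * (age - mid_age) +
    spec$day_amplitude * (0.5 - day_frac)
}

# Eigenbasis at a given age: base orientation rotated slowly in the plane of
# the two leading directions.
true_basis_at <- function(p, spec, age) {
  if (spec$k < 2 || p$rotation_deg_per_day == 0) return(spec$Q0)
  theta <- p$rotation_deg_per_day * pi / 180 * (age - p$age_range[1])
  R <- diag(spec$k)
  R[1, 1] <- cos(theta); R[2, 2] <- cos(theta)
  R[1, 2] <- -sin(theta); R[2, 1] <- sin(theta)
  spec$Q0 %*% R
}

true_eigenvalues_at <- function(p, spec, age, tod) {
  H <- entropy_schedule(p, spec, age, tod)
  scale <- exp(2 * (H - gauss_entropy_const(spec$k)) / spec$k)
  scale * spec$spectrum
}

# True generating covariance at (age, time of day).
true_cov_at <- function(p, spec, age, tod) {
  Q <- true_basis_at(p, spec, age)
  ev <- true_eigenvalues_at(p, spec, age, tod)
  Q %*% (ev * t(Q))
}

#' Ground-truth differential entropy of the generating distribution
#'
#' Returns the entropy (nats) of the generating Gaussian for one syllable at
#' a production age and time of day: `0.5*log(det(Sigma)) + (k/2)*(1+log(2*pi))`.
#'
#' @param params a [ground_truth_params()] object.
#' @param age production age in dph; must lie within `params$age_range`.
#' @param tod time of day in hours; must lie within `params$day_window`.
#' @param bird,syllable which syllable's schedule to evaluate.
#' @return Entropy in nats (vectorised over `age`/`tod`).
#' @export
true_entropy_at <- function(params, age, tod, bird = 1, syllable = 1) {
  stopifnot(inherits(params, "gt_params"))
  if (any(age < params$age_range[1] - 1e-9 | age > params$age_range[2] + 1e-9))
    stop("age outside the generated range")
  if (any(tod < params$day_window[1] - 1e-9 | tod > params$day_window[2] + 1e-9))
    stop("time of day outside the lights-on window")
  spec <- syllable_spec(params, bird, syllable)
  entropy_schedule(params, spec, age, tod)
}
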