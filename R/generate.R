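#' Generate a synthetic developmental latent dataset
#'
#' Draws timestamped syllable renditions from the generating process defined
#' by a [ground_truth_params()] object: for each syllable and each day,
#' `renditions_per_day` production times uniform inside the lights-on window,
#' with latent vectors drawn from `N(mu*(age), Sigma*(age, tod))`. Identical
#' parameters (including the seed) reproduce the dataset exactly, and each
#' (bird, syllable) stream is seeded independently.
#'
#' @param params a [ground_truth_params()] object.
#' @return An object of class `songdev_dataset`: a list with elements
#'   `renditions` (a flat data frame with columns `bird_id`, `syllable_id`,
#'   `age_dph`, `time_of_day_h`, `day_index`, `z1..zK`, where syllables with
#'   fewer latent dimensions are NA-padded), `syllables` (per-syllable
#'   dimensionality table) and `params`.
#' @export
generate_dataset <- function(params) {
  stopifnot(inherits(params, "gt_params"))
  p <- params
  day0 <- floor(p$age_range[1])
  days <- day0:(floor(p$age_range[2]) - 1)
  kmax <- max(p$k)
  out <- list()
  for (b in seq_len(p$n_birds)) {
    for (s in seq_len(p$syllables_per_bird[b])) {
      spec <- syllable_spec(p, b, s)
      n <- length(days) * p$renditions_per_day
      with_seed(substream_seed(p$seed, 10000 + spec$index), {
        tod <- runif(n, p$day_window[1], p$day_window[2])
        noise <- matrix(rnorm(n * spec$k), n, spec$k)
      })
      day <- rep(days, each = p$renditions_per_day)
      ord <- order(day, tod)
      day <- day[ord]; tod <- tod[ord]
      age <- day + tod / 24
      z <- matrix(NA_real_, n, kmax)
      for (i in seq_len(n)) {
        Sig <- true_cov_at(p, spec, age[i], tod[i])
        mu <- true_mean_at(p, spec, age[i])
        z[i, seq_len(spec$k)] <- mu + drop(crossprod(chol(Sig), noise[i, ]))
      }
      out[[length(out) + 1]] <- data.frame(
        bird_id = spec$bird_id, syllable_id = spec$syllable_id,
        age_dph = age, time_of_day_h = tod, day_index = day,
        z, stringsAsFactors = FALSE)
    }
  }
  renditions <- do.call(rbind, out)
  names(renditions)[-(1:5)] <- paste0("z", seq_len(kmax))
  rownames(renditions) <- NULL
  structure(list(renditions = renditions, syllables = syllable_table(p),
                 params = p),
            class = "songdev_dataset")
}


#' @export
print.songdev_dataset <- function(x, ...) {
  cat(sprintf("<songdev_dataset> %d renditions, %d syllables, %d birds\n",
              nrow(x$renditions), nrow(x$syllables),
              length(unique(x$syllables$bird_id))))
  invisible(x)
}

#' Extract one syllable's renditions
#'
#' @param dataset a `songdev_dataset` or a flat rendition data frame.
#' @param syllable_id syllable identifier.
#' @return Data frame of that syllable's renditions with its `k` latent
#'   columns (NA padding dropped) and a `k` attribute.
#' @export
syllable_renditions <- function(dataset, syllable_id) {
  df <- if (inherits(dataset, "songdev_dataset")) dataset$renditions else dataset
  sub <- df[df$syllable_id == syllable_id, , drop = FALSE]
  if (nrow(sub) == 0) stop("unknown syllable_id: ", syllable_id)
  z <- latent_matrix(sub)
  keep <- c("bird_id", "syllable_id", "age_dph", "time_of_day_h", "day_index")
  out <- cbind(sub[keep], as.data.frame(z))
  rownames(out) <- NULL
  attr(out, "k") <- ncol(z)
  out
}

#' Write / read a dataset as CSV with a YAML parameter sidecar
#'
#' @param dataset a `songdev_dataset`.
#' @param path CSV path; the ground truth is written to `<path>.yaml`.
#' @param feather also write a binary columnar twin (`<path>.feather`,
#'   requires the `arrow` package).
#' @return `write_dataset` returns `path` invisibly; `read_dataset` returns a
#'   `songdev_dataset` (with `params` restored when the sidecar is present).
#' @export
write_dataset <- function(dataset, path, feather = FALSE) {
  stopifnot(inherits(dataset, "songdev_dataset"))
  write.csv(dataset$renditions, path, row.names = FALSE)
  if (feather) {
    if (!requireNamespace("arrow", quietly = TRUE))
      stop("the feather twin requires the 'arrow' package")
    arrow::write_feather(dataset$renditions, paste0(path, ".feather"))
  }
  par <- dataset$params
  yaml::write_yaml(unclass(par), paste0(path, ".yaml"))
  invisible(path)
}

#' @rdname write_dataset
#' @export
read_dataset <- function(path) {
  renditions <- read.csv(path, stringsAsFactors = FALSE)
  sidecar <- paste0(path, ".yaml")
  params <- NULL
  if (file.exists(sidecar)) {
    raw <- yaml::read_yaml(sidecar)
    params <- ground_truth_params(
      n_birds = raw$n_birds, syllables_per_bird = raw$syllables_per_bird,
      k = raw$k, age_range = raw$age_range, day_window = raw$day_window,
      mean_displacement = raw$mean_displacement,
      mean_curvature = raw$mean_curvature,
      entropy_base = raw$entropy_base, sigma_drift = raw$sigma_drift,
      entropy_day_amplitude = raw$entropy_day_amplitude,
      entropy_dev_slope = raw$entropy_dev_slope,
      eigen_decay = raw$eigen_decay,
      rotation_deg_per_day = raw$rotation_deg_per_day,
      renditions_per_day = raw$renditions_per_day,
      syllable_heterogeneity = raw$syllable_heterogeneity %||% 0.3,
      seed = raw$seed)
  }
  syl <- unique(renditions[c("bird_id", "syllable_id")])
  syl$k <- vapply(syl$syllable_id, function(id)
    ncol(latent_matrix(renditions[renditions$syllable_id == id, ])), 1L)
  structure(list(renditions = renditions, syllables = syl, params = params),
            class = "songdev_dataset")
}
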