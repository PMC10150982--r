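#' Amplitude-based syllable segmentation
#'
#' Finds maximal runs where the RMS amplitude envelope (5 ms centred window)
#' is at or above `amplitude_threshold`, merges runs separated by gaps
#' shorter than `min_gap` seconds and drops runs shorter than `min_duration`
#' seconds. Intervals are 0-based, half-open `[start, end)` sample indices,
#' non-overlapping and sorted; shifting the waveform shifts all intervals by
#' the same amount.
#'
#' @param waveform numeric vector.
#' @param sample_rate samples per second.
#' @param amplitude_threshold positive envelope threshold.
#' @param min_gap merge gaps shorter than this (seconds).
#' @param min_duration drop segments shorter than this (seconds).
#' @param envelope_window RMS window (seconds).
#' @return Integer matrix with columns `start`, `end` (possibly 0 rows).
#' @export
segment_sounds <- function(waveform, sample_rate, amplitude_threshold,
                           min_gap = 0.01, min_duration = 0.02,
                           envelope_window = 0.005) {
  stopifnot(amplitude_threshold > 0)
  empty <- matrix(integer(0), ncol = 2,
                  dimnames = list(NULL, c("start", "end")))
  if (length(waveform) == 0) return(empty)
  w <- max(1L, round(envelope_window * sample_rate))
  env <- sqrt(stats::filter(waveform^2, rep(1 / w, w), sides = 2))
  env[is.na(env)] <- 0
  above <- as.numeric(env) >= amplitude_threshold
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  runs <- cbind(starts[r$values], ends[r$values])
  if (nrow(runs) == 0) return(empty)
  # merge across short gaps
  merged <- runs[1, , drop = FALSE]
  if (nrow(runs) > 1) for (i in 2:nrow(runs)) {
    gap <- (runs[i, 1] - merged[nrow(merged), 2] - 1) / sample_rate
    if (gap < min_gap) merged[nrow(merged), 2] <- runs[i, 2]
    else merged <- rbind(merged, runs[i, ])
  }
  dur <- (merged[, 2] - merged[, 1] + 1) / sample_rate
  merged <- merged[dur >= min_duration, , drop = FALSE]
  if (nrow(merged) == 0) return(empty)
  # 1-based inclusive -> 0-based half-open
  out <- cbind(start = merged[, 1] - 1L, end = merged[, 2])
  storage.mode(out) <- "integer"
  out
}

hz_to_mel <- function(f) 2595 * log10(1 + f / 700)
mel_to_hz <- function(m) 700 * (10^(m / 2595) - 1)

# Triangular mel filterbank (n_mels x (n_fft/2 + 1)).
mel_filterbank <- function(n_mels, n_fft, sample_rate, fmin = 0,
                           fmax = sample_rate / 2) {
  n_bins <- n_fft %/% 2 + 1
  freqs <- seq(0, sample_rate / 2, length.out = n_bins)
  pts <- mel_to_hz(seq(hz_to_mel(fmin), hz_to_mel(fmax),
                       length.out = n_mels + 2))
  fb <- matrix(0, n_mels, n_bins)
  for (m in seq_len(n_mels)) {
    lo <- pts[m]; ce <- pts[m + 1]; hi <- pts[m + 2]
    up <- (freqs - lo) / max(ce - lo, 1e-12)
    down <- (hi - freqs) / max(hi - ce, 1e-12)
    fb[m, ] <- pmax(0, pmin(up, down))
  }
  fb
}

# Centre frequencies of the mel bins (used to locate spectral peaks).
mel_center_freqs <- function(n_mels, sample_rate, fmin = 0,
                             fmax = sample_rate / 2) {
  pts <- mel_to_hz(seq(hz_to_mel(fmin), hz_to_mel(fmax),
                       length.out = n_mels + 2))
  pts[2:(n_mels + 1)]
}

#' Mel-spectrogram image of one segmented sound
#'
#' Computes the log modulus of the short-time Fourier transform with 128
#' mel-spaced frequency bins (Hann window), clips values to
#' `[floor, ceiling]`, rescales them affinely to \[0, 1\] and symmetrically
#' zero-pads the time axis to 128 frames. Segments spanning more than 128
#' STFT frames at the configured hop are an error.
#'
#' @param segment numeric waveform segment.
#' @param sample_rate samples per second.
#' @param floor,ceiling log-amplitude clipping range.
#' @param n_mels,width image dimensions (frequency x time).
#' @param window STFT window length in samples.
#' @param hop hop in samples; default 2.5 ms (110 samples at 44.1 kHz), so
#'   128 frames cover about 0.3 s.
#' @return Object of class `spectrogram_image`: list with `values`
#'   (`n_mels` x `width`, in \[0, 1\]), `floor`, `ceiling`, `n_frames`.
#' @export
make_spectrogram <- function(segment, sample_rate, floor = -10, ceiling = 0,
                             n_mels = 128, width = 128, window = 512,
                             hop = max(1L, round(0.0025 * sample_rate))) {
  x <- as.numeric(segment)
  if (length(x) < window) x <- c(x, numeric(window - length(x)))
  n_frames <- (length(x) - window) %/% hop + 1
  if (n_frames > width)
    stop(sprintf(
      "segment too long: %d frames > %d; maximum duration %.3f s at this hop",
      n_frames, width, (window + (width - 1) * hop) / sample_rate))
  hann <- 0.5 - 0.5 * cos(2 * pi * seq_len(window) / (window + 1))
  frames <- vapply(seq_len(n_frames), function(i) {
    seg <- x[(i - 1) * hop + seq_len(window)] * hann
    Mod(stats::fft(seg))[seq_len(window %/% 2 + 1)]
  }, numeric(window %/% 2 + 1))
  fb <- mel_filterbank(n_mels, window, sample_rate)
  mel <- fb %*% frames
  img <- log(mel + 1e-12)
  img <- pmin(pmax(img, floor), ceiling)
  img <- (img - floor) / (ceiling - floor)
  pad_left <- (width - n_frames) %/% 2
  values <- matrix(0, n_mels, width)
  values[, pad_left + seq_len(n_frames)] <- img
  structure(list(values = values, floor = floor, ceiling = ceiling,
                 n_frames = n_frames, pad_left = pad_left,
                 sample_rate = sample_rate, window = window, hop = hop),
            class = "spectrogram_image")
}

#' Per-syllable PCA features at effective dimensionality
#'
#' Centres the input (flattened spectrogram images, or external encoder
#' latents such as a 32-d VAE embedding), fits an orthonormal principal
#' component basis and truncates it at the effective dimensionality k: the
#' smallest component count whose cumulative explained variance exceeds
#' `variance_threshold` (0.99, i.e. 6-8 components for typical syllables).
#'
#' @param X numeric matrix, one row per rendition.
#' @param variance_threshold cumulative variance to exceed.
#' @return Object of class `syllable_features`: `scores` (n x k), `k`,
#'   `pca_mean`, `pca_components` (p x k, orthonormal),
#'   `variance_explained`.
#' @export
fit_pca_features <- function(X, variance_threshold = 0.99) {
  X <- as.matrix(X)
  if (nrow(X) < 2) stop("at least 2 renditions required")
  pc <- stats::prcomp(X, center = TRUE, scale. = FALSE)
  v <- pc$sdev^2
  total <- sum(v)
  if (total == 0) stop("input has zero variance")
  cumvar <- cumsum(v) / total
  k <- which(cumvar > variance_threshold)[1]
  if (is.na(k)) {
    k <- length(v)
    warning("rank-deficient input: truncating at rank ", k)
  }
  structure(list(scores = pc$x[, seq_len(k), drop = FALSE],
                 k = k, pca_mean = pc$center,
                 pca_components = pc$rotation[, seq_len(k), drop = FALSE],
                 variance_explained = cumvar[k],
                 cumulative_variance = cumvar),
            class = "syllable_features")
}

#' Project new data onto a fitted PCA basis / reconstruct from scores
#'
#' @param features a `syllable_features` object.
#' @param X matrix of new renditions (rows).
#' @return `pca_project` returns n x k scores; `pca_reconstruct` maps scores
#'   back to the input space.
#' @export
pca_project <- function(features, X)
  sweep(as.matrix(X), 2, features$pca_mean) %*% features$pca_components

#' @rdname pca_project
#' @param scores n x k score matrix.
#' @export
pca_reconstruct <- function(features, scores)
  sweep(as.matrix(scores) %*% t(features$pca_components), 2,
        features$pca_mean, "+")

#' Replace a rendition table's latents with their PCA scores
#'
#' Projects the latent columns of a rendition data frame onto a fitted
#' per-syllable basis from [fit_pca_features()], returning the same table
#' with `z1..zk` replaced by the k-dimensional scores. This is the
#' coordinate system the downstream distribution models are fit in: each
#' syllable is modelled in its own principal axes at effective
#' dimensionality.
#'
#' @param features a `syllable_features` object (fit on the training side).
#' @param renditions rendition data frame with latent columns.
#' @return The rendition data frame with projected latent columns.
#' @export
pca_project_renditions <- function(features, renditions) {
  scores <- pca_project(features, latent_matrix(renditions))
  meta <- setdiff(names(renditions), latent_cols(renditions))
  out <- cbind(renditions[meta],
               stats::setNames(as.data.frame(scores),
                               paste0("z", seq_len(ncol(scores)))))
  rownames(out) <- NULL
  attr(out, "k") <- ncol(scores)
  out
}
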