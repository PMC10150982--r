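#' Synthesise a toy syllable waveform
#'
#' Generates a short (< 0.3 s) harmonic-stack syllable whose fundamental
#' frequency and duration vary smoothly with production age, shaped by a
#' Hann amplitude envelope and embedded centred in silence. A small seeded
#' jitter on the fundamental makes renditions differ reproducibly. Used as a
#' fixture for the feature-extraction path; it makes no attempt at realistic
#' vocal-tract synthesis.
#'
#' @param age production age in dph (controls pitch and duration).
#' @param seed RNG seed for rendition jitter.
#' @param sample_rate samples per second.
#' @param f0 fundamental frequency in Hz; `NULL` derives it from `age`.
#' @param duration syllable duration in seconds; `NULL` derives it from
#'   `age`.
#' @param amplitude peak amplitude in \[0, 1\]; 0 returns pure silence.
#' @param n_harmonics harmonics in the stack.
#' @param total_duration length of the returned clip in seconds.
#' @return List with `waveform` and `sample_rate`.
#' @export
synth_syllable_audio <- function(age = 60, seed = 1L, sample_rate = 44100,
                                 f0 = NULL, duration = NULL, amplitude = 0.6,
                                 n_harmonics = 4, total_duration = 0.4) {
  n_total <- round(total_duration * sample_rate)
  wave <- numeric(n_total)
  if (amplitude == 0) return(list(waveform = wave, sample_rate = sample_rate))
  f0 <- f0 %||% (1500 + 10 * (age - 60))
  duration <- duration %||% min(0.08 + 0.0008 * (age - 60), 0.29)
  jitter <- with_seed(seed, rnorm(1, sd = 0.01))
  f <- f0 * (1 + jitter)
  n <- round(duration * sample_rate)
  t <- seq_len(n) / sample_rate
  syl <- numeric(n)
  for (h in seq_len(n_harmonics))
    syl <- syl + (1 / h) * sin(2 * pi * h * f * t)
  env <- 0.5 - 0.5 * cos(2 * pi * seq_len(n) / (n + 1))
  syl <- amplitude * env * syl / max(abs(syl))
  start <- (n_total - n) %/% 2
  wave[start + seq_len(n)] <- syl
  list(waveform = wave, sample_rate = sample_rate)
}

#' Read and write mono 16-bit PCM WAV files
#'
#' Minimal RIFF/WAVE support for the package's audio fixtures (44.1 kHz
#' 16-bit mono by default).
#'
#' @param waveform numeric vector in \[-1, 1\].
#' @param sample_rate samples per second.
#' @param path file path.
#' @return `write_wav` returns `path` invisibly; `read_wav` returns a list
#'   with `waveform` and `sample_rate`.
#' @export
write_wav <- function(waveform, sample_rate, path) {
  samples <- as.integer(round(pmin(pmax(waveform, -1), 1) * 32767))
  n <- length(samples)
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36 + 2 * n), con, size = 4, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")
  writeBin(1L, con, size = 2, endian = "little")            # PCM
  writeBin(1L, con, size = 2, endian = "little")            # mono
  writeBin(as.integer(sample_rate), con, size = 4, endian = "little")
  writeBin(as.integer(sample_rate * 2), con, size = 4, endian = "little")
  writeBin(2L, con, size = 2, endian = "little")            # block align
  writeBin(16L, con, size = 2, endian = "little")           # bits/sample
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(2 * n), con, size = 4, endian = "little")
  writeBin(samples, con, size = 2, endian = "little")
  invisible(path)
}

#' @rdname write_wav
#' @export
read_wav <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4)
  if (!identical(riff, "RIFF")) stop("not a RIFF file: ", path)
  invisible(readBin(con, integer(), size = 4, endian = "little"))
  if (!identical(readChar(con, 4), "WAVE")) stop("not a WAVE file: ", path)
  sample_rate <- NULL; bits <- NULL; channels <- NULL; samples <- NULL
  repeat {
    id <- readChar(con, 4)
    if (length(id) == 0 || nchar(id) < 4) break
    size <- readBin(con, integer(), size = 4, endian = "little")
    if (identical(id, "fmt ")) {
      fmt <- readBin(con, integer(), n = 2, size = 2, endian = "little")
      channels <- fmt[2]
      sample_rate <- readBin(con, integer(), size = 4, endian = "little")
      invisible(readBin(con, integer(), size = 4, endian = "little"))
      invisible(readBin(con, integer(), size = 2, endian = "little"))
      bits <- readBin(con, integer(), size = 2, endian = "little")
      if (size > 16) invisible(readBin(con, raw(), n = size - 16))
    } else if (identical(id, "data")) {
      if (!identical(bits, 16L)) stop("only 16-bit PCM supported")
      samples <- readBin(con, integer(), n = size %/% 2, size = 2,
                         signed = TRUE, endian = "little")
      break
    } else {
      invisible(readBin(con, raw(), n = size))
    }
  }
  if (is.null(samples)) stop("no data chunk found in ", path)
  if (!identical(channels, 1L)) stop("only mono WAV supported")
  list(waveform = samples / 32767, sample_rate = sample_rate)
}
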