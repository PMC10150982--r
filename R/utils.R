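# Internal helpers: seed substreams and small utilities.

# Derive a reproducible 31-bit substream seed from a master seed and a
# counter, so per-(bird, syllable) streams can be regenerated independently.
substream_seed <- function(master, index) {
  stopifnot(is.numeric(master), is.numeric(index))
  as.integer((as.double(master) + 1000003 * as.double(index)) %% 2147483647)
}

# Run code under a temporary RNG state.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Names of the latent coordinate columns present in a rendition table.
latent_cols <- function(df) grep("^z[0-9]+$", names(df), value = TRUE)

#' Latent coordinate matrix of a rendition table
#'
#' Extracts the `z1..zk` columns of one syllable's renditions as a numeric
#' matrix, dropping all-NA padding columns that arise when syllables of
#' different dimensionality share a flat table.
#'
#' @param df rendition data frame.
#' @param k keep exactly the first `k` latent columns instead.
#' @return Numeric matrix with one row per rendition.
#' @export
latent_matrix <- function(df, k = NULL) {
  cols <- latent_cols(df)
  m <- as.matrix(df[cols])
  if (is.null(k)) {
    keep <- colSums(!is.na(m)) > 0
    m <- m[, keep, drop = FALSE]
  } else {
    m <- m[, seq_len(k), drop = FALSE]
  }
  storage.mode(m) <- "double"
  m
}

# Random orthogonal matrix (QR of a Gaussian matrix, sign-fixed).
random_orthogonal <- function(k) {
  qr_ <- qr(matrix(rnorm(k * k), k, k))
  q <- qr.Q(qr_)
  q %*% diag(sign(diag(qr.R(qr_))), k)
}

gauss_entropy_const <- function(k) (k / 2) * (1 + log(2 * pi))
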