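#' Savitzky-Golay smoothing of spectra
#'
#' Row-wise local least-squares polynomial smoothing. Each band value is
#' replaced by the value at its own position of a degree-`polyorder`
#' polynomial fitted to the surrounding `window` bands. At the spectrum ends
#' the window is truncated to the available bands and the polynomial refitted
#' there (no padding), so no reflectance values are fabricated beyond the
#' measured range.
#'
#' Defaults (`window = 11`, `polyorder = 2`) are the common chemometrics
#' choice at band counts of a few hundred.
#'
#' @param spectra Numeric matrix, seeds x bands (a single spectrum may be
#'   passed as a vector).
#' @param window Odd window length, `polyorder < window <= bands`.
#' @param polyorder Polynomial degree.
#' @return Smoothed matrix of the same shape.
#' @export
savitzky_golay_smooth <- function(spectra, window = 11L, polyorder = 2L) {
  if (is.vector(spectra)) spectra <- matrix(spectra, nrow = 1L)
  stopifnot(is.matrix(spectra))
  window <- as.integer(window); polyorder <- as.integer(polyorder)
  if (window %% 2L == 0L) stop("`window` must be odd")
  if (window <= polyorder) stop("`window` must exceed `polyorder`")
  n <- ncol(spectra)
  if (window > n) stop("`window` (", window, ") exceeds band count (", n, ")")
  h <- (window - 1L) %/% 2L
  # n x n smoother matrix; row i holds the SG weights for output band i
  S <- matrix(0, n, n)
  for (i in seq_len(n)) {
    lo <- max(1L, i - h); hi <- min(n, i + h)
    t_off <- (lo:hi) - i
    A <- outer(t_off, 0:polyorder, `^`)
    w <- solve(crossprod(A), t(A))[1L, ]   # fitted value at offset 0
    S[i, lo:hi] <- w
  }
  out <- spectra %*% t(S)
  dimnames(out) <- dimnames(spectra)
  out
}

#' Standard normal variate transform
#'
#' Centers and scales each spectrum (row) to mean 0 and unit sample standard
#' deviation, removing multiplicative scatter and baseline offsets. A constant
#' row has no SNV image and raises an error naming the row.
#'
#' @param spectra Numeric matrix, seeds x bands.
#' @return Transformed matrix of the same shape.
#' @export
snv_transform <- function(spectra) {
  if (is.vector(spectra)) spectra <- matrix(spectra, nrow = 1L)
  stopifnot(is.matrix(spectra), ncol(spectra) >= 2L)
  mu <- rowMeans(spectra)
  sdv <- apply(spectra, 1L, stats::sd)
  bad <- which(sdv == 0)
  if (length(bad))
    stop("degenerate (constant) spectrum in row(s): ",
         paste(bad, collapse = ", "))
  out <- (spectra - mu) / sdv
  dimnames(out) <- dimnames(spectra)
  out
}

#' Z-score standardization of block sets using training statistics
#'
#' Computes a per-band (spectral channel) mean and standard deviation over all
#' pixels of the training blocks only, and z-scores both block sets with those
#' statistics. Keeping the statistics training-only prevents test-set leakage;
#' they are returned so inference-time data can be scaled identically.
#'
#' @param train_blocks A `block_set` (see [extract_blocks()]); statistics come
#'   from here.
#' @param other_blocks Optional second `block_set` (e.g. the test split)
#'   scaled with the training statistics.
#' @return List with `train`, `other` (or `NULL`) and `stats`
#'   (list of per-band `mean`, `sd`).
#' @export
standardize_blocks <- function(train_blocks, other_blocks = NULL) {
  stopifnot(inherits(train_blocks, "block_set"))
  if (length(train_blocks$blocks) == 0L) stop("`train_blocks` is empty")
  K <- dim(train_blocks$blocks[[1L]]$data)[3L]
  # pool pixel values per band across all training blocks
  mat <- do.call(rbind, lapply(train_blocks$blocks,
                               function(b) matrix(b$data, ncol = K)))
  mu <- colMeans(mat)
  sdv <- apply(mat, 2L, stats::sd)
  zero <- sdv == 0 | is.na(sdv)
  if (any(zero)) {
    warning(sum(zero), " band(s) with zero variance; sd clamped to 1e-8")
    sdv[zero] <- 1e-8
  }
  stats <- list(mean = mu, sd = sdv)
  list(train = apply_block_standardization(train_blocks, stats),
       other = if (!is.null(other_blocks))
         apply_block_standardization(other_blocks, stats),
       stats = stats)
}

#' Apply stored standardization statistics to a block set
#'
#' @param blocks A `block_set`.
#' @param stats Per-band `mean`/`sd` list from [standardize_blocks()].
#' @return The standardized `block_set`.
#' @export
apply_block_standardization <- function(blocks, stats) {
  stopifnot(inherits(blocks, "block_set"))
  mu <- stats$mean; sdv <- stats$sd
  blocks$blocks <- lapply(blocks$blocks, function(b) {
    d <- dim(b$data)
    b$data <- array(sweep(sweep(matrix(b$data, ncol = d[3L]), 2L, mu), 2L,
                          sdv, `/`), d)
    b
  })
  blocks$standardized <- TRUE
  blocks
}
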