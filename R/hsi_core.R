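#' Hyperspectral reflectance cube
#'
#' Container for a calibrated (or raw) hyperspectral image: a
#' `height x width x bands` numeric array together with the ordered vector of
#' band-center wavelengths in nanometres. Reflectance is unitless and nominally
#' in `[0, 1]` after white/dark calibration.
#'
#' @param data Numeric array, `height x width x bands`.
#' @param wavelengths Strictly increasing numeric vector of band centers (nm),
#'   one per band.
#' @return An object of class `hyper_cube`.
#' @examples
#' cube <- hyper_cube(array(0.5, c(4, 4, 3)), c(500, 600, 700))
#' dim(cube$data)
#' @export
hyper_cube <- function(data, wavelengths) {
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("`data` must be a 3-d array (height x width x bands)")
  wavelengths <- as.numeric(wavelengths)
  if (length(wavelengths) != dim(data)[3L])
    stop("length(wavelengths) must equal the number of bands (",
         dim(data)[3L], "), got ", length(wavelengths))
  if (any(diff(wavelengths) <= 0))
    stop("`wavelengths` must be strictly increasing")
  structure(list(data = data, wavelengths = wavelengths),
            class = "hyper_cube")
}

#' @export
print.hyper_cube <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<hyper_cube> %d x %d pixels, %d bands (%.1f-%.1f nm)\n",
              d[1], d[2], d[3], min(x$wavelengths), max(x$wavelengths)))
  invisible(x)
}

#' Calibration triplet (raw / white / dark cubes)
#'
#' Bundles the three acquisitions needed for reflectance calibration: the raw
#' sample image, a white-board reference captured under the same illumination,
#' and a dark-current reference captured with the lens covered. All three must
#' share the same dimensions.
#'
#' @param raw,white,dark Numeric arrays of identical `height x width x bands`
#'   shape (raw sensor intensities).
#' @param wavelengths Band centers (nm), one per band.
#' @return An object of class `calibration_set`.
#' @seealso [calibrate_cube()]
#' @export
calibration_set <- function(raw, white, dark, wavelengths) {
  for (nm in c("raw", "white", "dark")) {
    a <- get(nm)
    if (!is.array(a) || length(dim(a)) != 3L)
      stop("`", nm, "` must be a 3-d array")
  }
  if (!identical(dim(raw), dim(white)) || !identical(dim(raw), dim(dark)))
    stop("raw, white and dark cubes must have identical dimensions")
  wavelengths <- as.numeric(wavelengths)
  if (length(wavelengths) != dim(raw)[3L])
    stop("length(wavelengths) must equal the number of bands")
  structure(list(raw = raw, white = white, dark = dark,
                 wavelengths = wavelengths),
            class = "calibration_set")
}

#' Reflectance calibration against white and dark references
#'
#' Converts raw intensities to reflectance voxel-by-voxel as
#' `(raw - dark) / (white - dark)`, removing illumination non-uniformity and
#' camera dark current. The white board reflects ~99% of incident light and the
#' dark frame is acquired with the light off and the lens covered, so the
#' quotient is the sample reflectance on a 0-1 scale.
#'
#' @param cal A [calibration_set()].
#' @return A [hyper_cube()] of reflectance, wavelengths passed through.
#' @examples
#' raw <- array(0.6, c(2, 2, 1)); white <- array(1, c(2, 2, 1))
#' dark <- array(0.2, c(2, 2, 1))
#' calibrate_cube(calibration_set(raw, white, dark, 800))$data[1, 1, 1]  # 0.5
#' @export
calibrate_cube <- function(cal) {
  stopifnot(inherits(cal, "calibration_set"))
  denom <- cal$white - cal$dark
  if (any(denom == 0))
    stop("degenerate reference: white == dark on ", sum(denom == 0), " voxel(s)")
  hyper_cube((cal$raw - cal$dark) / denom, cal$wavelengths)
}

#' Subset a cube to a wavelength range
#'
#' Keeps the bands whose centers fall inside `[lo_nm, hi_nm]` (inclusive),
#' preserving order. Typical use: restricting a Vis-SWNIR cube to the
#' information-rich 420-1000 nm window before band selection.
#'
#' @param cube A [hyper_cube()].
#' @param lo_nm,hi_nm Range bounds in nm, `lo_nm < hi_nm`.
#' @return A [hyper_cube()] with the retained bands.
#' @export
subset_wavelengths <- function(cube, lo_nm, hi_nm) {
  stopifnot(inherits(cube, "hyper_cube"))
  if (!(lo_nm < hi_nm)) stop("`lo_nm` must be < `hi_nm`")
  keep <- which(cube$wavelengths >= lo_nm & cube$wavelengths <= hi_nm)
  if (length(keep) == 0L)
    stop("empty wavelength selection: no band in [", lo_nm, ", ", hi_nm, "] nm")
  hyper_cube(cube$data[, , keep, drop = FALSE], cube$wavelengths[keep])
}

#' Nearest band index for a requested wavelength
#'
#' Minimal absolute nm distance; exact ties resolve to the lower band.
#'
#' @param cube A [hyper_cube()].
#' @param band_nm Requested wavelength (nm).
#' @return Integer band index.
#' @export
nearest_band <- function(cube, band_nm) {
  stopifnot(inherits(cube, "hyper_cube"), length(band_nm) == 1L)
  d <- abs(cube$wavelengths - band_nm)
  which.min(d)  # which.min takes the first (lower) index on ties
}

#' Integer-labeled seed instance mask
#'
#' @param labels Integer matrix; 0 = background, `k >= 1` = pixels of seed
#'   instance `k`. Labels are made consecutive `1..n_seeds`.
#' @return An object of class `seed_mask` with fields `labels` and `n_seeds`.
#' @export
seed_mask <- function(labels) {
  if (!is.matrix(labels)) stop("`labels` must be a matrix")
  labels <- matrix(as.integer(labels), nrow(labels), ncol(labels))
  if (any(labels < 0L)) stop("labels must be >= 0")
  ids <- sort(unique(labels[labels > 0L]))
  if (length(ids) && !identical(ids, seq_along(ids))) {
    relab <- integer(max(ids)); relab[ids] <- seq_along(ids)
    pos <- labels > 0L
    labels[pos] <- relab[labels[pos]]
  }
  structure(list(labels = labels, n_seeds = length(ids)), class = "seed_mask")
}

#' @export
print.seed_mask <- function(x, ...) {
  cat(sprintf("<seed_mask> %d x %d pixels, %d seed(s)\n",
              nrow(x$labels), ncol(x$labels), x$n_seeds))
  invisible(x)
}

#' Otsu's threshold of a grayscale image
#'
#' Maximizes between-class variance on a 256-bin histogram of the image range.
#' Used as the default cutoff when segmenting bright seeds from the dark stage
#' background at the mask band.
#'
#' @param img Numeric matrix.
#' @param n_bins Histogram resolution.
#' @return Threshold on the intensity scale of `img`.
#' @export
otsu_threshold <- function(img, n_bins = 256L) {
  v <- as.numeric(img)
  r <- range(v)
  if (r[1] == r[2]) return(r[1])
  brk <- seq(r[1], r[2], length.out = n_bins + 1L)
  h <- tabulate(findInterval(v, brk, rightmost.closed = TRUE), n_bins)
  p <- h / sum(h)
  mids <- (brk[-1] + brk[-length(brk)]) / 2
  w0 <- cumsum(p)
  mu <- cumsum(p * mids)
  mu_t <- mu[n_bins]
  w1 <- 1 - w0
  valid <- w0 > 0 & w1 > 0
  sigma_b <- rep(-Inf, n_bins)
  sigma_b[valid] <- (mu_t * w0[valid] - mu[valid])^2 / (w0[valid] * w1[valid])
  mids[which.max(sigma_b)]
}

# 4-connected component labeling of a logical matrix (two-pass union-find).
label_components <- function(fg) {
  nr <- nrow(fg); nc <- ncol(fg)
  lab <- matrix(0L, nr, nc)
  parent <- integer(0)
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  nxt <- 0L
  for (j in seq_len(nc)) for (i in seq_len(nr)) {
    if (!fg[i, j]) next
    up   <- if (i > 1L) lab[i - 1L, j] else 0L
    left <- if (j > 1L) lab[i, j - 1L] else 0L
    if (up == 0L && left == 0L) {
      nxt <- nxt + 1L; parent[nxt] <- nxt; lab[i, j] <- nxt
    } else if (up != 0L && left != 0L) {
      ru <- find(up); rl <- find(left)
      lab[i, j] <- min(ru, rl)
      if (ru != rl) parent[max(ru, rl)] <- min(ru, rl)
    } else {
      lab[i, j] <- max(up, left)
    }
  }
  if (nxt == 0L) return(lab)
  roots <- vapply(seq_len(nxt), find, integer(1))
  remap <- integer(nxt)
  remap[sort(unique(roots))] <- seq_along(unique(roots))
  pos <- lab > 0L
  lab[pos] <- remap[roots[lab[pos]]]
  lab
}

#' Segment seed instances by thresholding one band
#'
#' Thresholds the grayscale image at the band nearest `band_nm` (foreground =
#' reflectance strictly above the cutoff), removes connected components smaller
#' than `min_area` pixels, and relabels the survivors `1..n`. Components are
#' 4-connected. With `threshold = NULL` the cutoff is Otsu's threshold on that
#' band image.
#'
#' @param cube A [hyper_cube()].
#' @param band_nm Mask band in nm (e.g. 801 for Vis-SWNIR, 1098 for LWNIR);
#'   nearest band is used.
#' @param threshold Fixed reflectance cutoff, or `NULL` for Otsu.
#' @param min_area Minimum component area (pixels); smaller specks are dropped.
#' @return A [seed_mask()]. A scene with no foreground yields a zero-seed mask
#'   with a warning, not an error.
#' @export
segment_seeds <- function(cube, band_nm, threshold = NULL, min_area = 50L) {
  stopifnot(inherits(cube, "hyper_cube"))
  if (min_area < 0) stop("`min_area` must be >= 0")
  img <- cube$data[, , nearest_band(cube, band_nm)]
  if (is.null(threshold)) threshold <- otsu_threshold(img)
  if (threshold < 0) stop("`threshold` must be >= 0")
  fg <- img > threshold
  if (!any(fg)) {
    warning("no foreground above threshold ", signif(threshold, 4),
            "; returning zero-seed mask")
    return(seed_mask(matrix(0L, nrow(img), ncol(img))))
  }
  lab <- label_components(fg)
  sizes <- tabulate(lab[lab > 0L])
  small <- which(sizes < min_area)
  if (length(small)) lab[lab %in% small] <- 0L
  if (!any(lab > 0L)) {
    warning("all components below min_area = ", min_area,
            "; returning zero-seed mask")
  }
  seed_mask(lab)
}

#' Per-seed mean spectra under a mask
#'
#' Averages reflectance over the pixels of each seed instance, band by band,
#' yielding one mean spectrum per seed.
#'
#' @param cube A [hyper_cube()].
#' @param mask A [seed_mask()] aligned to the cube's spatial grid.
#' @param class_labels Optional per-seed class vector (length `n_seeds`),
#'   stored alongside the spectra.
#' @return A `spectral_table`: list with `spectra` (`n_seeds x bands` matrix),
#'   `wavelengths`, `seed_ids`, `class_labels`.
#' @export
mean_spectra <- function(cube, mask, class_labels = NULL) {
  stopifnot(inherits(cube, "hyper_cube"), inherits(mask, "seed_mask"))
  d <- dim(cube$data)
  if (!identical(d[1:2], dim(mask$labels)))
    stop("mask shape ", paste(dim(mask$labels), collapse = "x"),
         " does not match cube spatial shape ", paste(d[1:2], collapse = "x"))
  n <- mask$n_seeds
  if (!is.null(class_labels) && length(class_labels) != n)
    stop("class_labels must have one entry per seed")
  spec <- matrix(NA_real_, n, d[3L],
                 dimnames = list(NULL, paste0("nm", cube$wavelengths)))
  lab <- as.vector(mask$labels)
  flat <- matrix(cube$data, d[1L] * d[2L], d[3L])
  for (k in seq_len(n)) {
    px <- which(lab == k)
    if (length(px) == 0L) stop("seed instance ", k, " is empty")
    spec[k, ] <- colMeans(flat[px, , drop = FALSE])
  }
  structure(list(spectra = spec, wavelengths = cube$wavelengths,
                 seed_ids = seq_len(n), class_labels = class_labels),
            class = "spectral_table")
}

#' @export
print.spectral_table <- function(x, ...) {
  cat(sprintf("<spectral_table> %d seed(s) x %d band(s)\n",
              nrow(x$spectra), ncol(x$spectra)))
  invisible(x)
}
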