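#' Specification of a synthetic hyperspectral seed scene
#'
#' Describes the world the generator emulates: a motorized stage holding up
#' to 96 seeds imaged as bright ellipses on a dark background, with per-class
#' smooth mean reflectance curves, per-seed smooth deviations, and white
#' pixel noise. Aged (nonviable) seeds reflect more than viable ones, so the
#' nonviable class carries a positive reflectance offset — across all bands
#' by default, or confined to `informative_bands` when band-selection
#' recovery is being tested.
#'
#' @param n_seeds Number of seeds (default: the 96-sample stage capacity).
#' @param image_size `c(rows, cols)` of the scene.
#' @param n_bands Number of spectral bands.
#' @param wavelength_range Band-center range in nm.
#' @param class_assignment `"batched"`: seeds arrive in aging batches of
#'   `batch_size`, alternating viable/nonviable tray by tray (mirrors
#'   sequential acquisition along the aging gradient and keeps a stride-10
#'   systematic test set class-balanced); `"random"`: iid draws with
#'   `class_fractions`.
#' @param class_fractions Probabilities of (viable, nonviable) under random
#'   assignment; must sum to 1.
#' @param batch_size Batch extent under batched assignment.
#' @param class_offset Reflectance offset added to the nonviable class.
#' @param informative_bands Band indices carrying the offset (`NULL` = all).
#'   When set, each nonviable seed scales the offset at every informative
#'   band by an independent `U(1 - informative_jitter, 1 + informative_jitter)`
#'   factor — seeds age to different degrees and the elevation of the water
#'   and protein bands varies seed by seed — which makes the class contrast
#'   span the informative bands rather than a single direction.
#' @param informative_jitter Relative spread of the per-seed, per-band aging
#'   factors (only used with `informative_bands`).
#' @param seed_axes_px Nominal ellipse semi-axes (row, col) in pixels,
#'   jittered per seed.
#' @param seed_deviation_sd Amplitude of the smooth per-seed spectral
#'   deviation.
#' @param noise_sd Per-pixel white noise standard deviation.
#' @param background_reflectance Dark stage background level.
#' @param white_level Intensity of the synthesized white reference (a power
#'   of two, so the noise-free calibration round trip is exact in floating
#'   point).
#' @param seed RNG seed; the generator is fully deterministic given the spec.
#' @return A `scene_spec` list.
#' @export
scene_spec <- function(n_seeds = 96L, image_size = c(512L, 512L),
                       n_bands = 64L, wavelength_range = c(420, 1000),
                       class_assignment = c("batched", "random"),
                       class_fractions = c(0.5, 0.5), batch_size = 10L,
                       class_offset = 0.05, informative_bands = NULL,
                       informative_jitter = 0.4,
                       seed_axes_px = c(9, 7), seed_deviation_sd = 0.01,
                       noise_sd = 0.01, background_reflectance = 0.03,
                       white_level = 4, seed = 1L) {
  class_assignment <- match.arg(class_assignment)
  if (abs(sum(class_fractions) - 1) > 1e-9)
    stop("`class_fractions` must sum to 1")
  if (noise_sd < 0) stop("`noise_sd` must be >= 0")
  if (!is.null(informative_bands) &&
      (any(informative_bands < 1L) || any(informative_bands > n_bands)))
    stop("`informative_bands` outside the band range")
  structure(as.list(environment()), class = "scene_spec")
}

# smooth curve over wavelengths: sum of Gaussian bumps
gaussian_bumps <- function(wl, n_bumps, amp_range, width_range, base = 0) {
  y <- rep(base, length(wl))
  span <- diff(range(wl))
  for (g in seq_len(n_bumps)) {
    ctr <- stats::runif(1, min(wl), max(wl))
    amp <- stats::runif(1, amp_range[1], amp_range[2])
    wdt <- stats::runif(1, width_range[1], width_range[2]) * span
    y <- y + amp * exp(-(wl - ctr)^2 / (2 * wdt^2))
  }
  y
}

#' Generate a synthetic hyperspectral seed scene
#'
#' Places non-overlapping elliptical seeds on a grid (row-major order =
#' acquisition order), builds per-pixel spectra as class mean + smooth
#' per-seed deviation + white noise, and synthesizes a raw/white/dark
#' calibration triplet such that [calibrate_cube()] recovers the intended
#' reflectance exactly in the noise-free limit (dark = 0, white a power of
#' two).
#'
#' @param spec A [scene_spec()].
#' @return List with `calibration` (a [calibration_set()]), `mask` (ground
#'   truth [seed_mask()]), `classes` (per-seed 1 = viable / 2 = nonviable),
#'   `class_spectra` (2 x bands generating means), `seed_spectra`
#'   (n_seeds x bands: class mean + per-seed deviation, the recoverable
#'   target of [mean_spectra()]), `wavelengths` and `spec`.
#' @export
generate_seed_scene <- function(spec) {
  stopifnot(inherits(spec, "scene_spec"))
  set.seed(spec$seed)
  nr <- spec$image_size[1L]; nc <- spec$image_size[2L]
  B <- spec$n_bands
  wl <- seq(spec$wavelength_range[1L], spec$wavelength_range[2L],
            length.out = B)
  # grid layout: as square as possible
  g_rows <- floor(sqrt(spec$n_seeds * nr / nc))
  g_rows <- max(1L, g_rows)
  g_cols <- ceiling(spec$n_seeds / g_rows)
  cell_r <- nr %/% (g_rows + 0L); cell_c <- nc %/% g_cols
  if (cell_r < 2 * spec$seed_axes_px[1L] + 4 ||
      cell_c < 2 * spec$seed_axes_px[2L] + 4)
    stop("layout cannot fit ", spec$n_seeds, " seeds of the requested size")
  # class means: viable = smooth bump curve; nonviable = viable + offset
  mu_v <- gaussian_bumps(wl, n_bumps = 4L, amp_range = c(0.05, 0.15),
                         width_range = c(0.08, 0.25), base = 0.25)
  offset <- rep(spec$class_offset, B)
  if (!is.null(spec$informative_bands)) {
    offset <- rep(0, B)
    offset[spec$informative_bands] <- spec$class_offset
  }
  mu_n <- mu_v + offset
  class_spectra <- rbind(viable = mu_v, nonviable = mu_n)
  # classes along the acquisition order
  classes <- if (spec$class_assignment == "batched") {
    1L + (((seq_len(spec$n_seeds) - 1L) %/% spec$batch_size) %% 2L)
  } else {
    sample(1:2, spec$n_seeds, replace = TRUE, prob = spec$class_fractions)
  }
  labels <- matrix(0L, nr, nc)
  reflect <- array(spec$background_reflectance, c(nr, nc, B))
  seed_spectra <- matrix(NA_real_, spec$n_seeds, B)
  for (k in seq_len(spec$n_seeds)) {
    gi <- (k - 1L) %/% g_cols; gj <- (k - 1L) %% g_cols
    ctr_r <- gi * cell_r + cell_r / 2 + stats::runif(1, -2, 2)
    ctr_c <- gj * cell_c + cell_c / 2 + stats::runif(1, -2, 2)
    ax_r <- spec$seed_axes_px[1L] * stats::runif(1, 0.85, 1.15)
    ax_c <- spec$seed_axes_px[2L] * stats::runif(1, 0.85, 1.15)
    rr <- max(1L, floor(ctr_r - ax_r)):min(nr, ceiling(ctr_r + ax_r))
    cc <- max(1L, floor(ctr_c - ax_c)):min(nc, ceiling(ctr_c + ax_c))
    inside <- outer(((rr - ctr_r) / ax_r)^2, ((cc - ctr_c) / ax_c)^2, `+`) <= 1
    if (!any(inside)) stop("degenerate seed placement for seed ", k)
    dev <- gaussian_bumps(wl, n_bumps = 3L,
                          amp_range = c(-spec$seed_deviation_sd,
                                        spec$seed_deviation_sd),
                          width_range = c(0.1, 0.3))
    mu_k <- class_spectra[classes[k], ]
    if (!is.null(spec$informative_bands) && classes[k] == 2L) {
      # seed-specific aging degree per informative band
      u <- stats::runif(length(spec$informative_bands),
                        1 - spec$informative_jitter,
                        1 + spec$informative_jitter)
      mu_k <- mu_v
      mu_k[spec$informative_bands] <- mu_k[spec$informative_bands] +
        spec$class_offset * u
    }
    seed_spectra[k, ] <- mu_k + dev
    idx <- which(inside, arr.ind = TRUE)
    px_r <- rr[idx[, 1L]]; px_c <- cc[idx[, 2L]]
    labels[cbind(px_r, px_c)] <- k
    for (b in seq_len(B))
      reflect[cbind(px_r, px_c, b)] <- seed_spectra[k, b]
  }
  if (spec$noise_sd > 0)
    reflect <- reflect + stats::rnorm(length(reflect), 0, spec$noise_sd)
  white <- array(spec$white_level, c(nr, nc, B))
  dark <- array(0, c(nr, nc, B))
  raw <- reflect * spec$white_level
  list(calibration = calibration_set(raw, white, dark, wl),
       mask = seed_mask(labels),
       classes = classes,
       class_spectra = class_spectra,
       seed_spectra = seed_spectra,
       wavelengths = wl,
       spec = spec)
}

#' Specification of a synthetic bud mask
#'
#' @param length_px Geodesic centerline length in pixels (unit-length steps,
#'   so the generating arc length is exactly this value).
#' @param width_px Strip width (dilation diameter), `>= 1` and `<
#'   length_px`.
#' @param curvature Total heading turn of the centerline in radians (0 =
#'   straight bud).
#' @param n_spurs Number of short side branches attached to the strip.
#' @param spur_length_px Length of each spur.
#' @param margin_px Background margin around the shape.
#' @param seed RNG seed.
#' @return A `bud_spec` list.
#' @export
bud_spec <- function(length_px = 100, width_px = 5, curvature = 0,
                     n_spurs = 0L, spur_length_px = 10, margin_px = 6L,
                     seed = 1L) {
  if (width_px < 1) stop("`width_px` must be >= 1")
  if (length_px <= width_px) stop("`length_px` must exceed `width_px`")
  structure(as.list(environment()), class = "bud_spec")
}

# distance from every pixel of a grid to the nearest of a set of points
min_dist_to_points <- function(nr, nc, pts) {
  px <- cbind(rep(seq_len(nr), nc), rep(seq_len(nc), each = nr))
  d2 <- matrix(Inf, nr, nc)
  chunk <- 200L
  for (s in seq(1L, nrow(pts), by = chunk)) {
    e <- min(s + chunk - 1L, nrow(pts))
    sub <- pts[s:e, , drop = FALSE]
    dd <- outer(px[, 1L], sub[, 1L], `-`)^2 + outer(px[, 2L], sub[, 2L], `-`)^2
    d2 <- pmin(d2, matrix(apply(dd, 1L, min), nr, nc))
  }
  sqrt(d2)
}

#' Generate a synthetic bud mask of known centerline length
#'
#' Draws a smooth curved centerline of exactly `length_px` arc length (unit
#' steps with a slowly varying heading), thickens it to `width_px`, and
#' optionally attaches perpendicular spurs. If the requested curvature folds
#' the strip onto itself the draw is retried with a derived seed, up to
#' `max_retries` times.
#'
#' @param spec A [bud_spec()].
#' @param max_retries Bounded retries for self-intersecting draws.
#' @return List with `mask` (0/1 integer matrix), `true_length_px` (the
#'   generating arc length), `centerline` (continuous coordinates) and
#'   `spec`.
#' @export
generate_bud_mask <- function(spec, max_retries = 20L) {
  stopifnot(inherits(spec, "bud_spec"))
  w <- spec$width_px
  for (attempt in seq_len(max_retries)) {
    set.seed(spec$seed + 7919L * (attempt - 1L))
    L <- round(spec$length_px)
    theta0 <- stats::runif(1, 0, 2 * pi)
    phase <- stats::runif(1, 0, pi)
    amp <- spec$curvature * stats::runif(1, 0.9, 1.1)
    tseq <- seq_len(L)
    heading <- theta0 + amp * sin(pi * tseq / L + phase) / 2
    xs <- cumsum(c(0, cos(heading)))
    ys <- cumsum(c(0, sin(heading)))
    pts <- cbind(xs, ys)
    # reject draws whose strip would self-overlap: any pair of centerline
    # points far apart along the curve but closer than the strip width
    ok <- TRUE
    if (L > 4 * w) {
      sep <- 3L * ceiling(w)
      for (i in seq(1L, L + 1L, by = 2L)) {
        far <- pts[seq_len(L + 1L) > i + sep, , drop = FALSE]
        if (nrow(far) == 0L) break
        d <- sqrt((far[, 1L] - pts[i, 1L])^2 + (far[, 2L] - pts[i, 2L])^2)
        if (min(d) < w + 1) { ok <- FALSE; break }
      }
    }
    if (ok) break
    if (attempt == max_retries)
      stop("could not draw a non-self-intersecting centerline; ",
           "reduce `curvature`")
  }
  all_pts <- pts
  # spurs: perpendicular straight branches from interior centerline points
  if (spec$n_spurs > 0L) {
    at <- round(seq(0.25, 0.75, length.out = spec$n_spurs) * L)
    for (si in seq_len(spec$n_spurs)) {
      t0 <- at[si]
      side <- if (si %% 2L == 0L) 1 else -1
      ang <- heading[min(t0, L)] + side * pi / 2
      sp <- cbind(pts[t0, 1L] + cos(ang) * seq_len(round(spec$spur_length_px)),
                  pts[t0, 2L] + sin(ang) * seq_len(round(spec$spur_length_px)))
      all_pts <- rbind(all_pts, sp)
    }
  }
  # densify for accurate distance-based rasterization
  dense <- all_pts[rep(seq_len(nrow(all_pts)), each = 1L), , drop = FALSE]
  m <- spec$margin_px + w
  offs_x <- m - min(all_pts[, 1L]); offs_y <- m - min(all_pts[, 2L])
  dense[, 1L] <- dense[, 1L] + offs_x
  dense[, 2L] <- dense[, 2L] + offs_y
  nr <- ceiling(max(dense[, 1L]) + m)
  nc <- ceiling(max(dense[, 2L]) + m)
  dist <- min_dist_to_points(nr, nc, dense)
  mask <- matrix(as.integer(dist <= w / 2), nr, nc)
  centerline <- cbind(pts[, 1L] + offs_x, pts[, 2L] + offs_y)
  list(mask = mask, true_length_px = L, centerline = centerline, spec = spec)
}
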