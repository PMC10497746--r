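# shift a matrix so result[i, j] = m[i + dr, j + dc], zero-filled borders
shift_mat <- function(m, dr, dc) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(0L, nr, nc)
  rs <- max(1L, 1L + dr):min(nr, nr + dr)
  cs <- max(1L, 1L + dc):min(nc, nc + dc)
  out[rs - dr, cs - dc] <- m[rs, cs]
  out
}

#' Skeleton (central line) of a binary mask
#'
#' Iterative Zhang-Suen thinning: boundary pixels are peeled in two
#' alternating sub-iterations until the shape stabilizes at a one-pixel-wide,
#' 8-connected centerline contained in the foreground. A shape that is
#' already one pixel wide is returned unchanged; a filled disk collapses to a
#' short central remnant (the degenerate skeleton of a disk).
#'
#' @param mask Logical/0-1 matrix, or a [seed_mask()] (any positive label is
#'   foreground); must contain at least one foreground pixel.
#' @return Logical matrix marking skeleton pixels.
#' @export
medial_axis_skeleton <- function(mask) {
  m <- if (inherits(mask, "seed_mask")) mask$labels > 0L else mask > 0
  if (!is.matrix(m)) stop("`mask` must be a matrix")
  if (!any(m)) stop("empty mask: no foreground pixel")
  img <- matrix(as.integer(m), nrow(m), ncol(m))
  repeat {
    changed <- FALSE
    for (pass in 1:2) {
      # neighbours p2..p9 clockwise from north
      p2 <- shift_mat(img, -1L,  0L); p3 <- shift_mat(img, -1L,  1L)
      p4 <- shift_mat(img,  0L,  1L); p5 <- shift_mat(img,  1L,  1L)
      p6 <- shift_mat(img,  1L,  0L); p7 <- shift_mat(img,  1L, -1L)
      p8 <- shift_mat(img,  0L, -1L); p9 <- shift_mat(img, -1L, -1L)
      B <- p2 + p3 + p4 + p5 + p6 + p7 + p8 + p9
      A <- (p2 == 0L & p3 == 1L) + (p3 == 0L & p4 == 1L) +
           (p4 == 0L & p5 == 1L) + (p5 == 0L & p6 == 1L) +
           (p6 == 0L & p7 == 1L) + (p7 == 0L & p8 == 1L) +
           (p8 == 0L & p9 == 1L) + (p9 == 0L & p2 == 1L)
      del <- img == 1L & B >= 2L & B <= 6L & A == 1L
      if (pass == 1L)
        del <- del & (p2 * p4 * p6 == 0L) & (p4 * p6 * p8 == 0L)
      else
        del <- del & (p2 * p4 * p8 == 0L) & (p2 * p6 * p8 == 0L)
      if (any(del)) { img[del] <- 0L; changed <- TRUE }
    }
    if (!changed) break
  }
  img == 1L
}

# skeleton pixels -> igraph with chamfer edge weights (1 axial, sqrt(2) diag)
skeleton_graph <- function(skel) {
  px <- which(skel, arr.ind = TRUE)
  n <- nrow(px)
  id <- matrix(0L, nrow(skel), ncol(skel))
  id[px] <- seq_len(n)
  from <- integer(0); to <- integer(0); w <- numeric(0)
  offs <- rbind(c(0L, 1L), c(1L, 0L), c(1L, 1L), c(1L, -1L))
  for (o in seq_len(nrow(offs))) {
    dr <- offs[o, 1L]; dc <- offs[o, 2L]
    r2 <- px[, 1L] + dr; c2 <- px[, 2L] + dc
    ok <- r2 >= 1L & r2 <= nrow(skel) & c2 >= 1L & c2 <= ncol(skel)
    ok[ok] <- skel[cbind(r2[ok], c2[ok])]
    if (!any(ok)) next
    from <- c(from, id[px[ok, , drop = FALSE]])
    to <- c(to, id[cbind(r2[ok], c2[ok])])
    w <- c(w, rep(if (dr != 0L && dc != 0L) sqrt(2) else 1, sum(ok)))
  }
  g <- igraph::graph_from_edgelist(cbind(from, to), directed = FALSE)
  g <- igraph::add_vertices(g, max(0L, n - igraph::vcount(g)))
  igraph::E(g)$weight <- w
  list(graph = g, coords = px)
}

#' Prune a skeleton to its central path
#'
#' The bud's central line is taken as the skeleton-graph diameter: the longest
#' geodesic (chamfer-weighted shortest path) between any two skeleton
#' endpoints, where an endpoint is a pixel with exactly one 8-neighbor. Side
#' branches (germination spurs, thinning artifacts) are discarded because no
#' endpoint pair through them beats the main path. An endpoint-free skeleton
#' (a closed loop) is opened at the shortest edge of its shortest cycle, with
#' a warning, before the diameter search.
#'
#' @param skeleton Logical matrix from [medial_axis_skeleton()] (or a 0/1
#'   matrix that is already one pixel wide).
#' @param pixel_pitch_mm Optional mm-per-pixel scale; fills `length_mm`.
#' @return A `skeleton_path`: list with `coords` (ordered pixel coordinates,
#'   consecutive rows 8-adjacent), `length_px` (chamfer geodesic length) and
#'   `length_mm` (`NA` unless a pitch is given).
#' @export
prune_to_central_path <- function(skeleton, pixel_pitch_mm = NA_real_) {
  skel <- skeleton > 0
  if (!any(skel)) stop("empty skeleton")
  sg <- skeleton_graph(skel)
  g <- sg$graph; coords <- sg$coords
  comp <- igraph::components(g)
  if (comp$no > 1L) {
    warning("skeleton has ", comp$no,
            " connected components; using the largest")
    keep <- which(comp$membership == which.max(comp$csize))
    g <- igraph::induced_subgraph(g, keep)
    coords <- coords[keep, , drop = FALSE]
  }
  if (nrow(coords) == 1L)
    return(structure(list(coords = coords, length_px = 0,
                          length_mm = 0 * pixel_pitch_mm),
                     class = "skeleton_path"))
  deg <- igraph::degree(g)
  ends <- which(deg == 1L)
  if (length(ends) < 2L) {
    warning("skeleton is a closed loop (fewer than two endpoints); ",
            "searching the longest geodesic over all skeleton pixels")
    ends <- seq_len(igraph::vcount(g))
  }
  dm <- igraph::distances(g, v = ends, to = ends)
  dm[!is.finite(dm)] <- -Inf
  best <- arrayInd(which.max(dm), dim(dm))
  vp <- igraph::shortest_paths(g, from = ends[best[1L]],
                               to = ends[best[2L]])$vpath[[1L]]
  path_coords <- coords[as.integer(vp), , drop = FALSE]
  lp <- path_length_pixels(path_coords)
  structure(list(coords = path_coords, length_px = lp,
                 length_mm = lp * pixel_pitch_mm),
            class = "skeleton_path")
}

#' @export
print.skeleton_path <- function(x, ...) {
  cat(sprintf("<skeleton_path> %d pixel(s), length %.2f px%s\n",
              nrow(x$coords), x$length_px,
              if (is.na(x$length_mm)) "" else
                sprintf(" = %.2f mm", x$length_mm)))
  invisible(x)
}

#' Chamfer length of an ordered pixel path
#'
#' Sums per-step distances along the path: 1 for axial steps, `sqrt(2)` for
#' diagonal steps (the Euclidean chamfer metric, unbiased on diagonals where
#' a raw pixel count would overestimate). A single-pixel path has length 0.
#'
#' @param path A `skeleton_path` or an ordered `n x 2` coordinate matrix with
#'   consecutive rows 8-adjacent.
#' @return Length in pixels.
#' @export
path_length_pixels <- function(path) {
  coords <- if (inherits(path, "skeleton_path")) path$coords else path
  if (is.null(dim(coords)) || ncol(coords) != 2L)
    stop("`path` must be an n x 2 coordinate matrix")
  n <- nrow(coords)
  if (n <= 1L) return(0)
  dr <- abs(diff(coords[, 1L])); dc <- abs(diff(coords[, 2L]))
  if (any(dr > 1L | dc > 1L | (dr == 0L & dc == 0L)))
    stop("consecutive path pixels must be distinct and 8-adjacent")
  sum(ifelse(dr == 1L & dc == 1L, sqrt(2), 1))
}

#' Pixel-to-millimetre conversion via a reference object
#'
#' The imaging scene contains a box of known physical side length spanning a
#' known number of pixels; lengths scale by `box_side_mm / box_side_px`. With
#' the default 250 mm box spanning 1164 px, one pixel corresponds to 0.215
#' mm.
#'
#' @param length_px Length in pixels.
#' @param box_side_mm Physical side length of the reference box (mm).
#' @param box_side_px Pixels spanned by that side in the image.
#' @return Length in millimetres.
#' @examples
#' round(pixels_to_mm(1, 250, 1164), 3)  # 0.215 mm per pixel
#' @export
pixels_to_mm <- function(length_px, box_side_mm = 250, box_side_px = 1164) {
  if (box_side_px <= 0) stop("`box_side_px` must be positive")
  length_px * (box_side_mm / box_side_px)
}

# Euclidean length of the path resampled every `m` pixels: averages out the
# rasterization zigzag that biases the raw chamfer sum by up to ~8% on
# straight lines at unlucky angles (worst at 22.5 degrees)
resampled_path_length <- function(coords, m = 5L) {
  n <- nrow(coords)
  if (n <= 1L) return(0)
  idx <- unique(c(seq(1L, n, by = m), n))
  p <- coords[idx, , drop = FALSE]
  sum(sqrt(rowSums(diff(p)^2)))
}

#' Measure bud length from a binary mask
#'
#' Full measurement chain: skeletonize the mask, prune to the central path,
#' estimate the path length, convert to millimetres. The reported length is
#' the Euclidean length of the central path resampled every `resample`
#' pixels, which removes the raster zigzag bias of the raw chamfer sum
#' (the chamfer metric overestimates straight segments by up to ~8% at
#' orientations near 22.5 degrees; the resampled estimate stays within
#' ~2.5% at any orientation). The raw chamfer path is returned in `path`.
#' The mask is measured as given; separating the bud from the kernel is the
#' upstream segmenter's job.
#'
#' @param mask Binary matrix (1 = bud).
#' @param box_side_mm,box_side_px Reference-object scale (see
#'   [pixels_to_mm()]).
#' @param resample Resampling stride (pixels) of the length estimator.
#' @return A `bud_measurement`: list with `length_px` (resampled estimate),
#'   `length_mm`, and `path` (the pruned `skeleton_path`, whose own
#'   `length_px` is the chamfer geodesic).
#' @export
measure_bud_length <- function(mask, box_side_mm = 250, box_side_px = 1164,
                               resample = 5L) {
  skel <- medial_axis_skeleton(mask)
  pitch <- box_side_mm / box_side_px
  path <- prune_to_central_path(skel, pixel_pitch_mm = pitch)
  len <- resampled_path_length(path$coords, resample)
  structure(list(length_px = len, length_mm = len * pitch, path = path),
            class = "bud_measurement")
}

#' @export
print.bud_measurement <- function(x, ...) {
  cat(sprintf("<bud_measurement> %.2f px = %.2f mm (chamfer %.2f px)\n",
              x$length_px, x$length_mm, x$path$length_px))
  invisible(x)
}
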