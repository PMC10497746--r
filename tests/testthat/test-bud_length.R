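test_that("skeleton of a wide rectangle is its middle row", {
  mask <- matrix(0L, 11, 56)
  mask[4:8, 4:53] <- 1L  # 5 px tall, 50 px wide
  sk <- medial_axis_skeleton(mask)
  px <- which(sk, arr.ind = TRUE)
  expect_true(all(px[, 1] %in% 5:7))            # near the center row
  expect_gt(diff(range(px[, 2])), 40)           # spans most of the length
  expect_true(all(mask[px] == 1L))              # contained in foreground
})

test_that("a one-pixel-wide line is its own skeleton", {
  mask <- matrix(0L, 10, 30)
  mask[5, 3:27] <- 1L
  expect_equal(medial_axis_skeleton(mask), mask == 1L)
  diagm <- matrix(0L, 20, 20)
  diagm[cbind(3:17, 3:17)] <- 1L
  expect_equal(medial_axis_skeleton(diagm), diagm == 1L)
  expect_error(medial_axis_skeleton(matrix(0L, 5, 5)), "empty mask")
})

test_that("a disk collapses to a short central remnant", {
  mask <- matrix(0L, 31, 31)
  rr <- seq_len(31)
  mask[outer((rr - 16)^2, (rr - 16)^2, `+`) <= 144] <- 1L  # radius 12
  sk <- medial_axis_skeleton(mask)
  path <- prune_to_central_path(sk)
  expect_lt(path$length_px, 12)  # far shorter than the 24 px diameter
})

test_that("pruning returns the longest endpoint geodesic, dropping spurs", {
  sk <- matrix(FALSE, 15, 40)
  sk[8, 4:33] <- TRUE        # 30-pixel main path
  sk[4:7, 15] <- TRUE        # 4-pixel spur
  path <- prune_to_central_path(sk)
  expect_equal(path$length_px, 29)          # 30 pixels = 29 unit steps
  expect_true(all(path$coords[, 1] == 8))
  # unbranched path is returned unchanged
  line <- matrix(FALSE, 10, 20)
  line[5, 2:18] <- TRUE
  p2 <- prune_to_central_path(line)
  expect_setequal(which(line), p2$coords[, 1] + (p2$coords[, 2] - 1) * 10)
})

test_that("Y-shaped skeleton keeps the two long arms", {
  sk <- matrix(FALSE, 50, 50)
  sk[25, 5:25] <- TRUE                    # west arm, ~20 px
  sk[25, 25:45] <- TRUE                   # east arm, ~20 px
  sk[cbind(24:20, 26:30)] <- TRUE         # short diagonal arm, 5 px
  path <- prune_to_central_path(sk)
  expect_equal(path$length_px, 40)        # both long arms
  # agrees with the all-pairs Dijkstra oracle
  oracle <- dijkstra_all_pairs(sk)
  deg1 <- which(rowSums(oracle$dist <= 1 + 1e-9 & oracle$dist > 0) == 1)
  expect_equal(path$length_px, max(oracle$dist[deg1, deg1]), tolerance = 1e-9)
})

test_that("pruned length is maximal among endpoint geodesics (random trees)", {
  set.seed(50)
  for (rep in 1:5) {
    sk <- matrix(FALSE, 30, 30)
    r <- 15; c <- 15
    sk[r, c] <- TRUE
    for (arm in 1:4) {
      rr <- r; cc <- c
      dir <- sample(list(c(0, 1), c(1, 0), c(1, 1), c(0, -1), c(-1, 0)), 1)[[1]]
      for (step in seq_len(sample(4:10, 1))) {
        rr <- min(max(rr + dir[1], 1), 30)
        cc <- min(max(cc + dir[2], 1), 30)
        sk[rr, cc] <- TRUE
      }
    }
    path <- prune_to_central_path(sk)
    oracle <- dijkstra_all_pairs(sk)
    expect_equal(path$length_px, max(oracle$dist[is.finite(oracle$dist)]),
                 tolerance = 1e-9)
  }
})

test_that("a closed loop is opened with a warning", {
  sk <- matrix(FALSE, 12, 12)
  sk[3, 3:9] <- TRUE; sk[9, 3:9] <- TRUE
  sk[3:9, 3] <- TRUE; sk[3:9, 9] <- TRUE
  expect_warning(path <- prune_to_central_path(sk), "closed loop")
  expect_gt(path$length_px, 10)
})

test_that("chamfer path length: 1 per axial step, sqrt(2) per diagonal", {
  horiz <- cbind(rep(5, 11), 1:11)
  expect_equal(path_length_pixels(horiz), 10)
  diag <- cbind(1:11, 1:11)
  expect_equal(path_length_pixels(diag), 10 * sqrt(2))
  expect_equal(path_length_pixels(cbind(3, 3)), 0)
  expect_error(path_length_pixels(cbind(c(1, 5), c(1, 1))), "8-adjacent")
})

test_that("pixel-to-mm conversion reproduces the 250 mm / 1164 px scale", {
  expect_equal(round(pixels_to_mm(1), 3), 0.215)
  expect_equal(pixels_to_mm(100), 100 * 250 / 1164)
  expect_equal(pixels_to_mm(0), 0)
  expect_equal(pixels_to_mm(10, 100, 50), 20)
  expect_error(pixels_to_mm(10, 250, 0), "positive")
})

test_that("synthetic bud lengths are recovered within tolerance", {
  for (cfg in list(list(L = 80, cur = 0, sp = 0L),
                   list(L = 120, cur = 1.2, sp = 0L),
                   list(L = 100, cur = 0.8, sp = 3L))) {
    bud <- generate_bud_mask(bud_spec(length_px = cfg$L, width_px = 5,
                                      curvature = cfg$cur, n_spurs = cfg$sp,
                                      spur_length_px = 9, seed = 60 + cfg$L))
    res <- measure_bud_length(bud$mask)
    expect_lt(res$length_px - bud$true_length_px,
              0.05 * bud$true_length_px)
    expect_lt(bud$true_length_px - res$length_px,
              0.05 * bud$true_length_px + 5)  # width allowance at the tips
    expect_equal(res$length_mm, res$length_px * 250 / 1164)
  }
})

test_that("measured length is rotation-robust", {
  # the same 64-px straight strip drawn axis-aligned and at 45 degrees
  strip_mask <- function(angle, L = 64, w = 5, n = 90) {
    p0 <- c(20, 12)
    dir <- c(sin(angle), cos(angle))
    t_dense <- seq(0, L, by = 0.25)
    pts <- cbind(p0[1] + dir[1] * t_dense, p0[2] + dir[2] * t_dense)
    rr <- seq_len(n); cc <- seq_len(n)
    d2 <- matrix(Inf, n, n)
    for (i in seq_len(nrow(pts)))
      d2 <- pmin(d2, outer((rr - pts[i, 1])^2, (cc - pts[i, 2])^2, `+`))
    matrix(as.integer(sqrt(d2) <= w / 2), n, n)
  }
  l0 <- measure_bud_length(strip_mask(0))$length_px
  l45 <- measure_bud_length(strip_mask(pi / 4))$length_px
  expect_lt(abs(l45 - l0), 0.03 * l0)
})
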