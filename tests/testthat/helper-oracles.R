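# Independent brute-force oracles used by the unit and acceptance tests.
# These deliberately avoid the package's own code paths.

# SPA oracle: explicit QR re-orthogonalization at every step
spa_oracle <- function(X, start_band, k) {
  sel <- start_band
  while (length(sel) < k) {
    Q <- qr.Q(qr(X[, sel, drop = FALSE]))
    R <- X - Q %*% (t(Q) %*% X)
    norms <- sqrt(colSums(R^2))
    norms[sel] <- -Inf
    sel <- c(sel, which.max(norms))
  }
  sel
}

# block-extraction oracle: naive scan over every grid placement of one seed
oracle_block_count <- function(labels, seed_id, s) {
  px <- which(labels == seed_id, arr.ind = TRUE)
  if (nrow(px) == 0L) return(0L)
  r0 <- min(px[, 1]); c0 <- min(px[, 2])
  r1 <- max(px[, 1]); c1 <- max(px[, 2])
  count <- 0L
  rr <- r0
  while (rr + s - 1 <= min(r1, nrow(labels))) {
    cc <- c0
    while (cc + s - 1 <= min(c1, ncol(labels))) {
      full <- TRUE
      for (i in rr:(rr + s - 1)) {
        for (j in cc:(cc + s - 1)) {
          if (labels[i, j] != seed_id) { full <- FALSE; break }
        }
        if (!full) break
      }
      if (full) count <- count + 1L
      cc <- cc + s
    }
    rr <- rr + s
  }
  count
}

# AP oracle: enumerate every distinct threshold, sum the step-curve area
ap_oracle <- function(scores, truth, n_positives = sum(truth)) {
  thr <- sort(unique(scores), decreasing = TRUE)
  prev_rec <- 0
  ap <- 0
  for (t in thr) {
    keep <- scores >= t
    prec <- sum(truth[keep]) / sum(keep)
    rec <- sum(truth[keep]) / n_positives
    ap <- ap + (rec - prev_rec) * prec
    prev_rec <- rec
  }
  ap
}

# all-pairs geodesic oracle on a skeleton: O(V^2) Dijkstra, chamfer weights
dijkstra_all_pairs <- function(skel) {
  px <- which(skel, arr.ind = TRUE)
  n <- nrow(px)
  adj <- vector("list", n)
  for (i in seq_len(n)) {
    dr <- abs(px[, 1] - px[i, 1]); dc <- abs(px[, 2] - px[i, 2])
    nb <- which(dr <= 1 & dc <= 1 & (dr + dc) > 0)
    adj[[i]] <- list(j = nb, w = ifelse(dr[nb] + dc[nb] == 2, sqrt(2), 1))
  }
  D <- matrix(Inf, n, n)
  for (s in seq_len(n)) {
    dist <- rep(Inf, n); dist[s] <- 0
    done <- rep(FALSE, n)
    repeat {
      u <- which(!done & dist == min(dist[!done]))[1]
      if (!is.finite(dist[u])) break
      done[u] <- TRUE
      for (e in seq_along(adj[[u]]$j)) {
        v <- adj[[u]]$j[e]
        nd <- dist[u] + adj[[u]]$w[e]
        if (nd < dist[v]) dist[v] <- nd
      }
      if (all(done | !is.finite(dist))) break
    }
    D[s, ] <- dist
  }
  list(coords = px, dist = D)
}

# random blobby label mask (unioned rectangles + ellipses), for block oracles
random_blob_mask <- function(nr = 40, nc = 40, n_seeds = 2) {
  labels <- matrix(0L, nr, nc)
  for (k in seq_len(n_seeds)) {
    ctr <- c(sample(8:(nr - 8), 1), sample(8:(nc - 8), 1))
    for (piece in seq_len(sample(1:3, 1))) {
      if (runif(1) < 0.5) {
        h <- sample(3:12, 1); w <- sample(3:12, 1)
        r0 <- max(1, ctr[1] - h %/% 2 + sample(-3:3, 1))
        c0 <- max(1, ctr[2] - w %/% 2 + sample(-3:3, 1))
        labels[r0:min(nr, r0 + h), c0:min(nc, c0 + w)] <- k
      } else {
        a <- runif(1, 2, 7); b <- runif(1, 2, 7)
        rr <- seq_len(nr); cc <- seq_len(nc)
        inside <- outer(((rr - ctr[1]) / a)^2, ((cc - ctr[2]) / b)^2, `+`) <= 1
        labels[inside] <- k
      }
    }
  }
  labels
}

# small standardized block set of two separable classes, for model tests
make_separable_blocks <- function(n_per_class = 10, s = 5, K = 6,
                                  offset = 1, noise = 0.2, seed = 1) {
  set.seed(seed)
  blocks <- list()
  for (i in seq_len(2 * n_per_class)) {
    cls <- if (i <= n_per_class) 1L else 2L
    base <- if (cls == 1L) 0 else offset
    blocks[[i]] <- list(
      data = array(base + rnorm(s * s * K, sd = noise), c(s, s, K)),
      seed_id = i, class_label = cls, origin = c(1L, 1L))
  }
  structure(list(blocks = blocks, block_size = s, band_indices = NULL,
                 dropped_seeds = integer(0)),
            class = "block_set")
}

# ellipse painter for segmentation fixtures
paint_ellipse <- function(img, ctr, ax, value) {
  rr <- seq_len(nrow(img)); cc <- seq_len(ncol(img))
  inside <- outer(((rr - ctr[1]) / ax[1])^2, ((cc - ctr[2]) / ax[2])^2, `+`) <= 1
  img[inside] <- value
  img
}
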