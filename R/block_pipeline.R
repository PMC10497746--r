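#' Decompose masked seeds into full-foreground spatial blocks
#'
#' Tiles each seed instance with non-overlapping `s x s` windows on a grid
#' anchored at the seed's bounding-box top-left corner and keeps a block only
#' if every one of its pixels belongs to that seed (blocks touching background
#' are discarded, so no 0-pixels reach the classifier). Each kept block
#' carries the seed's identity and class label. Anchoring at the per-seed
#' bounding box rather than the scene corner maximizes the number of
#' full-foreground blocks a seed can contribute.
#'
#' @param cube A [hyper_cube()] (typically already reduced to the selected
#'   key wavelengths).
#' @param mask A [seed_mask()] aligned to the cube.
#' @param block_size Window side `s` in pixels (classification uses 5).
#' @param labels Per-seed class vector, length `n_seeds`; coded 1 = viable,
#'   2 = nonviable. May be `NULL` at pure inference time.
#' @param overlap_stride Grid step; defaults to `block_size` (disjoint tiles).
#' @return A `block_set`: list with `blocks` (each a list `data` `s x s x K`,
#'   `seed_id`, `class_label`, `origin` = 1-based (row, col) of the top-left
#'   pixel), `block_size`, `band_indices` (`NULL` unless set by the caller)
#'   and `dropped_seeds` (ids too small to host any full window, warned
#'   about).
#' @export
extract_blocks <- function(cube, mask, block_size = 5L, labels = NULL,
                           overlap_stride = NULL) {
  stopifnot(inherits(cube, "hyper_cube"), inherits(mask, "seed_mask"))
  s <- as.integer(block_size)
  if (s < 1L) stop("`block_size` must be >= 1")
  stride <- if (is.null(overlap_stride)) s else as.integer(overlap_stride)
  if (stride < 1L) stop("`overlap_stride` must be >= 1")
  d <- dim(cube$data)
  if (!identical(d[1:2], dim(mask$labels))) stop("cube and mask are misaligned")
  if (!is.null(labels) && length(labels) != mask$n_seeds)
    stop("`labels` must have one class per seed")
  blocks <- list()
  dropped <- integer(0)
  lab <- mask$labels
  for (k in seq_len(mask$n_seeds)) {
    px <- which(lab == k, arr.ind = TRUE)
    r0 <- min(px[, 1L]); c0 <- min(px[, 2L])
    r1 <- max(px[, 1L]); c1 <- max(px[, 2L])
    kept <- 0L
    if (r1 - r0 + 1L < s || c1 - c0 + 1L < s) { dropped <- c(dropped, k); next }
    for (rr in seq(r0, r1 - s + 1L, by = stride)) {
      if (rr + s - 1L > d[1L]) break
      for (cc in seq(c0, c1 - s + 1L, by = stride)) {
        if (cc + s - 1L > d[2L]) break
        win <- lab[rr:(rr + s - 1L), cc:(cc + s - 1L)]
        if (all(win == k)) {
          kept <- kept + 1L
          blocks[[length(blocks) + 1L]] <- list(
            data = cube$data[rr:(rr + s - 1L), cc:(cc + s - 1L), , drop = FALSE],
            seed_id = k,
            class_label = if (!is.null(labels)) labels[k] else NA_integer_,
            origin = c(rr, cc))
        }
      }
    }
    if (kept == 0L) dropped <- c(dropped, k)
  }
  if (length(dropped))
    warning("seed(s) too small for any full ", s, "x", s, " block, dropped: ",
            paste(dropped, collapse = ", "))
  structure(list(blocks = blocks, block_size = s, band_indices = NULL,
                 dropped_seeds = dropped),
            class = "block_set")
}

#' @export
print.block_set <- function(x, ...) {
  cat(sprintf("<block_set> %d block(s) of %dx%d from %d seed(s)\n",
              length(x$blocks), x$block_size, x$block_size,
              length(unique(vapply(x$blocks, `[[`, 0L, "seed_id")))))
  invisible(x)
}

#' Subset a block set by seed ids
#'
#' Splits stay at the seed level: all blocks of a seed travel together.
#'
#' @param blocks A `block_set`.
#' @param seed_ids Seeds to keep.
#' @return A `block_set` with only those seeds' blocks.
#' @export
subset_blocks <- function(blocks, seed_ids) {
  stopifnot(inherits(blocks, "block_set"))
  keep <- vapply(blocks$blocks, function(b) b$seed_id %in% seed_ids, logical(1))
  blocks$blocks <- blocks$blocks[keep]
  blocks
}

#' Systematic train/test split over the acquisition order
#'
#' Seeds are imaged sequentially along the aging gradient, so a systematic
#' pick of every `stride`-th seed (starting with the first) yields a test set
#' spanning all aging stages: test ordinals are `1, 1+stride, 1+2*stride, ...`
#' and the remainder trains. With 750 seeds and stride 10 this gives exactly
#' 75 test and 675 training seeds. The split is at the seed level; blocks
#' never straddle it.
#'
#' @param n_seeds Number of seeds, ordered by acquisition.
#' @param stride Sampling stride, `>= 2`.
#' @return List with integer vectors `train` and `test` (ordinal positions).
#' @export
systematic_split <- function(n_seeds, stride = 10L) {
  n_seeds <- as.integer(n_seeds); stride <- as.integer(stride)
  if (stride < 2L) stop("`stride` must be >= 2")
  if (n_seeds < 1L) stop("`n_seeds` must be >= 1")
  if (stride >= n_seeds)
    warning("stride >= n_seeds gives a trivial split (test = {seed 1})")
  test <- seq.int(1L, n_seeds, by = stride)
  list(train = setdiff(seq_len(n_seeds), test), test = test)
}

#' Aggregate block votes into a whole-seed call
#'
#' The seed is assigned the modal class of its block predictions, requiring
#' strictly more than half of the blocks for a decided call; an exact tie is
#' resolved by `tie_rule`. The default tie rule is `"nonviable"`: calling a
#' viable seed dead wastes one seed, calling a dead seed viable wastes a field
#' slot, so the conservative call is nonviable.
#'
#' @param block_votes Vector of per-block predicted classes (1 = viable,
#'   2 = nonviable).
#' @param tie_rule `"nonviable"`, `"viable"`, or `"first"` (modal class with
#'   the lowest label).
#' @param seed_id Optional id recorded in the result.
#' @param block_scores Optional per-block class-score matrix carried through.
#' @return A `seed_prediction`: list with `seed_id`, `block_votes`,
#'   `voted_class`, `vote_fraction` (modal count / total) and `tie` flag.
#' @export
vote_seed <- function(block_votes, tie_rule = c("nonviable", "viable", "first"),
                      seed_id = NA_integer_, block_scores = NULL) {
  tie_rule <- match.arg(tie_rule)
  if (length(block_votes) == 0L) stop("empty block vote vector")
  tab <- table(block_votes)
  top <- max(tab)
  winners <- as.integer(names(tab)[tab == top])
  tie <- length(winners) > 1L
  voted <- if (!tie) winners else switch(tie_rule,
    nonviable = 2L,
    viable = 1L,
    first = min(winners))
  structure(list(seed_id = seed_id, block_votes = block_votes,
                 block_scores = block_scores, voted_class = voted,
                 vote_fraction = top / length(block_votes), tie = tie),
            class = "seed_prediction")
}

#' Seed-level accuracy of voted predictions
#'
#' @param predictions List of `seed_prediction` objects (see [vote_seed()]).
#' @param truth Named or positional per-seed class vector; names (or
#'   positions) must cover every predicted `seed_id`.
#' @return Fraction of seeds whose voted class equals the truth.
#' @export
seed_level_accuracy <- function(predictions, truth) {
  if (length(predictions) == 0L) stop("empty prediction list")
  ids <- vapply(predictions, `[[`, 0L, "seed_id")
  voted <- vapply(predictions, `[[`, 0L, "voted_class")
  if (!is.null(names(truth))) {
    miss <- setdiff(as.character(ids), names(truth))
    if (length(miss)) stop("no truth entry for seed(s): ",
                           paste(miss, collapse = ", "))
    tr <- truth[as.character(ids)]
  } else {
    if (any(ids < 1L) || any(ids > length(truth)))
      stop("prediction seed_id outside truth range")
    tr <- truth[ids]
  }
  mean(voted == as.integer(tr))
}
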