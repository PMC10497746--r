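make_cube_mask <- function(labels, K = 3) {
  d <- dim(labels)
  list(cube = hyper_cube(array(runif(prod(d) * K), c(d, K)), seq_len(K)),
       mask = seed_mask(labels))
}

test_that("a 10x10 square seed tiles into exactly four 5x5 blocks", {
  lab <- matrix(0L, 20, 20); lab[6:15, 4:13] <- 1L
  cm <- make_cube_mask(lab)
  bs <- extract_blocks(cm$cube, cm$mask, 5, labels = 2L)
  expect_length(bs$blocks, 4L)
  expect_equal(sort(vapply(bs$blocks, function(b) paste(b$origin,
    collapse = ","), "")), c("11,4", "11,9", "6,4", "6,9"))
  expect_true(all(vapply(bs$blocks, function(b) b$class_label, 0L) == 2L))
  expect_true(all(vapply(bs$blocks, function(b)
    identical(dim(b$data), c(5L, 5L, 3L)), TRUE)))
})

test_that("a seed with no full window is dropped with a warning", {
  lab <- matrix(0L, 15, 15)
  lab[cbind(c(1, 3, 5, 7, 9, 11, 13, 2, 4, 6, 8, 10),
            c(1, 4, 7, 10, 13, 2, 5, 8, 11, 14, 3, 6))] <- 1L
  cm <- make_cube_mask(lab)
  expect_warning(bs <- extract_blocks(cm$cube, cm$mask, 5), "dropped")
  expect_length(bs$blocks, 0L)
  expect_equal(bs$dropped_seeds, 1L)
})

test_that("kept-block counts match the brute-force placement oracle", {
  # deterministic circle fixture
  lab <- matrix(0L, 30, 30)
  rr <- seq_len(30)
  lab[outer((rr - 15)^2, (rr - 15)^2, `+`) <= 100] <- 1L
  cm <- make_cube_mask(lab)
  bs <- extract_blocks(cm$cube, cm$mask, 5)
  expect_length(bs$blocks, oracle_block_count(lab, 1L, 5L))
  # random blob masks, several block sizes
  set.seed(40)
  for (rep in 1:10) {
    lab <- random_blob_mask(n_seeds = 2)
    cm <- make_cube_mask(lab)
    for (s in c(3L, 5L)) {
      bs <- suppressWarnings(extract_blocks(cm$cube, cm$mask, s))
      want <- sum(vapply(seq_len(max(lab)), function(k)
        oracle_block_count(lab, k, s), 0L))
      expect_length(bs$blocks, want)
    }
  }
})

test_that("no block contains a background or foreign pixel", {
  set.seed(41)
  lab <- random_blob_mask(50, 50, 3)
  cm <- make_cube_mask(lab)
  bs <- suppressWarnings(extract_blocks(cm$cube, cm$mask, 5))
  for (b in bs$blocks) {
    win <- cm$mask$labels[b$origin[1] + 0:4, b$origin[2] + 0:4]
    expect_true(all(win == b$seed_id))
  }
})

test_that("systematic stride-10 split of 750 seeds gives 75 test / 675 train", {
  spl <- systematic_split(750, 10)
  expect_length(spl$test, 75L)
  expect_length(spl$train, 675L)
  expect_equal(spl$test[1:3], c(1L, 11L, 21L))
})

test_that("systematic split partitions the seeds", {
  for (n in c(10, 37, 96, 750)) {
    spl <- suppressWarnings(systematic_split(n, 10))
    expect_setequal(c(spl$train, spl$test), seq_len(n))
    expect_length(intersect(spl$train, spl$test), 0L)
    if (n %% 10 == 0) expect_equal(length(spl$test) / n, 0.1)
  }
  expect_warning(spl <- systematic_split(10, 10), "trivial")
  expect_equal(spl$test, 1L)
  expect_error(systematic_split(10, 1), "stride")
})

test_that("voting follows the majority with the documented tie rule", {
  v <- vote_seed(c(1, 1, 1, 1))
  expect_equal(v$voted_class, 1L)
  expect_equal(v$vote_fraction, 1)
  v <- vote_seed(c(1, 1, 2))
  expect_equal(v$voted_class, 1L)
  expect_equal(v$vote_fraction, 2 / 3)
  v <- vote_seed(c(1, 2))  # exact tie -> nonviable by default
  expect_equal(v$voted_class, 2L)
  expect_true(v$tie)
  expect_equal(vote_seed(c(1, 2), tie_rule = "viable")$voted_class, 1L)
  expect_error(vote_seed(integer(0)), "empty")
})

test_that("flipping minority votes never changes the call; all majority does", {
  set.seed(42)
  for (rep in 1:50) {
    n <- sample(3:11, 1)
    votes <- sample(1:2, n, replace = TRUE)
    v <- vote_seed(votes)
    if (v$tie) next
    minority <- which(votes != v$voted_class)
    if (length(minority)) {
      flip <- votes
      keep <- sample(minority, sample(length(minority), 1))
      flip[keep] <- v$voted_class
      expect_equal(vote_seed(flip)$voted_class, v$voted_class)
    }
    all_flip <- votes
    all_flip[votes == v$voted_class] <- 3L - v$voted_class
    expect_false(vote_seed(all_flip)$voted_class == v$voted_class)
  }
})

test_that("seed-level accuracy counts voted matches", {
  preds <- list(vote_seed(c(1, 1), seed_id = 1L),
                vote_seed(c(2, 2), seed_id = 2L),
                vote_seed(c(1, 1, 1), seed_id = 3L),
                vote_seed(c(2), seed_id = 4L))
  expect_equal(seed_level_accuracy(preds, c(1, 2, 1, 2)), 1)
  expect_equal(seed_level_accuracy(preds, c(1, 2, 2, 2)), 0.75)
  expect_error(seed_level_accuracy(list(), c(1)), "empty")
  expect_error(seed_level_accuracy(preds, c(`5` = 1, `6` = 2, `7` = 1,
                                            `8` = 2)), "no truth")
})

test_that("seed-level splits keep all blocks of a seed together", {
  set.seed(43)
  lab <- random_blob_mask(60, 60, 3)
  cm <- make_cube_mask(lab)
  bs <- suppressWarnings(extract_blocks(cm$cube, cm$mask, 3))
  sub <- subset_blocks(bs, c(1L, 3L))
  ids <- vapply(sub$blocks, `[[`, 0L, "seed_id")
  expect_true(all(ids %in% c(1L, 3L)))
})
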