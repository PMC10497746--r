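#' Configuration for the 3D convolutional viability classifier
#'
#' Two architectures share one engine. The `multiscale` variant runs, in each
#' of three convolution modules, four parallel 3D-convolution branches with
#' kernels 3x3x3, 3x3x5, 3x5x5 and 5x5x5 (depth x height x width, spectral
#' depth first), 16/32/64 filters per branch in modules 1/2/3, ReLU after
#' every branch, and channel concatenation (module widths 64/128/256). The
#' `conventional` variant is the single-branch 3x3x3 baseline with the same
#' 16/32/64 filter progression. All branches use same-padding and stride 1 so
#' their outputs are channel-concatenable; max pooling of extent 2 along the
#' spectral axis follows modules 1 and 2 (the 5x5 spatial grid is left
#' intact). A 128-unit fully connected layer and a softmax output layer
#' produce the two class scores. Training minimizes cross-entropy with Adam.
#'
#' @param architecture `"multiscale"` or `"conventional"`.
#' @param input_shape Block shape `c(s, s, K)`: spatial side and band count.
#' @param kernel_bank List of kernel triples (depth, height, width); defaults
#'   depend on `architecture`.
#' @param filters_per_module Filters per branch in each module.
#' @param fc_width Width of the fully connected layer.
#' @param n_classes Number of classes (2: viable / nonviable).
#' @param pool_after Logical per module: spectral max pooling after it.
#' @param learning_rate,batch_size,epochs Adam optimizer settings.
#' @param seed Integer seed governing weight init and batch shuffling; a
#'   fixed seed makes training bit-reproducible on one machine.
#' @return A `model_config` list.
#' @export
model_config <- function(architecture = c("multiscale", "conventional"),
                         input_shape = c(5L, 5L, 18L),
                         kernel_bank = NULL,
                         filters_per_module = c(16L, 32L, 64L),
                         fc_width = 128L, n_classes = 2L,
                         pool_after = c(TRUE, TRUE, FALSE),
                         learning_rate = 1e-3, batch_size = 64L,
                         epochs = 70L, seed = 1L) {
  architecture <- match.arg(architecture)
  if (is.null(kernel_bank))
    kernel_bank <- if (architecture == "multiscale")
      list(c(3L, 3L, 3L), c(3L, 3L, 5L), c(3L, 5L, 5L), c(5L, 5L, 5L))
    else list(c(3L, 3L, 3L))
  if (length(filters_per_module) != 3L)
    stop("`filters_per_module` must have length 3")
  if (length(pool_after) != length(filters_per_module))
    stop("`pool_after` must have one entry per module")
  s <- input_shape[1L]
  for (kk in kernel_bank) {
    if (length(kk) != 3L || any(kk %% 2L == 0L))
      stop("kernels must be odd triples (depth, height, width)")
    if (kk[2L] > s || kk[3L] > s)
      stop("kernel spatial extent ", kk[2L], "x", kk[3L],
           " exceeds block size ", s)
  }
  structure(list(architecture = architecture,
                 input_shape = as.integer(input_shape),
                 kernel_bank = kernel_bank,
                 filters_per_module = as.integer(filters_per_module),
                 fc_width = as.integer(fc_width),
                 n_classes = as.integer(n_classes),
                 pool_after = as.logical(pool_after),
                 learning_rate = learning_rate,
                 batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs),
                 seed = as.integer(seed)),
            class = "model_config")
}

config_kernels <- function(config) {
  do.call(rbind, config$kernel_bank)
}

# (D, H, W) tensor dims of a block: spectral depth first
config_dhw <- function(config) {
  c(config$input_shape[3L], config$input_shape[1L], config$input_shape[2L])
}

#' Build (initialize) a viability classifier
#'
#' Allocates and He-initializes the weights for the architecture described by
#' `config`. Weights are plain R matrices in the returned object, so they can
#' be inspected, serialized with `saveRDS()`, or zeroed for diagnostic
#' purposes.
#'
#' @param config A [model_config()].
#' @return A `viability_model`: list with `config`, `weights`, and
#'   `module_channels` (post-concatenation channel widths, 4x the per-branch
#'   filter count for the multiscale variant).
#' @export
build_model <- function(config) {
  stopifnot(inherits(config, "model_config"))
  w <- cnn3d_init(config_kernels(config), config$filters_per_module,
                  as.integer(config$pool_after), config_dhw(config),
                  config$fc_width, config$n_classes, config$seed)
  structure(list(config = config,
                 weights = w[c("conv_W", "conv_b", "fc1_W", "fc1_b",
                               "fc2_W", "fc2_b")],
                 module_channels = w$module_channels,
                 flat_dim = w$flat_dim,
                 trained = FALSE),
            class = "viability_model")
}

#' @export
print.viability_model <- function(x, ...) {
  cat(sprintf("<viability_model> %s, input %s, module channels %s%s\n",
              x$config$architecture,
              paste(x$config$input_shape, collapse = "x"),
              paste(x$module_channels, collapse = "/"),
              if (isTRUE(x$trained)) " (trained)" else ""))
  invisible(x)
}

# block_set -> (flattened tensor vector, labels); tensor dim (D=K, H=s, W=s, N)
blocks_to_tensor <- function(blocks, config) {
  stopifnot(inherits(blocks, "block_set"))
  n <- length(blocks$blocks)
  dhw <- config_dhw(config)
  if (n == 0L) return(list(x = numeric(0), y = integer(0), n = 0L))
  x <- vapply(blocks$blocks, function(b) {
    d <- dim(b$data)
    if (!identical(as.integer(d), config$input_shape))
      stop("block shape ", paste(d, collapse = "x"),
           " does not match model input ",
           paste(config$input_shape, collapse = "x"))
    as.vector(aperm(b$data, c(3L, 1L, 2L)))  # (band, row, col) = (D, H, W)
  }, numeric(prod(dhw)))
  y <- vapply(blocks$blocks, function(b) as.integer(b$class_label), 0L)
  list(x = as.vector(x), y = y, n = n)
}

#' Train a viability classifier on standardized blocks
#'
#' Minimizes softmax cross-entropy with Adam. All randomness (weight
#' initialization happened in [build_model()]; here, epoch-wise batch
#' shuffling) derives from `config$seed`, so two runs with the same data and
#' seed give identical histories. Blocks should be standardized first
#' ([standardize_blocks()]).
#'
#' @param model A `viability_model` from [build_model()].
#' @param train_blocks Training `block_set` with class labels (both classes
#'   must be present).
#' @param eval_blocks Optional held-out `block_set` scored every epoch.
#' @param epochs,batch_size,learning_rate Optional overrides of the config.
#' @return List with `model` (trained) and `history` (data.frame: epoch,
#'   train_loss, train_accuracy, test_accuracy).
#' @export
train_model <- function(model, train_blocks, eval_blocks = NULL,
                        epochs = NULL, batch_size = NULL,
                        learning_rate = NULL) {
  stopifnot(inherits(model, "viability_model"))
  cfg <- model$config
  tr <- blocks_to_tensor(train_blocks, cfg)
  if (tr$n == 0L) stop("empty training block set")
  if (anyNA(tr$y)) stop("training blocks must carry class labels")
  if (length(unique(tr$y)) < 2L)
    stop("training set contains a single class; need both")
  ev <- if (!is.null(eval_blocks)) blocks_to_tensor(eval_blocks, cfg)
        else list(x = numeric(0), y = integer(0), n = 0L)
  res <- cnn3d_train(model$weights, config_kernels(cfg),
                     cfg$filters_per_module, as.integer(cfg$pool_after),
                     config_dhw(cfg), cfg$fc_width, cfg$n_classes,
                     tr$x, tr$y, ev$x, ev$y,
                     if (is.null(epochs)) cfg$epochs else as.integer(epochs),
                     if (is.null(batch_size)) cfg$batch_size
                     else as.integer(batch_size),
                     if (is.null(learning_rate)) cfg$learning_rate
                     else learning_rate,
                     cfg$seed)
  model$weights <- res$weights
  model$trained <- TRUE
  list(model = model, history = res$history)
}

#' Per-block class scores and labels
#'
#' Forward pass of the classifier over a block set. Scores are softmax
#' probabilities (each row sums to 1); labels are the argmax class.
#'
#' @param model A `viability_model`.
#' @param blocks A `block_set` whose block shape matches the model input.
#' @return List with `scores` (n_blocks x n_classes matrix), `labels`
#'   (argmax class, 1 = viable / 2 = nonviable) and `seed_ids`.
#' @export
predict_blocks <- function(model, blocks) {
  stopifnot(inherits(model, "viability_model"))
  te <- blocks_to_tensor(blocks, model$config)
  if (te$n == 0L) stop("empty block set")
  cfg <- model$config
  sc <- cnn3d_predict(model$weights, config_kernels(cfg),
                      cfg$filters_per_module, as.integer(cfg$pool_after),
                      config_dhw(cfg), cfg$fc_width, cfg$n_classes,
                      te$x, te$n)
  list(scores = sc,
       labels = max.col(sc, ties.method = "first"),
       seed_ids = vapply(blocks$blocks, `[[`, 0L, "seed_id"))
}

#' Voted per-seed predictions from block scores
#'
#' Runs [predict_blocks()] and aggregates each seed's block calls with
#' [vote_seed()].
#'
#' @param model A `viability_model`.
#' @param blocks A `block_set`.
#' @param tie_rule Passed to [vote_seed()].
#' @return List of `seed_prediction`, one per seed present in `blocks`.
#' @export
predict_seeds <- function(model, blocks, tie_rule = "nonviable") {
  pr <- predict_blocks(model, blocks)
  ids <- sort(unique(pr$seed_ids))
  lapply(ids, function(id) {
    sel <- pr$seed_ids == id
    vote_seed(pr$labels[sel], tie_rule = tie_rule, seed_id = id,
              block_scores = pr$scores[sel, , drop = FALSE])
  })
}
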