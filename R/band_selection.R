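#' Successive projections algorithm (SPA) band selection
#'
#' Greedy forward selection of minimally collinear bands. Starting from
#' `start_band`, each step orthogonally projects every unselected band column
#' onto the complement of the span of the already-selected columns and picks
#' the band with the largest residual norm; collinear bands therefore have
#' vanishing residuals and are never picked before independent ones.
#'
#' @param spectra Numeric matrix, samples x bands (columns are band vectors).
#' @param start_band Index of the first selected band.
#' @param k Number of bands to select, `1 <= k <= min(samples, bands)`.
#' @param tol Residual norm below which a column is treated as linearly
#'   dependent on the selection.
#' @return A `band_subset`: list with `indices` (selection order),
#'   `wavelengths_nm` (if wavelengths are attached to `spectra` via
#'   `attr(spectra, "wavelengths")` or supplied downstream), `residual_norms`
#'   (norm of each pick at selection time) and `criterion_trace` (`NULL` here;
#'   filled by [choose_subset_size()]).
#' @examples
#' X <- diag(3) * c(3, 2, 1)
#' spa_select(X, start_band = 1, k = 2)$indices  # 1 then 2
#' @export
spa_select <- function(spectra, start_band, k, tol = 1e-10) {
  X <- as.matrix(spectra)
  n <- nrow(X); p <- ncol(X)
  if (k < 1L || k > min(n, p))
    stop("`k` must be in [1, min(samples, bands)] = [1, ", min(n, p), "]")
  if (start_band < 1L || start_band > p) stop("invalid `start_band`")
  sel <- integer(k)
  norms <- numeric(k)
  R <- X                                  # residuals of all columns
  cur <- as.integer(start_band)
  for (step in seq_len(k)) {
    r <- R[, cur]
    nr <- sqrt(sum(r^2))
    if (nr < tol)
      stop("rank deficiency: residual norm vanished at step ", step,
           " (k exceeds the effective rank of the data)")
    sel[step] <- cur
    norms[step] <- nr
    if (step == k) break
    q <- r / nr
    R <- R - q %*% crossprod(q, R)        # project out the new direction
    R[, sel[seq_len(step)]] <- 0
    resn <- sqrt(colSums(R^2))
    resn[sel[seq_len(step)]] <- -Inf
    cur <- which.max(resn)                # ties -> lowest index
  }
  wl <- attr(spectra, "wavelengths")
  structure(list(indices = sel,
                 wavelengths_nm = if (!is.null(wl)) wl[sel],
                 residual_norms = norms,
                 criterion_trace = NULL),
            class = "band_subset")
}

#' @export
print.band_subset <- function(x, ...) {
  cat("<band_subset> k =", length(x$indices), "bands:",
      paste(x$indices, collapse = ", "), "\n")
  if (!is.null(x$wavelengths_nm))
    cat("  nm:", paste(round(x$wavelengths_nm, 1), collapse = ", "), "\n")
  invisible(x)
}

# stratified fold assignment: within each class, cycle folds in sample order
stratified_folds <- function(labels, n_folds, seed) {
  set.seed(seed)
  fold <- integer(length(labels))
  for (cl in unique(labels)) {
    idx <- which(labels == cl)
    idx <- idx[sample.int(length(idx))]
    fold[idx] <- rep_len(seq_len(n_folds), length(idx))
  }
  fold
}

# nearest-class-mean classification error on selected columns
nearest_mean_cv_error <- function(X, labels, cols, fold) {
  n_folds <- max(fold)
  err <- 0L
  for (f in seq_len(n_folds)) {
    tr <- fold != f; te <- !tr
    if (!any(te)) next
    classes <- sort(unique(labels[tr]))
    mu <- t(vapply(classes,
                   function(cl) colMeans(X[tr & labels == cl, cols, drop = FALSE]),
                   numeric(length(cols))))
    Xte <- X[te, cols, drop = FALSE]
    d2 <- outer(rowSums(Xte^2), rowSums(mu^2), `+`) - 2 * Xte %*% t(mu)
    pred <- classes[max.col(-d2, ties.method = "first")]
    err <- err + sum(pred != labels[te])
  }
  err / length(labels)
}

#' Choose the SPA subset size by cross-validated screening
#'
#' Runs [spa_select()] for every size in `k_range` and every candidate start
#' band, scores each subset by the stratified `n_folds`-fold cross-validated
#' error of a nearest-class-mean classifier, and returns the subset with the
#' lowest error (ties: smaller `k`, then earlier start band). The
#' nearest-mean scorer is deliberately simple and deterministic given the fold
#' assignment, and independent of the downstream CNN.
#'
#' @param spectra Samples x bands matrix (optionally with a `wavelengths`
#'   attribute).
#' @param labels Per-sample class vector with at least two classes.
#' @param k_range Integer vector of candidate subset sizes.
#' @param start_bands Candidate start bands (default: all bands).
#' @param n_folds Cross-validation folds.
#' @param seed Seed for the fold assignment.
#' @return A `band_subset` with `criterion_trace`: a data.frame of the best
#'   cross-validated error per candidate `k`.
#' @export
choose_subset_size <- function(spectra, labels, k_range,
                               start_bands = NULL, n_folds = 5L, seed = 1L) {
  X <- as.matrix(spectra)
  labels <- as.vector(labels)
  if (length(labels) != nrow(X)) stop("one label per sample required")
  if (length(unique(labels)) < 2L)
    stop("degenerate labels: need at least two classes")
  k_range <- sort(unique(as.integer(k_range)))
  if (any(k_range < 1L) || any(k_range > min(dim(X))))
    stop("`k_range` outside valid subset sizes")
  if (is.null(start_bands)) start_bands <- seq_len(ncol(X))
  fold <- stratified_folds(labels, n_folds, seed)
  best <- NULL; best_err <- Inf
  trace_err <- rep(NA_real_, length(k_range))
  for (ki in seq_along(k_range)) {
    k <- k_range[ki]
    for (s in start_bands) {
      sub <- try(spa_select(X, s, k), silent = TRUE)
      if (inherits(sub, "try-error")) next
      e <- nearest_mean_cv_error(X, labels, sub$indices, fold)
      if (is.na(trace_err[ki]) || e < trace_err[ki]) trace_err[ki] <- e
      if (e < best_err) { best_err <- e; best <- sub }
    }
  }
  if (is.null(best)) stop("no admissible subset found over k_range")
  best$criterion_trace <- data.frame(k = k_range, cv_error = trace_err)
  best
}
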