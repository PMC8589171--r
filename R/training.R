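#' Shuffled k-fold split
#'
#' Partitions `1..n` into `n_folds` near-equal shuffled folds; each fold
#' serves once as the test set. Uses the current RNG state, so call
#' [set.seed()] first for reproducibility.
#'
#' @param n number of samples.
#' @param n_folds number of folds (>= 2).
#' @return List of length `n_folds`; each element has `fold_id`,
#'   `n_folds`, `train_indices`, `test_indices` (1-based).
#' @export
kfold_split <- function(n, n_folds = 5) {
  n <- as.integer(n); n_folds <- as.integer(n_folds)
  if (n_folds < 2L) stop("n_folds must be >= 2", call. = FALSE)
  if (n < n_folds) stop("need at least one sample per fold", call. = FALSE)
  perm <- sample.int(n)
  # near-equal sizes: assign shuffled indices round-robin
  fold_of <- rep(seq_len(n_folds), length.out = n)
  lapply(seq_len(n_folds), function(f) {
    test <- sort(perm[fold_of == f])
    list(fold_id = f, n_folds = n_folds,
         train_indices = setdiff(seq_len(n), test),
         test_indices = test)
  })
}

#' Fit a feature standardizer on a training fold
#'
#' Column-wise z-scoring; constant columns get unit scale. Distance-based
#' components (prototype distances, K-means, cosine similarity) are
#' scale-sensitive, so every method is given standardized features, fit on
#' the training fold only.
#'
#' @param x training feature matrix.
#' @return Object of class `standardizer` with `center` and `scale`.
#' @export
fit_standardizer <- function(x) {
  x <- as.matrix(x)
  center <- colMeans(x)
  scale <- apply(x, 2L, stats::sd)
  scale[!is.finite(scale) | scale < 1e-12] <- 1
  structure(list(center = center, scale = scale), class = "standardizer")
}

#' Apply a fitted standardizer
#'
#' @param std a [fit_standardizer()] result.
#' @param x feature matrix to transform.
#' @return Standardized matrix.
#' @export
apply_standardizer <- function(std, x) {
  x <- as.matrix(x)
  sweep(sweep(x, 2L, std$center, `-`), 2L, std$scale, `/`)
}

# view of a cohort restricted to an index vector
cohort_subset <- function(cohort, idx) {
  list(x = cohort$x[idx, , drop = FALSE],
       t = cohort$t[idx],
       y = cohort$y[idx],
       p_true = if (!is.null(cohort$p_true))
         cohort$p_true[idx, , drop = FALSE])
}
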