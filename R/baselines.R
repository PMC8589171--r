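#' Fit the KMNN baseline (K-means + neural classifier)
#'
#' Two separate phases, deliberately not tuned jointly: (1) K-means on the
#' observed features alone, ignoring treatments and outcomes; (2) a small
#' fully connected classifier (same head shape as the DPNN classifier)
#' trained on the concatenation of each patient's distances to the cluster
#' centroids and the one-hot treatment, predicting the observed outcome.
#'
#' @param cohort_train list with `x`, `t` (0-based), `y`.
#' @param n_clusters number of K-means clusters (>= 2).
#' @param classifier_hidden hidden nodes of the classifier.
#' @param learning_rate,epochs,batch_size Adam schedule of the classifier.
#' @param seed seed for K-means restarts, weight init and shuffling.
#' @param distance `"sqeuclidean"` (default) or `"euclidean"` distances to
#'   centroids.
#' @return Object of class `kmnn_model`.
#' @export
kmnn_fit <- function(cohort_train, n_clusters = 5, classifier_hidden = 16,
                     learning_rate = 1e-4, epochs = 100, batch_size = 10,
                     seed = 1L, distance = c("sqeuclidean", "euclidean")) {
  distance <- match.arg(distance)
  if (n_clusters < 2L) stop("n_clusters must be >= 2", call. = FALSE)
  x <- as.matrix(cohort_train$x)
  k <- length(unique(cohort_train$t))
  k <- max(k, max(cohort_train$t) + 1L)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  km <- stats::kmeans(x, centers = n_clusters, nstart = 10, iter.max = 50)
  centroids <- unname(km$centers)
  rep_train <- centroid_distances(x, centroids, distance)
  onehot <- matrix(0, nrow(x), k)
  onehot[cbind(seq_len(nrow(x)), cohort_train$t + 1L)] <- 1
  cin <- cbind(rep_train, onehot)
  params <- list(W1 = init_mat(ncol(cin), classifier_hidden, ncol(cin)),
                 b1 = init_mat(1, classifier_hidden, ncol(cin)),
                 w2 = init_mat(classifier_hidden, 1, classifier_hidden),
                 b2 = init_mat(1, 1, classifier_hidden))
  fit <- cpp_mlp_train(params, cin, as.numeric(cohort_train$y),
                       learning_rate, as.integer(epochs),
                       as.integer(batch_size), 1e-7, as.integer(seed))
  structure(list(centroids = centroids, classifier = fit$params,
                 n_clusters = as.integer(n_clusters),
                 n_treatments = as.integer(k), distance = distance,
                 epoch_loss = as.numeric(fit$epoch_loss)),
            class = "kmnn_model")
}

centroid_distances <- function(x, centroids, distance) {
  d2 <- outer(rowSums(x^2), rep(1, nrow(centroids))) +
    outer(rep(1, nrow(x)), rowSums(centroids^2)) -
    2 * x %*% t(centroids)
  d2[d2 < 0] <- 0
  if (distance == "euclidean") sqrt(d2) else d2
}

#' KMNN predictions for every patient-treatment pair
#'
#' @param model a [kmnn_fit()] result.
#' @param x feature matrix on the training scale.
#' @return N x n_treatments matrix of remission probabilities.
#' @export
kmnn_predict_all <- function(model, x) {
  x <- as.matrix(x)
  rep_x <- centroid_distances(x, model$centroids, model$distance)
  k <- model$n_treatments
  out <- matrix(NA_real_, nrow(x), k)
  for (j in seq_len(k)) {
    onehot <- matrix(0, nrow(x), k)
    onehot[, j] <- 1
    out[, j] <- as.numeric(cpp_mlp_forward(model$classifier,
                                           cbind(rep_x, onehot)))
  }
  out
}

#' Fit the case-based reasoning (CBR) baseline
#'
#' Stores the training patients split by received treatment arm. At
#' prediction time the remission probability of arm `t` is the
#' cosine-similarity-weighted mean outcome of the `n_neighbors` most
#' similar training patients who received `t`.
#'
#' @param cohort_train list with `x`, `t` (0-based), `y`.
#' @param n_neighbors neighbors per arm.
#' @return Object of class `cbr_model`.
#' @export
cbr_fit <- function(cohort_train, n_neighbors = 10) {
  x <- as.matrix(cohort_train$x)
  t <- as.integer(cohort_train$t)
  k <- max(t) + 1L
  arms <- lapply(seq_len(k) - 1L, function(j) {
    idx <- which(t == j)
    if (length(idx) == 0L)
      stop("treatment arm ", j, " has no training patients", call. = FALSE)
    list(x = x[idx, , drop = FALSE], y = cohort_train$y[idx])
  })
  smallest <- min(vapply(arms, function(a) length(a$y), 1L))
  if (n_neighbors > smallest)
    stop("n_neighbors exceeds the smallest treatment arm (", smallest, ")",
         call. = FALSE)
  structure(list(arms = arms, n_neighbors = as.integer(n_neighbors),
                 n_treatments = k),
            class = "cbr_model")
}

#' CBR predictions for every patient-treatment pair
#'
#' Cosine similarities below zero are clamped to zero; when every selected
#' neighbor has zero weight the prediction falls back to the arm's base
#' remission rate. Predictions are convex combinations of stored outcomes,
#' hence always in `[0,1]`.
#'
#' @param model a [cbr_fit()] result.
#' @param x query feature matrix on the training scale.
#' @return N x n_treatments matrix of remission probabilities.
#' @export
cbr_predict_all <- function(model, x) {
  x <- as.matrix(x)
  qn <- sqrt(rowSums(x^2)); qn[qn < 1e-12] <- 1e-12
  out <- matrix(NA_real_, nrow(x), model$n_treatments)
  for (j in seq_len(model$n_treatments)) {
    arm <- model$arms[[j]]
    an <- sqrt(rowSums(arm$x^2)); an[an < 1e-12] <- 1e-12
    sim <- (x %*% t(arm$x)) / outer(qn, an)         # N x arm-size cosine
    base <- mean(arm$y)
    nn <- model$n_neighbors
    out[, j] <- apply(sim, 1L, function(s) {
      top <- order(s, decreasing = TRUE)[seq_len(nn)]
      w <- pmax(s[top], 0)
      if (sum(w) <= 0) base else sum(w * arm$y[top]) / sum(w)
    })
  }
  out
}

#' Uniformly random treatment recommendations
#'
#' Reference policy for "random treatment allocation" comparisons. Uses
#' the current RNG state.
#'
#' @param n number of patients.
#' @param k number of treatment arms.
#' @return Integer vector of recommended arms in `0..k-1`.
#' @export
random_policy <- function(n, k) {
  sample.int(k, n, replace = TRUE) - 1L
}
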