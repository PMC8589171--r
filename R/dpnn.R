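#' DPNN hyperparameter configuration
#'
#' Collects every tunable quantity of the differential prototype network:
#' architecture sizes, the three loss weights, and the optimization
#' schedule. Defaults reproduce the synthetic-benchmark setting: 5
#' prototypes, a single 14-node hidden layer in the encoder (mirrored in
#' the decoder), a single 16-node hidden layer in the classifier, loss
#' weights `lambda1 = 0.01` (reconstruction), `lambda2 = 0.05` (prototype
#' variance), `alpha = 0.85` (intra- vs inter-prototype balance), Adam at
#' learning rate 1e-4, 100 epochs of mini-batches of 10.
#'
#' @param n_prototypes number of trainable latent prototypes (>= 2).
#' @param input_dim number of observed features.
#' @param latent_dim dimension of the autoencoder bottleneck.
#' @param encoder_hidden nodes in the single encoder hidden layer.
#' @param classifier_hidden nodes in the single classifier hidden layer.
#' @param lambda1 weight of the reconstruction loss.
#' @param lambda2 weight of the (negated) prototype-variance loss.
#' @param alpha balance between intra-prototype (weight `alpha`) and
#'   inter-prototype (weight `1 - alpha`) variance; must be in (0,1).
#' @param learning_rate Adam learning rate.
#' @param epochs training epochs.
#' @param batch_size mini-batch size.
#' @param n_treatments number of treatment arms.
#' @param seed seed for weight initialization and batch shuffling.
#' @param distance distance between encoded patients and prototypes:
#'   squared Euclidean (default, smooth everywhere) or plain Euclidean.
#' @param variance_normalizer divisor used inside the intra/inter variance
#'   terms: `"l"` divides by the number of prototypes (default), `"lk"` by
#'   prototypes times treatments.
#' @param use_prototypes set `FALSE` to bypass the prototype layer and feed
#'   the latent code directly to the classifier (a plain autoencoder +
#'   classifier; mainly a diagnostic).
#' @param eps probability clamp used inside the cross-entropy loss.
#' @return Object of class `dpnn_config`.
#' @export
dpnn_config <- function(n_prototypes = 5,
                        input_dim = 20,
                        latent_dim = 10,
                        encoder_hidden = 14,
                        classifier_hidden = 16,
                        lambda1 = 0.01,
                        lambda2 = 0.05,
                        alpha = 0.85,
                        learning_rate = 1e-4,
                        epochs = 100,
                        batch_size = 10,
                        n_treatments = 4,
                        seed = 1L,
                        distance = c("sqeuclidean", "euclidean"),
                        variance_normalizer = c("l", "lk"),
                        use_prototypes = TRUE,
                        eps = 1e-7) {
  distance <- match.arg(distance)
  variance_normalizer <- match.arg(variance_normalizer)
  cfg <- list(n_prototypes = as.integer(n_prototypes),
              input_dim = as.integer(input_dim),
              latent_dim = as.integer(latent_dim),
              encoder_hidden = as.integer(encoder_hidden),
              classifier_hidden = as.integer(classifier_hidden),
              lambda1 = lambda1, lambda2 = lambda2, alpha = alpha,
              learning_rate = learning_rate,
              epochs = as.integer(epochs),
              batch_size = as.integer(batch_size),
              n_treatments = as.integer(n_treatments),
              seed = as.integer(seed),
              distance = distance,
              variance_normalizer = variance_normalizer,
              use_prototypes = isTRUE(use_prototypes),
              eps = eps)
  if (cfg$n_prototypes < 2L) stop("n_prototypes must be >= 2", call. = FALSE)
  if (cfg$alpha <= 0 || cfg$alpha >= 1) stop("alpha must be in (0,1)", call. = FALSE)
  if (cfg$lambda1 < 0 || cfg$lambda2 < 0)
    stop("lambda1 and lambda2 must be >= 0", call. = FALSE)
  structure(cfg, class = "dpnn_config")
}

# uniform fan-in initialization, U(-1/sqrt(fan_in), 1/sqrt(fan_in))
init_mat <- function(nr, nc, fan_in) {
  b <- 1 / sqrt(fan_in)
  matrix(stats::runif(nr * nc, -b, b), nr, nc)
}

#' Initialize an untrained DPNN
#'
#' Weights use uniform fan-in initialization; prototypes are i.i.d.
#' standard normal in the latent space. Deterministic given
#' `config$seed`.
#'
#' @param config a [dpnn_config()].
#' @return Object of class `dpnn_model`: named weight matrices (`We1`,
#'   `be1`, `We2`, `be2` encoder; `Wd1`, `bd1`, `Wd2`, `bd2` decoder; `P`
#'   prototypes; `Wc1`, `bc1`, `wc2`, `bc2` classifier) plus `config`.
#' @export
dpnn_init <- function(config) {
  stopifnot(inherits(config, "dpnn_config"))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(config$seed)
  m <- config$input_dim; q <- config$latent_dim
  he <- config$encoder_hidden; hc <- config$classifier_hidden
  ell <- config$n_prototypes; k <- config$n_treatments
  rep_dim <- if (config$use_prototypes) ell else q
  params <- list(
    We1 = init_mat(m, he, m),  be1 = init_mat(1, he, m),
    We2 = init_mat(he, q, he), be2 = init_mat(1, q, he),
    Wd1 = init_mat(q, he, q),  bd1 = init_mat(1, he, q),
    Wd2 = init_mat(he, m, he), bd2 = init_mat(1, m, he),
    P   = matrix(stats::rnorm(ell * q), ell, q),
    Wc1 = init_mat(rep_dim + k, hc, rep_dim + k),
    bc1 = init_mat(1, hc, rep_dim + k),
    wc2 = init_mat(hc, 1, hc), bc2 = init_mat(1, 1, hc))
  structure(c(params, list(config = config)), class = "dpnn_model")
}

#' @export
print.dpnn_model <- function(x, ...) {
  cfg <- x$config
  cat(sprintf(paste0("differential prototype network: %d -> %d -> %d, ",
                     "%d prototypes, %d treatment arms\n"),
              cfg$input_dim, cfg$encoder_hidden, cfg$latent_dim,
              cfg$n_prototypes, cfg$n_treatments))
  invisible(x)
}

model_params <- function(model)
  model[c("We1", "be1", "We2", "be2", "Wd1", "bd1", "Wd2", "bd2",
          "P", "Wc1", "bc1", "wc2", "bc2")]

relu <- function(x) pmax(x, 0)

#' Encode observed features into the latent space
#'
#' @param model a `dpnn_model`.
#' @param x N x input_dim feature matrix (a single vector is accepted).
#' @return N x latent_dim matrix of latent codes.
#' @export
encode <- function(model, x) {
  if (!is.matrix(x)) x <- matrix(x, nrow = 1L)
  if (ncol(x) != model$config$input_dim)
    stop("x has ", ncol(x), " columns; model expects ",
         model$config$input_dim, call. = FALSE)
  h1 <- relu(sweep(x %*% model$We1, 2L, model$be1[1L, ], `+`))
  sweep(h1 %*% model$We2, 2L, model$be2[1L, ], `+`)
}

#' Reconstruct observed features from latent codes
#'
#' @param model a `dpnn_model`.
#' @param codes N x latent_dim matrix of latent codes.
#' @return N x input_dim matrix of reconstructions.
#' @export
reconstruct <- function(model, codes) {
  if (!is.matrix(codes)) codes <- matrix(codes, nrow = 1L)
  if (ncol(codes) != model$config$latent_dim)
    stop("codes have ", ncol(codes), " columns; model expects ",
         model$config$latent_dim, call. = FALSE)
  g1 <- relu(sweep(codes %*% model$Wd1, 2L, model$bd1[1L, ], `+`))
  sweep(g1 %*% model$Wd2, 2L, model$bd2[1L, ], `+`)
}

#' Distances between latent codes and the prototypes
#'
#' Squared Euclidean by default (`config$distance`); this l-vector of
#' distances is the patient representation the classifier consumes.
#'
#' @param model a `dpnn_model`.
#' @param codes N x latent_dim matrix.
#' @return N x n_prototypes matrix of nonnegative distances.
#' @export
prototype_distances <- function(model, codes) {
  if (!is.matrix(codes)) codes <- matrix(codes, nrow = 1L)
  d2 <- outer(rowSums(codes^2), rep(1, nrow(model$P))) +
    outer(rep(1, nrow(codes)), rowSums(model$P^2)) -
    2 * codes %*% t(model$P)
  d2[d2 < 0] <- 0
  if (model$config$distance == "euclidean") sqrt(d2) else d2
}

#' Remission probability from a distance representation and a treatment
#'
#' Runs the classification head on the concatenation of the prototype
#' distance vectors and one-hot treatment encodings.
#'
#' @param model a `dpnn_model`.
#' @param d N x n_prototypes distance matrix (or N x latent_dim codes when
#'   the prototype layer is bypassed).
#' @param treatments integer vector of received arms in `0..k-1`.
#' @return Vector of remission probabilities in `[0,1]`.
#' @export
classify <- function(model, d, treatments) {
  if (!is.matrix(d)) d <- matrix(d, nrow = 1L)
  k <- model$config$n_treatments
  treatments <- as.integer(treatments)
  if (any(treatments < 0L | treatments >= k))
    stop("treatment index out of range 0..k-1", call. = FALSE)
  if (length(treatments) != nrow(d))
    stop("treatments and distance rows are not aligned", call. = FALSE)
  onehot <- matrix(0, nrow(d), k)
  onehot[cbind(seq_len(nrow(d)), treatments + 1L)] <- 1
  cin <- cbind(d, onehot)
  h2 <- relu(sweep(cin %*% model$Wc1, 2L, model$bc1[1L, ], `+`))
  as.vector(stats::plogis(h2 %*% model$wc2 + model$bc2[1L, 1L]))
}

#' Prototype outcome matrix
#'
#' Feeds every prototype, represented by its distance vector to all
#' prototypes (self-distance 0), through the classifier under each
#' treatment. The resulting l x k matrix of remission probabilities is
#' what the prototype-variance loss acts on.
#'
#' @param model a `dpnn_model`.
#' @return n_prototypes x n_treatments matrix with entries in `[0,1]`.
#' @export
prototype_outcome_matrix <- function(model) {
  dp <- prototype_distances(model, model$P)
  diag(dp) <- 0
  k <- model$config$n_treatments
  vapply(seq_len(k) - 1L,
         function(j) classify(model, dp, rep(j, nrow(dp))),
         numeric(nrow(dp)))
}

#' Binary cross-entropy accuracy loss
#'
#' @param probs predicted remission probabilities.
#' @param y binary observed outcomes.
#' @param average divide by the number of samples (default) rather than
#'   summing.
#' @param eps probability clamp preventing `log(0)`.
#' @return Nonnegative scalar; lower is better.
#' @export
loss_accuracy <- function(probs, y, average = TRUE, eps = 1e-7) {
  stopifnot(length(probs) == length(y))
  p <- pmin(pmax(probs, eps), 1 - eps)
  s <- -sum(y * log(p) + (1 - y) * log(1 - p))
  if (average) s / length(y) else s
}

#' Autoencoder reconstruction loss
#'
#' Per-sample (unsquared) Euclidean distance between original and
#' reconstructed feature vectors.
#'
#' @param x original N x m matrix.
#' @param xhat reconstructed N x m matrix.
#' @param average divide by N (default) rather than summing.
#' @return Nonnegative scalar; 0 iff the reconstruction is perfect.
#' @export
loss_reconstruction <- function(x, xhat, average = TRUE) {
  if (!is.matrix(x)) x <- matrix(x, nrow = 1L)
  if (!is.matrix(xhat)) xhat <- matrix(xhat, nrow = 1L)
  if (!all(dim(x) == dim(xhat)))
    stop("x and xhat must have identical shapes", call. = FALSE)
  s <- sum(sqrt(rowSums((x - xhat)^2)))
  if (average) s / nrow(x) else s
}

#' Intra-prototype variance of a prototype outcome matrix
#'
#' Spread of predicted remission probabilities across treatments within
#' each prototype: the sum over all cells of the squared deviation from
#' the row (prototype) mean, divided by the number of prototypes
#' (`normalizer = "l"`) or by prototypes times treatments (`"lk"`).
#' Prototypes whose best and worst treatments differ sharply score high;
#' this is the "actionability" the training loss rewards.
#'
#' @param y_p l x k matrix of prototype-by-treatment probabilities.
#' @param normalizer `"l"` (default) or `"lk"`.
#' @return Nonnegative scalar.
#' @export
intra_variance <- function(y_p, normalizer = c("l", "lk")) {
  normalizer <- match.arg(normalizer)
  y_p <- as.matrix(y_p)
  div <- if (normalizer == "lk") nrow(y_p) * ncol(y_p) else nrow(y_p)
  sum(sweep(y_p, 1L, rowMeans(y_p), `-`)^2) / div
}

#' Inter-prototype variance of a prototype outcome matrix
#'
#' Spread of predicted remission probabilities across prototypes within
#' each treatment: squared deviations from the column (treatment) mean,
#' same normalizer as [intra_variance()]. High values mean the prototypes
#' genuinely differ in their predicted response to a given arm.
#'
#' @inheritParams intra_variance
#' @return Nonnegative scalar.
#' @export
inter_variance <- function(y_p, normalizer = c("l", "lk")) {
  normalizer <- match.arg(normalizer)
  y_p <- as.matrix(y_p)
  div <- if (normalizer == "lk") nrow(y_p) * ncol(y_p) else nrow(y_p)
  sum(sweep(y_p, 2L, colMeans(y_p), `-`)^2) / div
}

#' Prototype variance loss
#'
#' The negated convex combination `-(alpha * intra + (1 - alpha) * inter)`;
#' negated because training *increases* both variance terms while
#' minimizing the combined loss. Always <= 0.
#'
#' @inheritParams intra_variance
#' @param alpha balance in (0,1).
#' @return Nonpositive scalar.
#' @export
loss_prototype_variance <- function(y_p, alpha, normalizer = c("l", "lk")) {
  normalizer <- match.arg(normalizer)
  -(alpha * intra_variance(y_p, normalizer) +
      (1 - alpha) * inter_variance(y_p, normalizer))
}

#' Combined training loss
#'
#' `L1 + lambda1 * L2 + lambda2 * L3`.
#'
#' @param l1 accuracy loss.
#' @param l2 reconstruction loss.
#' @param l3 prototype variance loss (nonpositive).
#' @param lambda1,lambda2 nonnegative weights.
#' @return Scalar combined loss.
#' @export
combined_loss <- function(l1, l2, l3, lambda1, lambda2) {
  stopifnot(lambda1 >= 0, lambda2 >= 0)
  l1 + lambda1 * l2 + lambda2 * l3
}

#' Combined loss and analytic gradients on one mini-batch
#'
#' Evaluates the full forward pass (encoder, decoder, prototype distances,
#' classifier, prototype outcome matrix) and, optionally, the analytic
#' gradient of the combined loss with respect to every trainable
#' parameter. This is the exact computation the training loop performs at
#' each step; the test suite verifies the gradients against central finite
#' differences.
#'
#' @param model a `dpnn_model`.
#' @param x mini-batch feature matrix.
#' @param treatments integer vector of received arms (0-based).
#' @param y binary outcomes.
#' @param with_grad also return gradients (default `TRUE`).
#' @return List with `loss`, `L1`, `L2`, `L3`, `intra`, `inter` and, when
#'   requested, `grad` (named list matching the parameter matrices).
#' @export
dpnn_loss_gradient <- function(model, x, treatments, y, with_grad = TRUE) {
  cfg <- model$config
  cpp_dpnn_loss_grad(model_params(model), x, as.integer(treatments),
                     as.numeric(y), cfg$n_treatments, cfg$lambda1,
                     cfg$lambda2, cfg$alpha,
                     cfg$distance == "sqeuclidean",
                     cfg$variance_normalizer == "lk",
                     cfg$use_prototypes, cfg$eps, with_grad)
}

#' Train a DPNN
#'
#' Joint mini-batch training of all components: every step runs the full
#' forward pass (including a fresh prototype outcome matrix), evaluates
#' the combined loss and back-propagates through classifier, decoder,
#' prototypes and encoder simultaneously, with Adam updates. Shuffling is
#' re-seeded from `config$seed`, so training is reproducible.
#'
#' @param cohort_train list with `x` (features), `t` (0-based treatments)
#'   and `y` (binary outcomes), e.g. a [generate_cohort()] result or a
#'   subset of one. Features are used as given; standardize beforehand
#'   (see [fit_standardizer()]).
#' @param config a [dpnn_config()].
#' @return A trained `dpnn_model` with an `epoch_loss` attribute (mean
#'   combined loss per epoch).
#' @export
train_dpnn <- function(cohort_train, config) {
  stopifnot(inherits(config, "dpnn_config"))
  x <- as.matrix(cohort_train$x)
  if (nrow(x) < config$batch_size)
    stop("training set smaller than one batch", call. = FALSE)
  if (ncol(x) != config$input_dim)
    stop("cohort has ", ncol(x), " features; config expects ",
         config$input_dim, call. = FALSE)
  model <- dpnn_init(config)
  if (config$epochs == 0L) {
    attr(model, "epoch_loss") <- numeric(0)
    return(model)
  }
  fit <- cpp_dpnn_train(model_params(model), x,
                        as.integer(cohort_train$t),
                        as.numeric(cohort_train$y),
                        config$n_treatments, config$lambda1, config$lambda2,
                        config$alpha, config$learning_rate, config$epochs,
                        config$batch_size,
                        config$distance == "sqeuclidean",
                        config$variance_normalizer == "lk",
                        config$use_prototypes, config$eps, config$seed)
  model[names(fit$params)] <- fit$params
  attr(model, "epoch_loss") <- as.numeric(fit$epoch_loss)
  model
}

#' Predict remission probabilities for every patient-treatment pair
#'
#' @param model a trained `dpnn_model`.
#' @param x N x input_dim feature matrix (same scaling as during
#'   training).
#' @return N x n_treatments matrix of independent per-arm remission
#'   probabilities (rows need not sum to 1).
#' @export
predict_all_treatments <- function(model, x) {
  if (!is.matrix(x)) x <- matrix(x, nrow = 1L)
  if (ncol(x) != model$config$input_dim)
    stop("x has ", ncol(x), " columns; model expects ",
         model$config$input_dim, call. = FALSE)
  cfg <- model$config
  cpp_dpnn_predict_all(model_params(model), x, cfg$n_treatments,
                       cfg$distance == "sqeuclidean", cfg$use_prototypes)
}

#' Save a DPNN checkpoint as JSON
#'
#' Weights, prototypes and config in a single plain-text file.
#'
#' @param model a `dpnn_model`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
save_dpnn <- function(model, path) {
  payload <- list(config = unclass(model$config),
                  params = lapply(model_params(model), function(m)
                    list(dim = dim(m), data = as.vector(m))))
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Load a DPNN checkpoint written by [save_dpnn()]
#'
#' @param path JSON checkpoint file.
#' @return A `dpnn_model`.
#' @export
load_dpnn <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = TRUE)
  known <- intersect(names(payload$config), names(formals(dpnn_config)))
  config <- do.call(dpnn_config, payload$config[known])
  extra <- setdiff(names(payload$config), known)
  config[extra] <- payload$config[extra]   # e.g. feature scaling metadata
  params <- lapply(payload$params, function(p)
    matrix(p$data, p$dim[1L], p$dim[2L]))
  structure(c(params, list(config = config)), class = "dpnn_model")
}
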