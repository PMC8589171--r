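# Small deterministic fixtures shared across test files. Everything is
# built in code; no data files.

# a small synthetic config that keeps unit tests fast
small_synth_config <- function(seed = 1L, ...) {
  synthetic_config(n_prototypes_true = 3, latent_dim = 4,
                   patients_per_prototype = 60, n_treatments = 3,
                   observed_dim = 6, n_irrelevant = 2, seed = seed, ...)
}

# a small dpnn config matched to small_synth_config(); any dpnn_config
# argument can be overridden
small_dpnn_config <- function(...) {
  args <- list(n_prototypes = 3, input_dim = 8, latent_dim = 4,
               encoder_hidden = 5, classifier_hidden = 7, n_treatments = 3,
               epochs = 2, batch_size = 16, seed = 5L)
  dots <- list(...)
  args[names(dots)] <- dots
  do.call(dpnn_config, args)
}

# a toy two-arm cohort in which arm 0 always remits and arm 1 never does;
# features carry no signal about the outcome beyond noise
separable_cohort <- function(n = 200, d = 6, seed = 3L) {
  set.seed(seed)
  t <- rep(c(0L, 1L), length.out = n)
  list(x = matrix(stats::rnorm(n * d), n, d), t = t, y = 1L - t)
}

# set every parameter matrix of a dpnn model to zero
zero_weights <- function(model) {
  for (nm in c("We1", "be1", "We2", "be2", "Wd1", "bd1", "Wd2", "bd2",
               "P", "Wc1", "bc1", "wc2", "bc2"))
    model[[nm]][] <- 0
  model
}

# prototype-by-treatment probability matrices used in the loss examples:
# one with strong within-prototype (across-treatment) spread, one with
# strong between-prototype spread only
yp_high_intra <- matrix(c(0.3, 0.25, 0.7,
                          0.35, 0.2, 0.65,
                          0.8, 0.02, 0.03), nrow = 3, byrow = TRUE)
yp_low_intra <- matrix(c(0.81, 0.8, 0.83,
                         0.45, 0.44, 0.47,
                         0.19, 0.2, 0.18), nrow = 3, byrow = TRUE)

# explicit loop oracle for the variance terms (divisor = #prototypes)
variance_oracle <- function(yp) {
  l <- nrow(yp); k <- ncol(yp)
  intra <- 0
  for (i in seq_len(l)) {
    mu <- mean(yp[i, ])
    for (j in seq_len(k)) intra <- intra + (yp[i, j] - mu)^2
  }
  inter <- 0
  for (j in seq_len(k)) {
    mu <- mean(yp[, j])
    for (i in seq_len(l)) inter <- inter + (yp[i, j] - mu)^2
  }
  list(intra = intra / l, inter = inter / l)
}

# brute-force pairwise-concordance AUC
auc_oracle <- function(probs, y) {
  pos <- which(y == 1); neg <- which(y == 0)
  tot <- 0
  for (i in pos) for (j in neg)
    tot <- tot + (probs[i] > probs[j]) + 0.5 * (probs[i] == probs[j])
  tot / (length(pos) * length(neg))
}
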