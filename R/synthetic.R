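#' Configuration for the synthetic benchmark cohort
#'
#' Describes a cohort in which patients cluster around a small number of
#' prototypes in a latent space, each treatment arm carries its own random
#' non-linear remission function defined on that latent space, and the
#' observed features are a linear decoding of the latent coordinates plus
#' irrelevant noise columns. Because outcomes are sampled from known
#' probabilities, the full counterfactual remission surface is available
#' for every patient, which is what makes ranking metrics such as MRR and
#' RPL computable.
#'
#' @param n_prototypes_true number of latent subgroups the cohort is built
#'   around.
#' @param latent_dim dimension of the latent space the prototypes live in.
#' @param patients_per_prototype patients sampled around each prototype;
#'   total cohort size is `n_prototypes_true * patients_per_prototype`.
#' @param n_treatments number of treatment arms.
#' @param prototype_sd standard deviation of the centered normal from which
#'   prototype coordinates are drawn.
#' @param patient_sd standard deviation of the normal spread of patients
#'   around their prototype (same scale as `prototype_sd` by default).
#' @param remission_hidden_dim hidden width of the random two-layer ReLU
#'   remission function attached to each treatment arm.
#' @param observed_dim number of observed features obtained by linear
#'   decoding of the latent coordinates.
#' @param n_irrelevant number of additional pure-noise features appended to
#'   the observed block; final feature dimension is
#'   `observed_dim + n_irrelevant`.
#' @param seed integer seed making the cohort reproducible.
#' @return An object of class `synthetic_config`.
#' @export
synthetic_config <- function(n_prototypes_true = 5,
                             latent_dim = 10,
                             patients_per_prototype = 2000,
                             n_treatments = 4,
                             prototype_sd = 10,
                             patient_sd = 10,
                             remission_hidden_dim = 5,
                             observed_dim = 16,
                             n_irrelevant = 4,
                             seed = 1L) {
  cfg <- list(n_prototypes_true = as.integer(n_prototypes_true),
              latent_dim = as.integer(latent_dim),
              patients_per_prototype = as.integer(patients_per_prototype),
              n_treatments = as.integer(n_treatments),
              prototype_sd = prototype_sd,
              patient_sd = patient_sd,
              remission_hidden_dim = as.integer(remission_hidden_dim),
              observed_dim = as.integer(observed_dim),
              n_irrelevant = as.integer(n_irrelevant),
              seed = as.integer(seed))
  validate_synthetic_config(cfg)
  structure(cfg, class = "synthetic_config")
}

validate_synthetic_config <- function(cfg) {
  counts <- c("n_prototypes_true", "latent_dim", "patients_per_prototype",
              "n_treatments", "remission_hidden_dim", "observed_dim")
  for (f in counts)
    if (length(cfg[[f]]) != 1L || is.na(cfg[[f]]) || cfg[[f]] < 1L)
      stop("synthetic_config: '", f, "' must be a count >= 1", call. = FALSE)
  if (cfg$n_irrelevant < 0L)
    stop("synthetic_config: 'n_irrelevant' must be >= 0", call. = FALSE)
  if (cfg$prototype_sd < 0 || cfg$patient_sd < 0)
    stop("synthetic_config: standard deviations must be >= 0", call. = FALSE)
  invisible(cfg)
}

#' Sample the latent prototypes
#'
#' Draws the prototype matrix, one row per latent subgroup, with i.i.d.
#' Normal(0, `prototype_sd`) entries. Uses the current RNG state; seed the
#' stream with [set.seed()] (or go through [generate_cohort()], which seeds
#' everything from the config).
#'
#' @param config a [synthetic_config()].
#' @return Numeric matrix `n_prototypes_true x latent_dim`.
#' @export
generate_prototypes <- function(config) {
  validate_synthetic_config(config)
  matrix(stats::rnorm(config$n_prototypes_true * config$latent_dim,
                      mean = 0, sd = config$prototype_sd),
         nrow = config$n_prototypes_true, ncol = config$latent_dim)
}

#' Sample latent patients around the prototypes
#'
#' Each prototype spawns `patients_per_prototype` patients whose latent
#' coordinates are drawn coordinate-wise from Normal(prototype,
#' `patient_sd`).
#'
#' @param prototypes matrix returned by [generate_prototypes()].
#' @param config a [synthetic_config()].
#' @return List with `latent_z` (N x latent_dim matrix) and
#'   `prototype_label` (integer vector, 1-based generating prototype).
#' @export
generate_latent_patients <- function(prototypes, config) {
  validate_synthetic_config(config)
  if (!is.matrix(prototypes) ||
      nrow(prototypes) != config$n_prototypes_true ||
      ncol(prototypes) != config$latent_dim)
    stop("prototypes must be an n_prototypes_true x latent_dim matrix",
         call. = FALSE)
  npp <- config$patients_per_prototype
  q <- config$latent_dim
  blocks <- lapply(seq_len(nrow(prototypes)), function(i) {
    noise <- matrix(stats::rnorm(npp * q, sd = config$patient_sd), npp, q)
    sweep(noise, 2L, prototypes[i, ], `+`)
  })
  list(latent_z = do.call(rbind, blocks),
       prototype_label = rep(seq_len(nrow(prototypes)), each = npp))
}

#' Draw the per-treatment random remission functions
#'
#' Each treatment arm gets an independent two-layer network: a
#' `latent_dim x remission_hidden_dim` matrix, a ReLU, and a
#' `remission_hidden_dim x 2` matrix whose two outputs are the
#' non-remission and remission logits combined by a softmax. All entries
#' are standard normal.
#'
#' @param config a [synthetic_config()].
#' @return Object of class `remission_function_set`: a list with one
#'   `list(W1, W2)` element per treatment.
#' @export
remission_function_set <- function(config) {
  validate_synthetic_config(config)
  q <- config$latent_dim
  h <- config$remission_hidden_dim
  fns <- lapply(seq_len(config$n_treatments), function(j)
    list(W1 = matrix(stats::rnorm(q * h), q, h),
         W2 = matrix(stats::rnorm(h * 2), h, 2)))
  structure(fns, class = "remission_function_set")
}

# Softmax saturates in double precision for the logit scales this
# generator produces; clamping keeps probabilities strictly inside (0,1)
# while preserving the exact ties among saturated entries.
PROB_CLAMP <- 1e-12

#' True remission probability of a latent patient under one treatment
#'
#' Evaluates softmax(ReLU(z W1) W2) and returns the remission component,
#' clamped away from exactly 0 and 1.
#'
#' @param fns a [remission_function_set()].
#' @param z latent coordinate vector (or N x latent_dim matrix).
#' @param treatment treatment index in `0..k-1`.
#' @return Remission probability (vector when `z` is a matrix), in (0,1).
#' @export
true_remission_probability <- function(fns, z, treatment) {
  if (length(treatment) != 1L || treatment < 0L || treatment >= length(fns))
    stop("treatment must be a single index in 0..k-1", call. = FALSE)
  f <- fns[[treatment + 1L]]
  zm <- if (is.matrix(z)) z else matrix(z, nrow = 1L)
  if (ncol(zm) != nrow(f$W1))
    stop("latent vector length does not match the remission function",
         call. = FALSE)
  logits <- pmax(zm %*% f$W1, 0) %*% f$W2   # col 1: non-remission, col 2: remission
  p <- stats::plogis(logits[, 2L] - logits[, 1L])
  pmin(pmax(p, PROB_CLAMP), 1 - PROB_CLAMP)
}

#' Assign treatments uniformly and sample observed outcomes
#'
#' Treatments are assigned uniformly at random, independent of patient
#' features (the unbiased-allocation assumption of a randomized trial).
#' The full counterfactual probability matrix is evaluated for every
#' patient, and the single observed outcome is a Bernoulli draw from the
#' probability of the received arm.
#'
#' @param latent_z N x latent_dim matrix of latent patients.
#' @param fns a [remission_function_set()].
#' @param config a [synthetic_config()].
#' @return List with `t` (integer, 0-based received arm), `y` (0/1 observed
#'   outcome) and `p_true` (N x k matrix of true remission probabilities).
#' @export
assign_treatments_and_outcomes <- function(latent_z, fns, config) {
  validate_synthetic_config(config)
  k <- config$n_treatments
  if (length(fns) != k)
    stop("remission function set size does not match n_treatments",
         call. = FALSE)
  n <- nrow(latent_z)
  t <- sample.int(k, n, replace = TRUE) - 1L
  p_true <- vapply(seq_len(k) - 1L,
                   function(j) true_remission_probability(fns, latent_z, j),
                   numeric(n))
  p_received <- p_true[cbind(seq_len(n), t + 1L)]
  y <- as.integer(stats::runif(n) < p_received)
  list(t = t, y = y, p_true = p_true)
}

#' Decode latent patients into the observed feature space
#'
#' The observed block is `latent_z %*% D` with a `latent_dim x
#' observed_dim` standard-normal decoding matrix drawn once per cohort;
#' `n_irrelevant` i.i.d. standard-normal noise columns are appended raw.
#'
#' @param latent_z N x latent_dim matrix.
#' @param config a [synthetic_config()].
#' @param decoder optional pre-drawn decoding matrix (drawn here when
#'   `NULL`).
#' @return List with `x` (N x d feature matrix, d = observed_dim +
#'   n_irrelevant) and `decoder`.
#' @export
decode_to_observed <- function(latent_z, config, decoder = NULL) {
  validate_synthetic_config(config)
  if (ncol(latent_z) != config$latent_dim)
    stop("latent_z column count does not match latent_dim", call. = FALSE)
  if (is.null(decoder))
    decoder <- matrix(stats::rnorm(config$latent_dim * config$observed_dim),
                      config$latent_dim, config$observed_dim)
  n <- nrow(latent_z)
  x <- cbind(latent_z %*% decoder,
             matrix(stats::rnorm(n * config$n_irrelevant), n,
                    config$n_irrelevant))
  colnames(x) <- paste0("f", seq_len(ncol(x)) - 1L)
  list(x = x, decoder = decoder)
}

#' Generate a full synthetic cohort
#'
#' Runs the whole simulation: prototypes, latent patients, per-arm
#' remission functions, uniform treatment assignment with Bernoulli
#' outcomes, and decoding into observed features. Everything is seeded
#' from `config$seed`, so equal configs give bit-identical cohorts.
#'
#' @param config a [synthetic_config()].
#' @return Object of class `cohort`: list with `x` (N x d), `t` (0-based
#'   integer), `y` (0/1), `p_true` (N x k), `latent_z`, `prototype_label`,
#'   `fns`, `decoder` and `config`. Models must only ever see `x`, `t`,
#'   `y`; the remaining fields are simulation ground truth kept for
#'   evaluation.
#' @export
generate_cohort <- function(config) {
  validate_synthetic_config(config)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(config$seed)
  prototypes <- generate_prototypes(config)
  lat <- generate_latent_patients(prototypes, config)
  fns <- remission_function_set(config)
  out <- assign_treatments_and_outcomes(lat$latent_z, fns, config)
  dec <- decode_to_observed(lat$latent_z, config)
  structure(list(x = dec$x, t = out$t, y = out$y, p_true = out$p_true,
                 latent_z = lat$latent_z,
                 prototype_label = lat$prototype_label,
                 prototypes = prototypes, fns = fns, decoder = dec$decoder,
                 config = config),
            class = "cohort")
}

#' @export
print.cohort <- function(x, ...) {
  k <- if (!is.null(x$p_true)) ncol(x$p_true) else max(x$t) + 1L
  kind <- if (!is.null(x$p_true)) "synthetic cohort" else "cohort"
  cat(sprintf("%s: %d patients, %d features, %d treatment arms\n",
              kind, nrow(x$x), ncol(x$x), k))
  cat(sprintf("observed remission rate: %.3f\n", mean(x$y)))
  invisible(x)
}

# save/restore the global RNG state so generate_cohort() does not clobber
# the caller's stream
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' Write a cohort to plain-text files
#'
#' Writes `cohort.csv` (columns `f0..f{d-1}`, `treatment`, `outcome`),
#' `p_true.csv` (columns `p0..p{k-1}`) and `config.json` into `dir`.
#'
#' @param cohort a [generate_cohort()] result.
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  main <- data.frame(cohort$x, treatment = cohort$t, outcome = cohort$y,
                     check.names = FALSE)
  utils::write.csv(main, file.path(dir, "cohort.csv"), row.names = FALSE)
  if (!is.null(cohort$p_true)) {
    pt <- as.data.frame(cohort$p_true)
    names(pt) <- paste0("p", seq_len(ncol(pt)) - 1L)
    utils::write.csv(pt, file.path(dir, "p_true.csv"), row.names = FALSE)
  }
  jsonlite::write_json(unclass(cohort$config),
                       file.path(dir, "config.json"), auto_unbox = TRUE)
  invisible(dir)
}

#' Read a cohort written by [write_cohort()]
#'
#' @param dir directory containing `cohort.csv` (and optionally
#'   `p_true.csv`, `config.json`).
#' @return A `cohort` object (ground-truth fields present only when the
#'   sidecar files exist).
#' @export
read_cohort <- function(dir) {
  main <- utils::read.csv(file.path(dir, "cohort.csv"), check.names = FALSE)
  feat <- setdiff(names(main), c("treatment", "outcome"))
  x <- as.matrix(main[feat])
  p_true <- NULL
  ptf <- file.path(dir, "p_true.csv")
  if (file.exists(ptf)) p_true <- as.matrix(utils::read.csv(ptf))
  config <- NULL
  cf <- file.path(dir, "config.json")
  if (file.exists(cf)) {
    config <- jsonlite::read_json(cf, simplifyVector = TRUE)
    config <- do.call(synthetic_config, config)
  }
  structure(list(x = x, t = as.integer(main$treatment),
                 y = as.integer(main$outcome), p_true = p_true,
                 config = config),
            class = "cohort")
}
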