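#' Minimal grid search over DPNN hyperparameters
#'
#' Evaluates every combination of the supplied parameter values by k-fold
#' cross-validation on one cohort and reports the mean of the chosen
#' policy metric per combination. Deliberately simple — an exhaustive
#' grid with a fixed split per evaluation, no early stopping or adaptive
#' search.
#'
#' @param cohort a `cohort` (the counterfactual matrix is required for
#'   `metric = "mrr"` or `"rpl"`).
#' @param base_config a [dpnn_config()] supplying every parameter not in
#'   the grid.
#' @param grid named list of parameter value vectors, e.g.
#'   `list(lambda2 = c(0, 0.05), n_prototypes = c(3, 5))`.
#' @param n_folds folds per evaluation.
#' @param metric `"rpl"` (minimized), `"mrr"`, `"rr"` or `"auc"`
#'   (maximized).
#' @param master_seed seed for the fold split and training.
#' @param standardize z-score features per training fold.
#' @return `data.frame` with one row per combination, its mean metric
#'   over the folds, and a `best` attribute holding the winning
#'   parameter list.
#' @export
grid_search_dpnn <- function(cohort, base_config, grid, n_folds = 5,
                             metric = c("rpl", "mrr", "rr", "auc"),
                             master_seed = 1L, standardize = TRUE) {
  metric <- match.arg(metric)
  stopifnot(inherits(base_config, "dpnn_config"), length(grid) >= 1,
            !is.null(names(grid)), all(names(grid) != ""))
  unknown <- setdiff(names(grid), names(base_config))
  if (length(unknown))
    stop("unknown config fields in grid: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  combos <- expand.grid(grid, KEEP.OUT.ATTRS = FALSE,
                        stringsAsFactors = FALSE)
  cfg_exp <- experiment_config(cohort, methods = "dpnn", n_folds = n_folds,
                               n_repetitions = 1, master_seed = master_seed,
                               dpnn = base_config,
                               standardize = standardize)
  scores <- numeric(nrow(combos))
  for (i in seq_len(nrow(combos))) {
    cfg_i <- cfg_exp
    for (nm in names(grid)) cfg_i$dpnn[[nm]] <- combos[i, nm]
    samples <- run_experiment(cfg_i)
    scores[i] <- samples[[metric]][1L]
  }
  out <- cbind(combos, metric = metric, score = scores)
  best_i <- if (metric == "rpl") which.min(scores) else which.max(scores)
  attr(out, "best") <- as.list(combos[best_i, , drop = FALSE])
  out
}

# the six antidepressant treatment arms of the documented clinical
# cohort interface, in label-encoding order 0..5
CLINICAL_ARMS <- c("escitalopram", "citalopram", "venlafaxine",
                   "sertraline", "bupropion+escitalopram",
                   "mirtazapine+venlafaxine")

#' Read a clinical cohort CSV (interface definition)
#'
#' Documented loader for real clinical cohorts: a CSV with 26 baseline
#' feature columns (sociodemographic and symptom questionnaire items,
#' categorically encoded), a `treatment` column naming one of six
#' antidepressant courses, and a binary `outcome` column (1 = remission
#' at follow-up). No clinical data ships with the package — the
#' underlying trial datasets are access-restricted — so this function
#' only defines and validates the exchange format. Cohorts read here
#' have no counterfactual matrix: only the retrospective remission rate
#' and the classification metrics are computable.
#'
#' @param path CSV file with 26 feature columns plus `treatment` and
#'   `outcome`.
#' @param arms valid treatment labels, in label-encoding order; defaults
#'   to the six antidepressant courses
#'   (`escitalopram`, `citalopram`, `venlafaxine`, `sertraline`,
#'   `bupropion+escitalopram`, `mirtazapine+venlafaxine`).
#' @param n_features expected feature count (default 26).
#' @return A `cohort` object with `x`, `t` (0-based arm codes), `y` and
#'   an `arm_labels` field; `p_true` is absent.
#' @export
read_clinical_cohort <- function(path, arms = CLINICAL_ARMS,
                                 n_features = 26L) {
  df <- utils::read.csv(path, check.names = FALSE)
  for (col in c("treatment", "outcome"))
    if (!col %in% names(df))
      stop("clinical cohort is missing the '", col, "' column",
           call. = FALSE)
  feat <- setdiff(names(df), c("treatment", "outcome"))
  if (length(feat) != n_features)
    stop("expected ", n_features, " feature columns, found ", length(feat),
         call. = FALSE)
  bad <- setdiff(unique(df$treatment), arms)
  if (length(bad))
    stop("unknown treatment label(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  if (!all(df$outcome %in% c(0L, 1L)))
    stop("outcome must be binary 0/1", call. = FALSE)
  x <- as.matrix(df[feat])
  if (!is.numeric(x))
    stop("feature columns must be numeric (categorical items encoded)",
         call. = FALSE)
  structure(list(x = x,
                 t = match(df$treatment, arms) - 1L,
                 y = as.integer(df$outcome),
                 p_true = NULL, arm_labels = arms),
            class = "cohort")
}
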