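#' Configuration of a repeated cross-validation experiment
#'
#' Describes the cohort, the methods to compare, the cross-validation
#' protocol and the metric conventions. The cohort is generated (or
#' loaded) once; each repetition redraws the fold split and retrains every
#' method on identical splits.
#'
#' @param cohort a `cohort` object, or a [synthetic_config()] from which
#'   one is generated.
#' @param methods character subset of `c("dpnn", "kmnn", "cbr",
#'   "random")`.
#' @param n_folds folds per repetition.
#' @param n_repetitions repetitions (fresh splits, fresh seeds).
#' @param master_seed base seed; repetition `r` uses `master_seed + r` for
#'   its split and derived per-method training seeds.
#' @param dpnn a [dpnn_config()] template (its `input_dim`,
#'   `n_treatments` and `seed` are overridden per run).
#' @param kmnn list of [kmnn_fit()] arguments (e.g. `n_clusters`).
#' @param cbr list of [cbr_fit()] arguments (e.g. `n_neighbors`).
#' @param mrr_convention rank convention passed to [mrr()];
#'   `"shifted"` (default) is the scale of the reference synthetic
#'   benchmark results (see [mrr()]).
#' @param standardize z-score features per training fold (default TRUE).
#' @return Object of class `experiment_config`.
#' @export
experiment_config <- function(cohort,
                              methods = c("dpnn", "kmnn", "cbr", "random"),
                              n_folds = 5,
                              n_repetitions = 100,
                              master_seed = 1L,
                              dpnn = dpnn_config(),
                              kmnn = list(n_clusters = 5),
                              cbr = list(n_neighbors = 10),
                              mrr_convention = c("shifted", "reciprocal"),
                              standardize = TRUE) {
  methods <- match.arg(methods, several.ok = TRUE)
  if (anyDuplicated(methods)) stop("method names must be unique", call. = FALSE)
  if (inherits(cohort, "synthetic_config")) cohort <- generate_cohort(cohort)
  stopifnot(inherits(cohort, "cohort"), n_repetitions >= 1)
  structure(list(cohort = cohort, methods = methods,
                 n_folds = as.integer(n_folds),
                 n_repetitions = as.integer(n_repetitions),
                 master_seed = as.integer(master_seed),
                 dpnn = dpnn, kmnn = kmnn, cbr = cbr,
                 mrr_convention = match.arg(mrr_convention),
                 standardize = isTRUE(standardize)),
            class = "experiment_config")
}

# train one method on a training fold and return an N x k prediction
# matrix for the test fold; features arrive already standardized; k is
# the cohort-wide number of treatment arms
fit_and_predict <- function(method, train, test_x, config, seed, k) {
  switch(method,
    dpnn = {
      cfg <- config$dpnn
      cfg$input_dim <- ncol(train$x)
      cfg$n_treatments <- k
      cfg$seed <- seed
      model <- train_dpnn(train, cfg)
      predict_all_treatments(model, test_x)
    },
    kmnn = {
      args <- c(list(cohort_train = train, seed = seed), config$kmnn)
      model <- do.call(kmnn_fit, args)
      kmnn_predict_all(model, test_x)
    },
    cbr = {
      model <- do.call(cbr_fit, c(list(cohort_train = train), config$cbr))
      cbr_predict_all(model, test_x)
    },
    random = {
      set.seed(seed)
      # random scores; their argmax is a uniform recommendation
      matrix(stats::runif(nrow(test_x) * k), nrow(test_x), k)
    },
    stop("unknown method: ", method, call. = FALSE))
}

evaluate_fold <- function(pred, test, mrr_convention) {
  rec <- recommend(pred)
  rr <- remission_rate_retrospective(rec$recommended, test$t, test$y)
  cls <- classification_metrics(pred[cbind(seq_along(test$t), test$t + 1L)],
                                test$y)
  out <- list(mrr = NA_real_, rpl = NA_real_, rr = rr$rr,
              rr_support = rr$support, auc = cls$auc,
              sensitivity = cls$sensitivity, specificity = cls$specificity,
              ppv = cls$ppv, npv = cls$npv)
  if (!is.null(test$p_true)) {
    out$mrr <- mrr(pred, test$p_true, convention = mrr_convention)
    out$rpl <- rpl(pred, test$p_true)
  }
  out
}

#' Run a repeated cross-validation experiment
#'
#' For each repetition a fresh k-fold split is drawn (seeded by
#' `master_seed + repetition`) and every method is trained and evaluated
#' on byte-identical splits. Fold metrics are averaged into one record
#' per method and repetition; folds with zero retrospective-remission
#' support are dropped from the RR average. Per-method failures are
#' caught, reported as a warning and recorded as missing.
#'
#' @param config an [experiment_config()].
#' @param verbose print one line per repetition.
#' @return `data.frame` with one row per method x repetition: `method`,
#'   `repetition`, `mrr`, `rpl`, `rr`, `rr_support`, `auc`,
#'   `sensitivity`, `specificity`, `ppv`, `npv`, plus the
#'   `mrr_convention` attribute.
#' @export
run_experiment <- function(config, verbose = FALSE) {
  stopifnot(inherits(config, "experiment_config"))
  cohort <- config$cohort
  n <- nrow(cohort$x)
  k <- if (!is.null(cohort$p_true)) ncol(cohort$p_true) else
    max(cohort$t) + 1L
  rows <- list()
  for (rep_i in seq_len(config$n_repetitions)) {
    set.seed(config$master_seed + rep_i)
    folds <- kfold_split(n, config$n_folds)
    fold_metrics <- lapply(config$methods, function(m) list())
    names(fold_metrics) <- config$methods
    for (fold in folds) {
      train <- cohort_subset(cohort, fold$train_indices)
      test <- cohort_subset(cohort, fold$test_indices)
      if (config$standardize) {
        std <- fit_standardizer(train$x)
        train$x <- apply_standardizer(std, train$x)
        test_x <- apply_standardizer(std, test$x)
      } else test_x <- test$x
      for (mi in seq_along(config$methods)) {
        m <- config$methods[mi]
        seed <- config$master_seed + 1000L * rep_i + 10L * fold$fold_id + mi
        res <- tryCatch(
          evaluate_fold(fit_and_predict(m, train, test_x, config, seed, k),
                        test, config$mrr_convention),
          error = function(e) {
            warning(sprintf("method %s failed (rep %d fold %d): %s",
                            m, rep_i, fold$fold_id, conditionMessage(e)),
                    call. = FALSE)
            NULL
          })
        fold_metrics[[m]] <- c(fold_metrics[[m]], list(res))
      }
    }
    for (m in config$methods) {
      ok <- Filter(Negate(is.null), fold_metrics[[m]])
      if (length(ok) == 0L) {
        rows[[length(rows) + 1L]] <- data.frame(
          method = m, repetition = rep_i, mrr = NA_real_, rpl = NA_real_,
          rr = NA_real_, rr_support = NA_real_, auc = NA_real_,
          sensitivity = NA_real_, specificity = NA_real_, ppv = NA_real_,
          npv = NA_real_)
        next
      }
      getm <- function(f) vapply(ok, function(r) as.numeric(r[[f]]), 0)
      rr_vals <- getm("rr"); rr_sup <- getm("rr_support")
      rr_keep <- rr_sup > 0 & is.finite(rr_vals)
      rows[[length(rows) + 1L]] <- data.frame(
        method = m, repetition = rep_i,
        mrr = mean(getm("mrr")), rpl = mean(getm("rpl")),
        rr = if (any(rr_keep)) mean(rr_vals[rr_keep]) else NA_real_,
        rr_support = mean(rr_sup),
        auc = mean(getm("auc"), na.rm = TRUE),
        sensitivity = mean(getm("sensitivity"), na.rm = TRUE),
        specificity = mean(getm("specificity"), na.rm = TRUE),
        ppv = mean(getm("ppv"), na.rm = TRUE),
        npv = mean(getm("npv"), na.rm = TRUE))
    }
    if (verbose)
      message(sprintf("repetition %d/%d done", rep_i, config$n_repetitions))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "mrr_convention") <- config$mrr_convention
  out
}

#' Aggregate metric samples into medians and MADs
#'
#' The median absolute deviation is reported raw (no consistency
#' constant), matching how robust spreads are usually quoted next to
#' medians in method-comparison tables.
#'
#' @param samples a [run_experiment()] result.
#' @return `data.frame` with one row per method x metric: `method`,
#'   `metric`, `median`, `mad`, `n`.
#' @export
aggregate_metrics <- function(samples) {
  metrics <- setdiff(names(samples), c("method", "repetition"))
  rows <- list()
  for (m in unique(samples$method)) {
    sub <- samples[samples$method == m, , drop = FALSE]
    for (met in metrics) {
      v <- sub[[met]]
      v <- v[is.finite(v)]
      rows[[length(rows) + 1L]] <- data.frame(
        method = m, metric = met,
        median = if (length(v)) stats::median(v) else NA_real_,
        mad = if (length(v)) stats::mad(v, constant = 1) else NA_real_,
        n = length(v))
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Nonparametric comparison of methods on one metric
#'
#' Screens each method's samples with the Shapiro-Wilk normality test,
#' compares all methods with Friedman's test on the
#' repetition-by-method matrix, and, when Friedman is significant,
#' follows up with pairwise Wilcoxon signed-rank tests under Bonferroni
#' correction. Only repetitions with complete observations across
#' methods enter the paired tests.
#'
#' @param samples a [run_experiment()] result.
#' @param metric metric column to compare (e.g. `"rpl"`).
#' @param alpha significance level for flagging pairs (default 0.01).
#' @return List with `shapiro` (per-method p-values), `friedman`
#'   (htest), `pairwise` (data.frame with raw and Bonferroni-adjusted
#'   p-values and significance flags) and `n_complete`.
#' @export
compare_methods <- function(samples, metric, alpha = 0.01) {
  methods <- unique(samples$method)
  if (length(methods) < 2L) stop("need at least two methods", call. = FALSE)
  wide <- stats::reshape(
    samples[c("method", "repetition", metric)],
    idvar = "repetition", timevar = "method", direction = "wide")
  mat <- as.matrix(wide[, -1, drop = FALSE])
  colnames(mat) <- sub(paste0("^", metric, "\\."), "", colnames(mat))
  complete <- stats::complete.cases(mat)
  mat <- mat[complete, , drop = FALSE]
  if (nrow(mat) < 2L) stop("need >= 2 complete repetitions", call. = FALSE)
  shapiro <- vapply(colnames(mat), function(m) {
    v <- mat[, m]
    if (length(unique(v)) < 3L) NA_real_ else stats::shapiro.test(v)$p.value
  }, 0)
  fried <- stats::friedman.test(mat)
  pairs <- utils::combn(colnames(mat), 2L)
  pw <- data.frame(method_a = pairs[1L, ], method_b = pairs[2L, ],
                   p_raw = NA_real_)
  for (i in seq_len(ncol(pairs))) {
    a <- mat[, pairs[1L, i]]; b <- mat[, pairs[2L, i]]
    pw$p_raw[i] <- if (all(a == b)) 1 else
      suppressWarnings(stats::wilcox.test(a, b, paired = TRUE)$p.value)
  }
  pw$p_adjusted <- stats::p.adjust(pw$p_raw, method = "bonferroni")
  pw$significant <- pw$p_adjusted <= alpha
  list(metric = metric, shapiro = shapiro, friedman = fried,
       friedman_significant = is.finite(fried$p.value) &&
         fried$p.value <= alpha,
       pairwise = pw, n_complete = nrow(mat), alpha = alpha)
}

#' Sensitivity of the prototype methods to the number of prototypes
#'
#' Re-runs the configured methods at each prototype count under the same
#' repeated cross-validation protocol as [run_experiment()] (a small
#' number of fold-averaged repetitions per value) and reports mean
#' metrics per value.
#'
#' @param config an [experiment_config()]; its `dpnn$n_prototypes` and
#'   `kmnn$n_clusters` are overridden by `l_values`.
#' @param l_values prototype counts to evaluate (e.g. `2:9`).
#' @param n_runs fold-averaged repetitions per value (default 5).
#' @param methods methods to sweep (default intersection of configured
#'   methods with dpnn/kmnn).
#' @return `data.frame`: one row per method x prototype count with mean
#'   `auc`, `mrr`, `rpl` (and `rr`) over the runs.
#' @export
sensitivity_sweep <- function(config, l_values, n_runs = 5,
                              methods = intersect(config$methods,
                                                  c("dpnn", "kmnn"))) {
  stopifnot(length(l_values) >= 1)
  rows <- list()
  for (l in l_values) {
    cfg <- config
    cfg$n_repetitions <- as.integer(n_runs)
    cfg$methods <- methods
    cfg$dpnn$n_prototypes <- as.integer(l)
    cfg$kmnn$n_clusters <- as.integer(l)
    cfg$master_seed <- config$master_seed + 100000L * as.integer(l)
    samples <- run_experiment(cfg)
    for (m in methods) {
      sub <- samples[samples$method == m, , drop = FALSE]
      rows[[length(rows) + 1L]] <- data.frame(
        method = m, n_prototypes = as.integer(l),
        auc = mean(sub$auc, na.rm = TRUE),
        mrr = mean(sub$mrr, na.rm = TRUE),
        rpl = mean(sub$rpl, na.rm = TRUE),
        rr = mean(sub$rr, na.rm = TRUE),
        n_runs = nrow(sub))
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
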