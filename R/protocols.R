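#' Fit the intermediate regressors on a training cohort
#'
#' Builds both intermediate targets from the training patients — the
#' outcome-adjusted reasoning-oriented score (1--11) and, for comparison,
#' the numeric Gleason score (6--10) — scales each by its theoretical
#' range, and fits one ridge regressor per target on the composition
#' vectors. The BCR label is consumed here, as a training label, and
#' nowhere downstream of fitting.
#'
#' @param patients training patient table (gleason_primary,
#'   gleason_secondary, gleason_score, bcr).
#' @param compositions n x k row-normalized composition matrix.
#' @param seed integer seed (inner-CV fold shuffle).
#' @param penalty_grid,cv_folds passed to [fit_intermediate()].
#' @return named list with elements `reasoning` and `gleason`.
#' @export
fit_intermediates <- function(patients, compositions, seed = 1L,
                              penalty_grid = 10^seq(-3, 3, by = 1),
                              cv_folds = 5L) {
  base <- base_score(patients$gleason_score, patients$gleason_primary,
                     patients$gleason_secondary)
  adj <- adjusted_score(base, patients$bcr)
  tr <- scale_target(adj, "reasoning")
  tg <- scale_target(patients$gleason_score, "gleason")
  list(
    reasoning = fit_intermediate(compositions, tr$values, tr$scaler,
                                 penalty_grid, cv_folds,
                                 seed = derive_seed(seed, 10L)),
    gleason = fit_intermediate(compositions, tg$values, tg$scaler,
                               penalty_grid, cv_folds,
                               seed = derive_seed(seed, 11L))
  )
}

assert_disjoint_ids <- function(train_ids, test_ids, what = "cohorts") {
  overlap <- intersect(train_ids, test_ids)
  if (length(overlap) > 0L) {
    stop_prostir("patient ids appear in both training and test %s (%s): refusing to evaluate with leakage",
                 what, paste(utils::head(overlap, 3L), collapse = ", "))
  }
  invisible(TRUE)
}

#' Evaluation report for one cohort and one configuration
#'
#' Bundles the metric suite on held-out predictions: bootstrap AUROC with
#' 95 percent percentile CI, Brier score, calibration curve and
#' decision-curve analysis.
#'
#' @param cohort,config labels for the report.
#' @param scores raw linear scores (AUROC).
#' @param probabilities recalibrated probabilities (Brier, calibration,
#'   net benefit).
#' @param labels 0/1 outcomes.
#' @param n_boot bootstrap iterations.
#' @param seed integer seed for the bootstrap.
#' @param n_bins calibration bins.
#' @param thresholds decision-curve thresholds.
#' @return a list of class `evaluation_report`.
#' @export
evaluation_report <- function(cohort, config, scores, probabilities, labels,
                              n_boot = 2000L, seed = 1L, n_bins = 10L,
                              thresholds = seq(0.05, 0.60, by = 0.05)) {
  ba <- bootstrap_auroc(scores, labels, n_boot = n_boot, seed = seed)
  rep <- list(
    cohort = cohort, config = config, n = length(labels),
    auroc = ba$auroc, ci_low = ba$ci_low, ci_high = ba$ci_high,
    n_boot = n_boot,
    brier = brier(probabilities, labels),
    calibration = calibration_curve(probabilities, labels, n_bins),
    net_benefit = decision_curve(probabilities, labels, thresholds),
    seed = seed
  )
  class(rep) <- "evaluation_report"
  rep
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf("<evaluation_report> %s / %s  n=%d\n", x$cohort, x$config, x$n))
  cat(sprintf("  AUROC %.3f [95%% CI %.3f-%.3f]  (bootstrap n=%d)\n",
              x$auroc, x$ci_low, x$ci_high, x$n_boot))
  cat(sprintf("  Brier %.3f\n", x$brier))
  invisible(x)
}

#' Internal validation: stratified k-fold cross-validation
#'
#' The reference protocol for the internal cohort: each patient lands in
#' exactly one test fold; all fitting — the intermediate regressors, the
#' final linear model and its recalibration — uses only the training
#' folds; pooled out-of-fold scores feed the bootstrap AUROC. Folds are
#' stratified by outcome so every fold carries both classes.
#'
#' @param patients internal-cohort patient table.
#' @param compositions n x k composition matrix aligned with `patients`.
#' @param configs named list of [bcr_config()]s (default all five).
#' @param k folds (default 3).
#' @param stratified stratify folds by outcome (default TRUE).
#' @param seed integer seed (fold shuffle, bootstrap).
#' @param n_boot bootstrap iterations for the pooled AUROC.
#' @param ... passed to [evaluation_report()].
#' @return list with `folds` (per-patient fold id), `reports` (one
#'   `evaluation_report` per config) and `oof` (pooled out-of-fold
#'   predictions per config).
#' @export
kfold_protocol <- function(patients, compositions,
                           configs = all_bcr_configs(), k = 3L,
                           stratified = TRUE, seed = 1L, n_boot = 2000L,
                           ...) {
  n <- nrow(patients)
  k <- as.integer(k)
  if (n < k) stop_prostir("need at least k = %d patients", k)
  if (anyDuplicated(patients$patient_id)) {
    stop_prostir("duplicated patient ids in the cohort: the leakage guard cannot certify fold disjointness")
  }
  compositions <- as.matrix(compositions)
  y <- patients$bcr
  fold_id <- with_seed(derive_seed(seed, 12L), {
    if (stratified) {
      f <- integer(n)
      for (cls in unique(y)) {
        idx <- which(y == cls)
        if (length(idx) < k) {
          stop_prostir("class %s has fewer members (%d) than folds (%d)",
                       cls, length(idx), k)
        }
        f[idx] <- sample(rep_len(seq_len(k), length(idx)))
      }
      f
    } else {
      sample(rep_len(seq_len(k), n))
    }
  })

  oof <- lapply(configs, function(cfg) {
    data.frame(patient_id = patients$patient_id, fold = fold_id,
               score = NA_real_, probability = NA_real_, bcr = y)
  })
  for (f in seq_len(k)) {
    tr <- fold_id != f
    assert_disjoint_ids(patients$patient_id[tr], patients$patient_id[!tr],
                        "folds")
    inter <- fit_intermediates(patients[tr, , drop = FALSE],
                               compositions[tr, , drop = FALSE],
                               seed = derive_seed(seed, 100L + f))
    for (nm in names(configs)) {
      cfg <- configs[[nm]]
      xtr <- build_design(cfg, patients[tr, , drop = FALSE],
                          compositions[tr, , drop = FALSE], inter)
      mod <- fit_bcr(xtr, y[tr])
      xte <- build_design(cfg, patients[!tr, , drop = FALSE],
                          compositions[!tr, , drop = FALSE], inter)
      pred <- predict_bcr(mod, xte)
      oof[[nm]]$score[!tr] <- pred$score
      oof[[nm]]$probability[!tr] <- pred$probability
    }
  }
  reports <- lapply(names(configs), function(nm) {
    evaluation_report(cohort = patients$cohort[1L], config = nm,
                      scores = oof[[nm]]$score,
                      probabilities = oof[[nm]]$probability,
                      labels = y, n_boot = n_boot,
                      seed = derive_seed(seed, 13L), ...)
  })
  names(reports) <- names(configs)
  list(folds = fold_id, reports = reports, oof = oof)
}

#' External validation protocol
#'
#' Fits the intermediate regressors and one final model per configuration
#' on the training cohort only, then applies them unchanged to each
#' external cohort. Overlapping patient ids across cohorts are a hard
#' error (leakage guard).
#'
#' @param train list with `patients` and `compositions` for the training
#'   cohort.
#' @param externals named list of external cohorts, each a list with
#'   `patients` and `compositions`; must be nonempty tables.
#' @param configs named list of [bcr_config()]s (default all five).
#' @param seed integer seed.
#' @param n_boot bootstrap iterations.
#' @param ... passed to [evaluation_report()].
#' @return list with `bundles` (fitted model per config), `intermediate`,
#'   and `reports` (per external cohort, per config).
#' @export
external_protocol <- function(train, externals,
                              configs = all_bcr_configs(), seed = 1L,
                              n_boot = 2000L, ...) {
  if (length(externals) == 0L) stop_prostir("no external cohorts supplied")
  for (ex in externals) {
    if (is.null(ex$patients) || nrow(ex$patients) == 0L) {
      stop_prostir("empty external cohort")
    }
    assert_disjoint_ids(train$patients$patient_id, ex$patients$patient_id)
  }
  inter <- fit_intermediates(train$patients, train$compositions,
                             seed = derive_seed(seed, 20L))
  bundles <- lapply(configs, function(cfg) {
    x <- build_design(cfg, train$patients, train$compositions, inter)
    fit_bcr(x, train$patients$bcr)
  })
  reports <- lapply(names(externals), function(ex_nm) {
    ex <- externals[[ex_nm]]
    out <- lapply(names(configs), function(nm) {
      x <- build_design(configs[[nm]], ex$patients, ex$compositions, inter)
      pred <- predict_bcr(bundles[[nm]], x)
      evaluation_report(cohort = ex_nm, config = nm,
                        scores = pred$score,
                        probabilities = pred$probability,
                        labels = ex$patients$bcr, n_boot = n_boot,
                        seed = derive_seed(seed, 21L), ...)
    })
    names(out) <- names(configs)
    out
  })
  names(reports) <- names(externals)
  list(bundles = bundles, intermediate = inter, reports = reports)
}

#' Flatten evaluation reports to a results table
#'
#' One row per cohort x configuration: AUROC with CI and Brier score —
#' the layout of a multi-cohort results table.
#'
#' @param reports a named list (cohorts) of named lists (configs) of
#'   `evaluation_report`s, or a flat named list of reports.
#' @return data.frame cohort, config, n, auroc, ci_low, ci_high, brier.
#' @export
reports_table <- function(reports) {
  flat <- list()
  for (el in reports) {
    if (inherits(el, "evaluation_report")) flat <- c(flat, list(el))
    else flat <- c(flat, unname(el))
  }
  do.call(rbind, lapply(flat, function(r) {
    data.frame(cohort = r$cohort, config = r$config, n = r$n,
               auroc = r$auroc, ci_low = r$ci_low, ci_high = r$ci_high,
               brier = r$brier)
  }))
}
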