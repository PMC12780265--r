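#' Final BCR model configuration
#'
#' The five input configurations compared throughout the pipeline:
#' \describe{
#'   \item{gleason_only}{numeric Gleason score, 1 column;}
#'   \item{direct_100}{the k composition fractions directly;}
#'   \item{ml_gleason}{ML-predicted Gleason score (intermediate regressor
#'     with a Gleason target), 1 column;}
#'   \item{ml_reasoning}{ML-predicted reasoning-oriented score, 1 column;}
#'   \item{psa_plus_ml_reasoning}{PSA plus the predicted reasoning score,
#'     2 columns.}
#' }
#'
#' @param inputs one of the five configuration names.
#' @param psa_transform `"raw"` (default) or `"log"` for config 5.
#' @param seed integer seed carried for provenance.
#' @return a list of class `bcr_config`.
#' @export
bcr_config <- function(inputs = c("gleason_only", "direct_100", "ml_gleason",
                                  "ml_reasoning", "psa_plus_ml_reasoning"),
                       psa_transform = c("raw", "log"), seed = 1L) {
  structure(list(inputs = match.arg(inputs),
                 psa_transform = match.arg(psa_transform),
                 seed = as.integer(seed)),
            class = "bcr_config")
}

#' All five BCR model configurations
#'
#' @param psa_transform passed to [bcr_config()] for config 5.
#' @return named list of the five `bcr_config` objects.
#' @export
all_bcr_configs <- function(psa_transform = "raw") {
  nm <- c("gleason_only", "direct_100", "ml_gleason", "ml_reasoning",
          "psa_plus_ml_reasoning")
  stats::setNames(lapply(nm, bcr_config, psa_transform = psa_transform), nm)
}

#' Build the design matrix for one BCR configuration
#'
#' Never consumes the outcome: BCR is a training label for [fit_bcr()],
#' not a predictor, so designs built here are safe for inference.
#'
#' @param config a [bcr_config()].
#' @param patients patient table with at least `gleason_score` (configs 1)
#'   and `psa` (config 5).
#' @param compositions n x k composition matrix (config 2, and input to
#'   the intermediate predictions for configs 3--5).
#' @param intermediate named list of fitted `intermediate_regressor`s with
#'   elements `gleason` and/or `reasoning` (configs 3--5).
#' @return numeric design matrix with named columns.
#' @export
build_design <- function(config, patients, compositions = NULL,
                         intermediate = NULL) {
  stopifnot(inherits(config, "bcr_config"))
  need_comp <- config$inputs != "gleason_only"
  if (need_comp && is.null(compositions)) {
    stop_prostir("config '%s' needs composition vectors", config$inputs)
  }
  if (!is.null(compositions)) compositions <- as.matrix(compositions)
  x <- switch(
    config$inputs,
    gleason_only = {
      cbind(gleason = as.numeric(patients$gleason_score))
    },
    direct_100 = compositions,
    ml_gleason = {
      m <- intermediate$gleason
      if (is.null(m)) stop_prostir("no fitted intermediate Gleason model")
      cbind(ml_gleason = predict_score(m, compositions)$score)
    },
    ml_reasoning = {
      m <- intermediate$reasoning
      if (is.null(m)) stop_prostir("no fitted intermediate reasoning model")
      cbind(ml_reasoning = predict_score(m, compositions)$score)
    },
    psa_plus_ml_reasoning = {
      m <- intermediate$reasoning
      if (is.null(m)) stop_prostir("no fitted intermediate reasoning model")
      if (is.null(patients$psa)) stop_prostir("PSA column required for config 5")
      psa <- if (config$psa_transform == "log") log(patients$psa)
             else patients$psa
      cbind(psa = as.numeric(psa),
            ml_reasoning = predict_score(m, compositions)$score)
    }
  )
  assert_no_outcome(x)
  x
}

assert_no_outcome <- function(design) {
  if (!is.null(colnames(design)) &&
      any(tolower(colnames(design)) %in% c("bcr", "outcome", "label"))) {
    stop_prostir("outcome column found in a design matrix: BCR is a training label, never a predictor")
  }
  invisible(design)
}

#' Fit a final BCR model with logistic recalibration
#'
#' Least-squares linear fit of the binary 5-year BCR label on the design
#' (ridge with a small fixed penalty for the composition-only config when
#' n <= k), followed by a logistic recalibration of the outcome on the
#' linear score fitted on the same training data ("updating" to the
#' outcome incidence): by the logistic score equations the mean
#' recalibrated probability equals the training incidence.
#'
#' @param design numeric design matrix from [build_design()].
#' @param bcr 0/1 training labels; both classes required.
#' @param recalibrate `"slope"` (logistic intercept + slope, default) or
#'   `"intercept"` (slope fixed at 1 on the linear score).
#' @param ridge_fallback penalty used when the design is not solvable by
#'   plain least squares (n <= p), as for k composition columns at small n.
#' @return a `bcr_model`: `config` columns, `weights`, `intercept`,
#'   `recalibration` (a, b), `incidence`, `fitted` (score, probability).
#' @export
fit_bcr <- function(design, bcr, recalibrate = c("slope", "intercept"),
                    ridge_fallback = 1) {
  recalibrate <- match.arg(recalibrate)
  x <- as.matrix(design)
  assert_no_outcome(x)
  y <- check_binary(bcr, "bcr")
  if (nrow(x) != length(y)) stop_prostir("labels do not match design rows")

  constant <- all(apply(x, 2, function(v) stats::sd(v) < 1e-12))
  if (constant) {
    # degenerate design: constant-probability model at the incidence
    inc <- mean(y)
    mod <- list(columns = colnames(x), weights = rep(0, ncol(x)),
                intercept = inc, ridge_penalty = 0,
                recalibration = list(a = stats::qlogis(min(max(inc, 1e-12),
                                                           1 - 1e-12)),
                                     b = 0, kind = recalibrate),
                incidence = inc,
                fitted = data.frame(score = rep(inc, length(y)),
                                    probability = rep(inc, length(y))))
    class(mod) <- "bcr_model"
    return(mod)
  }

  lambda <- 0
  if (nrow(x) <= ncol(x)) lambda <- ridge_fallback
  fit <- ridge_solve(x, y, lambda)
  if (lambda == 0 && any(!is.finite(fit$weights))) {
    stop_prostir("rank-deficient design without a penalty")
  }
  score <- drop(x %*% fit$weights) + fit$intercept

  inc <- mean(y)
  if (recalibrate == "slope") {
    cal <- suppressWarnings(stats::glm(y ~ score, family = stats::binomial()))
    a <- unname(stats::coef(cal)[1]); b <- unname(stats::coef(cal)[2])
    if (!is.finite(b)) { a <- stats::qlogis(inc); b <- 0 }
  } else {
    cal <- suppressWarnings(
      stats::glm(y ~ 1 + offset(score), family = stats::binomial())
    )
    a <- unname(stats::coef(cal)[1]); b <- 1
  }
  prob <- clamp_prob(stats::plogis(a + b * score))
  mod <- list(columns = colnames(x), weights = fit$weights,
              intercept = fit$intercept, ridge_penalty = lambda,
              recalibration = list(a = a, b = b, kind = recalibrate),
              incidence = inc,
              fitted = data.frame(score = score, probability = prob))
  class(mod) <- "bcr_model"
  mod
}

#' Predict BCR scores and probabilities
#'
#' Returns the raw linear score (used for AUROC — invariant to the
#' strictly monotone recalibration) and the recalibrated probability in
#' (0,1) (used for Brier, calibration and decision curves).
#'
#' @param model a `bcr_model`.
#' @param design design matrix with the same columns as at fit time.
#' @return data.frame with columns `score`, `probability`.
#' @export
predict_bcr <- function(model, design) {
  stopifnot(inherits(model, "bcr_model"))
  x <- as.matrix(design)
  assert_no_outcome(x)
  if (ncol(x) != length(model$weights)) {
    stop_prostir("design has %d columns, model expects %d",
                 ncol(x), length(model$weights))
  }
  if (!is.null(model$columns) && !is.null(colnames(x)) &&
      !identical(colnames(x), model$columns)) {
    stop_prostir("design columns (%s) do not match the fitted model (%s)",
                 paste(colnames(x), collapse = ","),
                 paste(model$columns, collapse = ","))
  }
  score <- drop(x %*% model$weights) + model$intercept
  prob <- clamp_prob(stats::plogis(model$recalibration$a +
                                     model$recalibration$b * score))
  data.frame(score = score, probability = prob)
}
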