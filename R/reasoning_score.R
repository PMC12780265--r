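#' The reasoning-oriented grading scale
#'
#' The nine clinically observed Gleason pattern pairs and their newly
#' assigned base scores. The order refines the Gleason score by its
#' pattern composition — e.g. 7 (4+3) sits above 7 (3+4) — and is **not**
#' monotone in the Gleason score itself: 8 (5+3) and 9 (5+4) rank above
#' 9 (4+5), reflecting the worse prognosis of a primary pattern 5. The
#' mapping is fixed; a +/-1 outcome adjustment on training samples yields
#' the final 1--11 scale.
#'
#' @return data.frame with columns `gleason_score`, `primary`,
#'   `secondary`, `base`.
#' @export
reasoning_scale <- function() {
  data.frame(
    gleason_score = c(6L, 7L, 7L, 8L, 8L, 9L, 8L, 9L, 10L),
    primary       = c(3L, 3L, 4L, 4L, 3L, 4L, 5L, 5L, 5L),
    secondary     = c(3L, 4L, 3L, 4L, 5L, 5L, 3L, 4L, 5L),
    base          = c(2L, 3L, 4L, 5L, 6L, 7L, 8L, 9L, 10L)
  )
}

#' Base score on the reasoning-oriented scale
#'
#' Exact lookup of the pattern-pair mapping in [reasoning_scale()].
#' Vectorized; any combination outside the nine listed rows is an error
#' (e.g. 4+2 is not a supported pattern pair). The non-monotonicity in
#' Gleason score is intentional and must not be "corrected".
#'
#' @param gleason_score integer Gleason score 6--10 (primary + secondary).
#' @param primary,secondary Gleason patterns in \{3, 4, 5\}.
#' @return integer base score(s) in 2--10.
#' @export
base_score <- function(gleason_score, primary, secondary) {
  tab <- reasoning_scale()
  key <- paste(gleason_score, primary, secondary)
  idx <- match(key, paste(tab$gleason_score, tab$primary, tab$secondary))
  if (anyNA(idx)) {
    bad <- unique(key[is.na(idx)])
    stop_prostir("unsupported Gleason pattern combination: %s",
                 paste(bad, collapse = ", "))
  }
  tab$base[idx]
}

#' Outcome-adjusted reasoning score (training samples only)
#'
#' Adds one point for a positive 5-year BCR, subtracts one for a negative
#' BCR, giving the final 1--11 scale. The adjustment uses the observed
#' outcome and is therefore only ever applied to training samples; at
#' inference the score is predicted from composition features, never
#' observed.
#'
#' @param base base score(s) in 2--10 from [base_score()].
#' @param bcr binary outcome(s), 0/1.
#' @return integer adjusted score(s) in 1--11.
#' @export
adjusted_score <- function(base, bcr) {
  if (any(!base %in% 2:10)) stop_prostir("base score must lie in 2..10")
  if (any(!bcr %in% c(0, 1))) stop_prostir("bcr must be 0/1")
  as.integer(base + ifelse(bcr == 1, 1L, -1L))
}

#' Scale a regression target to \[0,1\]
#'
#' Affine min-max map using the *theoretical* range of the target — the
#' reasoning scale spans 1--11, the Gleason score 6--10 — so the scaler is
#' data-independent and identical across internal and external cohorts.
#'
#' @param scores numeric scores.
#' @param kind `"reasoning"` (range 1--11) or `"gleason"` (range 6--10).
#' @return list with `values` (scaled), and `scaler` (list `lo`, `hi`,
#'   `kind`) usable with [unscale_target()].
#' @export
scale_target <- function(scores, kind = c("reasoning", "gleason")) {
  kind <- match.arg(kind)
  rng <- if (kind == "reasoning") c(1, 11) else c(6, 10)
  if (any(scores < rng[1] | scores > rng[2])) {
    stop_prostir("scores outside the %s range %g..%g", kind, rng[1], rng[2])
  }
  scaler <- list(lo = rng[1], hi = rng[2], kind = kind)
  list(values = (scores - rng[1]) / (rng[2] - rng[1]), scaler = scaler)
}

#' Invert the target scaler
#'
#' @param values scaled values.
#' @param scaler the `scaler` element returned by [scale_target()].
#' @return values mapped back to the original scale.
#' @export
unscale_target <- function(values, scaler) {
  scaler$lo + values * (scaler$hi - scaler$lo)
}

# ridge solution of min ||y - Xw - b||^2 + lambda ||w||^2 (intercept
# unpenalized), via QR on the lambda-augmented design
ridge_solve <- function(x, y, lambda) {
  n <- nrow(x); p <- ncol(x)
  xa <- rbind(cbind(1, x), cbind(0, sqrt(lambda) * diag(p)))
  ya <- c(y, rep(0, p))
  fit <- stats::lm.fit(xa, ya)
  co <- fit$coefficients
  co[is.na(co)] <- 0
  list(intercept = unname(co[1]), weights = unname(co[-1]))
}

#' Fit the intermediate ridge regressor
#'
#' Ridge regression of a scaled target (the reasoning score, or the
#' Gleason score for comparison) on composition vectors, minimizing
#' \eqn{\|y - Xw - b\|^2 + \lambda \|w\|^2} with the penalty chosen from a
#' grid by inner k-fold cross-validated mean squared error. Deterministic
#' given `seed`.
#'
#' @param compositions n x k matrix of row-normalized composition vectors.
#' @param targets_scaled scaled targets in \[0,1\] from [scale_target()].
#' @param scaler the scaler that produced `targets_scaled` (stored so
#'   predictions can be mapped back).
#' @param penalty_grid candidate lambdas (default 10^-3..10^3, log-spaced).
#' @param cv_folds inner CV folds (default 5; capped at n).
#' @param seed integer seed for the fold shuffle.
#' @return an `intermediate_regressor`: weights, intercept, ridge_penalty,
#'   target_kind, scaler, cv_mse table.
#' @export
fit_intermediate <- function(compositions, targets_scaled, scaler,
                             penalty_grid = 10^seq(-3, 3, by = 1),
                             cv_folds = 5L, seed = 1L) {
  x <- as.matrix(compositions)
  y <- as.numeric(targets_scaled)
  if (nrow(x) < 2L) stop_prostir("need at least 2 training samples")
  if (nrow(x) != length(y)) stop_prostir("targets do not match compositions")
  if (length(penalty_grid) == 0L) stop_prostir("penalty_grid is empty")
  n <- nrow(x)
  folds <- max(2L, min(as.integer(cv_folds), n))

  cv_mse <- rep(NA_real_, length(penalty_grid))
  if (length(penalty_grid) > 1L) {
    fold_id <- with_seed(derive_seed(seed, 4L), {
      sample(rep_len(seq_len(folds), n))
    })
    for (j in seq_along(penalty_grid)) {
      errs <- numeric(0)
      for (f in seq_len(folds)) {
        tr <- fold_id != f
        if (sum(tr) < 1L || sum(!tr) < 1L) next
        fit <- ridge_solve(x[tr, , drop = FALSE], y[tr], penalty_grid[j])
        pred <- drop(x[!tr, , drop = FALSE] %*% fit$weights) + fit$intercept
        errs <- c(errs, (pred - y[!tr])^2)
      }
      cv_mse[j] <- mean(errs)
    }
    lambda <- penalty_grid[which.min(cv_mse)]
  } else {
    lambda <- penalty_grid[1]
  }
  fit <- ridge_solve(x, y, lambda)
  out <- list(weights = fit$weights, intercept = fit$intercept,
              ridge_penalty = lambda,
              target_kind = scaler$kind, scaler = scaler,
              cv_mse = data.frame(lambda = penalty_grid, mse = cv_mse))
  class(out) <- "intermediate_regressor"
  out
}

#' Predict the reasoning-oriented (or Gleason) score from compositions
#'
#' Returns the raw linear prediction on the scaled scale, its back-mapped
#' value on the original 1--11 (or 6--10) scale with no clipping (ranking
#' uses), and a clipped copy for display.
#'
#' @param model an `intermediate_regressor`.
#' @param compositions m x k matrix matching the training dimensionality.
#' @return data.frame with columns `scaled`, `score`, `score_clipped`.
#' @export
predict_score <- function(model, compositions) {
  stopifnot(inherits(model, "intermediate_regressor"))
  x <- as.matrix(compositions)
  if (ncol(x) != length(model$weights)) {
    stop_prostir("composition dim %d does not match model dim %d",
                 ncol(x), length(model$weights))
  }
  scaled <- drop(x %*% model$weights) + model$intercept
  score <- unscale_target(scaled, model$scaler)
  data.frame(scaled = scaled, score = score,
             score_clipped = pmin(pmax(score, model$scaler$lo),
                                  model$scaler$hi))
}
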