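#' Area under the ROC curve (Mann--Whitney formulation)
#'
#' Probability that a random positive outranks a random negative, with
#' ties counted 1/2 — computed from midranks, so it is exact for tied
#' scores.
#'
#' @param scores numeric scores, higher = more positive.
#' @param labels 0/1 labels, both classes present.
#' @return AUROC in \[0,1\].
#' @export
auroc <- function(scores, labels) {
  labels <- check_binary(labels, "labels")
  if (any(!is.finite(scores))) stop_prostir("scores must be finite")
  n1 <- sum(labels == 1L)
  n0 <- sum(labels == 0L)
  r <- rank(scores)  # midranks
  (sum(r[labels == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Patient-level bootstrap AUROC with percentile CI
#'
#' Resamples patients with replacement; a resample lacking one of the two
#' outcome classes is redrawn (keeping the iteration count exact).
#' Percentile 2.5/97.5 bounds. Deterministic given `seed`.
#'
#' @param scores,labels as in [auroc()].
#' @param n_boot bootstrap iterations (the reference protocol uses 10,000).
#' @param seed integer seed.
#' @return list with `auroc` (point estimate on the full sample),
#'   `ci_low`, `ci_high`, `n_boot`, `boot` (the resampled values).
#' @export
bootstrap_auroc <- function(scores, labels, n_boot = 10000L, seed = 1L) {
  labels <- check_binary(labels, "labels")
  n_boot <- as.integer(n_boot)
  if (n_boot < 1L) stop_prostir("n_boot must be >= 1")
  n <- length(scores)
  point <- auroc(scores, labels)
  boot <- with_seed(derive_seed(seed, 5L), {
    vapply(seq_len(n_boot), function(b) {
      repeat {
        idx <- sample.int(n, n, replace = TRUE)
        if (length(unique(labels[idx])) == 2L) break
      }
      auroc(scores[idx], labels[idx])
    }, numeric(1))
  })
  ci <- unname(stats::quantile(boot, c(0.025, 0.975), type = 7))
  list(auroc = point, ci_low = ci[1], ci_high = ci[2],
       n_boot = n_boot, boot = boot)
}

#' Brier score
#'
#' Mean squared difference between predicted probability and the binary
#' outcome; 0 is perfect, 0.25 is an uninformative constant 0.5.
#'
#' @param probabilities predicted probabilities in \[0,1\].
#' @param labels 0/1 outcomes.
#' @return the Brier score.
#' @export
brier <- function(probabilities, labels) {
  if (any(probabilities < 0 | probabilities > 1)) {
    stop_prostir("probabilities must lie in [0, 1]")
  }
  if (length(probabilities) != length(labels)) {
    stop_prostir("probabilities and labels differ in length")
  }
  mean((probabilities - labels)^2)
}

#' Calibration curve on equal-width bins
#'
#' Bins \[0,1\] into `n_bins` equal-width bins; per nonempty bin reports
#' the mean predicted probability and the observed outcome fraction.
#' Empty bins are omitted.
#'
#' @param probabilities predicted probabilities in \[0,1\].
#' @param labels 0/1 outcomes.
#' @param n_bins number of bins (>= 2; default 10).
#' @return data.frame bin, bin_mean_pred, bin_mean_obs, n.
#' @export
calibration_curve <- function(probabilities, labels, n_bins = 10L) {
  if (any(probabilities < 0 | probabilities > 1)) {
    stop_prostir("probabilities must lie in [0, 1]")
  }
  n_bins <- as.integer(n_bins)
  if (n_bins < 2L) stop_prostir("n_bins must be >= 2")
  bin <- pmin(pmax(ceiling(probabilities * n_bins), 1L), n_bins)
  keep <- sort(unique(bin))
  data.frame(
    bin = keep,
    bin_mean_pred = vapply(keep, function(b) mean(probabilities[bin == b]),
                           numeric(1)),
    bin_mean_obs = vapply(keep, function(b) mean(labels[bin == b]),
                          numeric(1)),
    n = vapply(keep, function(b) sum(bin == b), integer(1))
  )
}

#' Decision-curve analysis (net benefit)
#'
#' Net benefit of treating at threshold t when a patient is treated iff
#' their predicted probability >= t:
#' \deqn{NB(t) = TP(t)/n - FP(t)/n \cdot t/(1-t)}
#' together with the treat-all benefit \eqn{\pi - (1-\pi) t/(1-t)} and the
#' treat-none benefit 0.
#'
#' @param probabilities predicted probabilities in \[0,1\].
#' @param labels 0/1 outcomes.
#' @param thresholds thresholds strictly inside (0,1); default the
#'   clinically relevant grid 0.05--0.60 by 0.05.
#' @return data.frame threshold, model_nb, treat_all_nb, treat_none_nb.
#' @export
decision_curve <- function(probabilities, labels,
                           thresholds = seq(0.05, 0.60, by = 0.05)) {
  if (any(thresholds <= 0 | thresholds >= 1)) {
    stop_prostir("thresholds must lie strictly inside (0, 1)")
  }
  n <- length(labels)
  prev <- mean(labels)
  rows <- lapply(thresholds, function(t) {
    treat <- probabilities >= t
    tp <- sum(treat & labels == 1)
    fp <- sum(treat & labels == 0)
    data.frame(threshold = t,
               model_nb = tp / n - fp / n * t / (1 - t),
               treat_all_nb = prev - (1 - prev) * t / (1 - t),
               treat_none_nb = 0)
  })
  do.call(rbind, rows)
}

#' Fisher's exact test for a 2x2 table (two-sided)
#'
#' Two-sided p-value for the table \code{rbind(c(a, b), c(c, d))} under
#' the minimum-likelihood rule: the sum of hypergeometric probabilities of
#' all tables with the same margins whose probability does not exceed the
#' observed table's.
#'
#' @param a,b,c,d nonnegative integer cell counts; both margins positive.
#' @return the two-sided p-value.
#' @export
fisher_exact_2x2 <- function(a, b, c, d) {
  cells <- c(a, b, c, d)
  if (any(cells < 0) || any(cells != round(cells))) {
    stop_prostir("cell counts must be nonnegative integers")
  }
  if ((a + b) == 0 || (c + d) == 0 || (a + c) == 0 || (b + d) == 0) {
    stop_prostir("both margins of the 2x2 table must be positive")
  }
  stats::fisher.test(matrix(c(a, c, b, d), 2L, 2L))$p.value
}

#' Wilcoxon rank-sum test (two-sided)
#'
#' Midrank statistic throughout. For total n <= 10 the p-value is computed
#' by exact enumeration over all group assignments (valid under ties,
#' where the classical exact distribution is not); for larger samples the
#' normal approximation with continuity correction is used.
#'
#' @param x,y numeric samples, each nonempty.
#' @return the two-sided p-value.
#' @export
wilcoxon_rank_sum <- function(x, y) {
  if (length(x) == 0L || length(y) == 0L) {
    stop_prostir("both groups must be nonempty")
  }
  n1 <- length(x); n2 <- length(y); n <- n1 + n2
  if (n <= 10L) {
    r <- rank(c(x, y))
    mu <- n1 * (n + 1) / 2
    obs <- abs(sum(r[seq_len(n1)]) - mu)
    combs <- utils::combn(n, n1)
    stat <- abs(colSums(matrix(r[combs], nrow = n1)) - mu)
    mean(stat >= obs - 1e-9)
  } else {
    stats::wilcox.test(x, y, exact = FALSE, correct = TRUE)$p.value
  }
}
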