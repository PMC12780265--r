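test_that("AUROC matches brute-force pair counting and its identities", {
  expect_equal(auroc(c(1, 2, 3, 4), c(0, 0, 1, 1)), 1.0)
  expect_equal(auroc(rep(1, 6), rep(c(0, 1), 3)), 0.5)
  expect_equal(auroc(c(0.1, 0.4, 0.35, 0.8), c(0, 0, 1, 1)), 0.75)
  expect_error(auroc(1:3, c(1, 1, 1)), "both outcome classes")

  set.seed(31)
  for (rep in 1:20) {
    n <- sample(6:30, 1)
    s <- sample(rnorm(n), n)  # may contain ties via rounding
    s <- round(s, 1)
    y <- rbinom(n, 1, 0.5)
    if (length(unique(y)) < 2) next
    expect_equal(auroc(s, y), auroc_bruteforce(s, y))
    if (!any(duplicated(s))) {
      expect_equal(auroc(s, y) + auroc(-s, y), 1.0)
    }
  }
  # pROC as an extra independent implementation
  set.seed(32)
  s <- rnorm(40); y <- rbinom(40, 1, 0.5)
  expect_equal(auroc(s, y),
               as.numeric(suppressMessages(pROC::auc(y, s, direction = "<"))))
})

test_that("bootstrap CIs bracket the point estimate and behave degenerately", {
  s <- c(1, 2, 10, 20)
  y <- c(0, 0, 1, 1)  # every resample with both classes has AUROC 1
  bb <- bootstrap_auroc(s, y, n_boot = 200L, seed = 1L)
  expect_equal(c(bb$ci_low, bb$ci_high), c(1, 1))
  expect_equal(bb$auroc, 1)
  expect_error(bootstrap_auroc(s, y, n_boot = 0L), "n_boot")

  set.seed(33)
  s2 <- rnorm(50); y2 <- rbinom(50, 1, 0.5)
  for (sd in 1:20) {
    b <- bootstrap_auroc(s2, y2, n_boot = 300L, seed = sd)
    expect_lte(b$ci_low, b$auroc)
    expect_gte(b$ci_high, b$auroc)
  }
  # determinism
  b1 <- bootstrap_auroc(s2, y2, n_boot = 100L, seed = 9L)
  b2 <- bootstrap_auroc(s2, y2, n_boot = 100L, seed = 9L)
  expect_identical(b1$boot, b2$boot)
})

test_that("bootstrap CI width shrinks with sample size", {
  widths <- sapply(1:10, function(sd) {
    draw <- function(n) {
      withr::with_seed(1000L + sd * 7L + n, {
        y <- rep(c(0L, 1L), length.out = n)
        s <- rnorm(n, mean = y)  # same effect size at both n
        bootstrap_auroc(s, y, n_boot = 300L, seed = sd)
      })
    }
    small <- draw(100L); big <- draw(800L)
    c(small$ci_high - small$ci_low, big$ci_high - big$ci_low)
  })
  expect_gt(mean(widths[1, ]), mean(widths[2, ]))
})

test_that("Brier score equals the mean squared probability error", {
  expect_equal(brier(c(1, 0, 1), c(1, 0, 1)), 0)
  expect_equal(brier(rep(0.5, 8), rep(c(0, 1), 4)), 0.25)
  expect_equal(brier(c(1, 0, 0.5), c(1, 0, 1)), 0.25 / 3)
  expect_error(brier(c(1.2, 0.5), c(1, 0)), "\\[0, 1\\]")
})

test_that("calibration bins track observed frequencies", {
  withr::with_seed(34L, {
    p <- runif(1e5)
    y <- rbinom(1e5, 1, p)
    cal <- calibration_curve(p, y, n_bins = 10L)
    expect_equal(nrow(cal), 10L)
    expect_lt(max(abs(cal$bin_mean_pred - cal$bin_mean_obs)), 0.02)
    expect_equal(sum(cal$n), 1e5L)
  })
  one <- calibration_curve(rep(0.42, 20), rep(c(0, 1), 10))
  expect_equal(nrow(one), 1L)
  expect_equal(one$bin_mean_obs, 0.5)
  expect_equal(one$bin_mean_pred, 0.42)
  expect_error(calibration_curve(0.5, 1, n_bins = 1L), "n_bins")
})

test_that("net benefit matches hand-counted arithmetic", {
  # perfect predictor: NB(t) = prevalence for every t
  p <- c(0.9, 0.95, 0.99, 0.05, 0.01, 0.1)
  y <- c(1, 1, 1, 0, 0, 0)
  dc <- decision_curve(p, y, thresholds = c(0.2, 0.5, 0.8))
  expect_equal(dc$model_nb, rep(0.5, 3))
  # treat-all at t = 0.5 with prevalence 0.5 -> 0
  expect_equal(dc$treat_all_nb[dc$threshold == 0.5], 0)
  expect_equal(dc$treat_none_nb, rep(0, 3))

  # n = 6 mixed fixture, hand enumeration at t = 0.3:
  # treated = p >= 0.3 -> {0.8, 0.4, 0.3}: TP = 2, FP = 1
  p2 <- c(0.8, 0.4, 0.3, 0.2, 0.1, 0.05)
  y2 <- c(1, 0, 1, 1, 0, 0)
  dc2 <- decision_curve(p2, y2, thresholds = 0.3)
  expect_equal(dc2$model_nb, 2 / 6 - (1 / 6) * (0.3 / 0.7))
  expect_equal(dc2$treat_all_nb, 0.5 - 0.5 * (0.3 / 0.7))
  expect_error(decision_curve(p2, y2, thresholds = 1), "strictly inside")
})

test_that("Fisher p-values equal full hypergeometric enumeration", {
  expect_equal(round(fisher_exact_2x2(26, 56, 11, 77), 3), 0.003)
  expect_equal(fisher_exact_2x2(1, 0, 0, 1), 1.0)
  # row swap symmetry
  expect_equal(fisher_exact_2x2(7, 3, 2, 9), fisher_exact_2x2(2, 9, 7, 3))

  # exhaustive: all tables with total n <= 12 and positive margins
  for (n in 2:12) {
    for (a in 0:n) for (b in 0:(n - a)) for (cc in 0:(n - a - b)) {
      d <- n - a - b - cc
      if ((a + b) == 0 || (cc + d) == 0 || (a + cc) == 0 || (b + d) == 0) next
      expect_equal(fisher_exact_2x2(a, b, cc, d),
                   fisher_enumeration(a, b, cc, d), tolerance = 1e-9)
    }
  }
  # random larger tables up to n = 40
  set.seed(35)
  for (rep in 1:50) {
    cells <- as.vector(stats::rmultinom(1, sample(13:40, 1), rep(0.25, 4)))
    if ((cells[1] + cells[2]) == 0 || (cells[3] + cells[4]) == 0 ||
        (cells[1] + cells[3]) == 0 || (cells[2] + cells[4]) == 0) next
    expect_equal(do.call(fisher_exact_2x2, as.list(cells)),
                 do.call(fisher_enumeration, as.list(cells)),
                 tolerance = 1e-9)
  }
  expect_error(fisher_exact_2x2(0, 0, 3, 4), "margins")
})

test_that("Wilcoxon rank-sum: exact enumeration, ties, and the normal approximation", {
  expect_equal(wilcoxon_rank_sum(c(1, 2), c(3, 4)), 1 / 3)
  expect_equal(wilcoxon_rank_sum(c(1, 2, 3), c(1, 2, 3)), 1.0)
  expect_error(wilcoxon_rank_sum(numeric(0), 1:3), "nonempty")

  # dual-path: exact enumeration vs continuity-corrected normal at n = 10
  set.seed(36)
  for (rep in 1:20) {
    x <- rnorm(5); y <- rnorm(5)
    exact <- wilcoxon_rank_sum(x, y)
    approx <- stats::wilcox.test(x, y, exact = FALSE, correct = TRUE)$p.value
    expect_lt(abs(exact - approx), 0.02)
  }
  # large-sample path agrees with the reference implementation
  set.seed(37)
  x <- rnorm(30); y <- rnorm(25, 0.5)
  expect_equal(wilcoxon_rank_sum(x, y),
               stats::wilcox.test(x, y, exact = FALSE, correct = TRUE)$p.value)
})

test_that("recalibration makes arbitrary-scale scores usable as probabilities", {
  co <- generate_cohort(tiny_config(n_patients = 90L, seed = 47L))
  comp <- compose_counts(co$counts)
  inter <- fit_intermediates(co$patients, comp, seed = 1L)
  x <- build_design(bcr_config("ml_reasoning"), co$patients, comp, inter)
  mod <- fit_bcr(x, co$patients$bcr)
  y <- co$patients$bcr
  # a monotone rescaling of the score leaves AUROC untouched but destroys
  # its probability interpretation; recalibration restores it
  wild <- 10 * mod$fitted$score - 2
  cal <- suppressWarnings(stats::glm(y ~ wild, family = stats::binomial()))
  recal <- stats::fitted(cal)
  expect_equal(auroc(wild, y), auroc(mod$fitted$score, y))
  expect_lt(brier(recal, y), brier(pmin(pmax(wild, 0), 1), y))
  # and the recalibrated model cannot do worse than ignoring the score
  expect_lte(brier(mod$fitted$probability, y),
             brier(rep(mean(y), length(y)), y) + 1e-9)
})

test_that("3-fold protocol partitions patients and guards against leakage", {
  co <- generate_cohort(tiny_config(n_patients = 9L, seed = 48L))
  comp <- compose_counts(co$counts)
  p <- co$patients
  # force both classes for stratification at this tiny n
  p$bcr <- rep(c(0L, 1L, 0L), 3L)
  res <- kfold_protocol(p, comp, configs = all_bcr_configs()["gleason_only"],
                        k = 3L, seed = 1L, n_boot = 50L)
  expect_equal(sort(unique(res$folds)), 1:3)
  expect_equal(as.vector(table(res$folds)), rep(3L, 3L))
  expect_false(any(is.na(res$oof$gleason_only$score)))

  # duplicated patient id across folds must abort
  p2 <- p; p2$patient_id[2] <- p2$patient_id[1]
  expect_error(
    kfold_protocol(p2, comp, configs = all_bcr_configs()["gleason_only"],
                   k = 3L, seed = 1L, n_boot = 10L),
    "leakage")
})

test_that("k-fold results are reproducible under a fixed seed", {
  co <- generate_cohort(tiny_config(n_patients = 45L, seed = 49L))
  comp <- compose_counts(co$counts)
  r1 <- kfold_protocol(co$patients, comp, k = 3L, seed = 6L, n_boot = 50L)
  r2 <- kfold_protocol(co$patients, comp, k = 3L, seed = 6L, n_boot = 50L)
  expect_identical(r1$folds, r2$folds)
  expect_identical(reports_table(r1$reports), reports_table(r2$reports))
})

test_that("external validation reuses one fitted bundle and rejects overlap", {
  co <- generate_cohort(tiny_config(n_patients = 60L, seed = 50L))
  comp <- compose_counts(co$counts)
  train <- list(patients = co$patients, compositions = comp)

  # an external cohort identical to training reproduces resubstitution AUROC
  twin <- co$patients
  twin$patient_id <- paste0("twin-", twin$patient_id)
  ext <- list(twin = list(patients = twin, compositions = comp))
  res <- external_protocol(train, ext, seed = 1L, n_boot = 50L)
  mod <- res$bundles$gleason_only
  resub <- auroc(mod$fitted$score, co$patients$bcr)
  expect_equal(res$reports$twin$gleason_only$auroc, resub)

  expect_error(external_protocol(train, list(bad = list(
    patients = co$patients[0, ], compositions = comp[0, , drop = FALSE]
  )), seed = 1L), "empty external")
  expect_error(external_protocol(train, list(bad = train), seed = 1L),
               "leakage")
})
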