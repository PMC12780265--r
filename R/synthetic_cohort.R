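#' Configuration for a synthetic BCR cohort
#'
#' Defines the generative model for a synthetic cohort of prostate-cancer
#' patients: a Gleason pattern-pair distribution over the nine clinically
#' observed combinations, log-normal PSA, a latent ("hidden") histologic
#' prognostic signal, a logistic outcome model, and a Dirichlet-multinomial
#' model for per-patient patch-cluster counts whose cluster weights carry
#' the hidden signal. An optional domain shift emulates an external
#' institution: it perturbs the marginal composition/stain statistics
#' (Dirichlet concentration multiplier, stain-channel offsets) while the
#' outcome mechanism (the betas) is unchanged.
#'
#' The outcome model is
#' \deqn{P(BCR=1) = logistic(\beta_0 + \beta_g s + \beta_p \log PSA + \beta_h h)}
#' where \eqn{s} is the base reasoning-scale score of the patient's Gleason
#' pattern pair (see [base_score()]) and \eqn{h \sim N(0, hidden\_sd^2)} is
#' the latent signal. Cluster probabilities are
#' \deqn{p \sim Dirichlet(c \cdot softmax(w_0 + z_s \cdot grade\_loadings
#'   + h \cdot impact\_loadings))}
#' where \eqn{z_s} is the standardized base score, so composition encodes
#' the Gleason patterns visible in the tissue *and* a hidden prognostic
#' signal partially independent of them — the structure that makes an
#' intermediate reasoning step informative.
#'
#' @param n_patients number of patients.
#' @param cohort cohort label stamped on every patient.
#' @param gleason_probs probability vector over the nine pattern pairs in
#'   the order of [reasoning_scale()] rows; must sum to 1.
#' @param psa_mu,psa_sigma log-scale location and scale of PSA (ng/mL).
#'   Defaults match a mean ~10.9 and SD ~7.3 ng/mL.
#' @param beta0,beta_grade,beta_psa,beta_hidden coefficients of the
#'   logistic outcome model (intercept, base score, log-PSA, hidden signal).
#' @param hidden_sd standard deviation of the hidden histology signal.
#' @param n_clusters number of patch clusters k (composition length).
#' @param patches_min,patches_max inclusive range of tissue-patch totals
#'   per patient.
#' @param dirichlet_conc Dirichlet concentration (larger = compositions
#'   closer to their expected softmax weights).
#' @param base_weights length-k baseline cluster logits; default is a fixed
#'   smooth spread so cluster prevalences are unequal.
#' @param impact_loadings length-k loadings linking the hidden signal to
#'   cluster logits; default alternates +0.5/-0.5 (period 2).
#' @param grade_loadings length-k loadings linking the standardized base
#'   score to cluster logits; default +/-0.35 with period 4, linearly
#'   independent of the default `impact_loadings` pattern.
#' @param shift domain-shift descriptor from [domain_shift()], or NULL.
#' @param seed integer seed; all draws are derived from it.
#' @return a list of class `cohort_config`.
#' @export
cohort_config <- function(n_patients = 170L,
                          cohort = "internal",
                          gleason_probs = c(0.20, 0.28, 0.18, 0.12, 0.02,
                                            0.10, 0.01, 0.06, 0.03),
                          psa_mu = 2.2, psa_sigma = 0.6,
                          beta0 = -3.7, beta_grade = 0.35,
                          beta_psa = 0.9, beta_hidden = 2.2,
                          hidden_sd = 1,
                          n_clusters = 100L,
                          patches_min = 200L, patches_max = 400L,
                          dirichlet_conc = 200,
                          base_weights = NULL,
                          impact_loadings = NULL,
                          grade_loadings = NULL,
                          shift = NULL,
                          seed = 1L) {
  k <- as.integer(n_clusters)
  if (is.null(base_weights)) base_weights <- 0.5 * sin(seq_len(k) * 0.7)
  if (is.null(impact_loadings)) {
    impact_loadings <- rep(c(0.5, -0.5), length.out = k)
  }
  if (is.null(grade_loadings)) {
    grade_loadings <- rep(c(0.35, 0.35, -0.35, -0.35), length.out = k)
  }
  cfg <- list(
    n_patients = as.integer(n_patients), cohort = as.character(cohort),
    gleason_probs = as.numeric(gleason_probs),
    psa_mu = psa_mu, psa_sigma = psa_sigma,
    beta0 = beta0, beta_grade = beta_grade,
    beta_psa = beta_psa, beta_hidden = beta_hidden,
    hidden_sd = hidden_sd,
    n_clusters = k,
    patches_min = as.integer(patches_min),
    patches_max = as.integer(patches_max),
    dirichlet_conc = dirichlet_conc,
    base_weights = as.numeric(base_weights),
    impact_loadings = as.numeric(impact_loadings),
    grade_loadings = as.numeric(grade_loadings),
    shift = shift,
    seed = as.integer(seed)
  )
  class(cfg) <- "cohort_config"
  validate_cohort_config(cfg)
}

validate_cohort_config <- function(cfg) {
  if (length(cfg$gleason_probs) != 9L) {
    stop_prostir("gleason_probs must have 9 entries (one per pattern pair)")
  }
  check_prob_vector(cfg$gleason_probs, "gleason_probs")
  betas <- c(cfg$beta0, cfg$beta_grade, cfg$beta_psa, cfg$beta_hidden)
  if (any(!is.finite(betas))) stop_prostir("outcome coefficients must be finite")
  if (cfg$psa_sigma <= 0) stop_prostir("psa_sigma must be > 0")
  if (cfg$hidden_sd < 0) stop_prostir("hidden_sd must be >= 0")
  if (cfg$dirichlet_conc <= 0) stop_prostir("dirichlet_conc must be > 0")
  if (cfg$n_patients < 1L || cfg$n_clusters < 1L) {
    stop_prostir("n_patients and n_clusters must be >= 1")
  }
  if (cfg$patches_min < 1L || cfg$patches_max < cfg$patches_min) {
    stop_prostir("need 1 <= patches_min <= patches_max")
  }
  if (length(cfg$base_weights) != cfg$n_clusters ||
      length(cfg$impact_loadings) != cfg$n_clusters ||
      length(cfg$grade_loadings) != cfg$n_clusters) {
    stop_prostir("base_weights, impact_loadings and grade_loadings must have n_clusters entries")
  }
  cfg
}

#' Domain-shift descriptor for an external institution
#'
#' @param conc_multiplier multiplier applied to the Dirichlet concentration
#'   (values < 1 make compositions noisier, as in a site with different
#'   sampling protocols).
#' @param stain_offset length-3 RGB offset applied to slide stain colors.
#' @return a list of class `domain_shift`.
#' @export
domain_shift <- function(conc_multiplier = 0.5,
                         stain_offset = c(0.04, -0.03, 0.02)) {
  stopifnot(conc_multiplier > 0, length(stain_offset) == 3L)
  structure(list(conc_multiplier = conc_multiplier,
                 stain_offset = as.numeric(stain_offset)),
            class = "domain_shift")
}

#' Derive an external-cohort configuration from an internal one
#'
#' Copies the outcome mechanism (all betas, loadings, base weights) and
#' applies a domain shift, a new cohort label, size and seed — emulating an
#' external institution whose data distribution differs but whose biology
#' does not.
#'
#' @param config a [cohort_config()].
#' @param cohort new cohort label.
#' @param n_patients external cohort size.
#' @param shift a [domain_shift()].
#' @param seed seed for the external cohort.
#' @return a new `cohort_config`.
#' @export
shifted_config <- function(config, cohort, n_patients,
                           shift = domain_shift(), seed) {
  stopifnot(inherits(config, "cohort_config"))
  config$cohort <- as.character(cohort)
  config$n_patients <- as.integer(n_patients)
  config$shift <- shift
  config$seed <- as.integer(seed)
  validate_cohort_config(config)
}

#' Generate a synthetic cohort
#'
#' Draws patients (Gleason pattern pair, PSA, hidden signal, binary 5-year
#' BCR) and per-patient patch-cluster count vectors from the generative
#' model in [cohort_config()]. Deterministic given the config seed.
#'
#' @param config a [cohort_config()].
#' @return a list with `patients` (data.frame with columns patient_id,
#'   cohort, gleason_primary, gleason_secondary, gleason_score, psa, bcr,
#'   hidden) and `counts` (n x k integer matrix, columns c000...).
#' @export
generate_cohort <- function(config) {
  cfg <- validate_cohort_config(config)
  k <- cfg$n_clusters
  n <- cfg$n_patients
  scale_tab <- reasoning_scale()
  conc <- cfg$dirichlet_conc
  if (!is.null(cfg$shift)) conc <- conc * cfg$shift$conc_multiplier

  with_seed(derive_seed(cfg$seed, 1L), {
    pair_idx <- sample.int(9L, n, replace = TRUE, prob = cfg$gleason_probs)
    psa <- stats::rlnorm(n, cfg$psa_mu, cfg$psa_sigma)
    hidden <- stats::rnorm(n, 0, cfg$hidden_sd)
    base <- scale_tab$base[pair_idx]
    lp <- cfg$beta0 + cfg$beta_grade * base +
      cfg$beta_psa * log(psa) + cfg$beta_hidden * hidden
    bcr <- stats::rbinom(n, 1L, stats::plogis(lp))
    n_patch <- if (cfg$patches_max > cfg$patches_min) {
      cfg$patches_min +
        sample.int(cfg$patches_max - cfg$patches_min + 1L, n, replace = TRUE) - 1L
    } else {
      rep(cfg$patches_min, n)
    }
    counts <- matrix(0L, n, k)
    grade_z <- (base - 4.3) / 2.5  # standardize by fixed population constants
    for (i in seq_len(n)) {
      w <- softmax(cfg$base_weights + grade_z[i] * cfg$grade_loadings +
                     hidden[i] * cfg$impact_loadings)
      g <- stats::rgamma(k, shape = conc * w, rate = 1)
      g <- pmax(g, .Machine$double.xmin)  # Dirichlet draws strictly positive
      p <- g / sum(g)
      counts[i, ] <- as.integer(stats::rmultinom(1L, n_patch[i], p))
    }
    colnames(counts) <- sprintf("c%03d", seq_len(k) - 1L)
    patients <- data.frame(
      patient_id = sprintf("%s-%04d", cfg$cohort, seq_len(n)),
      cohort = cfg$cohort,
      gleason_primary = scale_tab$primary[pair_idx],
      gleason_secondary = scale_tab$secondary[pair_idx],
      gleason_score = scale_tab$gleason_score[pair_idx],
      psa = psa,
      bcr = bcr,
      hidden = hidden,
      stringsAsFactors = FALSE
    )
    rownames(counts) <- patients$patient_id
    list(patients = patients, counts = counts, config = cfg)
  })
}

#' Write a synthetic cohort to CSV files
#'
#' Emits `<prefix>_patients.csv` (header patient_id,cohort,gleason_primary,
#' gleason_secondary,gleason_score,psa,bcr) and `<prefix>_counts.csv`
#' (patients x clusters matrix, columns c000...).
#'
#' @param cohort result of [generate_cohort()].
#' @param dir output directory.
#' @param prefix file name prefix.
#' @return invisibly, the two file paths written.
#' @export
write_cohort <- function(cohort, dir, prefix = "cohort") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  pat <- cohort$patients
  pat$hidden <- NULL  # latent signal is generator-internal, not observable
  f1 <- file.path(dir, paste0(prefix, "_patients.csv"))
  f2 <- file.path(dir, paste0(prefix, "_counts.csv"))
  utils::write.csv(pat, f1, row.names = FALSE)
  cnt <- data.frame(patient_id = rownames(cohort$counts),
                    cohort$counts, check.names = FALSE)
  utils::write.csv(cnt, f2, row.names = FALSE)
  invisible(c(patients = f1, counts = f2))
}
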