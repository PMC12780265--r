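#' Fit the feature bank from a cohort's synthetic slides
#'
#' Image-mode counterpart of the tabular count matrices: renders one slide
#' per patient, tiles it with the non-overlapping training convention,
#' removes background patches, fits the embedding backend (supervised with
#' patch-level BCR labels when requested), fits the k-means codebook on
#' the tissue-patch embeddings, and attaches per-cluster impact scores.
#'
#' @param cohort result of [generate_cohort()].
#' @param texture_params a [default_texture_params()]; its `patch_px`
#'   defines the tiling patch size.
#' @param k_codebook number of codebook clusters (defaults to the
#'   generator's cluster count).
#' @param supervised fit the linear-discriminant coordinate on patch-level
#'   BCR labels (default TRUE).
#' @param max_patients cap on the number of slides used for fitting (the
#'   codebook does not need every slide).
#' @param seed integer seed.
#' @return list with `backend`, `codebook` (impact attached), and
#'   `patches_used`.
#' @export
fit_feature_bank <- function(cohort, texture_params,
                             k_codebook = NULL, supervised = TRUE,
                             max_patients = 25L, seed = 1L) {
  if (is.null(k_codebook)) k_codebook <- cohort$config$n_clusters
  pats <- cohort$patients
  use <- seq_len(min(nrow(pats), max_patients))
  ps <- texture_params$patch_px

  patches <- list(); plabels <- integer(0); ppatient <- integer(0)
  for (i in use) {
    sl <- generate_slide(pats[i, ], cohort$counts[i, ], texture_params,
                         seed = derive_seed(seed, 1000L + i))
    tiled <- flag_tissue(tile(sl$image, ps, ps, slide_id = sl$slide_id))
    keep <- which(tiled$patches$tissue)
    for (j in keep) {
      patches[[length(patches) + 1L]] <- get_patch(tiled, j)
      plabels <- c(plabels, pats$bcr[i])
      ppatient <- c(ppatient, i)
    }
  }
  if (length(patches) < k_codebook) {
    stop_prostir("only %d tissue patches collected; need >= k = %d",
                 length(patches), k_codebook)
  }
  backend <- fit_default_backend(patches,
                                 labels = if (supervised) plabels else NULL)
  emb <- embed_patches(backend, patches)
  cb <- fit_codebook(emb, k = k_codebook, seed = derive_seed(seed, 40L),
                     backend_name = backend$name)
  assign <- assign_clusters(cb, emb)
  by_pat <- split(assign, ppatient)
  cb$impact <- impact_scores(by_pat, pats$bcr[as.integer(names(by_pat))],
                             k = cb$k)
  list(backend = backend, codebook = cb, patches_used = length(patches))
}

#' Composition vectors from slides via the feature bank
#'
#' Renders each patient's slide, tiles it with the (overlapping, when
#' `stride < patch`) inference convention, flags background, embeds and
#' assigns tissue patches, and tallies cluster fractions.
#'
#' @param cohort result of [generate_cohort()].
#' @param texture_params a [default_texture_params()].
#' @param backend,codebook from [fit_feature_bank()].
#' @param stride inference tiling stride (default the patch size).
#' @param seed integer seed (slide rendering).
#' @return n x k matrix of composition fractions, rows = patients.
#' @export
slide_compositions <- function(cohort, texture_params, backend, codebook,
                               stride = NULL, seed = 1L) {
  pats <- cohort$patients
  ps <- texture_params$patch_px
  if (is.null(stride)) stride <- ps
  comp <- matrix(NA_real_, nrow(pats), codebook$k,
                 dimnames = list(pats$patient_id,
                                 sprintf("c%03d", seq_len(codebook$k) - 1L)))
  for (i in seq_len(nrow(pats))) {
    sl <- generate_slide(pats[i, ], cohort$counts[i, ], texture_params,
                         seed = derive_seed(seed, 1000L + i))
    tiled <- flag_tissue(tile(sl$image, ps, stride, slide_id = sl$slide_id))
    keep <- which(tiled$patches$tissue)
    if (length(keep) == 0L) {
      stop_prostir("slide %s has no tissue patches", sl$slide_id)
    }
    emb <- embed_patches(backend, lapply(keep, function(j) get_patch(tiled, j)))
    assign <- assign_clusters(codebook, emb)
    comp[i, ] <- compose(assign, k = codebook$k,
                         sample_id = sl$slide_id)$fractions
  }
  comp
}

#' Run the full synthetic study
#'
#' End-to-end experiment on the synthetic generator: one internal cohort
#' and domain-shifted external cohorts, the intermediate reasoning step,
#' the five BCR model configurations, stratified 3-fold internal
#' cross-validation and external validation with the complete metric
#' suite. In `"tabular"` mode compositions come directly from the
#' generator's count matrices; in `"image"` mode they are recovered from
#' rendered slides through the tiling / embedding / codebook stages.
#'
#' @param seed single integer run seed; every stage derives its own seed
#'   from it.
#' @param n_internal internal-cohort size.
#' @param n_external named vector of external cohort sizes.
#' @param k_clusters generator (and codebook) cluster count.
#' @param mode `"tabular"` or `"image"`.
#' @param configs named list of [bcr_config()]s (default all five).
#' @param k_folds internal CV folds.
#' @param n_boot bootstrap iterations per report.
#' @param shift [domain_shift()] applied to external cohorts.
#' @param internal_config optional pre-built [cohort_config()] for the
#'   internal cohort (its seed/cohort/size are kept).
#' @param patch_px patch edge (image mode).
#' @param stride inference stride (image mode; default = patch, i.e.
#'   non-overlapping; set smaller for overlap).
#' @param max_bank_patients slides used to fit the feature bank (image
#'   mode).
#' @param ... passed to the generator's [cohort_config()].
#' @return list with `internal` ([kfold_protocol()] result), `external`
#'   ([external_protocol()] result), `table` (flat results table), and
#'   `cohorts`.
#' @export
run_study <- function(seed = 1L, n_internal = 170L,
                      n_external = c(external_A = 71L, external_B = 39L),
                      k_clusters = 100L, mode = c("tabular", "image"),
                      configs = all_bcr_configs(), k_folds = 3L,
                      n_boot = 2000L, shift = domain_shift(),
                      internal_config = NULL,
                      patch_px = 16L, stride = NULL,
                      max_bank_patients = 25L, ...) {
  mode <- match.arg(mode)
  if (is.null(internal_config)) {
    internal_config <- cohort_config(n_patients = n_internal,
                                     cohort = "internal",
                                     n_clusters = k_clusters,
                                     seed = derive_seed(seed, 30L), ...)
  }
  cohorts <- list(internal = generate_cohort(internal_config))
  for (j in seq_along(n_external)) {
    nm <- names(n_external)[j]
    cfg <- shifted_config(internal_config, cohort = nm,
                          n_patients = n_external[[j]], shift = shift,
                          seed = derive_seed(seed, 30L + j))
    cohorts[[nm]] <- generate_cohort(cfg)
  }

  if (mode == "tabular") {
    comps <- lapply(cohorts, function(co) compose_counts(co$counts))
  } else {
    tp_int <- default_texture_params(k_clusters, patch_px)
    bank <- fit_feature_bank(cohorts$internal, tp_int,
                             max_patients = max_bank_patients,
                             seed = derive_seed(seed, 50L))
    comps <- list()
    for (nm in names(cohorts)) {
      off <- cohorts[[nm]]$config$shift
      tp <- default_texture_params(
        k_clusters, patch_px,
        stain_offset = if (is.null(off)) c(0, 0, 0) else off$stain_offset
      )
      comps[[nm]] <- slide_compositions(cohorts[[nm]], tp, bank$backend,
                                        bank$codebook, stride = stride,
                                        seed = derive_seed(seed, 60L))
    }
  }

  internal <- kfold_protocol(cohorts$internal$patients, comps$internal,
                             configs = configs, k = k_folds,
                             seed = derive_seed(seed, 70L), n_boot = n_boot)
  externals <- lapply(names(n_external), function(nm) {
    list(patients = cohorts[[nm]]$patients, compositions = comps[[nm]])
  })
  names(externals) <- names(n_external)
  external <- external_protocol(
    list(patients = cohorts$internal$patients,
         compositions = comps$internal),
    externals, configs = configs, seed = derive_seed(seed, 71L),
    n_boot = n_boot
  )
  tab <- rbind(reports_table(internal$reports),
               do.call(rbind, lapply(external$reports, reports_table)))
  rownames(tab) <- NULL
  list(internal = internal, external = external, table = tab,
       cohorts = cohorts, compositions = comps, seed = seed)
}
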