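#' Fit a visual codebook by k-means
#'
#' Clusters patch embeddings into `k` key features with Lloyd k-means
#' (via [stats::kmeans()]) seeded by k-means++ initialization; the best of
#' `n_restarts` runs by within-cluster sum of squares is kept.
#' Deterministic given `seed`.
#'
#' By default embedding columns are standardized (z-scored) before
#' clustering and the standardization is stored with the codebook, so
#' heterogeneous feature scales — e.g. a supervised discriminant
#' coordinate next to raw color moments — do not dominate the Euclidean
#' metric. Assignment applies the same transform.
#'
#' @param embeddings n x dim matrix of patch embeddings, `n >= k`.
#' @param standardize z-score columns before clustering (default TRUE).
#' @param k cluster count (the "key features"; default 100, `k >= 2`).
#' @param seed integer seed.
#' @param n_restarts number of restarts.
#' @param backend_name label of the embedding backend that produced the
#'   embeddings (stored for provenance).
#' @return a `codebook`: list with `k`, `centroids` (k x dim), `impact`
#'   (k-vector, NA until [impact_scores()] is attached), `wcss`,
#'   `backend_name`, `fit_seed`.
#' @export
fit_codebook <- function(embeddings, k = 100L, seed = 1L, n_restarts = 5L,
                         backend_name = "descriptor", standardize = TRUE) {
  embeddings <- as.matrix(embeddings)
  k <- as.integer(k)
  if (k < 2L) stop_prostir("k must be >= 2")
  if (nrow(embeddings) < k) {
    stop_prostir("need at least k = %d embeddings, got %d", k, nrow(embeddings))
  }
  if (any(!is.finite(embeddings))) stop_prostir("embeddings must be finite")

  center <- NULL; scale <- NULL
  if (standardize) {
    center <- colMeans(embeddings)
    scale <- apply(embeddings, 2, stats::sd)
    scale[scale < 1e-8] <- 1  # constant columns carry no information
    embeddings <- scale(embeddings, center = center, scale = scale)
  }

  best <- NULL
  with_seed(derive_seed(seed, 3L), {
    for (r in seq_len(n_restarts)) {
      init <- kmeanspp_init(embeddings, k)
      km <- suppressWarnings(
        stats::kmeans(embeddings, centers = init, iter.max = 100L,
                      algorithm = "Lloyd")
      )
      if (is.null(best) || km$tot.withinss < best$tot.withinss) best <- km
    }
  })
  cb <- list(k = k, centroids = unname(best$centers),
             impact = rep(NA_real_, k), wcss = best$tot.withinss,
             center = center, scale = scale,
             backend_name = backend_name, fit_seed = as.integer(seed))
  class(cb) <- "codebook"
  cb
}

# map embeddings into the codebook's (possibly standardized) metric space
codebook_space <- function(codebook, embeddings) {
  embeddings <- as.matrix(embeddings)
  if (ncol(embeddings) != ncol(codebook$centroids)) {
    stop_prostir("embedding dim %d does not match codebook dim %d",
                 ncol(embeddings), ncol(codebook$centroids))
  }
  if (!is.null(codebook$center)) {
    embeddings <- scale(embeddings, center = codebook$center,
                        scale = codebook$scale)
  }
  embeddings
}

# k-means++ seeding: first center uniform, then proportional to squared
# distance to the nearest chosen center (base kmeans has no ++ option)
kmeanspp_init <- function(x, k) {
  n <- nrow(x)
  centers <- matrix(NA_real_, k, ncol(x))
  idx <- sample.int(n, 1L)
  centers[1L, ] <- x[idx, ]
  d2 <- rowSums(sweep(x, 2, centers[1L, ])^2)
  for (j in seq_len(k - 1L) + 1L) {
    if (sum(d2) <= 0) {
      idx <- sample.int(n, 1L)       # all points coincide with a center
    } else {
      idx <- sample.int(n, 1L, prob = d2)
    }
    centers[j, ] <- x[idx, ]
    d2 <- pmin(d2, rowSums(sweep(x, 2, centers[j, ])^2))
  }
  # kmeans() requires distinct centers; jitter exact duplicates minimally
  dup <- duplicated(centers)
  if (any(dup)) {
    centers[dup, ] <- centers[dup, , drop = FALSE] +
      matrix(stats::rnorm(sum(dup) * ncol(x), 0, 1e-9), sum(dup))
  }
  centers
}

#' Assign embeddings to codebook clusters
#'
#' Nearest centroid by Euclidean distance; ties broken by the lowest
#' cluster index.
#'
#' @param codebook a `codebook`.
#' @param embeddings n x dim matrix, dim matching the codebook.
#' @return integer vector of 1-based cluster indices.
#' @export
assign_clusters <- function(codebook, embeddings) {
  stopifnot(inherits(codebook, "codebook"))
  embeddings <- codebook_space(codebook, embeddings)
  # squared distances n x k: |x|^2 - 2 x.c + |c|^2
  cc <- rowSums(codebook$centroids^2)
  d2 <- outer(rowSums(embeddings^2), cc, "+") -
    2 * embeddings %*% t(codebook$centroids)
  # max.col(-d2, "first") would be float-order dependent on exact ties;
  # apply which.min keeps the lowest-index tie rule explicitly
  apply(d2, 1L, which.min)
}

#' Build a composition vector from cluster assignments
#'
#' Tallies tissue-patch assignments per cluster and divides by the number
#' of tissue patches (background patches are excluded from both numerator
#' and denominator). Fractions are nonnegative and sum to 1.
#'
#' @param assignments integer cluster indices (1-based), one per patch.
#' @param tissue_mask logical vector, same length; NULL means all tissue.
#' @param k number of clusters.
#' @param sample_id identifier carried on the result.
#' @return a `composition`: list with `sample_id`, `fractions` (length k),
#'   `n_tissue_patches`.
#' @export
compose <- function(assignments, tissue_mask = NULL, k,
                    sample_id = "sample") {
  if (is.null(tissue_mask)) tissue_mask <- rep(TRUE, length(assignments))
  stopifnot(length(tissue_mask) == length(assignments))
  a <- assignments[tissue_mask]
  if (length(a) == 0L) {
    stop_prostir("sample '%s' has zero tissue patches", sample_id)
  }
  if (any(a < 1L | a > k)) stop_prostir("cluster index outside 1..k")
  tal <- tabulate(a, nbins = k)
  structure(list(sample_id = sample_id, fractions = tal / length(a),
                 n_tissue_patches = length(a)),
            class = "composition")
}

#' Normalize a patient x cluster count matrix to compositions
#'
#' Tabular-mode counterpart of [compose()] for cohorts supplied as count
#' matrices (e.g. from [generate_cohort()]).
#'
#' @param counts n x k nonnegative matrix; each row must have a positive sum.
#' @return n x k matrix of row fractions (rows sum to 1).
#' @export
compose_counts <- function(counts) {
  counts <- as.matrix(counts)
  tot <- rowSums(counts)
  if (any(tot <= 0)) stop_prostir("every patient needs at least one patch")
  sweep(counts, 1, tot, "/")
}

#' Per-cluster impact scores
#'
#' The impact score of cluster c is the smoothed fraction of its patches
#' that originate from BCR-positive patients:
#' \deqn{impact_c = (n_c^+ + s) / (n_c^+ + n_c^- + 2 s)}
#' with smoothing s. Scores live in \[0,1\]; 0.5 is neutral (a cluster
#' equally represented in both outcome groups); with s > 0 scores are
#' strictly inside (0,1).
#'
#' @param assignments_by_patient list of integer assignment vectors, one
#'   per patient.
#' @param bcr_labels 0/1 outcome per patient; both classes required.
#' @param k number of clusters.
#' @param smoothing additive smoothing count (default 1).
#' @return numeric k-vector of impact scores.
#' @export
impact_scores <- function(assignments_by_patient, bcr_labels, k,
                          smoothing = 1) {
  if (length(assignments_by_patient) != length(bcr_labels)) {
    stop_prostir("one assignment vector per patient is required")
  }
  bcr_labels <- check_binary(bcr_labels, "bcr_labels")
  pos <- integer(k); neg <- integer(k)
  for (i in seq_along(assignments_by_patient)) {
    a <- assignments_by_patient[[i]]
    if (any(a < 1L | a > k)) stop_prostir("cluster index outside 1..k")
    tal <- tabulate(a, nbins = k)
    if (bcr_labels[i] == 1L) pos <- pos + tal else neg <- neg + tal
  }
  (pos + smoothing) / (pos + neg + 2 * smoothing)
}

#' Display size of a key feature
#'
#' Rendering size used when ranking representative feature images:
#' `|0.5 - impact| + 2.5`, so a neutral feature draws at 2.5 units and the
#' most outcome-associated features at 3.0.
#'
#' @param impact impact score(s) in \[0,1\].
#' @return numeric size(s).
#' @export
display_size <- function(impact) {
  if (any(!is.finite(impact)) || any(impact < 0 | impact > 1)) {
    stop_prostir("impact scores must lie in [0, 1]")
  }
  abs(0.5 - impact) + 2.5
}

#' Representative patches per cluster
#'
#' For each cluster, the `n` assigned patches closest to the centroid
#' (Euclidean distance, ascending; ties broken by patch order). Clusters
#' with fewer than `n` patches are returned short and flagged; empty
#' clusters are reported, not fatal.
#'
#' @param codebook a `codebook`.
#' @param embeddings n x dim matrix.
#' @param patch_refs vector identifying each embedding's source patch
#'   (indices, ids, ...); defaults to row numbers.
#' @param n patches per cluster (default 3).
#' @return data.frame cluster, rank, patch_ref, distance, short, empty.
#' @export
representative_patches <- function(codebook, embeddings,
                                   patch_refs = NULL, n = 3L) {
  stopifnot(inherits(codebook, "codebook"))
  if (is.null(patch_refs)) patch_refs <- seq_len(nrow(as.matrix(embeddings)))
  assign <- assign_clusters(codebook, embeddings)
  embeddings <- codebook_space(codebook, embeddings)
  out <- vector("list", codebook$k)
  for (c in seq_len(codebook$k)) {
    idx <- which(assign == c)
    if (length(idx) == 0L) {
      out[[c]] <- data.frame(cluster = c, rank = NA_integer_,
                             patch_ref = NA, distance = NA_real_,
                             short = NA, empty = TRUE)
      next
    }
    d <- sqrt(rowSums(sweep(embeddings[idx, , drop = FALSE], 2,
                            codebook$centroids[c, ])^2))
    ord <- order(d, seq_along(d))   # stable: ties by patch order
    take <- ord[seq_len(min(n, length(ord)))]
    out[[c]] <- data.frame(cluster = c, rank = seq_along(take),
                           patch_ref = patch_refs[idx[take]],
                           distance = d[take],
                           short = length(idx) < n, empty = FALSE)
  }
  do.call(rbind, out)
}

#' Per-patch impact feature map
#'
#' Projects impact scores back onto the tiling lattice: tissue cells carry
#' the impact of their assigned cluster plus a high/low flag (impact above
#' 0.5 vs at or below); background cells are NA. This is the numeric form
#' of a slide overlay where high-impact regions shade one way and
#' low-impact regions the other, bar height encoding the score.
#'
#' @param patchset a `patch_set` with tissue flags set.
#' @param assignments integer cluster indices aligned with
#'   `patchset$patches` rows; entries for background patches may be NA.
#' @param codebook a `codebook` with impact scores attached.
#' @return list with matrices `impact` (numeric, NA on background) and
#'   `high` (logical, impact > 0.5), dimensions ny x nx on the lattice.
#' @export
feature_map <- function(patchset, assignments, codebook) {
  stopifnot(inherits(patchset, "patch_set"), inherits(codebook, "codebook"))
  if (length(assignments) != nrow(patchset$patches)) {
    stop_prostir("assignments do not match the tiling lattice (%d vs %d)",
                 length(assignments), nrow(patchset$patches))
  }
  if (any(is.na(codebook$impact))) {
    stop_prostir("codebook has no impact scores attached")
  }
  pp <- patchset$patches
  tissue <- !is.na(pp$tissue) & pp$tissue
  if (any(tissue & is.na(assignments))) {
    stop_prostir("tissue patches must all carry an assignment")
  }
  nx <- length(unique(pp$x0))
  ny <- length(unique(pp$y0))
  imp <- matrix(NA_real_, ny, nx)
  ix <- pp$x0 / patchset$stride + 1L
  iy <- pp$y0 / patchset$stride + 1L
  sel <- which(tissue)
  imp[cbind(iy[sel], ix[sel])] <- codebook$impact[assignments[sel]]
  list(impact = imp, high = imp > 0.5)
}
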