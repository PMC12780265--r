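test_that("embeddings are deterministic and constant patches have no gradients", {
  p1 <- solid_patch(16, c(0.3, 0.6, 0.2))
  p2 <- solid_patch(16, c(0.3, 0.6, 0.2))
  backend <- fit_default_backend(list(p1))
  e <- embed_patches(backend, list(p1, p2))
  expect_identical(e[1, ], e[2, ])
  expect_equal(backend$dim, 20L)
  # layout: 6 color moments, 8 gradient bins, 6 spectrum bins
  expect_equal(e[1, 7:14], rep(0, 8))
  expect_equal(e[1, 1:3], c(0.3, 0.6, 0.2))
})

test_that("the supervised discriminant coordinate separates two textures", {
  pa <- texture_patches(200, cluster = 0L, k = 2L, seed = 31L)
  pb <- texture_patches(200, cluster = 1L, k = 2L, seed = 32L)
  patches <- c(pa, pb)
  labels <- rep(c(0L, 1L), c(length(pa), length(pb)))
  backend <- fit_default_backend(patches, labels)
  expect_true(backend$supervised)
  expect_equal(backend$dim, 21L)
  emb <- embed_patches(backend, patches)
  ld <- emb[, 21]
  expect_gte(max(auroc(ld, labels), auroc(-ld, labels)), 0.95)

  expect_error(fit_default_backend(patches, rep(1L, length(patches))),
               "both outcome classes")
})

test_that("k-means codebook matches the exhaustive optimal 2-partition", {
  set.seed(13)
  x <- rbind(matrix(rnorm(12, 0, 0.3), ncol = 2),
             matrix(rnorm(10, 5, 0.3), ncol = 2))
  cb <- fit_codebook(x, k = 2L, seed = 3L, n_restarts = 3L)
  fit <- assign_clusters(cb, x)
  oracle <- best_two_partition(x)
  agree <- mean((fit - 1L) == oracle$grp)
  expect_true(agree %in% c(0, 1))  # identical up to label swap
  wcss_fit <- sum(vapply(1:2, function(g) {
    xg <- x[fit == g, , drop = FALSE]
    sum(sweep(xg, 2, colMeans(xg))^2)
  }, numeric(1)))
  expect_equal(wcss_fit, oracle$wcss, tolerance = 1e-10)
})

test_that("codebook degenerate cases behave per contract", {
  x <- matrix(rnorm(20), ncol = 2)
  expect_error(fit_codebook(x, k = 1L), "k must be >= 2")
  expect_error(fit_codebook(x[1:3, ], k = 5L), "at least k")
  cb <- fit_codebook(x, k = nrow(x), seed = 1L)
  expect_equal(cb$wcss, 0, tolerance = 1e-12)
  # determinism
  cb2 <- fit_codebook(x, k = 4L, seed = 9L)
  cb3 <- fit_codebook(x, k = 4L, seed = 9L)
  expect_identical(cb2$centroids, cb3$centroids)
})

test_that("assignment is nearest-centroid with lowest-index tie-break", {
  cb <- structure(list(k = 8L, centroids = diag(8), impact = rep(NA_real_, 8),
                       backend_name = "x", fit_seed = 1L),
                  class = "codebook")
  expect_equal(assign_clusters(cb, diag(8)[7, , drop = FALSE]), 7L)
  # equidistant to centroids 3 and 6 (1-based): midpoint
  mid <- (diag(8)[3, ] + diag(8)[6, ]) / 2
  expect_equal(assign_clusters(cb, matrix(mid, 1)), 3L)
  expect_error(assign_clusters(cb, matrix(0, 1, 5)), "dim")

  set.seed(77)
  emb <- matrix(rnorm(40 * 8), ncol = 8)
  fit <- assign_clusters(cb, emb)
  oracle <- apply(emb, 1, function(v) {
    which.min(colSums((t(cb$centroids) - v)^2))
  })
  expect_equal(fit, unname(oracle))
})

test_that("composition vectors normalize tissue tallies and respect background", {
  a <- compose(c(1L, 1L, 2L, 3L), k = 3L)
  expect_equal(a$fractions, c(0.5, 0.25, 0.25))
  expect_equal(sum(a$fractions), 1)

  onehot <- compose(rep(2L, 5L), k = 4L)
  expect_equal(onehot$fractions, c(0, 1, 0, 0))

  # 10 patches, only 4 tissue, all in cluster 1
  assign <- c(rep(1L, 4L), rep(3L, 6L))
  mask <- c(rep(TRUE, 4L), rep(FALSE, 6L))
  cc <- compose(assign, mask, k = 3L)
  expect_equal(cc$fractions, c(1, 0, 0))
  expect_equal(cc$n_tissue_patches, 4L)

  expect_error(compose(1:3, rep(FALSE, 3), k = 3L), "zero tissue")
})

test_that("composition is equivariant under cluster relabeling", {
  set.seed(5)
  assign <- sample.int(6L, 50L, replace = TRUE)
  perm <- sample(6L)
  f1 <- compose(assign, k = 6L)$fractions
  f2 <- compose(perm[assign], k = 6L)$fractions
  expect_equal(f2[perm], f1)
})

test_that("impact scores follow the smoothed positive-patient fraction", {
  # cluster 1 only from the BCR-positive patient, smoothing 0 -> 1.0
  by_pat <- list(c(1L, 1L, 2L), c(2L, 3L))
  imp0 <- impact_scores(by_pat, c(1, 0), k = 3L, smoothing = 0)
  expect_equal(imp0[1], 1.0)
  # cluster 2: one patch from each class -> 0.5
  expect_equal(imp0[2], 0.5)
  # n+ = 3, n- = 1, smoothing 1 -> 4/6
  by_pat2 <- list(rep(1L, 3L), rep(1L, 1L))
  expect_equal(impact_scores(by_pat2, c(1, 0), k = 1L, smoothing = 1),
               4 / 6)
  # smoothing keeps scores strictly inside (0, 1), including empty clusters
  imp <- impact_scores(by_pat, c(1, 0), k = 5L, smoothing = 1)
  expect_true(all(imp > 0 & imp < 1))
  expect_error(impact_scores(by_pat, c(1, 1), k = 3L), "both outcome classes")
})

test_that("display size follows |0.5 - impact| + 2.5", {
  expect_equal(display_size(0.5), 2.5)
  expect_equal(display_size(1.0), 3.0)
  expect_equal(display_size(0.0), 3.0)
  expect_equal(display_size(c(0.25, 0.75)), c(2.75, 2.75))
  expect_error(display_size(1.2), "\\[0, 1\\]")
})

test_that("representative patches are the centroid-nearest, stably ordered", {
  set.seed(8)
  x <- rbind(matrix(rnorm(20, 0, 0.5), ncol = 2),
             matrix(rnorm(4, 10, 0.5), ncol = 2))
  cb <- fit_codebook(x, k = 2L, seed = 2L, standardize = FALSE)
  reps <- representative_patches(cb, x, n = 3L)
  for (cl in 1:2) {
    sub <- reps[reps$cluster == cl & !reps$empty, ]
    assign <- assign_clusters(cb, x)
    idx <- which(assign == cl)
    d <- sqrt(colSums((t(x[idx, , drop = FALSE]) - cb$centroids[cl, ])^2))
    oracle <- idx[order(d, seq_along(d))][seq_len(min(3, length(idx)))]
    expect_equal(sub$patch_ref, oracle)
    expect_equal(sub$distance, sort(d)[seq_len(nrow(sub))])
  }
  # patch exactly at a centroid ranks first
  x2 <- rbind(cb$centroids[1, ], x)
  reps2 <- representative_patches(cb, x2, n = 3L)
  expect_equal(reps2$patch_ref[reps2$cluster == 1][1], 1L)
  # short cluster: 2 patches, n = 3 -> both returned, flagged
  x3 <- rbind(matrix(rnorm(16, 0, 0.3), ncol = 2),
              matrix(c(9, 9, 9.1, 9.1), ncol = 2, byrow = TRUE))
  cb3 <- fit_codebook(x3, k = 2L, seed = 4L, standardize = FALSE)
  reps3 <- representative_patches(cb3, x3, n = 3L)
  small <- reps3[reps3$cluster == assign_clusters(cb3, matrix(c(9, 9), 1)), ]
  expect_equal(nrow(small), 2L)
  expect_true(all(small$short))
})

test_that("feature maps project impact back onto the lattice", {
  img <- array(0.4, c(8, 8, 3))  # stained everywhere (sat 0 though!)
  img[, , 1] <- 0.6; img[, , 2] <- 0.2  # give it saturation
  ps <- flag_tissue(tile(img, 4, 4))
  cb <- structure(list(k = 2L, centroids = diag(2),
                       impact = c(0.9, 0.1), backend_name = "x",
                       fit_seed = 1L), class = "codebook")
  fm <- feature_map(ps, rep(1L, 4L), cb)
  expect_equal(dim(fm$impact), c(2L, 2L))
  expect_true(all(fm$impact == 0.9))
  expect_true(all(fm$high))

  # background-only slide -> all-null grid
  white <- array(1, c(8, 8, 3))
  psw <- flag_tissue(tile(white, 4, 4))
  fmw <- feature_map(psw, rep(NA_integer_, 4L), cb)
  expect_true(all(is.na(fmw$impact)))

  # mixed fixture: per-cell values equal assignment -> impact lookup
  assign <- c(1L, 2L, 2L, 1L)
  fmm <- feature_map(ps, assign, cb)
  expect_equal(as.vector(t(fmm$impact)), cb$impact[assign])

  expect_error(feature_map(ps, 1L, cb), "lattice")
  cb$impact <- rep(NA_real_, 2)
  expect_error(feature_map(ps, assign, cb), "impact")
})
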