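# Shared fixtures: everything is generated in code at test time.

# small-k generator config for fast end-to-end tests
tiny_config <- function(n_patients = 40L, k = 10L, seed = 11L, ...) {
  cohort_config(n_patients = n_patients, n_clusters = k,
                patches_min = 60L, patches_max = 80L, seed = seed, ...)
}

# a flat-color RGB patch
solid_patch <- function(px, rgb) {
  arr <- array(0, c(px, px, 3))
  for (ch in 1:3) arr[, , ch] <- rgb[ch]
  arr
}

# textured patches of a given cluster, rendered through the generator
texture_patches <- function(n, cluster, k = 2L, px = 16L, seed = 1L,
                            noise_sd = 0.015) {
  tp <- default_texture_params(k, px, noise_sd = noise_sd)
  counts <- integer(k)
  counts[cluster + 1L] <- n
  sl <- generate_slide(NULL, counts, tp, seed = seed)
  ps <- tile(sl$image, px, px)
  lapply(seq_len(nrow(ps$patches)), function(i) get_patch(ps, i))
}

# independent AUROC oracle: brute-force concordant-pair counting
auroc_bruteforce <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  mean(outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b)))
}

# independent Fisher oracle: full hypergeometric enumeration,
# minimum-likelihood two-sided rule
fisher_enumeration <- function(a, b, c, d) {
  r1 <- a + b; c1 <- a + c; n <- a + b + c + d
  support <- max(0, r1 + c1 - n):min(r1, c1)
  pr <- stats::dhyper(support, c1, n - c1, r1)
  obs <- stats::dhyper(a, c1, n - c1, r1)
  sum(pr[pr <= obs * (1 + 1e-7)])
}

# independent ridge oracle: closed form with unpenalized intercept,
# optional row weights
ridge_closed_form <- function(x, y, lambda, w = NULL) {
  x <- as.matrix(x)
  if (is.null(w)) w <- rep(1, nrow(x))
  xa <- cbind(1, x)
  pen <- diag(c(0, rep(lambda, ncol(x))))
  co <- solve(t(xa) %*% (w * xa) + pen, t(xa) %*% (w * y))
  list(intercept = co[1], weights = as.numeric(co[-1]))
}

# exhaustive optimal 2-partition by within-cluster sum of squares
best_two_partition <- function(x) {
  n <- nrow(x)
  best <- NULL
  for (code in 1:(2^(n - 1) - 1)) {
    grp <- as.integer(intToBits(code))[1:n]
    if (all(grp == grp[1])) next
    wcss <- 0
    for (g in 0:1) {
      xg <- x[grp == g, , drop = FALSE]
      wcss <- wcss + sum(sweep(xg, 2, colMeans(xg))^2)
    }
    if (is.null(best) || wcss < best$wcss) best <- list(grp = grp, wcss = wcss)
  }
  best
}
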