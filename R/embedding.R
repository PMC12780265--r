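#' Patch descriptor: color moments + gradients + spectrum
#'
#' Handcrafted 20-dimensional descriptor used by the default embedding
#' backend: per-channel mean and standard deviation (6), a magnitude-
#' weighted 8-bin gradient-orientation histogram on the luminance channel
#' (8), and 6 log-power radial spectrum bins (DC excluded). Deterministic;
#' a constant-color patch has an all-zero gradient block.
#'
#' @param patch p x p x 3 array in \[0,1\] (grayscale p x p also accepted).
#' @return numeric vector of length 20.
#' @keywords internal
patch_descriptor <- function(patch) {
  if (length(dim(patch)) == 2L) {
    patch <- array(rep(patch, 3L), c(dim(patch), 3L))
  }
  p <- dim(patch)[1]
  moments <- c(apply(patch, 3, mean), apply(patch, 3, stats::sd))
  gray <- (patch[, , 1] + patch[, , 2] + patch[, , 3]) / 3

  # central differences on the interior
  gx <- (gray[2:(p - 1), 3:p] - gray[2:(p - 1), 1:(p - 2)]) / 2
  gy <- (gray[3:p, 2:(p - 1)] - gray[1:(p - 2), 2:(p - 1)]) / 2
  mag <- sqrt(gx^2 + gy^2)
  ang <- atan2(gy, gx)                      # (-pi, pi]
  bin <- pmin(floor((ang + pi) / (2 * pi / 8)) + 1L, 8L)
  ghist <- vapply(1:8, function(b) sum(mag[bin == b]), numeric(1)) /
    length(mag)

  # radial power spectrum (luminance), DC excluded, 6 bins on (0, 0.71]
  fr <- stats::fft(gray)
  pow <- Mod(fr)^2 / length(gray)
  fx <- c(seq.int(0L, floor(p / 2)), seq.int(-(ceiling(p / 2) - 1L), -1L)) / p
  r <- sqrt(outer(fx^2, fx^2, "+"))
  rbin <- pmin(ceiling(r / (0.71 / 6)), 6L)
  spec <- vapply(1:6, function(b) {
    sel <- rbin == b & r > 0
    if (!any(sel)) 0 else log1p(mean(pow[sel]))
  }, numeric(1))

  c(moments, ghist, spec)
}

#' Fit the default embedding backend
#'
#' The backend maps a patch to a real vector ("embedding"). The default is
#' the handcrafted [patch_descriptor()]; when patch-level outcome labels
#' are supplied, a linear discriminant (BCR-positive vs negative) is fitted
#' on the descriptors and its coordinate appended, preserving in miniature
#' the contract of a penultimate representation trained on outcome labels.
#'
#' @param patches list of patch arrays (used to fit the discriminant and to
#'   record the dimensionality; at least one required).
#' @param labels optional 0/1 patch-level outcome labels, same length as
#'   `patches`; both classes must be present.
#' @return an `embedding_backend` with fields `name`, `dim`, `supervised`.
#' @export
fit_default_backend <- function(patches, labels = NULL) {
  if (length(patches) < 1L) stop_prostir("need at least one tissue patch")
  desc <- t(vapply(patches, patch_descriptor, numeric(20)))
  lda_fit <- NULL
  if (!is.null(labels)) {
    labels <- as.integer(labels)
    if (length(labels) != length(patches)) {
      stop_prostir("labels must match patches in length")
    }
    if (length(unique(labels)) < 2L) {
      stop_prostir("supervised mode needs both outcome classes among patches")
    }
    keep <- apply(desc, 2, stats::sd) > 1e-12  # lda chokes on constant columns
    lda_fit <- list(keep = keep,
                    model = MASS::lda(desc[, keep, drop = FALSE],
                                      grouping = labels, tol = 1e-12))
  }
  backend <- list(
    name = if (is.null(lda_fit)) "descriptor" else "descriptor+lda",
    dim = 20L + (!is.null(lda_fit)),
    supervised = !is.null(lda_fit),
    lda = lda_fit
  )
  class(backend) <- "embedding_backend"
  backend
}

#' Embed patches with a fitted backend
#'
#' @param backend an `embedding_backend` from [fit_default_backend()].
#' @param patches list of patch arrays.
#' @return n x dim numeric matrix; rows are embeddings.
#' @export
embed_patches <- function(backend, patches) {
  stopifnot(inherits(backend, "embedding_backend"))
  desc <- t(vapply(patches, patch_descriptor, numeric(20)))
  if (backend$supervised) {
    x <- desc[, backend$lda$keep, drop = FALSE]
    ld <- stats::predict(backend$lda$model, x)$x[, 1]
    desc <- cbind(desc, ld)
  }
  if (any(!is.finite(desc))) stop_prostir("non-finite embedding produced")
  unname(desc)
}
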