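#' Default texture parameters for synthetic slides
#'
#' One distinguishable texture family per cluster: an H&E-like stain color
#' interpolated between a hematoxylin-like purple and an eosin-like pink,
#' modulated by an oriented sinusoidal grating whose frequency and
#' orientation vary with the cluster index, plus low-amplitude pixel noise.
#' A [domain_shift()] stain offset can be folded in to emulate a scanner /
#' staining difference between institutions.
#'
#' @param n_clusters number of texture families.
#' @param patch_px patch edge length in pixels.
#' @param stain_offset length-3 RGB offset added to all stain colors.
#' @param noise_sd pixel noise standard deviation.
#' @param background background gray level (near-white, unstained glass).
#' @return a list of class `texture_params` with one row per cluster in
#'   `$families` (color, frequency, orientation).
#' @export
default_texture_params <- function(n_clusters, patch_px = 32L,
                                   stain_offset = c(0, 0, 0),
                                   noise_sd = 0.015,
                                   background = 0.97) {
  k <- as.integer(n_clusters)
  stopifnot(k >= 1L, patch_px >= 4L, length(stain_offset) == 3L)
  hema <- c(0.35, 0.20, 0.55)
  eosin <- c(0.92, 0.55, 0.65)
  mix <- (seq_len(k) - 0.5) / k
  cols <- t(vapply(mix, function(w) {
    pmin(pmax((1 - w) * hema + w * eosin + stain_offset, 0), 1)
  }, numeric(3)))
  fams <- data.frame(
    cluster = seq_len(k) - 1L,
    r = cols[, 1], g = cols[, 2], b = cols[, 3],
    freq = 2 + (seq_len(k) - 1L) %% 4L,
    theta = pi * (seq_len(k) - 1L) / k
  )
  structure(list(families = fams, patch_px = as.integer(patch_px),
                 depth = 0.35, noise_sd = noise_sd, background = background),
            class = "texture_params")
}

render_texture_patch <- function(tp, cluster, phase = 0) {
  ps <- tp$patch_px
  fam <- tp$families[cluster + 1L, ]
  xy <- expand.grid(x = seq_len(ps) - 1L, y = seq_len(ps) - 1L)
  proj <- xy$x * cos(fam$theta) + xy$y * sin(fam$theta)
  patt <- 0.5 + 0.5 * sin(2 * pi * fam$freq * proj / ps + phase)
  shade <- 1 - tp$depth + tp$depth * patt
  px <- array(0, c(ps, ps, 3))
  base <- c(fam$r, fam$g, fam$b)
  for (ch in 1:3) {
    px[, , ch] <- matrix(base[ch] * shade, ps, ps)  # row = y, col = x
  }
  px
}

#' Render a synthetic slide for one patient
#'
#' Lays the patient's patches (drawn per the cluster-count vector, in
#' randomized order) on a near-square grid with an optional background
#' margin, rendering each patch with its cluster's texture family. Returns
#' the 8-bit-RGB-ready image array and a ground-truth table mapping each
#' placed patch to its generating cluster. Deterministic given the seed.
#'
#' @param patient one-row data.frame from [generate_cohort()]`$patients`
#'   (only `patient_id` is used; pass NULL for an anonymous slide).
#' @param counts integer vector of patches per cluster; `sum(counts) > 0`.
#' @param texture_params a [default_texture_params()] object with at least
#'   `length(counts)` families.
#' @param seed integer seed for patch order and noise.
#' @param margin background margin in pixels around the patch grid.
#' @return list with `image` (H x W x 3 array in \[0,1\]) and
#'   `ground_truth` (data.frame x0,y0,x1,y1,cluster; 0-based, half-open
#'   pixel intervals).
#' @export
generate_slide <- function(patient, counts, texture_params, seed,
                           margin = 0L) {
  stopifnot(inherits(texture_params, "texture_params"))
  counts <- as.integer(counts)
  if (any(counts < 0)) stop_prostir("counts must be nonnegative")
  n <- sum(counts)
  if (n == 0L) stop_prostir("counts are all zero: nothing to render")
  if (nrow(texture_params$families) < length(counts)) {
    stop_prostir("texture_params defines %d families but counts has %d clusters",
                 nrow(texture_params$families), length(counts))
  }
  ps <- texture_params$patch_px
  ncol_g <- ceiling(sqrt(n))
  nrow_g <- ceiling(n / ncol_g)
  width <- ncol_g * ps + 2L * margin
  height <- nrow_g * ps + 2L * margin

  with_seed(derive_seed(seed, 2L), {
    seq_clusters <- rep(seq_along(counts) - 1L, counts)
    seq_clusters <- sample(seq_clusters)
    img <- array(texture_params$background, c(height, width, 3))
    gt <- data.frame(x0 = integer(n), y0 = integer(n),
                     x1 = integer(n), y1 = integer(n),
                     cluster = integer(n))
    for (i in seq_len(n)) {
      gy <- (i - 1L) %/% ncol_g
      gx <- (i - 1L) %% ncol_g
      x0 <- margin + gx * ps
      y0 <- margin + gy * ps
      phase <- stats::runif(1, 0, 2 * pi)
      px <- render_texture_patch(texture_params, seq_clusters[i], phase)
      px <- px + array(stats::rnorm(length(px), 0, texture_params$noise_sd),
                       dim(px))
      px <- pmin(pmax(px, 0), 1)
      img[(y0 + 1L):(y0 + ps), (x0 + 1L):(x0 + ps), ] <- px
      gt[i, ] <- c(x0, y0, x0 + ps, y0 + ps, seq_clusters[i])
    }
    slide_id <- if (is.null(patient)) "slide" else patient$patient_id[1L]
    list(slide_id = slide_id, image = img, ground_truth = gt)
  })
}

#' Write a slide and its ground truth to disk
#'
#' @param slide result of [generate_slide()].
#' @param dir output directory.
#' @return invisibly, the PNG and CSV paths.
#' @export
write_slide <- function(slide, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  f_png <- file.path(dir, paste0(slide$slide_id, ".png"))
  f_csv <- file.path(dir, paste0(slide$slide_id, "_truth.csv"))
  png::writePNG(slide$image, f_png)
  utils::write.csv(slide$ground_truth, f_csv, row.names = FALSE)
  invisible(c(image = f_png, truth = f_csv))
}

#' Read a slide image from PNG/TIFF
#'
#' @param path path to an 8-bit RGB PNG (or grayscale, promoted to RGB).
#' @return H x W x 3 array in \[0,1\].
#' @export
read_slide <- function(path) {
  img <- png::readPNG(path)
  if (length(dim(img)) == 2L) img <- array(rep(img, 3L), c(dim(img), 3L))
  if (dim(img)[3] == 4L) img <- img[, , 1:3, drop = FALSE]
  img
}
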