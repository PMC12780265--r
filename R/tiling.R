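#' Tile a slide image into patches
#'
#' Enumerates patch origins on the stride lattice, row-major, 0-based,
#' half-open pixel intervals `[x0, x0 + patch_size)`. With
#' `stride == patch_size` patches are disjoint (the codebook-training
#' convention); with `stride < patch_size` they overlap (the inference
#' convention). Right/bottom remainders smaller than a full patch are
#' dropped — no padding.
#'
#' @param image H x W x 3 array in \[0,1\] (or H x W grayscale).
#' @param patch_size patch edge length in pixels.
#' @param stride lattice step in pixels, `1 <= stride <= patch_size`.
#' @param slide_id identifier carried on the patch set.
#' @return a `patch_set`: list with `slide_id`, `patch_size`, `stride`,
#'   `image`, and `patches` (data.frame x0, y0, tissue; tissue is NA until
#'   [flag_tissue()] is applied).
#' @export
tile <- function(image, patch_size, stride = patch_size,
                 slide_id = "slide") {
  d <- dim(image)
  if (is.null(d) || length(d) < 2L) stop_prostir("image must be a 2- or 3-d array")
  h <- d[1]; w <- d[2]
  patch_size <- as.integer(patch_size)
  stride <- as.integer(stride)
  if (patch_size < 1L) stop_prostir("patch_size must be >= 1")
  if (stride < 1L || stride > patch_size) {
    stop_prostir("stride must satisfy 1 <= stride <= patch_size")
  }
  if (w < patch_size || h < patch_size) {
    stop_prostir("image (%d x %d) is smaller than patch_size %d",
                 w, h, patch_size)
  }
  xs <- seq.int(0L, w - patch_size, by = stride)
  ys <- seq.int(0L, h - patch_size, by = stride)
  grid <- expand.grid(x0 = xs, y0 = ys)  # row-major: x fastest
  ps <- list(slide_id = slide_id, patch_size = patch_size, stride = stride,
             image = image,
             patches = data.frame(x0 = grid$x0, y0 = grid$y0,
                                  tissue = rep(NA, nrow(grid))))
  class(ps) <- "patch_set"
  ps
}

#' Extract the pixel block of one patch
#'
#' @param patchset a `patch_set` from [tile()].
#' @param i patch row index (1-based into `patchset$patches`).
#' @return patch_size x patch_size x channels array.
#' @export
get_patch <- function(patchset, i) {
  stopifnot(inherits(patchset, "patch_set"))
  p <- patchset$patches[i, ]
  n <- patchset$patch_size
  img <- patchset$image
  if (length(dim(img)) == 2L) {
    img[(p$y0 + 1L):(p$y0 + n), (p$x0 + 1L):(p$x0 + n), drop = FALSE]
  } else {
    img[(p$y0 + 1L):(p$y0 + n), (p$x0 + 1L):(p$x0 + n), , drop = FALSE]
  }
}

#' Flag background patches by an HSV rule
#'
#' A patch is tissue iff the fraction of its pixels that look stained —
#' saturation above `s_min` and brightness below `v_max` — exceeds `f_min`.
#' Unstained glass is near-white (low saturation, high brightness), so the
#' defaults separate it cleanly from H&E-stained tissue.
#'
#' @param patchset a `patch_set` from [tile()] (RGB image required).
#' @param s_min minimum saturation of a stained pixel.
#' @param v_max maximum brightness (value) of a stained pixel.
#' @param f_min minimum stained-pixel fraction for a tissue patch.
#' @return the patch set with the `tissue` column filled.
#' @export
flag_tissue <- function(patchset, s_min = 0.08, v_max = 0.95, f_min = 0.5) {
  stopifnot(inherits(patchset, "patch_set"))
  if (length(dim(patchset$image)) != 3L) {
    stop_prostir("flag_tissue needs an RGB image; no grayscale rule is declared")
  }
  n <- nrow(patchset$patches)
  flags <- logical(n)
  for (i in seq_len(n)) {
    px <- get_patch(patchset, i)
    hsv <- grDevices::rgb2hsv(r = as.vector(px[, , 1]),
                              g = as.vector(px[, , 2]),
                              b = as.vector(px[, , 3]),
                              maxColorValue = 1)
    stained <- hsv["s", ] > s_min & hsv["v", ] < v_max
    flags[i] <- mean(stained) > f_min
  }
  patchset$patches$tissue <- flags
  patchset
}

#' Write a patch index to CSV
#'
#' Columns: slide_id, x0, y0, tissue.
#'
#' @param patchset a `patch_set`.
#' @param path output CSV path.
#' @return invisibly, `path`.
#' @export
write_patch_index <- function(patchset, path) {
  df <- data.frame(slide_id = patchset$slide_id,
                   patchset$patches)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
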