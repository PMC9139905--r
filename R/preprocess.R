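# Tissue segmentation and tile extraction. The mask lives on a 32x
# downsampled canvas (area-averaged before HSV conversion); tiles are
# 512 x 512 full-resolution windows on a non-overlapping grid, kept only
# when their whole 16 x 16 mask footprint is tissue (100% threshold).

#' Block-mean downsampling of a matrix
#'
#' Area-averaging by non-overlapping `factor` x `factor` blocks. Edges
#' not filling a whole block are padded by replicating the last row and
#' column, so the output has `ceiling(dim / factor)` cells per axis.
#'
#' @param m Numeric matrix.
#' @param factor Integer downsampling factor.
#' @return Matrix of block means.
#' @export
downsample_mean <- function(m, factor) {
  f <- as.integer(factor)
  h <- nrow(m); w <- ncol(m)
  H <- ceiling(h / f) * f
  W <- ceiling(w / f) * f
  if (H != h) m <- m[c(seq_len(h), rep(h, H - h)), , drop = FALSE]
  if (W != w) m <- m[, c(seq_len(w), rep(w, W - w)), drop = FALSE]
  # reduce rows: f x (H/f) x W -> (H/f) x W, then columns the same way
  s <- colMeans(array(m, c(f, H %/% f, W)))
  t(colMeans(array(t(s), c(f, W %/% f, H %/% f))))
}

downsample_rgb <- function(img, factor) {
  out <- NULL
  for (ch in 1:3) {
    d <- downsample_mean(img[, , ch], factor)
    if (is.null(out)) out <- array(0, c(nrow(d), ncol(d), 3))
    out[, , ch] <- d
  }
  out
}

# HSV saturation S = 1 - min/max (0 where max = 0), as in 8-bit HSV
saturation_channel <- function(img) {
  mx <- pmax(img[, , 1], img[, , 2], img[, , 3])
  mn <- pmin(img[, , 1], img[, , 2], img[, , 3])
  s <- (mx - mn) / mx
  s[mx == 0] <- 0
  s
}

#' Otsu threshold over a 256-bin histogram
#'
#' Picks the bin split maximising the between-class variance of the two
#' sides (ties to the lowest split). Values are binned as
#' `floor(x * 255)` on `[0, 1]`.
#'
#' @param x Numeric values in `[0, 1]`.
#' @return Integer split bin `k` in `0..254`; foreground is `bin > k`.
#'   `NA` when the histogram is degenerate (a single occupied bin).
#' @export
otsu_threshold <- function(x) {
  bins <- pmin(pmax(floor(x * 255), 0), 255)
  counts <- tabulate(bins + 1L, nbins = 256L)
  if (sum(counts > 0L) < 2L) return(NA_integer_)
  p <- counts / sum(counts)
  lev <- 0:255
  omega <- cumsum(p)
  mu <- cumsum(p * lev)
  mu_t <- mu[256]
  k <- 1:255  # split after bin k-1: classes [0, k-1] and [k, 255]
  om <- omega[k]
  sb <- (mu_t * om - mu[k])^2 / (om * (1 - om))
  sb[!is.finite(sb)] <- -Inf
  as.integer(which.max(sb) - 1L)
}

#' Tissue mask by Otsu thresholding on the saturation channel
#'
#' The slide is 32x downsampled by area averaging, converted to HSV, and
#' the S channel is Otsu-binarised; tissue is the high-saturation side
#' (stained tissue against the whitish background). A constant-saturation
#' image yields an empty mask with a warning, not an error.
#'
#' @param image h x w x 3 RGB array in `[0, 1]`.
#' @param factor Downsampling factor (default 32).
#' @return Object of class `pathomil_tissue_mask`: list with `mask`
#'   (logical matrix, `ceiling(dim / factor)` per axis), `factor`, and
#'   the Otsu split `threshold_bin`.
#' @export
compute_tissue_mask <- function(image, factor = 32L) {
  stopifnot(length(dim(image)) == 3L, dim(image)[3] == 3L)
  small <- downsample_rgb(image, factor)
  s <- saturation_channel(small)
  k <- otsu_threshold(s)
  if (is.na(k)) {
    warning("saturation histogram is not bimodal; returning empty mask")
    mask <- matrix(FALSE, nrow(s), ncol(s))
  } else {
    mask <- floor(s * 255) > k
  }
  structure(list(mask = mask, factor = as.integer(factor),
                 threshold_bin = k,
                 slide_dims = dim(image)[1:2]),
            class = "pathomil_tissue_mask")
}

#' Extract full-tissue tiles on a non-overlapping grid
#'
#' Tiles of `tile_size` pixels are laid on a stride-`tile_size` grid at
#' full resolution; a tile is kept iff the fraction of tissue pixels in
#' its mask footprint reaches `tissue_threshold` (the default 1.0 keeps
#' only tiles completely inside the mask). Tiles are ordered row-major
#' (left to right, then top to bottom) with 0-based pixel coordinates.
#'
#' @param mask A `pathomil_tissue_mask`.
#' @param slide_id Identifier stored in each record.
#' @param tile_size Tile side in full-resolution pixels; must be a
#'   multiple of the mask's downsampling factor.
#' @param tissue_threshold Minimum tissue fraction in the footprint.
#' @return data.frame of tile records: `slide_id`, `tile_index` (0-based
#'   over kept tiles), `x`, `y` (0-based top-left), `size`,
#'   `strong_label` (NA until assigned).
#' @export
extract_tiles <- function(mask, slide_id = "slide", tile_size = 512L,
                          tissue_threshold = 1.0) {
  stopifnot(inherits(mask, "pathomil_tissue_mask"))
  f <- mask$factor
  if (tile_size %% f != 0L) {
    stop("tile_size must be divisible by the downsampling factor")
  }
  fp <- tile_size %/% f                # footprint side on the mask
  ny <- nrow(mask$mask) %/% fp
  nx <- ncol(mask$mask) %/% fp
  if (!is.null(mask$slide_dims)) {     # tiles must fit the full-res slide
    ny <- min(ny, mask$slide_dims[1] %/% tile_size)
    nx <- min(nx, mask$slide_dims[2] %/% tile_size)
  }
  empty <- data.frame(slide_id = character(0), tile_index = integer(0),
                      x = integer(0), y = integer(0), size = integer(0),
                      strong_label = integer(0), stringsAsFactors = FALSE)
  if (ny < 1L || nx < 1L) return(empty)
  frac <- downsample_mean(mask$mask[seq_len(ny * fp), seq_len(nx * fp),
                                    drop = FALSE] * 1, fp)
  keep <- which(t(frac) >= tissue_threshold - 1e-12)  # t(): row-major order
  if (!length(keep)) return(empty)
  gx <- (keep - 1L) %% nx
  gy <- (keep - 1L) %/% nx
  data.frame(slide_id = slide_id,
             tile_index = seq_along(keep) - 1L,
             x = as.integer(gx * tile_size),
             y = as.integer(gy * tile_size),
             size = as.integer(tile_size),
             strong_label = NA_integer_,
             stringsAsFactors = FALSE)
}

#' Crop one tile's pixels from a slide image
#'
#' @param image h x w x 3 array.
#' @param tile One row of an [extract_tiles()] data.frame.
#' @return `size` x `size` x 3 array.
#' @export
get_tile <- function(image, tile) {
  ys <- tile$y + seq_len(tile$size)
  xs <- tile$x + seq_len(tile$size)
  stopifnot(max(ys) <= dim(image)[1], max(xs) <= dim(image)[2])
  image[ys, xs, , drop = FALSE]
}

#' Assign strong tile labels from a ground-truth grade mask
#'
#' Each tile's label is the worst (maximum) grade with any pixel
#' presence inside its window; windows containing no graded pixels get
#' grade 1 (non-neoplastic), consistent with the worst-case slide rule.
#' The mask may be at full resolution or at the tiling downsample
#' (nearest-neighbour correspondence via the `factor` argument).
#'
#' @param tiles data.frame from [extract_tiles()].
#' @param grade_truth_mask Integer matrix of grades, 0 = background.
#' @param factor Resolution of the mask relative to the slide: 1 for a
#'   full-resolution mask, 32 for one on the mask canvas.
#' @return `tiles` with `strong_label` filled in.
#' @export
assign_strong_labels <- function(tiles, grade_truth_mask, factor = 1L) {
  f <- as.integer(factor)
  if (nrow(tiles) == 0L) return(tiles)
  need_y <- (max(tiles$y + tiles$size) - 1L) %/% f + 1L
  need_x <- (max(tiles$x + tiles$size) - 1L) %/% f + 1L
  if (nrow(grade_truth_mask) < need_y || ncol(grade_truth_mask) < need_x) {
    stop("grade mask does not cover the tiled slide area")
  }
  tiles$strong_label <- vapply(seq_len(nrow(tiles)), function(i) {
    ys <- (tiles$y[i] %/% f + 1L):((tiles$y[i] + tiles$size[i] - 1L) %/% f + 1L)
    xs <- (tiles$x[i] %/% f + 1L):((tiles$x[i] + tiles$size[i] - 1L) %/% f + 1L)
    g <- grade_truth_mask[ys, xs]
    g <- g[g > 0L]
    if (length(g)) max(g) else 1L
  }, integer(1))
  tiles
}
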