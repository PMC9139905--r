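# Synthetic whole-slide fixtures: whitish background, saturated "tissue"
# blobs, and spot-textured lesion regions with a monotone visual ordinal
# signal (NNeo = plain light pink, LG = medium-density dark-purple spots,
# HG = denser and larger spots). Ground-truth tissue and grade masks and
# the worst-case slide label come with every slide.

#' Default per-grade texture parameters
#'
#' Grade 1 (non-neoplastic) tissue is uniform light pink. Grade 2 adds
#' medium-density dark-purple spots, grade 3 denser and larger ones, so
#' the three grades form a visually monotone ordinal scale. Spot density
#' is in spots per full-resolution pixel; radii in pixels.
#'
#' @return Named list over grades `"1"`, `"2"`, `"3"`.
#' @export
default_texture_params <- function() {
  list(
    `1` = list(base_rgb = c(0.91, 0.63, 0.74), spot_density = 0,
               spot_radius = 0, spot_rgb = NULL),
    `2` = list(base_rgb = c(0.91, 0.63, 0.74), spot_density = 265e-6,
               spot_radius = 6, spot_rgb = c(0.30, 0.10, 0.38)),
    `3` = list(base_rgb = c(0.91, 0.63, 0.74), spot_density = 500e-6,
               spot_radius = 11, spot_rgb = c(0.30, 0.10, 0.38))
  )
}

#' Specification of one synthetic slide
#'
#' @param width_px,height_px Full-resolution dimensions (>= 1024).
#' @param n_tissue_blobs Number of tissue blobs (one dominant central
#'   blob plus smaller satellites).
#' @param lesion_spec List of `list(grade =, frac =)` entries; `frac` is
#'   the lesion area as a fraction of the tissue area. The implied slide
#'   label is the maximum grade present (1 if empty).
#' @param texture_params Per-grade texture list, see
#'   [default_texture_params()].
#' @param background_rgb Whitish background triple in `[0, 1]`; its
#'   saturation must stay below the tissue's so the saturation histogram
#'   is bimodal.
#' @param seed Integer seed; generation is fully deterministic given it.
#' @return An object of class `pathomil_slide_spec`.
#' @export
synthetic_slide_spec <- function(width_px = 2560, height_px = 2560,
                                 n_tissue_blobs = 3,
                                 lesion_spec = list(),
                                 texture_params = default_texture_params(),
                                 background_rgb = c(245, 245, 245) / 255,
                                 seed = 1L) {
  stopifnot(width_px >= 1024, height_px >= 1024, n_tissue_blobs >= 1)
  for (ls in lesion_spec) {
    stopifnot(ls$grade %in% 1:3, ls$frac > 0)
  }
  structure(list(width_px = as.integer(width_px),
                 height_px = as.integer(height_px),
                 n_tissue_blobs = as.integer(n_tissue_blobs),
                 lesion_spec = lesion_spec,
                 texture_params = texture_params,
                 background_rgb = background_rgb,
                 seed = as.integer(seed)),
            class = "pathomil_slide_spec")
}

ellipse_mask <- function(h, w, cy, cx, ry, rx) {
  dy2 <- ((seq_len(h) - cy) / ry)^2
  dx2 <- ((seq_len(w) - cx) / rx)^2
  outer(dy2, dx2, `+`) <= 1
}

# ellipse restricted to its bounding box: list(ys, xs, m)
ellipse_window <- function(h, w, cy, cx, ry, rx) {
  ys <- max(1L, floor(cy - ry)):min(h, ceiling(cy + ry))
  xs <- max(1L, floor(cx - rx)):min(w, ceiling(cx + rx))
  dy2 <- ((ys - cy) / ry)^2
  dx2 <- ((xs - cx) / rx)^2
  list(ys = ys, xs = xs, m = outer(dy2, dx2, `+`) <= 1)
}

# paint filled disks at (cy, cx) with radius r and colour col into a
# list of three channel planes, modifying only a local window per spot
paint_spots <- function(planes, cys, cxs, rads, cols) {
  h <- nrow(planes[[1]]); w <- ncol(planes[[1]])
  for (s in seq_along(cys)) {
    r <- rads[s]
    y0 <- max(1L, floor(cys[s] - r)); y1 <- min(h, ceiling(cys[s] + r))
    x0 <- max(1L, floor(cxs[s] - r)); x1 <- min(w, ceiling(cxs[s] + r))
    if (y0 > y1 || x0 > x1) next
    yy <- y0:y1; xx <- x0:x1
    d <- outer((yy - cys[s])^2, (xx - cxs[s])^2, `+`) <= r^2
    for (ch in 1:3) {
      block <- planes[[ch]][yy, xx]
      block[d] <- cols[s, ch]
      planes[[ch]][yy, xx] <- block
    }
  }
  planes
}

#' Generate one synthetic whole-slide image with ground truth
#'
#' Renders tissue blobs over the whitish background, paints the lesion
#' regions with their grade textures, and returns the image together
#' with the binary tissue mask, the grade mask (0 = background, 1-3 =
#' grades) and the worst-case slide label. Byte-identical output for a
#' fixed spec (the image is quantised to 8-bit levels).
#'
#' @param spec A [synthetic_slide_spec()].
#' @return An object of class `pathomil_slide`: list with `image`
#'   (h x w x 3 array in `[0, 1]`), `tissue_truth_mask` (logical matrix),
#'   `grade_truth_mask` (integer matrix), `slide_label`, `spec`.
#' @export
generate_slide <- function(spec) {
  stopifnot(inherits(spec, "pathomil_slide_spec"))
  h <- spec$height_px; w <- spec$width_px
  withr::with_seed(spec$seed, {
    rmin <- min(h, w)
    # dominant central blob, slightly elliptical, keeping a background margin
    cy <- h / 2 + stats::runif(1, -0.015, 0.015) * h
    cx <- w / 2 + stats::runif(1, -0.015, 0.015) * w
    ry <- 0.46 * rmin * stats::runif(1, 0.96, 1.0)
    rx <- 0.46 * rmin * stats::runif(1, 0.96, 1.0)
    tissue <- ellipse_mask(h, w, cy, cx, ry, rx)
    if (spec$n_tissue_blobs > 1L) {
      for (b in seq_len(spec$n_tissue_blobs - 1L)) {
        rb <- stats::runif(1, 0.05, 0.09) * rmin
        cyb <- stats::runif(1, rb + 8, h - rb - 8)
        cxb <- stats::runif(1, rb + 8, w - rb - 8)
        ew <- ellipse_window(h, w, cyb, cxb, rb, rb)
        tissue[ew$ys, ew$xs] <- tissue[ew$ys, ew$xs] | ew$m
      }
    }
    tissue_area <- sum(tissue)
    fr <- vapply(spec$lesion_spec, `[[`, numeric(1), "frac")
    if (length(fr) && sum(fr) > 1) {
      stop("lesion area fraction exceeds the tissue area")
    }

    grade <- matrix(0L, h, w)
    grade[tissue] <- 1L
    # lesions inside the dominant blob, spread on a ring around its centre
    n_les <- length(spec$lesion_spec)
    lesion_masks <- vector("list", n_les)
    if (n_les) {
      base_angle <- stats::runif(1, 0, 2 * pi)
      for (i in seq_len(n_les)) {
        ls <- spec$lesion_spec[[i]]
        r <- sqrt(ls$frac * tissue_area / pi)
        dmax <- max(0, 0.97 * min(ry, rx) - r)
        ang <- base_angle + 2 * pi * (i - 1) / max(1, n_les)
        d <- dmax * stats::runif(1, 0.35, 0.7)
        lcy <- cy + d * sin(ang)
        lcx <- cx + d * cos(ang)
        ew <- ellipse_window(h, w, lcy, lcx, r, r)
        m <- ew$m & tissue[ew$ys, ew$xs]
        lesion_masks[[i]] <- list(area = sum(m), grade = as.integer(ls$grade),
                                  cy = lcy, cx = lcx, r = r)
        g <- grade[ew$ys, ew$xs]
        g[m] <- pmax(g[m], as.integer(ls$grade))
        grade[ew$ys, ew$xs] <- g
      }
    }

    # render: constant background, pink tissue with mild value noise
    tp1 <- spec$texture_params[["1"]]
    tis_idx <- which(tissue)
    noise <- stats::runif(length(tis_idx), 0.96, 1.04)
    planes <- lapply(1:3, function(ch) {
      plane <- matrix(spec$background_rgb[ch], h, w)
      plane[tis_idx] <- tp1$base_rgb[ch] * noise
      plane
    })
    # lesion spot textures
    for (lm in lesion_masks) {
      tp <- spec$texture_params[[as.character(lm$grade)]]
      if (is.null(tp) || tp$spot_density <= 0) next
      n_spots <- round(tp$spot_density * lm$area)
      if (n_spots < 1) next
      u <- stats::runif(n_spots); th <- stats::runif(n_spots, 0, 2 * pi)
      rr <- (lm$r - tp$spot_radius) * sqrt(u)
      cys <- lm$cy + rr * sin(th)
      cxs <- lm$cx + rr * cos(th)
      rads <- tp$spot_radius * stats::runif(n_spots, 0.8, 1.2)
      cols <- outer(stats::runif(n_spots, 0.85, 1.1), tp$spot_rgb)
      planes <- paint_spots(planes, cys, cxs, rads, cols)
    }
    # all colours are inside [0, 1] by construction; quantise to 8 bit
    img <- array(0, c(h, w, 3))
    for (ch in 1:3) {
      img[, , ch] <- round(planes[[ch]] * 255) / 255
    }

    label <- if (any(grade > 1L)) max(grade) else 1L
    structure(list(image = img,
                   tissue_truth_mask = tissue,
                   grade_truth_mask = grade,
                   slide_label = label,
                   spec = spec),
              class = "pathomil_slide")
  })
}

lesion_spec_for_label <- function(label, jitter = 0) {
  j <- function(x) max(0.06, x + jitter)
  switch(label,
         list(),
         list(list(grade = 2, frac = j(0.18))),
         list(list(grade = 2, frac = j(0.12)),
              list(grade = 3, frac = j(0.20))))
}

slide_seed <- function(dataset_seed, index) {
  as.integer((abs(as.numeric(dataset_seed)) * 1000003 + index * 7919) %%
               .Machine$integer.max)
}

#' Generate a manifest of synthetic slide specifications
#'
#' Draws slide labels from `class_mix`, marks an `annotated_fraction`
#' subset as strongly annotated (stratified across the labels present),
#' and derives one RNG stream per slide from the dataset seed and slide
#' index, so slides can be materialised independently and reproducibly.
#'
#' @param n_slides Number of slides (> 0).
#' @param class_mix Length-3 proportions over grades NNeo/LG/HG
#'   (must sum to 1).
#' @param annotated_fraction Fraction of slides carrying ground-truth
#'   grade masks for supervised pre-training (the adopted study design
#'   uses roughly 9%).
#' @param seed Dataset seed.
#' @param width_px,height_px,n_tissue_blobs Passed to each slide spec.
#' @return List with `manifest` (data.frame: slide_id, label, annotated,
#'   seed, path) and `specs` (list of [synthetic_slide_spec()]).
#' @export
synthetic_manifest <- function(n_slides, class_mix = c(1, 1, 1) / 3,
                               annotated_fraction = 0.09, seed = 0L,
                               width_px = 2560, height_px = 2560,
                               n_tissue_blobs = 3) {
  if (n_slides <= 0) stop("n_slides must be positive")
  if (abs(sum(class_mix) - 1) > 1e-8) stop("class_mix must sum to 1")
  withr::with_seed(as.integer(seed), {
    labels <- sample.int(3L, n_slides, replace = TRUE, prob = class_mix)
    n_ann <- round(annotated_fraction * n_slides)
    by_class <- lapply(1:3, function(k) {
      idx <- which(labels == k)
      if (length(idx) > 1L) sample(idx) else idx
    })
    # round-robin over classes so the annotated subset is stratified
    interleaved <- integer(0)
    while (any(lengths(by_class) > 0L)) {
      for (k in 1:3) {
        if (length(by_class[[k]])) {
          interleaved <- c(interleaved, by_class[[k]][1L])
          by_class[[k]] <- by_class[[k]][-1L]
        }
      }
    }
    annotated <- seq_len(n_slides) %in% interleaved[seq_len(n_ann)]
    jit <- stats::runif(n_slides, -0.04, 0.04)
    specs <- lapply(seq_len(n_slides), function(i) {
      synthetic_slide_spec(width_px = width_px, height_px = height_px,
                           n_tissue_blobs = n_tissue_blobs,
                           lesion_spec = lesion_spec_for_label(labels[i], jit[i]),
                           seed = slide_seed(seed, i))
    })
    manifest <- data.frame(
      slide_id = sprintf("synth_%03d", seq_len(n_slides)),
      label = labels,
      annotated = annotated,
      seed = vapply(specs, function(s) s$seed, integer(1)),
      path = NA_character_,
      stringsAsFactors = FALSE)
    list(manifest = manifest, specs = specs)
  })
}

#' Generate and (optionally) write a synthetic slide dataset
#'
#' Materialises every slide of a [synthetic_manifest()]. With `outdir`
#' set, writes per slide a full-resolution TIFF, PNG tissue and grade
#' masks, and a `manifest.csv`; otherwise the slides are returned in
#' memory (only advisable for small `n_slides`).
#'
#' @inheritParams synthetic_manifest
#' @param outdir Output directory, created if needed; `NULL` keeps the
#'   slides in memory.
#' @return List with `manifest`, `specs`, and (if `outdir` is `NULL`)
#'   `slides`.
#' @export
generate_dataset <- function(n_slides, class_mix = c(1, 1, 1) / 3,
                             annotated_fraction = 0.09, seed = 0L,
                             width_px = 2560, height_px = 2560,
                             n_tissue_blobs = 3, outdir = NULL) {
  mf <- synthetic_manifest(n_slides, class_mix, annotated_fraction, seed,
                           width_px, height_px, n_tissue_blobs)
  if (is.null(outdir)) {
    mf$slides <- lapply(mf$specs, generate_slide)
    return(mf)
  }
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  for (i in seq_len(n_slides)) {
    sl <- generate_slide(mf$specs[[i]])
    id <- mf$manifest$slide_id[i]
    img_path <- file.path(outdir, paste0(id, ".tiff"))
    tiff::writeTIFF(sl$image, img_path, bits.per.sample = 8L)
    png::writePNG(sl$tissue_truth_mask * 1,
                  file.path(outdir, paste0(id, "_tissue.png")))
    if (mf$manifest$annotated[i]) {
      png::writePNG(sl$grade_truth_mask / 3,
                    file.path(outdir, paste0(id, "_grade.png")))
    }
    mf$manifest$path[i] <- img_path
  }
  utils::write.csv(mf$manifest, file.path(outdir, "manifest.csv"),
                   row.names = FALSE)
  mf
}

#' Read back a grade mask written by [generate_dataset()]
#'
#' @param path PNG path (grades encoded as `grade / 3` grey levels).
#' @return Integer matrix of grades 0-3.
#' @export
read_grade_mask <- function(path) {
  m <- png::readPNG(path)
  if (length(dim(m)) == 3L) m <- m[, , 1L]
  matrix(as.integer(round(m * 3)), nrow(m), ncol(m))
}
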