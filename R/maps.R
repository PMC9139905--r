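# Tile-prediction maps: each tile's argmax grade is painted as a 16x16
# block on the 32x-downsampled slide canvas (green / blue / yellow for
# NNeo / LG / HG), alpha-blended over the thumbnail. The maps reuse the
# probabilities already computed for slide prediction, so they add no
# model passes.

#' Default grade palette
#'
#' @return 3 x 3 matrix of RGB rows: grade 1 green, 2 blue, 3 yellow.
#' @export
grade_palette <- function() {
  rbind(`1` = c(0, 170, 0),
        `2` = c(0, 90, 200),
        `3` = c(235, 200, 0)) / 255
}

#' Build a tile-prediction map on the downsampled canvas
#'
#' @param image Full-resolution h x w x 3 slide array.
#' @param tiles data.frame of tile records ([extract_tiles()]).
#' @param probs n x K matrix of tile probabilities (already computed by
#'   the pipeline; no model is invoked here).
#' @param factor Downsampling factor (32).
#' @param palette Grade-to-RGB matrix, rows = grades.
#' @param alpha Blend weight of the class colour over the thumbnail.
#' @return Object of class `pathomil_prediction_map`: list with
#'   `canvas` (downsampled RGB array with painted blocks), `legend`,
#'   `tile_grades`, `worst` (worst tile record with its probs).
#' @export
build_prediction_map <- function(image, tiles, probs, factor = 32L,
                                 palette = grade_palette(), alpha = 0.45) {
  stopifnot(nrow(tiles) == nrow(probs))
  canvas <- downsample_rgb(image, factor)
  grades <- max.col(as.matrix(probs), ties.method = "first")
  for (i in seq_len(nrow(tiles))) {
    side <- tiles$size[i] %/% factor
    ys <- tiles$y[i] %/% factor + seq_len(side)
    xs <- tiles$x[i] %/% factor + seq_len(side)
    if (max(ys) > nrow(canvas) || max(xs) > ncol(canvas)) {
      stop("tile footprint falls outside the canvas (coordinate bug)")
    }
    col <- palette[grades[i], ]
    for (ch in 1:3) {
      canvas[ys, xs, ch] <- (1 - alpha) * canvas[ys, xs, ch] + alpha * col[ch]
    }
  }
  w <- if (nrow(tiles)) worst_tile(tiles, probs) else NULL
  structure(list(canvas = canvas,
                 legend = c(`1` = "green", `2` = "blue", `3` = "yellow"),
                 tile_grades = grades, worst = w),
            class = "pathomil_prediction_map")
}

#' The clinically worst tile of a slide
#'
#' The tile with the highest expected score (ties to the lowest tile
#' index); equals top-1 selection by [rank_and_select()].
#'
#' @param tiles data.frame of tile records.
#' @param probs n x K matrix of tile probabilities.
#' @return List with `tile` (the record row), `grade` (its argmax),
#'   `probs`, `expected`, `row` (position in `tiles`).
#' @export
worst_tile <- function(tiles, probs) {
  probs <- as.matrix(probs)
  if (nrow(tiles) == 0L) stop("no tiles")
  e <- expected_score(probs)
  i <- order(-e, seq_len(nrow(tiles)))[1L]
  list(tile = tiles[i, , drop = FALSE],
       grade = which.max(probs[i, ]),
       probs = probs[i, ], expected = e[i], row = i)
}

#' Write a prediction map and its sidecar to disk
#'
#' Writes the canvas PNG and a JSON sidecar with per-tile grades and
#' coordinates.
#'
#' @param map A `pathomil_prediction_map`.
#' @param tiles The tile records used to build it.
#' @param path Output PNG path (the sidecar gets extension `.json`).
#' @return Invisibly, the PNG path.
#' @export
write_prediction_map <- function(map, tiles, path) {
  png::writePNG(map$canvas, path)
  sidecar <- lapply(seq_len(nrow(tiles)), function(i) {
    list(x = tiles$x[i], y = tiles$y[i], size = tiles$size[i],
         grade = map$tile_grades[i])
  })
  jsonlite::write_json(sidecar, sub("\\.png$", ".json", path),
                       auto_unbox = TRUE)
  invisible(path)
}
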