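# Frame-level breakup detection: classify overlapping 96x96 tiles of the
# central 384x384 region of interest and call the frame positive when the
# number of breakup-labeled tiles reaches a threshold. The integer tile
# count doubles as the sweepable score for ROC analysis.

#' Central region of interest of a frame
#'
#' Axis-aligned centered crop with floor rounding of the origin; for a
#' 640x480 frame and the default 384 px ROI the origin is (48, 128)
#' (0-based row, col).
#'
#' @param frame H x W x 3 image, at least `size` in both dimensions.
#' @param size ROI side in px.
#' @return List with `image` (the crop) and `origin` (0-based row, col).
#' @export
central_roi <- function(frame, size = 384) {
  assert_rgb(frame, "frame")
  h <- dim(frame)[1]; w <- dim(frame)[2]
  if (h < size || w < size)
    stop_invalid("frame %dx%d is smaller than the %d px ROI", h, w, size)
  rect <- roi_rect(h, w, size)
  list(image = frame[rect$rows, rect$cols, , drop = FALSE],
       origin = rect$origin)
}

#' Tile a region of interest into overlapping patches
#'
#' Tiles at origins 0, stride, 2 stride, ... along both axes. The detection
#' geometry (384 px ROI, 96 px patches, 48 px stride) yields a 7x7 grid of
#' 49 tiles in which adjacent tiles share a 48 px band, so no location can
#' fall between classification windows.
#'
#' @param roi_size Side of the (square) region of interest, px.
#' @param patch_size Tile side, px.
#' @param stride Step between tile origins, px; `roi_size - patch_size`
#'   must be divisible by it.
#' @return An object of class `tile_grid`: `origins` (n x 2 matrix of
#'   0-based row/col, row-major order), `patch_size`, `stride`,
#'   `per_axis`, `n`.
#' @export
tile_frame <- function(roi_size = 384, patch_size = 96, stride = 48) {
  if (patch_size > roi_size)
    stop_invalid("patch_size exceeds roi_size")
  rem <- (roi_size - patch_size) %% stride
  if (rem != 0)
    stop_invalid("(roi_size - patch_size) %% stride = %d, not 0", rem)
  patch_size <- as.integer(patch_size)
  stride <- as.integer(stride)
  roi_size <- as.integer(roi_size)
  per_axis <- (roi_size - patch_size) %/% stride + 1L
  starts <- seq(0L, by = stride, length.out = per_axis)
  origins <- cbind(row = rep(starts, each = per_axis),
                   col = rep(starts, times = per_axis))
  structure(list(origins = origins, patch_size = patch_size,
                 stride = stride, roi_size = roi_size,
                 per_axis = per_axis, n = nrow(origins)),
            class = "tile_grid")
}

#' @export
print.tile_grid <- function(x, ...) {
  cat(sprintf("Tile grid: %dx%d = %d tiles of %d px, stride %d, on %d px ROI\n",
              x$per_axis, x$per_axis, x$n, x$patch_size, x$stride,
              x$roi_size))
  invisible(x)
}

# Crop the tiles of a grid out of an ROI image, in grid order.
crop_tiles <- function(roi_image, grid) {
  lapply(seq_len(grid$n), function(i) {
    r0 <- grid$origins[i, 1]; c0 <- grid$origins[i, 2]
    roi_image[(r0 + 1):(r0 + grid$patch_size),
              (c0 + 1):(c0 + grid$patch_size), , drop = FALSE]
  })
}

#' Classify every tile of a frame
#'
#' Crops the central ROI, tiles it, and applies the patch classifier to each
#' tile independently; results follow the grid's row-major tile order.
#'
#' @param frame H x W x 3 image.
#' @param model A `tbd_head`.
#' @param backbone The backbone the head was trained on.
#' @param roi_size,patch_size,stride Detection geometry.
#' @return List with `labels` (per-tile class), `proba` (n x 9 matrix),
#'   `grid` and `roi_origin`.
#' @export
classify_frame <- function(frame, model, backbone, roi_size = 384,
                           patch_size = 96, stride = 48) {
  roi <- central_roi(frame, roi_size)
  grid <- tile_frame(roi_size, patch_size, stride)
  tiles <- crop_tiles(roi$image, grid)
  proba <- predict_proba(model, backbone, tiles)
  labels <- model$class_order[max.col(proba, ties.method = "first")]
  list(labels = labels, proba = proba, grid = grid,
       roi_origin = roi$origin)
}

#' Frame-level breakup decision from tile labels
#'
#' Counts tiles labeled with any breakup class (area, spot or line); the
#' frame is called breakup-positive when the count is greater than or equal
#' to `min_breakup_tiles` (inclusive rule).
#'
#' @param labels Per-tile class labels.
#' @param min_breakup_tiles Minimum breakup tiles for a positive call
#'   (>= 1; the default 1 is the most sensitive inclusive reading, and the
#'   ROC sweep covers all thresholds anyway).
#' @return An object of class `frame_decision`: `breakup`,
#'   `breakup_tile_count`, `score`, `per_class_tile_counts`,
#'   `min_breakup_tiles`, `tile_classes`.
#' @export
decide_frame <- function(labels, min_breakup_tiles = 1) {
  if (min_breakup_tiles < 1) stop_invalid("min_breakup_tiles must be >= 1")
  bad <- setdiff(unique(labels), tbd_classes())
  if (length(bad)) stop_invalid("unknown tile label '%s'", bad[1])
  per_class <- table(factor(labels, levels = tbd_classes()))
  count <- sum(per_class[tbd_breakup_classes()])
  structure(list(breakup = count >= min_breakup_tiles,
                 breakup_tile_count = as.integer(count),
                 score = as.integer(count),
                 per_class_tile_counts = per_class,
                 min_breakup_tiles = min_breakup_tiles,
                 tile_classes = labels),
            class = "frame_decision")
}

#' @export
print.frame_decision <- function(x, ...) {
  cat(sprintf("Frame decision: %s (%d breakup tile(s), threshold %d)\n",
              if (x$breakup) "BREAKUP" else "no breakup",
              x$breakup_tile_count, x$min_breakup_tiles))
  invisible(x)
}

#' Integer frame score for ROC analysis
#'
#' The number of breakup-labeled tiles (0 to the tile count). By
#' construction `decide_frame(labels, n)$breakup` is exactly `score >= n`,
#' so sweeping `n` over the integers traces the ROC curve of the decision
#' rule. A probability-sum alternative (`mode = "probability"`, requires the
#' tile probability matrix) sums the breakup-class probability mass over
#' tiles.
#'
#' @param labels Per-tile class labels.
#' @param mode `"count"` (default) or `"probability"`.
#' @param proba Tile probability matrix (for `mode = "probability"`).
#' @return A numeric score (integer-valued for `"count"`).
#' @export
frame_score <- function(labels, mode = c("count", "probability"),
                        proba = NULL) {
  mode <- match.arg(mode)
  if (mode == "count")
    return(sum(labels %in% tbd_breakup_classes()))
  if (is.null(proba)) stop_invalid("probability score needs `proba`")
  sum(proba[, tbd_breakup_classes(), drop = FALSE])
}

#' Overlay tile classifications on a frame
#'
#' Semi-transparent fill over breakup-labeled tiles: purple for area, blue
#' for spot, green for line; non-breakup tiles are unmarked. Overlapping
#' tiles of the same class tint their union once (single-pass mask
#' rendering, no double blending); where patterns overlap, the class
#' earlier in the canonical order wins.
#'
#' @param frame H x W x 3 image.
#' @param labels Per-tile labels aligned with `grid`.
#' @param grid A [tile_frame()] grid.
#' @param roi_origin 0-based (row, col) of the ROI in the frame.
#' @param alpha Blend weight of the tint.
#' @return The annotated H x W x 3 image.
#' @export
render_overlay <- function(frame, labels, grid,
                           roi_origin = central_roi(frame)$origin,
                           alpha = 0.35) {
  assert_rgb(frame, "frame")
  if (length(labels) != grid$n)
    stop_invalid("%d labels for %d tiles", length(labels), grid$n)
  colors <- list(area = c(0.5, 0, 0.5), spot = c(0, 0, 1), line = c(0, 1, 0))
  h <- dim(frame)[1]; w <- dim(frame)[2]
  # per-pixel class map built first, so every tinted pixel blends exactly once
  class_map <- matrix(0L, h, w)
  for (ci in rev(seq_along(tbd_breakup_classes()))) {
    cls <- tbd_breakup_classes()[ci]
    for (i in which(labels == cls)) {
      r0 <- roi_origin[1] + grid$origins[i, 1]
      c0 <- roi_origin[2] + grid$origins[i, 2]
      class_map[(r0 + 1):(r0 + grid$patch_size),
                (c0 + 1):(c0 + grid$patch_size)] <- ci
    }
  }
  for (ci in seq_along(tbd_breakup_classes())) {
    mask <- class_map == ci
    if (!any(mask)) next
    col <- colors[[tbd_breakup_classes()[ci]]]
    for (k in 1:3) {
      ch <- frame[, , k]
      ch[mask] <- (1 - alpha) * ch[mask] + alpha * col[k]
      frame[, , k] <- ch
    }
  }
  frame
}
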