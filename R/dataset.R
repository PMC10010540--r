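# Patch dataset management: manifests, on-the-fly augmentation, and input
# preparation for the classifier (96x96 patches resized to the backbone's
# input resolution).

#' Augmentation policy for training patches
#'
#' The training protocol uses scaling, horizontal and vertical shifting and
#' horizontal flipping. Vertical flipping is never applied: several breakup
#' patterns have vertically oriented shape characteristics.
#'
#' @param scale_range Multiplicative scale bounds.
#' @param shift_range Maximum shift as a fraction of the patch side, applied
#'   independently horizontally and vertically.
#' @param hflip_probability Probability of a horizontal flip.
#' @param vflip_enabled Must be `FALSE`; present so that the constraint is
#'   explicit and testable.
#' @return An object of class `augmentation_policy`.
#' @export
augmentation_policy <- function(scale_range = c(0.9, 1.1), shift_range = 0.1,
                                hflip_probability = 0.5,
                                vflip_enabled = FALSE) {
  if (isTRUE(vflip_enabled))
    stop_invalid("vertical flipping is not permitted by the training protocol")
  if (length(scale_range) != 2L || any(scale_range <= 0) ||
      scale_range[1] > scale_range[2])
    stop_invalid("scale_range must be positive increasing bounds")
  if (shift_range < 0 || shift_range >= 1)
    stop_invalid("shift_range must be in [0, 1)")
  if (hflip_probability < 0 || hflip_probability > 1)
    stop_invalid("hflip_probability must be in [0, 1]")
  structure(list(scale_range = scale_range, shift_range = shift_range,
                 hflip_probability = hflip_probability,
                 vflip_enabled = FALSE),
            class = "augmentation_policy")
}

# Reflect a (possibly fractional) coordinate into [1, n].
reflect_coord <- function(x, n) {
  if (n == 1L) return(rep(1, length(x)))
  p <- 2 * (n - 1)
  y <- (x - 1) %% p
  ifelse(y > (n - 1), p - y, y) + 1
}

# Bilinear sampling of an RGB array at fractional (row, col) coordinate
# grids, with reflection padding at the borders.
bilinear_sample <- function(img, rcoord, ccoord) {
  h <- dim(img)[1]; w <- dim(img)[2]
  shape <- dim(rcoord)
  fr <- reflect_coord(as.vector(rcoord), h)
  fc <- reflect_coord(as.vector(ccoord), w)
  r0 <- if (h == 1L) rep(1, length(fr)) else pmin(floor(fr), h - 1)
  c0 <- if (w == 1L) rep(1, length(fc)) else pmin(floor(fc), w - 1)
  r1 <- pmin(r0 + 1, h); c1 <- pmin(c0 + 1, w)
  wr <- fr - r0; wc <- fc - c0
  out <- array(0, c(shape, 3))
  for (k in 1:3) {
    ch <- img[, , k]
    v <- (1 - wr) * (1 - wc) * ch[cbind(r0, c0)] +
      (1 - wr) * wc * ch[cbind(r0, c1)] +
      wr * (1 - wc) * ch[cbind(r1, c0)] +
      wr * wc * ch[cbind(r1, c1)]
    out[, , k] <- matrix(v, shape[1], shape[2])
  }
  out
}

#' Randomly augment a training patch
#'
#' Applies a random scale drawn from the policy's range, random horizontal
#' and vertical shifts (reflection padding at the borders, so no black edges
#' that could mimic the Eyelid class), and a horizontal flip with the
#' configured probability. Uses the current RNG stream; label metadata is
#' untouched. Output shape equals input shape.
#'
#' @param image H x W x 3 patch.
#' @param policy An [augmentation_policy()].
#' @return The augmented patch.
#' @export
augment <- function(image, policy = augmentation_policy()) {
  assert_rgb(image, "patch")
  stopifnot(inherits(policy, "augmentation_policy"))
  h <- dim(image)[1]; w <- dim(image)[2]
  s <- stats::runif(1, policy$scale_range[1], policy$scale_range[2])
  dy <- stats::runif(1, -policy$shift_range, policy$shift_range) * h
  dx <- stats::runif(1, -policy$shift_range, policy$shift_range) * w
  flip <- stats::runif(1) < policy$hflip_probability
  rows <- seq_len(h); cols <- seq_len(w)
  if (flip) cols_src <- (w + 1) - cols else cols_src <- cols
  cy <- (h + 1) / 2; cx <- (w + 1) / 2
  src_r <- (rows - cy) / s + cy - dy
  src_c <- (cols_src - cx) / s + cx - dx
  if (s == 1 && dx == 0 && dy == 0) {
    # exact integer grid: avoid interpolation round-off in the identity case
    ri <- round(reflect_coord(src_r, h)); ci <- round(reflect_coord(src_c, w))
    return(image[ri, ci, , drop = FALSE])
  }
  bilinear_sample(image, matrix(src_r, h, w), matrix(src_c, h, w, byrow = TRUE))
}

# General bilinear resize (pixel-center alignment convention).
resize_bilinear <- function(img, h_out, w_out) {
  h <- dim(img)[1]; w <- dim(img)[2]
  src_r <- (seq_len(h_out) - 0.5) * h / h_out + 0.5
  src_c <- (seq_len(w_out) - 0.5) * w / w_out + 0.5
  bilinear_sample(img, matrix(src_r, h_out, w_out),
                  matrix(src_c, h_out, w_out, byrow = TRUE))
}

#' Resize a 96x96 patch to the classifier input resolution
#'
#' Bilinear interpolation from 96x96x3 to 224x224x3 (pixel-center aligned);
#' values stay within the input range.
#'
#' @param image 96 x 96 x 3 patch.
#' @param size Output side (default 224).
#' @return `size` x `size` x 3 array.
#' @export
resize_to_input <- function(image, size = 224) {
  assert_rgb(image, "patch")
  if (dim(image)[1] != 96 || dim(image)[2] != 96)
    stop_invalid("expected a 96x96x3 patch, got %dx%dx%d",
                 dim(image)[1], dim(image)[2], dim(image)[3])
  resize_bilinear(image, size, size)
}

validate_manifest_df <- function(df, check_files = FALSE) {
  req <- c("path", "class", "video_id", "eye_id", "subject_id")
  missing_cols <- setdiff(req, names(df))
  if (length(missing_cols))
    stop_invalid("manifest is missing column(s): %s",
                 paste(missing_cols, collapse = ", "))
  bad <- which(!df$class %in% tbd_classes())
  if (length(bad))
    stop_invalid("unknown class label '%s' in manifest row %d",
                 df$class[bad[1]], bad[1])
  if (check_files && nrow(df)) {
    missing_files <- df$path[!file.exists(df$path)]
    if (length(missing_files))
      stop_invalid("manifest references missing file(s), first: %s",
                   missing_files[1])
  }
  df[req]
}

#' Build a patch manifest from a data frame or patch set
#'
#' @param x A data frame with columns `path`, `class`, `video_id`, `eye_id`,
#'   `subject_id`, or a `patch_set` from [emit_labeled_patches()] (in-memory
#'   images travel in the `images` attribute, `path` is empty).
#' @return An object of class `patch_manifest` (a data frame).
#' @export
as_patch_manifest <- function(x) {
  if (inherits(x, "patch_set")) {
    df <- data.frame(
      path = rep("", length(x)),
      class = vapply(x, `[[`, "", "label"),
      video_id = vapply(x, `[[`, "", "video_id"),
      eye_id = vapply(x, `[[`, "", "eye_id"),
      subject_id = vapply(x, `[[`, "", "subject_id"),
      stringsAsFactors = FALSE)
    df <- validate_manifest_df(df)
    attr(df, "images") <- lapply(x, `[[`, "image")
  } else {
    df <- validate_manifest_df(as.data.frame(x, stringsAsFactors = FALSE))
  }
  class(df) <- c("patch_manifest", "data.frame")
  df
}

#' Load a patch manifest CSV
#'
#' @param path CSV with header `path,class,video_id,eye_id,subject_id`.
#' @param check_files Verify that referenced patch files exist.
#' @return A `patch_manifest`.
#' @export
load_manifest <- function(path, check_files = TRUE) {
  if (!file.exists(path)) stop_invalid("manifest file not found: %s", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character")
  df$path <- resolve_paths(df$path, dirname(path))
  df <- validate_manifest_df(df, check_files = check_files)
  class(df) <- c("patch_manifest", "data.frame")
  df
}

#' Save a patch manifest CSV
#'
#' Round-trips with [load_manifest()]: records and their order are preserved.
#'
#' @param manifest A `patch_manifest`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
save_manifest <- function(manifest, path) {
  df <- validate_manifest_df(as.data.frame(manifest))
  utils::write.csv(df, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' Write a patch set to disk as PNGs plus a manifest
#'
#' @param patches A `patch_set`.
#' @param dir Output directory (created if needed); patches are written as
#'   `patch_<index>_<class>.png`.
#' @return The on-disk `patch_manifest`.
#' @export
write_patch_set <- function(patches, dir) {
  stopifnot(inherits(patches, "patch_set"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(length(patches))
  for (i in seq_along(patches)) {
    paths[i] <- file.path(dir, sprintf("patch_%04d_%s.png", i,
                                       patches[[i]]$label))
    write_image_png(patches[[i]]$image, paths[i])
  }
  m <- as_patch_manifest(patches)
  m$path <- paths
  attr(m, "images") <- NULL
  m
}

#' Per-class patch tallies
#'
#' @param manifest A `patch_manifest` (or any data frame with a `class`
#'   column of valid labels).
#' @return Named integer vector over the nine classes in canonical order,
#'   with a `total` attribute equal to the record count.
#' @export
class_counts <- function(manifest) {
  cls <- factor(manifest$class, levels = tbd_classes())
  counts <- table(cls)
  out <- stats::setNames(as.integer(counts), names(counts))
  attr(out, "total") <- sum(out)
  out
}

# Fetch the i-th patch image of a manifest (in-memory attribute or PNG).
manifest_image <- function(manifest, i) {
  imgs <- attr(manifest, "images")
  if (!is.null(imgs)) return(imgs[[i]])
  read_image_png(manifest$path[i])
}
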