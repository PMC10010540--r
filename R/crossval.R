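# Video-grouped six-fold cross-validation. All patches extracted from one
# video (and, by default, from the same subject) share a group, so no video
# ever spans train/validation/test; groups are balanced by class so that no
# group is starved of any patch class.

#' Assign videos to balanced cross-validation groups
#'
#' Greedy longest-first bin packing: assignment units (subjects by default,
#' so both eyes of one person share a group; videos if
#' `group_by_subject = FALSE`) are sorted by descending patch count and each
#' is placed into the group minimising a class-imbalance cost (the sum over
#' classes of squared deviation from the running per-group mean).
#' Deterministic for a fixed seed and invariant to the input record order.
#'
#' @param manifest A `patch_manifest` (or data frame with `class`,
#'   `video_id`, `eye_id`, `subject_id` columns).
#' @param k Number of groups (default 6).
#' @param seed Seed used to break exact cost ties.
#' @param tolerance Advisory relative deviation of per-group class counts
#'   from the ideal mean; exceeding it (which greedy packing may be forced
#'   into by large videos) triggers a warning, not an error.
#' @param group_by_subject Keep all videos of a subject in one group.
#' @return An object of class `fold_assignment`: `group_of_video` (named
#'   character vector video_id -> group label), `group_class_counts`
#'   (k x 9 matrix), `group_eye_counts`, `labels`.
#' @export
assign_groups <- function(manifest, k = 6, seed = 0L, tolerance = 0.3,
                          group_by_subject = TRUE) {
  if (k < 2) stop_invalid("k must be >= 2")
  if (!nrow(manifest)) stop_invalid("manifest is empty")
  unit_col <- if (group_by_subject) "subject_id" else "video_id"
  units <- unique(manifest[[unit_col]])
  if (length(units) < k)
    stop_invalid("only %d %ss for %d groups: infeasible",
                 length(units), sub("_id$", "", unit_col), k)
  classes <- tbd_classes()
  # per-unit class count matrix
  tab <- table(factor(manifest[[unit_col]], levels = sort(units)),
               factor(manifest$class, levels = classes))
  counts <- matrix(as.integer(tab), nrow = nrow(tab),
                   dimnames = dimnames(tab))
  ord <- order(-rowSums(counts), rownames(counts))
  counts <- counts[ord, , drop = FALSE]
  labels <- LETTERS[seq_len(k)]
  group_counts <- matrix(0L, k, length(classes),
                         dimnames = list(labels, classes))
  group_of_unit <- stats::setNames(character(nrow(counts)),
                                   rownames(counts))
  tie_rng <- with_local_seed(derive_seed(seed, "assign"),
                             stats::runif(nrow(counts)))
  filled <- logical(k)
  for (u in seq_len(nrow(counts))) {
    cost <- numeric(k)
    for (g in seq_len(k)) {
      trial <- group_counts
      trial[g, ] <- trial[g, ] + counts[u, ]
      mu <- colMeans(trial)
      cost[g] <- sum(sweep(trial, 2, mu)^2)
    }
    # every group must end up non-empty for the fold rotation to be
    # meaningful: while some are still empty, place only into those
    candidates <- if (all(filled)) seq_len(k) else which(!filled)
    cost[setdiff(seq_len(k), candidates)] <- Inf
    best <- which(cost <= min(cost) + 1e-9)
    pick <- if (length(best) == 1L) best else
      best[1L + floor(tie_rng[u] * length(best)) %% length(best)]
    group_counts[pick, ] <- group_counts[pick, ] + counts[u, ]
    filled[pick] <- TRUE
    group_of_unit[u] <- labels[pick]
  }
  # map back to videos
  vid_unit <- unique(manifest[c("video_id", unit_col)])
  group_of_video <- stats::setNames(group_of_unit[vid_unit[[unit_col]]],
                                    vid_unit$video_id)
  eyes <- unique(manifest[c("eye_id", "video_id")])
  eye_groups <- group_of_video[eyes$video_id]
  group_eye_counts <- table(factor(eye_groups, levels = labels))
  ideal <- colSums(group_counts) / k
  present <- ideal > 0
  reldev <- abs(sweep(group_counts[, present, drop = FALSE], 2,
                      ideal[present]) ) /
    matrix(ideal[present], k, sum(present), byrow = TRUE)
  if (max(reldev) > tolerance)
    warning(sprintf("max relative class deviation %.2f exceeds tolerance %.2f",
                    max(reldev), tolerance), call. = FALSE)
  structure(list(group_of_video = group_of_video,
                 group_class_counts = group_counts,
                 group_eye_counts = group_eye_counts,
                 max_relative_deviation = max(reldev),
                 labels = labels, k = k),
            class = "fold_assignment")
}

#' @export
print.fold_assignment <- function(x, ...) {
  cat(sprintf("Grouped CV assignment: %d videos in %d groups\n",
              length(x$group_of_video), x$k))
  print(x$group_class_counts)
  cat(sprintf("max relative class deviation: %.3f\n",
              x$max_relative_deviation))
  invisible(x)
}

#' Train/validation/test rotation plan
#'
#' For six groups, fold 1 trains on \{A, B, C, D\}, validates on E and tests
#' on F; each subsequent fold rotates the group sequence right by one
#' position (fold 2: train \{F, A, B, C\}, validation D, test E), so every
#' group serves as validation exactly once and as test exactly once. For
#' other `k` the same cyclic construction is used with `k - 2` training
#' groups.
#'
#' @param k Number of groups (>= 3).
#' @return An object of class `rotation_plan`: a list of `k` folds, each
#'   with `training`, `validation`, `test` group labels.
#' @export
rotation_plan <- function(k = 6) {
  if (k < 3) stop_invalid("k must be >= 3 (train/validation/test)")
  labels <- LETTERS[seq_len(k)]
  folds <- lapply(seq_len(k), function(i) {
    seqi <- labels[((seq_len(k) - i) %% k) + 1]  # rotate right by i - 1
    list(training = seqi[seq_len(k - 2)], validation = seqi[k - 1],
         test = seqi[k])
  })
  structure(list(folds = folds, k = k, labels = labels),
            class = "rotation_plan")
}

#' @export
print.rotation_plan <- function(x, ...) {
  cat(sprintf("%d-fold rotation plan\n", x$k))
  for (i in seq_along(x$folds)) {
    f <- x$folds[[i]]
    cat(sprintf("  fold %d: train {%s} | validation %s | test %s\n", i,
                paste(f$training, collapse = ","), f$validation, f$test))
  }
  invisible(x)
}

#' Materialise one cross-validation fold
#'
#' Splits the manifest records into train / validation / test according to
#' the group each record's video belongs to. The three parts are disjoint
#' and their union is the whole manifest.
#'
#' @param manifest A `patch_manifest`.
#' @param assignment A [assign_groups()] result.
#' @param plan A [rotation_plan()].
#' @param fold_index Fold number in `1..k`.
#' @return List with `train`, `validation`, `test` manifests (in-memory
#'   images, if any, are carried along).
#' @export
materialize_fold <- function(manifest, assignment, plan, fold_index) {
  stopifnot(inherits(assignment, "fold_assignment"),
            inherits(plan, "rotation_plan"))
  if (fold_index < 1 || fold_index > plan$k)
    stop_invalid("fold_index must be in 1..%d", plan$k)
  fold <- plan$folds[[fold_index]]
  grp <- assignment$group_of_video[manifest$video_id]
  subset_manifest <- function(idx) {
    part <- manifest[idx, , drop = FALSE]
    imgs <- attr(manifest, "images")
    if (!is.null(imgs)) attr(part, "images") <- imgs[idx]
    class(part) <- c("patch_manifest", "data.frame")
    part
  }
  list(train = subset_manifest(which(grp %in% fold$training)),
       validation = subset_manifest(which(grp == fold$validation)),
       test = subset_manifest(which(grp == fold$test)))
}
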