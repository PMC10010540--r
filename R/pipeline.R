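# Pipeline orchestration: reproducible configuration, the synthetic cohort
# commands, cross-validated training/evaluation and frame-level detection
# evaluation. Every stochastic stage derives its stream from the single
# top-level seed via named substreams, so stages can be rerun independently
# and reruns are byte-identical.

#' Pipeline run configuration
#'
#' @param seed Single top-level seed; all stages derive substreams from it.
#' @param out_dir Output directory for on-disk artifacts.
#' @param cohort Simulator parameters: `n_videos`, `duration` (s), `fps`,
#'   `frame_size` (width, height), `frames_per_video` (rendered evaluation
#'   frames sampled from the video timeline), `patches_per_class`,
#'   `max_frames_per_video` (evaluation-frame cap, protocol value 40).
#' @param training A [train_config()] (its seed is derived from `seed`).
#' @param detection `min_breakup_tiles`, `score_mode` ("count" or
#'   "probability"), `roi_size`, `patch_size`, `stride`.
#' @param evaluation `ci_method` ("delong" or "bootstrap").
#' @return An object of class `run_config`.
#' @export
run_config <- function(seed = 1L, out_dir = tempfile("tbd_run_"),
                       cohort = list(), training = NULL,
                       detection = list(), evaluation = list()) {
  cohort <- utils::modifyList(
    list(n_videos = 12L, duration = 30, fps = 30,
         frame_size = c(640L, 480L), frames_per_video = 6L,
         patches_per_class = 50L, max_frames_per_video = 40L), cohort)
  if (is.null(training))
    training <- train_config(seed = derive_seed(seed, "train"))
  detection <- utils::modifyList(
    list(min_breakup_tiles = 1L, score_mode = "count", roi_size = 384L,
         patch_size = 96L, stride = 48L), detection)
  evaluation <- utils::modifyList(list(ci_method = "delong"), evaluation)
  structure(list(seed = as.integer(seed), out_dir = out_dir,
                 cohort = cohort, training = training,
                 detection = detection, evaluation = evaluation),
            class = "run_config")
}

#' Read a run configuration from JSON or YAML
#'
#' @param path Config file; recognised top-level keys are the arguments of
#'   [run_config()].
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  cfg <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE))
    yaml::read_yaml(path) else jsonlite::fromJSON(path)
  tr <- NULL
  if (!is.null(cfg$training))
    tr <- do.call(train_config,
                  cfg$training[names(cfg$training) %in%
                                 names(formals(train_config))])
  run_config(seed = if (is.null(cfg$seed)) 1L else cfg$seed,
             out_dir = if (is.null(cfg$out_dir)) tempfile("tbd_run_")
                       else cfg$out_dir,
             cohort = if (is.null(cfg$cohort)) list() else cfg$cohort,
             training = tr,
             detection = if (is.null(cfg$detection)) list()
                         else cfg$detection,
             evaluation = if (is.null(cfg$evaluation)) list()
                          else cfg$evaluation)
}

#' Printed per-class training-set sizes of the reference protocol
#'
#' The nine-class patch counts of the clinical training set (total 9089),
#' used to shape desk fixtures.
#'
#' @return Named integer vector in canonical class order.
#' @export
reference_class_totals <- function() {
  stats::setNames(c(643L, 684L, 877L, 1099L, 1201L, 1046L, 1230L, 1119L,
                    1190L), tbd_classes())
}

#' Metadata-only synthetic cohort manifest
#'
#' Builds a patch manifest (labels and provenance only, no images) shaped
#' like the reference cohort: `n_eyes` eye videos from `n_subjects`
#' subjects (most subjects contribute both eyes), with the per-class patch
#' totals distributed over videos so that each video carries a sparse mix
#' of classes. Used for split/balance bookkeeping at full cohort scale
#' without rendering anything.
#'
#' @param class_totals Named per-class patch totals.
#' @param n_eyes Number of eye videos.
#' @param n_subjects Number of subjects.
#' @param seed Integer seed.
#' @return A `patch_manifest` with empty `path` entries.
#' @export
synthetic_cohort_manifest <- function(class_totals = reference_class_totals(),
                                      n_eyes = 350L, n_subjects = 178L,
                                      seed = 0L) {
  stopifnot(n_subjects <= n_eyes, n_eyes <= 2L * n_subjects)
  n_both <- n_eyes - n_subjects
  subject <- c(rep(seq_len(n_both), each = 2L),
               seq(n_both + 1L, n_subjects))
  eye_side <- c(rep(c("L", "R"), n_both), rep("L", n_subjects - n_both))
  subject_id <- sprintf("S%03d", subject)
  eye_id <- paste0(subject_id, eye_side)
  video_id <- paste0("V", eye_id)
  rows <- with_local_seed(derive_seed(seed, "cohort_meta"), {
    # each video carries a sparse random mix of classes
    wts <- matrix(stats::rexp(n_eyes * length(class_totals)), n_eyes)
    keep <- t(apply(wts, 1, function(x) x >= sort(x, decreasing = TRUE)[4]))
    wts <- wts * keep
    out <- vector("list", length(class_totals))
    for (ci in seq_along(class_totals)) {
      w <- wts[, ci]
      if (sum(w) == 0) w[sample(n_eyes, 3)] <- 1
      cnt <- as.vector(stats::rmultinom(1, class_totals[ci], w))
      out[[ci]] <- data.frame(
        video = rep(seq_len(n_eyes), cnt),
        class = names(class_totals)[ci], stringsAsFactors = FALSE)
    }
    do.call(rbind, out)
  })
  df <- data.frame(path = "", class = rows$class,
                   video_id = video_id[rows$video],
                   eye_id = eye_id[rows$video],
                   subject_id = subject_id[rows$video],
                   stringsAsFactors = FALSE)
  as_patch_manifest(df)
}

# Patch classes a scene can supply: its background class, its breakup
# patterns and its composited confounder kinds.
classes_of_spec <- function(sp) {
  unique(c(scene_background_class(sp),
           vapply(sp$events, function(e) e$pattern, character(1)),
           vapply(sp$confounders, function(cf) cf$kind, character(1))))
}

# Randomised scene specifications for a rendered desk cohort. Scenes cover
# all nine classes: uniform and fringe backgrounds, the three breakup
# morphologies with post-blink onset and growth, and the four image-space
# confounders.
build_cohort_specs <- function(cohort, seed) {
  n <- cohort$n_videos
  w <- cohort$frame_size[1]; h <- cohort$frame_size[2]
  roi <- roi_rect(h, w, min(384, h, w))
  with_local_seed(derive_seed(seed, "cohort_specs"), {
    lapply(seq_len(n), function(i) {
      subject <- sprintf("S%03d", (i + 1L) %/% 2L)
      eye <- paste0(subject, c("L", "R")[(i %% 2L) + 1L])
      fringe_scene <- i %% 2L == 0L
      base <- if (fringe_scene)
        list(mean = 90, amplitude = 18, corr_len = 70)
      else list(mean = 70, amplitude = 8, corr_len = 90)
      confs <- list()
      if (fringe_scene)
        confs <- c(confs, list(confounder(
          "interference_fringe",
          frequency = stats::runif(1, 0.012, 0.03),
          orientation = stats::runif(1, 0, pi),
          amplitude = stats::runif(1, 30, 50),
          phase = stats::runif(1, 0, 2 * pi))))
      confs <- c(confs, list(confounder(
        "eyelid", side = sample(c("top", "bottom"), 1),
        vertex = h * stats::runif(1, 0.10, 0.16),
        curvature = 1 / (2 * w),
        aperture_radius = 0.52 * min(h, w))))
      if (stats::runif(1) < 0.7) {
        k <- sample(5:12, 1)
        confs <- c(confs, list(confounder(
          "particle",
          centers = cbind(stats::runif(k, roi$rows[1], max(roi$rows)),
                          stats::runif(k, roi$cols[1], max(roi$cols))),
          radii = stats::runif(k, 2, 4))))
      }
      if (stats::runif(1) < 0.6) {
        c0 <- stats::runif(1, roi$cols[1] + 30, max(roi$cols) - 30)
        confs <- c(confs, list(confounder(
          "bright_reflection",
          center = c(stats::runif(1, roi$rows[1] + 30, max(roi$rows) - 30),
                     c0),
          radius = stats::runif(1, 12, 20),
          intensity = stats::runif(1, 0.8, 0.95))))
      }
      if (stats::runif(1) < 0.6) {
        from_top <- stats::runif(1) < 0.5
        cA <- stats::runif(1, w * 0.2, w * 0.8)
        cB <- cA + stats::runif(1, -60, 60)
        edge <- if (from_top) 1 else h
        # Bezier apex sits at half the middle control depth: place the
        # control so the lash tip reaches well past the lid arc
        mid <- if (from_top) h * stats::runif(1, 0.5, 0.9)
               else h * stats::runif(1, 0.1, 0.5)
        confs <- c(confs, list(confounder(
          "eyelash",
          control = rbind(c(edge, cA), c(mid, (cA + cB) / 2), c(edge, cB)),
          width = stats::runif(1, 2, 3.5))))
      }
      events <- list()
      if (i %% 3L != 0L) { # two thirds of videos develop breakup
        j <- i - i %/% 3L   # index among event-bearing videos
        pattern <- tbd_breakup_classes()[(j - 1L) %% 3L + 1L]
        onset <- stats::runif(1, 0.25, 0.5) * cohort$duration
        center <- c(stats::runif(1, roi$rows[1] + 80, max(roi$rows) - 80),
                    stats::runif(1, roi$cols[1] + 80, max(roi$cols) - 80))
        events <- list(switch(
          pattern,
          spot = breakup_event("spot", onset, center,
                               initial_size = stats::runif(1, 18, 28),
                               growth_rate = stats::runif(1, 1, 3),
                               elongation_rate = stats::runif(1, 0, 2)),
          line = breakup_event("line", onset, center,
                               initial_size = stats::runif(1, 14, 20),
                               growth_rate = 0,
                               elongation_rate = stats::runif(1, 4, 9)),
          area = breakup_event("area", onset, center,
                               initial_size = stats::runif(1, 45, 70),
                               growth_rate = stats::runif(1, 2, 5))))
      }
      scene_spec(video_id = sprintf("V%s_%02d", eye, i), eye_id = eye,
                 subject_id = subject, duration = cohort$duration,
                 fps = cohort$fps, frame_size = cohort$frame_size,
                 base_field = base, events = events, confounders = confs,
                 seed = derive_seed(seed, paste0("scene", i)))
    })
  })
}

#' Simulate a synthetic cohort to disk
#'
#' Renders each scene at `frames_per_video` evenly spread evaluation times,
#' writes frames as PNG (`frames/<video_id>/frame_<index>.png`), per-video
#' ground-truth JSON sidecars, a labeled-frame manifest CSV, labeled 96x96
#' patches with their manifest CSV, and a provenance JSON carrying the
#' config, seed and content hashes. Identical config + seed reproduce
#' byte-identical artifacts.
#'
#' @param config A [run_config()].
#' @param model An [optical_model()].
#' @return List with `patch_manifest`, `frame_manifest`, `paths`
#'   (named file locations) and `provenance`.
#' @export
simulate_cohort <- function(config = run_config(),
                            model = optical_model()) {
  stopifnot(inherits(config, "run_config"))
  out <- config$out_dir
  dir.create(file.path(out, "frames"), recursive = TRUE,
             showWarnings = FALSE)
  dir.create(file.path(out, "truth"), recursive = TRUE, showWarnings = FALSE)
  specs <- if (config$cohort$n_videos > 0)
    build_cohort_specs(config$cohort, config$seed) else list()
  frame_rows <- list(); patch_manifest <- NULL
  all_patches <- list()
  ppc <- config$cohort$patches_per_class
  supplier_counts <- table(factor(unlist(lapply(specs, classes_of_spec)),
                                  levels = tbd_classes()))
  remaining <- stats::setNames(rep(ppc, 9L), tbd_classes())
  for (sp in specs) {
    times <- seq(0, sp$duration * (1 - 1 / max(1, config$cohort$frames_per_video)),
                 length.out = config$cohort$frames_per_video)
    video <- render_video(sp, model, times = times,
                          roi_size = config$detection$roi_size)
    vdir <- file.path(out, "frames", sp$video_id)
    dir.create(vdir, showWarnings = FALSE)
    flab <- emit_labeled_frames(video,
                                max_per_video = config$cohort$max_frames_per_video,
                                seed = derive_seed(config$seed, sp$video_id))
    flab$path <- file.path(vdir, sprintf("frame_%03d.png", flab$frame_index))
    for (j in seq_len(nrow(flab)))
      write_image_png(video$frames[[flab$frame_index[j]]], flab$path[j])
    write_report_json(
      list(video_id = sp$video_id, times = flab$time,
           breakup = flab$breakup),
      file.path(out, "truth", paste0(sp$video_id, ".json")))
    frame_rows[[length(frame_rows) + 1L]] <- flab
    for (cls in intersect(classes_of_spec(sp),
                          names(remaining)[remaining > 0])) {
      quota <- min(remaining[cls],
                   ceiling(1.25 * ppc / max(1L, supplier_counts[cls])))
      got <- suppressWarnings(emit_labeled_patches(
        video, patches_per_class = quota, classes = cls,
        seed = derive_seed(config$seed, paste0("p", cls, sp$video_id))))
      remaining[cls] <- remaining[cls] - length(got)
      all_patches <- c(all_patches, got)
    }
  }
  if (any(remaining > 0) && ppc > 0)
    warning(sprintf("patch shortfall: %s",
                    paste(sprintf("%s %d", names(remaining)[remaining > 0],
                                  remaining[remaining > 0]),
                          collapse = ", ")), call. = FALSE)
  frame_manifest <- if (length(frame_rows)) do.call(rbind, frame_rows)
    else data.frame(video_id = character(0), frame_index = integer(0),
                    time = numeric(0), breakup = logical(0),
                    path = character(0))
  patch_set <- structure(all_patches, class = "patch_set")
  patch_manifest <- if (length(all_patches))
    write_patch_set(patch_set, file.path(out, "patches"))
  else as_patch_manifest(data.frame(path = character(0),
                                    class = character(0),
                                    video_id = character(0),
                                    eye_id = character(0),
                                    subject_id = character(0)))
  paths <- list(
    patch_manifest = file.path(out, "patch_manifest.csv"),
    frame_manifest = file.path(out, "frame_manifest.csv"),
    provenance = file.path(out, "provenance.json"))
  # manifests are written with paths relative to the run directory so that
  # rerunning the same config in another location is byte-identical
  relativize <- function(df) {
    df$path <- ifelse(df$path == "", "",
                      substring(df$path, nchar(out) + 2L))
    df
  }
  save_manifest(relativize(patch_manifest), paths$patch_manifest)
  utils::write.csv(relativize(frame_manifest), paths$frame_manifest,
                   row.names = FALSE)
  files <- sort(c(list.files(file.path(out, "frames"), recursive = TRUE,
                             full.names = TRUE),
                  list.files(file.path(out, "patches"), full.names = TRUE),
                  paths$patch_manifest, paths$frame_manifest))
  hashes <- as.list(tools::md5sum(files))
  names(hashes) <- substring(names(hashes), nchar(out) + 2L)
  provenance <- list(seed = config$seed, cohort = config$cohort,
                     n_videos = length(specs),
                     n_patches = nrow(patch_manifest),
                     n_frames = nrow(frame_manifest),
                     content_hashes = hashes)
  write_report_json(provenance, paths$provenance)
  list(patch_manifest = patch_manifest, frame_manifest = frame_manifest,
       paths = paths, provenance = provenance)
}

#' Load a labeled-frame manifest CSV
#'
#' Reads the frame manifest written by [simulate_cohort()], resolving
#' relative frame paths against the manifest's own directory.
#'
#' @param path Frame manifest CSV.
#' @return Data frame with `video_id`, `frame_index`, `time`, `breakup`,
#'   `path`.
#' @export
load_frame_manifest <- function(path) {
  if (!file.exists(path)) stop_invalid("frame manifest not found: %s", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  df$breakup <- as.logical(df$breakup)
  df$path <- resolve_paths(df$path, dirname(path))
  df
}

#' Cross-validated training and evaluation of the patch classifier
#'
#' Runs the full grouped protocol: balanced group assignment, the rotation
#' plan, one head trained per fold, per-fold test confusion matrices, pooled
#' nine-class and binary metrics, and the fold mean +/- SD summary.
#'
#' @param manifest A `patch_manifest` with images (in-memory or on disk).
#' @param backbone A `tbd_backbone`.
#' @param config A [run_config()]; its `training` element and seed are used.
#' @param k Number of folds.
#' @param report_path Optional path for the JSON report.
#' @return An object of class `tbd_cv_report`: `fold_results` (with per-fold
#'   heads), `pooled_confusion`, `pooled_metrics`, `binary`,
#'   `fold_summary`, `assignment`, `plan`.
#' @export
run_crossval <- function(manifest, backbone = conv_backbone(),
                         config = run_config(), k = 6,
                         report_path = NULL) {
  if (!nrow(manifest)) stop_invalid("patch manifest is empty")
  assignment <- assign_groups(manifest, k = k,
                              seed = derive_seed(config$seed, "split"))
  plan <- rotation_plan(k)
  folds <- list()
  pooled <- NULL
  fold_rows <- list()
  for (i in seq_len(k)) {
    parts <- materialize_fold(manifest, assignment, plan, i)
    cfg <- config$training
    cfg$seed <- derive_seed(config$seed, paste0("fold", i))
    model <- train_head(parts$train, parts$validation, backbone, cfg)
    te <- training_records(parts$test)
    pred <- if (length(te$images))
      predict_class(model, backbone, te$images) else character(0)
    cm <- confusion(te$labels, pred)
    pooled <- if (is.null(pooled)) unclass(cm) else pooled + unclass(cm)
    pm <- per_class_metrics(cm)
    bin <- aggregate_binary(cm)
    fold_rows[[i]] <- data.frame(
      accuracy = pm$accuracy,
      recall = mean(pm$table$recall, na.rm = TRUE),
      precision = mean(pm$table$precision, na.rm = TRUE),
      f1 = mean(pm$table$f1, na.rm = TRUE),
      binary_accuracy = bin$accuracy,
      sensitivity = bin$sensitivity,
      specificity = bin$specificity)
    folds[[i]] <- list(model = model, confusion = cm, metrics = pm,
                       binary = bin, n_test = nrow(parts$test))
  }
  pooled <- structure(pooled, class = c("confusion_matrix", "matrix"))
  fold_df <- do.call(rbind, fold_rows)
  report <- structure(
    list(fold_results = folds, pooled_confusion = pooled,
         pooled_metrics = per_class_metrics(pooled),
         binary = aggregate_binary(pooled),
         fold_summary = crossval_summary(fold_df),
         per_fold = fold_df,
         assignment = assignment, plan = plan,
         data_provenance = "synthetic",
         seed = config$seed, k = k),
    class = "tbd_cv_report")
  if (!is.null(report_path)) write_cv_report(report, report_path)
  report
}

#' @export
print.tbd_cv_report <- function(x, ...) {
  cat(sprintf("%d-fold grouped cross-validation (%s data)\n", x$k,
              x$data_provenance))
  cat(sprintf("  pooled 9-class accuracy: %.1f%%\n",
              100 * x$pooled_metrics$accuracy))
  cat(sprintf("  pooled binary: accuracy %.1f%%, sensitivity %.1f%%, specificity %.1f%%\n",
              100 * x$binary$accuracy, 100 * x$binary$sensitivity,
              100 * x$binary$specificity))
  invisible(x)
}

#' Write a cross-validation report as JSON
#'
#' Embeds the exact configuration, the group assignment, per-fold and pooled
#' metrics; deterministic content for a fixed input.
#'
#' @param report A `tbd_cv_report`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cv_report <- function(report, path) {
  payload <- list(
    data_provenance = report$data_provenance,
    seed = report$seed, k = report$k,
    group_of_video = as.list(report$assignment$group_of_video),
    group_class_counts = report$assignment$group_class_counts,
    rotation = lapply(report$plan$folds, function(f)
      list(training = f$training, validation = f$validation,
           test = f$test)),
    pooled_confusion = unclass(report$pooled_confusion),
    pooled_accuracy = report$pooled_metrics$accuracy,
    per_class = report$pooled_metrics$table,
    binary = report$binary[c("accuracy", "sensitivity", "specificity")],
    per_fold = report$per_fold,
    fold_summary = report$fold_summary)
  write_report_json(payload, path)
}

#' Frame-level detection evaluation with ROC analysis
#'
#' Scores every labeled frame (breakup-tile count by default), writes the
#' per-frame CSV and optional class-colored overlays, and reports
#' ROC/AUC with its 95% CI plus the operating point at the configured
#' tile threshold.
#'
#' @param frame_manifest Data frame with `path`, `video_id`, `breakup`
#'   columns (as produced by [simulate_cohort()]).
#' @param model A trained `tbd_head`.
#' @param backbone The matching backbone.
#' @param config A [run_config()] (detection and evaluation parameters).
#' @param overlay_dir Optional directory for overlay PNGs.
#' @param out_csv Optional path for the per-frame results CSV.
#' @return An object of class `tbd_detect_report`: `frames` (per-frame
#'   results), `roc`, `auc`, `ci95`, `operating`, `threshold`.
#' @export
run_detection_eval <- function(frame_manifest, model, backbone,
                               config = run_config(), overlay_dir = NULL,
                               out_csv = NULL) {
  if (is.null(frame_manifest) || !nrow(frame_manifest))
    stop_invalid("no labeled frames to evaluate")
  if (!inherits(model, "tbd_head")) stop_invalid("missing trained model")
  det <- config$detection
  rows <- vector("list", nrow(frame_manifest))
  if (!is.null(overlay_dir))
    dir.create(overlay_dir, recursive = TRUE, showWarnings = FALSE)
  for (i in seq_len(nrow(frame_manifest))) {
    frame <- read_image_png(frame_manifest$path[i])
    cf <- classify_frame(frame, model, backbone, det$roi_size,
                         det$patch_size, det$stride)
    score <- if (det$score_mode == "probability")
      frame_score(cf$labels, "probability", cf$proba)
    else frame_score(cf$labels)
    dec <- decide_frame(cf$labels, det$min_breakup_tiles)
    if (!is.null(overlay_dir)) {
      ov <- render_overlay(frame, cf$labels, cf$grid, cf$roi_origin)
      write_image_png(ov, file.path(
        overlay_dir, paste0(frame_manifest$video_id[i], "_",
                            basename(frame_manifest$path[i]))))
    }
    counts <- as.list(dec$per_class_tile_counts)
    names(counts) <- paste0("tiles_", names(counts))
    rows[[i]] <- cbind(
      data.frame(frame_path = frame_manifest$path[i],
                 video_id = frame_manifest$video_id[i],
                 breakup_actual = frame_manifest$breakup[i],
                 score = score, decision = dec$breakup,
                 stringsAsFactors = FALSE),
      as.data.frame(counts))
  }
  frames <- do.call(rbind, rows)
  if (length(unique(frames$breakup_actual)) < 2)
    stop_invalid(paste("AUC undefined: all frames share one label;",
                       "include videos with and without breakup"))
  roc <- roc_auc(frames$score, frames$breakup_actual)
  ci <- auc_ci95(frames$score, frames$breakup_actual,
                 method = config$evaluation$ci_method,
                 seed = derive_seed(config$seed, "ci"))
  op <- operating_point(frames$score, frames$breakup_actual,
                        det$min_breakup_tiles)
  if (!is.null(out_csv)) utils::write.csv(frames, out_csv, row.names = FALSE)
  structure(list(frames = frames, roc = roc, auc = roc$auc, ci95 = ci,
                 operating = op, threshold = det$min_breakup_tiles,
                 score_mode = det$score_mode,
                 data_provenance = "synthetic"),
            class = "tbd_detect_report")
}

#' @export
print.tbd_detect_report <- function(x, ...) {
  cat(sprintf("Frame-level breakup detection (%s data): %d frames\n",
              x$data_provenance, nrow(x$frames)))
  cat(sprintf("  AUC %.3f (95%% CI %.3f-%.3f)\n", x$auc, x$ci95[1],
              x$ci95[2]))
  cat(sprintf("  at >= %d breakup tile(s): sensitivity %.1f%%, specificity %.1f%%\n",
              x$threshold, 100 * x$operating["sensitivity"],
              100 * x$operating["specificity"]))
  invisible(x)
}

#' Write a detection report as JSON (plus ROC points CSV)
#'
#' @param report A `tbd_detect_report`.
#' @param path Output JSON path.
#' @param roc_csv Optional CSV path for the ROC points.
#' @return `path`, invisibly.
#' @export
write_detect_report <- function(report, path, roc_csv = NULL) {
  payload <- list(
    data_provenance = report$data_provenance,
    n_frames = nrow(report$frames),
    score_mode = report$score_mode,
    auc = report$auc,
    ci95 = as.numeric(report$ci95),
    threshold = report$threshold,
    sensitivity = as.numeric(report$operating["sensitivity"]),
    specificity = as.numeric(report$operating["specificity"]),
    roc_points = report$roc$points)
  if (!is.null(roc_csv))
    utils::write.csv(report$roc$points, roc_csv, row.names = FALSE)
  write_report_json(payload, path)
}
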