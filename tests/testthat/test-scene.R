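# Synthetic scene generator: thickness fields, breakup events, confounders,
# videos and labeled patch/frame emission.

test_that("base thickness field honors amplitude, seed determinism and fringe visibility", {
  sp0 <- small_scene(base_field = list(mean = 80, amplitude = 0,
                                       corr_len = 40))
  tm0 <- sample_base_thickness(sp0)
  expect_true(all(tm0$values == 80))

  sp <- small_scene(seed = 21)
  expect_identical(sample_base_thickness(sp)$values,
                   sample_base_thickness(sp)$values)

  # high-amplitude field produces visible color striping: per-row hue
  # variance well above the flat-field case
  m <- optical_model()
  spf <- small_scene(base_field = list(mean = 80, amplitude = 80,
                                       corr_len = 60), seed = 5)
  hue_var <- function(img) {
    v <- numeric(dim(img)[1])
    for (i in seq_len(dim(img)[1])) {
      hsv <- grDevices::rgb2hsv(rbind(img[i, , 1], img[i, , 2], img[i, , 3]),
                                maxColorValue = 1)
      v[i] <- stats::var(hsv[1, ])
    }
    mean(v)
  }
  img_flat <- render_interference(sample_base_thickness(sp0), m)
  img_fringe <- render_interference(sample_base_thickness(spf), m)
  expect_gt(hue_var(img_fringe), hue_var(img_flat) + 1e-4)

  # an explicit fringe confounder modulates the thickness field
  spc <- small_scene(confounders = list(
    confounder("interference_fringe", frequency = 0.03, amplitude = 40)))
  tmc <- sample_base_thickness(spc)
  expect_gt(stats::sd(tmc$values), stats::sd(sample_base_thickness(
    small_scene())$values))
})

test_that("breakup events rupture the film with the right geometry and timing", {
  tm <- thickness_map(matrix(100, 160, 200))
  ev <- breakup_event("spot", onset = 5, center = c(80, 100),
                      initial_size = 20)
  expect_identical(apply_breakup(tm, ev, 2), tm)        # pre-onset no-op

  out <- apply_breakup(tm, ev, 7)                        # static spot
  px <- which(out$rupture_mask, arr.ind = TRUE)
  d <- sqrt((px[, 1] - 80)^2 + (px[, 2] - 100)^2)
  expect_lte(max(d), 20 + 1)
  expect_gt(nrow(px), pi * 18^2)                         # nearly a full disk
  # disk aspect close to 1 at onset
  asp <- diff(range(px[, 1])) / diff(range(px[, 2]))
  expect_gt(asp, 1 / 1.5); expect_lt(asp, 1.5)

  # elongating spot: bounding-box aspect strictly increases
  ev2 <- breakup_event("spot", onset = 5, center = c(80, 100),
                       initial_size = 15, elongation_rate = 6)
  bb_aspect <- function(mask) {
    p <- which(mask, arr.ind = TRUE)
    diff(range(p[, 1])) / diff(range(p[, 2]))
  }
  a0 <- bb_aspect(apply_breakup(tm, ev2, 5)$rupture_mask)
  a5 <- bb_aspect(apply_breakup(tm, ev2, 10)$rupture_mask)
  expect_gt(a5, a0)

  # line: vertical capsule exceeding aspect 3 after elongation
  ev3 <- breakup_event("line", onset = 0, center = c(80, 100),
                       initial_size = 12, elongation_rate = 8)
  expect_gt(bb_aspect(apply_breakup(tm, ev3, 6)$rupture_mask), 3)

  # area: rupture blob plus soft thinning margin around the edge
  ev4 <- breakup_event("area", onset = 0, center = c(80, 100),
                       initial_size = 35)
  out4 <- apply_breakup(tm, ev4, 1)
  expect_gt(sum(out4$rupture_mask), 0)
  ring <- out4$values > 0 & out4$values < 100
  expect_gt(sum(ring), 100)                              # banded margin
  expect_error(breakup_event("blob", 0, c(1, 1), 5), "unknown")
})

test_that("image-space confounders composite as specified", {
  m <- optical_model()
  img <- render_interference(thickness_map(matrix(90, 160, 200)), m)
  expect_identical(composite_confounders(img, list()),
                   structure(img, footprints = list()))

  cf <- confounder("bright_reflection", center = c(80, 100), radius = 10,
                   intensity = 0.9)
  out <- composite_confounders(img, list(cf))
  fp <- attr(out, "footprints")$bright_reflection
  expect_gt(mean(out[, , 1][fp]), mean(img[, , 1][fp]))
  expect_true(all(out >= 0 & out <= 1))

  # 20 well-separated particles darken exactly 20 distinct blobs
  centers <- as.matrix(expand.grid(seq(20, 140, by = 30),
                                   seq(20, 180, by = 40)))[1:20, ]
  cfp <- confounder("particle", centers = centers, radii = 3)
  outp <- composite_confounders(img, list(cfp))
  dark <- which(outp[, , 2] < img[, , 2] - 1e-6, arr.ind = TRUE)
  d2 <- outer(dark[, 1], centers[, 1], `-`)^2 +
    outer(dark[, 2], centers[, 2], `-`)^2
  nearest <- apply(d2, 1, which.min)
  expect_true(all(sqrt(d2[cbind(seq_len(nrow(dark)), nearest)]) <= 3.5))
  expect_identical(sort(unique(nearest)), 1:20)

  # eyelid blacks out everything outside the aperture and behind the arc
  cfe <- confounder("eyelid", side = "top", vertex = 30,
                    aperture_radius = 70)
  oute <- composite_confounders(img, list(cfe))
  expect_lt(max(oute[1, 1, ]), 0.05)                     # corner masked
  expect_equal(as.numeric(oute[80, 100, ]), as.numeric(img[80, 100, ]),
               tolerance = 1e-12)                        # center untouched
})

test_that("rendered videos carry definitional frame labels and are seed-deterministic", {
  ev <- breakup_event("spot", onset = 5, center = c(80, 100),
                      initial_size = 18, growth_rate = 2)
  sp <- small_scene(events = list(ev), seed = 31)
  v <- render_video(sp, optical_model(), times = c(0, 3, 6, 9))
  lab <- vapply(v$truth, `[[`, logical(1), "breakup")
  expect_identical(lab, c(FALSE, FALSE, TRUE, TRUE))
  # label <=> rupture pixels inside the central ROI (definitional)
  for (i in seq_along(v$truth)) {
    rup <- v$truth[[i]]$rupture_by_pattern
    any_roi <- FALSE
    for (mm in rup) any_roi <- any_roi || any(mm[v$roi$rows, v$roi$cols])
    expect_identical(v$truth[[i]]$breakup, any_roi)
  }
  # no-event scene: every frame breakup-absent
  v0 <- render_video(small_scene(seed = 32), optical_model(),
                     times = c(0, 5))
  expect_false(any(vapply(v0$truth, `[[`, logical(1), "breakup")))
  # determinism: identical spec + seed give identical frames
  v2 <- render_video(sp, optical_model(), times = c(0, 3, 6, 9))
  expect_identical(v$frames, v2$frames)
})

test_that("labeled patches respect their class definitions", {
  ev <- breakup_event("spot", onset = 2, center = c(80, 100),
                      initial_size = 20, growth_rate = 1)
  sp <- small_scene(events = list(ev),
                    confounders = list(confounder(
                      "particle",
                      centers = rbind(c(40, 40), c(120, 160)),
                      radii = 3)),
                    seed = 41)
  v <- render_video(sp, optical_model(), times = c(0, 4, 8))
  expect_length(emit_labeled_patches(v, 0), 0)

  ps <- emit_labeled_patches(v, 4, classes = c("spot", "uniform",
                                               "particle"), seed = 2)
  labs <- vapply(ps, `[[`, "", "label")
  expect_identical(as.integer(table(labs)[c("spot", "uniform", "particle")]),
                   rep(4L, 3))
  # every patch carries provenance and the right shape
  for (p in ps) {
    expect_identical(dim(p$image), c(96L, 96L, 3L))
    expect_identical(p$video_id, "V1")
  }
  # non-breakup patches contain zero rupture pixels; uniform patches no
  # element pixels at all
  for (p in ps[labs != "spot"]) {
    fi <- p$frame_index
    rup <- v$truth[[fi]]$rupture_by_pattern$spot
    rows <- (p$center[1] - 48):(p$center[1] + 47)
    cols <- (p$center[2] - 48):(p$center[2] + 47)
    expect_identical(sum(rup[rows, cols]), 0L)
    if (p$label == "uniform")
      expect_identical(sum(v$footprints$particle[rows, cols]), 0L)
  }
  # unavailable class: reported shortfall, not silent padding
  expect_warning(
    got <- emit_labeled_patches(v, 3, classes = "eyelash", seed = 2),
    "eyelash")
  expect_length(got, 0)
  expect_identical(attr(got, "shortfall"), c(eyelash = 3))
})

test_that("evaluation frame sampling is capped, stratified and truthful", {
  ev <- breakup_event("area", onset = 3, center = c(80, 100),
                      initial_size = 40)
  sp <- small_scene(events = list(ev), duration = 10, fps = 1, seed = 51)
  v <- render_video(sp, optical_model())
  expect_identical(nrow(emit_labeled_frames(v, max_per_video = 40)), 10L)

  fl <- emit_labeled_frames(v, max_per_video = 4, seed = 3)
  expect_identical(nrow(fl), 4L)
  expect_true(any(fl$breakup) && any(!fl$breakup))   # stratified
  # labels match ground truth
  for (j in seq_len(nrow(fl)))
    expect_identical(fl$breakup[j], v$truth[[fl$frame_index[j]]]$breakup)

  v0 <- render_video(small_scene(duration = 6, fps = 1, seed = 52),
                     optical_model())
  fl0 <- emit_labeled_frames(v0, max_per_video = 3, seed = 4)
  expect_false(any(fl0$breakup))
})

test_that("scene specifications validate their invariants", {
  expect_error(scene_spec("V", duration = 0), "> 0")
  expect_error(scene_spec("V", events = list(
    breakup_event("spot", onset = 40, center = c(1, 1), initial_size = 5))),
    "onset")
  expect_error(confounder("glare"), "unknown")
  expect_error(breakup_event("spot", -1, c(0, 0), 5), ">= 0")
  expect_error(thickness_map(matrix(-1, 2, 2)), ">= 0")
  expect_error(thickness_map(matrix(1, 2, 2), matrix(TRUE, 3, 2)),
               "identical shape")
})
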