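# Synthetic tear-film scene generator: labeled videos, frames and 96x96
# patches covering the nine patch classes and frame-level breakup labels.
#
# A scene is a latent lipid thickness field evolving after a simulated blink
# (t = 0 at full eye opening). Breakup events carve a rupture mask into the
# field; interference-fringe structure lives in the thickness field itself;
# the remaining confounders (reflections, particles, eyelashes, eyelid /
# camera mask) are composited on the rendered image. Ground truth is
# definitional: a frame is breakup-positive iff any rupture pixel falls in
# the central 384x384 region of interest.

#' Scene specification for one synthetic video
#'
#' @param video_id,eye_id,subject_id Provenance identifiers.
#' @param duration Video duration in seconds.
#' @param fps Frames per second.
#' @param frame_size `c(width, height)` in pixels.
#' @param base_field Parameters of the smooth random thickness field:
#'   `mean` (nm), `amplitude` (nm), `corr_len` (px, Gaussian correlation
#'   length). Low amplitude gives the Uniform appearance; high amplitude
#'   gives visible fringe-like color striping.
#' @param events List of [breakup_event()]s.
#' @param confounders List of [confounder()]s.
#' @param seed Integer seed; all randomness in the scene derives from it.
#' @return An object of class `scene_spec`.
#' @export
scene_spec <- function(video_id, eye_id = video_id, subject_id = eye_id,
                       duration = 30, fps = 30, frame_size = c(640, 480),
                       base_field = list(mean = 70, amplitude = 12,
                                         corr_len = 80),
                       events = list(), confounders = list(), seed = 1L) {
  if (duration <= 0 || fps <= 0) stop_invalid("duration and fps must be > 0")
  if (length(frame_size) != 2L || any(frame_size < 1))
    stop_invalid("frame_size must be c(width, height)")
  defaults <- list(mean = 70, amplitude = 12, corr_len = 80)
  base_field <- utils::modifyList(defaults, as.list(base_field))
  for (e in events) {
    stopifnot(inherits(e, "breakup_event"))
    if (e$onset < 0 || e$onset > duration)
      stop_invalid("event onset %.2f outside [0, %.2f]", e$onset, duration)
  }
  for (cf in confounders) stopifnot(inherits(cf, "tbd_confounder"))
  structure(list(video_id = as.character(video_id),
                 eye_id = as.character(eye_id),
                 subject_id = as.character(subject_id),
                 duration = duration, fps = fps,
                 frame_size = as.integer(frame_size),
                 base_field = base_field, events = events,
                 confounders = confounders, seed = as.integer(seed)),
            class = "scene_spec")
}

#' @export
print.scene_spec <- function(x, ...) {
  cat(sprintf("Scene %s (eye %s, subject %s): %gs @ %g fps, %dx%d px\n",
              x$video_id, x$eye_id, x$subject_id, x$duration, x$fps,
              x$frame_size[1], x$frame_size[2]))
  cat(sprintf("  base field: mean %g nm, amplitude %g nm, corr %g px\n",
              x$base_field$mean, x$base_field$amplitude,
              x$base_field$corr_len))
  cat(sprintf("  %d breakup event(s), %d confounder(s), seed %d\n",
              length(x$events), length(x$confounders), x$seed))
  invisible(x)
}

#' Breakup event
#'
#' One of the three breakup morphologies appearing at `onset` seconds after
#' eye opening and growing thereafter: `area` (broad exposed region with a
#' thinning margin), `spot` (circular rupture) or `line` (vertical linear
#' rupture). Spots may stretch vertically over time (`elongation_rate`),
#' emulating the shape change driven by upward tear-fluid movement.
#'
#' @param pattern `"area"`, `"spot"` or `"line"`.
#' @param onset Onset time in seconds (>= 0).
#' @param center `c(row, col)` center in pixels.
#' @param initial_size Initial radius (area/spot) or line width, px.
#' @param growth_rate Radial growth in px/s.
#' @param elongation_rate Vertical elongation in px/s.
#' @return An object of class `breakup_event`.
#' @export
breakup_event <- function(pattern, onset, center, initial_size,
                          growth_rate = 0, elongation_rate = 0) {
  if (!pattern %in% tbd_breakup_classes())
    stop_invalid("unknown breakup pattern '%s'", pattern)
  if (initial_size < 0 || growth_rate < 0 || elongation_rate < 0)
    stop_invalid("sizes and rates must be >= 0")
  if (onset < 0) stop_invalid("onset must be >= 0")
  structure(list(pattern = pattern, onset = onset,
                 center = as.numeric(center),
                 initial_size = initial_size, growth_rate = growth_rate,
                 elongation_rate = elongation_rate),
            class = "breakup_event")
}

#' Imaging confounder
#'
#' Non-breakup scene elements corresponding to the six non-breakup patch
#' classes. `uniform` and `interference_fringe` describe the background
#' (fringes modulate the thickness field before rendering); the other four
#' are composited on the rendered image.
#'
#' @param kind One of `"uniform"`, `"interference_fringe"`,
#'   `"bright_reflection"`, `"particle"`, `"eyelash"`, `"eyelid"`.
#' @param ... Kind-specific geometry:
#'   \describe{
#'   \item{interference_fringe}{`frequency` (cycles/px), `orientation`
#'     (radians), `amplitude` (nm), `phase` (radians).}
#'   \item{bright_reflection}{`center` (row, col), `radius` px,
#'     `intensity` in \[0,1\].}
#'   \item{particle}{`centers` (k x 2 matrix of row, col), `radii`
#'     (length-k vector, px).}
#'   \item{eyelash}{`control` (3 x 2 matrix: quadratic Bezier control
#'     points, row/col), `width` px.}
#'   \item{eyelid}{`side` ("top"/"bottom"), `vertex` (arc apex row at the
#'     aperture center column), `curvature` (px^-1),
#'     `aperture_radius` px (circular camera mask).}
#'   }
#' @return An object of class `tbd_confounder`.
#' @export
confounder <- function(kind, ...) {
  kinds <- setdiff(tbd_classes(), tbd_breakup_classes())
  if (!kind %in% kinds)
    stop_invalid("unknown confounder kind '%s'", kind)
  geom <- list(...)
  structure(list(kind = kind, geometry = geom), class = "tbd_confounder")
}

# Gaussian-filtered white noise via FFT (periodic boundary), normalized to
# zero mean / unit sd. corr_len is the Gaussian sigma in pixels.
gaussian_field <- function(h, w, corr_len) {
  z <- matrix(stats::rnorm(h * w), h, w)
  fr <- c(0:(floor(h / 2)), -(ceiling(h / 2) - 1):-1) / h
  fc <- c(0:(floor(w / 2)), -(ceiling(w / 2) - 1):-1) / w
  g <- exp(-2 * pi^2 * corr_len^2 * outer(fr^2, fc^2, `+`))
  f <- Re(stats::fft(stats::fft(z) * g, inverse = TRUE)) / (h * w)
  (f - mean(f)) / stats::sd(f)
}

#' Sample the smooth base thickness field of a scene
#'
#' Low-pass-filtered Gaussian noise with the configured mean, amplitude and
#' correlation length, clipped at zero. Deterministic for a fixed scene seed.
#' Any `interference_fringe` confounders add their sinusoidal thickness
#' modulation here.
#'
#' @param spec A [scene_spec()].
#' @return A [thickness_map()].
#' @export
sample_base_thickness <- function(spec) {
  stopifnot(inherits(spec, "scene_spec"))
  w <- spec$frame_size[1]; h <- spec$frame_size[2]
  bf <- spec$base_field
  vals <- if (bf$amplitude == 0) {
    matrix(bf$mean, h, w)
  } else {
    f <- with_local_seed(derive_seed(spec$seed, "base"),
                         gaussian_field(h, w, bf$corr_len))
    bf$mean + bf$amplitude * f
  }
  for (cf in spec$confounders) {
    if (cf$kind != "interference_fringe") next
    g <- utils::modifyList(list(frequency = 0.02, orientation = pi / 6,
                                amplitude = 40, phase = 0), cf$geometry)
    rr <- matrix(seq_len(h), h, w)
    cc <- matrix(seq_len(w), h, w, byrow = TRUE)
    u <- rr * sin(g$orientation) + cc * cos(g$orientation)
    vals <- vals + g$amplitude * sin(2 * pi * g$frequency * u + g$phase)
  }
  thickness_map(pmax(vals, 0))
}

# Rasterized footprint of one event at time t (logical h x w), plus the
# soft thinning factor for area events (NULL otherwise).
event_footprint <- function(event, t, h, w) {
  dt <- t - event$onset
  if (dt < 0) return(NULL)
  rr <- matrix(seq_len(h), h, w)
  cc <- matrix(seq_len(w), h, w, byrow = TRUE)
  r0 <- event$center[1]; c0 <- event$center[2]
  if (event$pattern == "spot") {
    radius <- event$initial_size + event$growth_rate * dt
    half_len <- event$elongation_rate * dt
    dy <- pmax(abs(rr - r0) - half_len, 0)
    mask <- dy^2 + (cc - c0)^2 <= radius^2
    list(mask = mask, thin = NULL)
  } else if (event$pattern == "line") {
    radius <- event$initial_size / 2
    half_len <- 2 * event$initial_size + event$elongation_rate * dt
    dy <- pmax(abs(rr - r0) - half_len, 0)
    mask <- dy^2 + (cc - c0)^2 <= radius^2
    list(mask = mask, thin = NULL)
  } else { # area: irregular blob with a soft thinning margin
    radius <- event$initial_size + event$growth_rate * dt
    dr <- rr - r0; dc <- cc - c0
    dist <- sqrt(dr^2 + dc^2)
    ang <- atan2(dr, dc)
    ph <- (event$center[1] * 7 + event$center[2] * 13) %% (2 * pi)
    redge <- radius * (1 + 0.25 * sin(3 * ang + ph) +
                         0.15 * sin(5 * ang + 2 * ph))
    mask <- dist <= redge
    margin <- pmax(25, 0.3 * radius)
    thin <- clamp01((dist - redge) / margin)
    list(mask = mask, thin = thin)
  }
}

#' Apply a breakup event to a thickness map at time t
#'
#' Before onset the map is unchanged. From onset on, the event footprint is
#' added to the rupture mask; `area` events additionally thin the thickness
#' toward zero across a soft margin around the rupture edge, so the rendered
#' rim shows thin-film color banding.
#'
#' @param thickness A [thickness_map()].
#' @param event A [breakup_event()].
#' @param t Time in seconds (>= 0).
#' @return The updated [thickness_map()].
#' @export
apply_breakup <- function(thickness, event, t) {
  stopifnot(inherits(thickness, "thickness_map"),
            inherits(event, "breakup_event"))
  if (t < 0) stop_invalid("t must be >= 0")
  fp <- event_footprint(event, t, nrow(thickness$values),
                        ncol(thickness$values))
  if (is.null(fp)) return(thickness)
  vals <- thickness$values
  if (!is.null(fp$thin)) vals <- vals * fp$thin
  thickness_map(vals, thickness$rupture_mask | fp$mask)
}

# Quadratic Bezier points at parameters tt (n x 2 matrix of row, col).
bezier_points <- function(control, tt) {
  b <- cbind((1 - tt)^2, 2 * tt * (1 - tt), tt^2)
  b %*% control
}

# Footprint masks of image-space confounders (ignores background kinds).
confounder_footprint <- function(cf, h, w) {
  rr <- matrix(seq_len(h), h, w)
  cc <- matrix(seq_len(w), h, w, byrow = TRUE)
  g <- cf$geometry
  switch(cf$kind,
    bright_reflection = {
      g <- utils::modifyList(list(center = c(h / 2, w / 2), radius = 15,
                                  intensity = 0.9), g)
      (rr - g$center[1])^2 + (cc - g$center[2])^2 <= g$radius^2
    },
    particle = {
      g <- utils::modifyList(list(centers = matrix(c(h / 2, w / 2), 1),
                                  radii = 3), g)
      ctr <- g$centers
      radii <- rep_len(g$radii, nrow(ctr))
      m <- matrix(FALSE, h, w)
      for (i in seq_len(nrow(ctr)))
        m <- m | ((rr - ctr[i, 1])^2 + (cc - ctr[i, 2])^2 <= radii[i]^2)
      m
    },
    eyelash = {
      g <- utils::modifyList(list(control = rbind(c(1, w * 0.3),
                                                  c(h * 0.4, w * 0.45),
                                                  c(1, w * 0.6)),
                                  width = 2.5), g)
      pts <- bezier_points(g$control, seq(0, 1, length.out = 4L * h))
      m <- matrix(FALSE, h, w)
      half <- max(1, round(g$width / 2))
      pr <- round(pts[, 1]); pc <- round(pts[, 2])
      for (dr in -half:half) for (dc in -half:half) {
        r <- pr + dr; c <- pc + dc
        ok <- r >= 1 & r <= h & c >= 1 & c <= w
        m[cbind(r[ok], c[ok])] <- TRUE
      }
      m
    },
    eyelid = {
      g <- utils::modifyList(list(side = "top", vertex = h * 0.12,
                                  curvature = 1 / (2 * w),
                                  aperture_radius = 0.52 * min(h, w)), g)
      arc <- g$vertex - g$curvature * (cc - w / 2)^2
      lid <- if (g$side == "top") rr <= arc else rr >= (h - arc)
      outside <- (rr - h / 2)^2 + (cc - w / 2)^2 > g$aperture_radius^2
      lid | outside
    },
    matrix(FALSE, h, w)) # uniform / interference_fringe: no image footprint
}

#' Composite image-space confounders onto a rendered frame
#'
#' Overlays, in list order: bright reflections saturate toward white inside
#' their footprint, particles darken small blobs, eyelashes draw thin dark
#' curves, and the eyelid/camera mask blacks out everything outside the
#' circular aperture and behind the lid arc. Background kinds (`uniform`,
#' `interference_fringe`) act on the thickness field and are passed over
#' here. Pixel values stay in \[0, 1\].
#'
#' @param image H x W x 3 rendered frame.
#' @param confounders List of [confounder()]s.
#' @return The composited image, with a `footprints` attribute holding one
#'   logical mask per composited kind (union over confounders of that kind).
#' @export
composite_confounders <- function(image, confounders) {
  assert_rgb(image)
  h <- dim(image)[1]; w <- dim(image)[2]
  foot <- list()
  for (cf in confounders) {
    if (cf$kind %in% c("uniform", "interference_fringe")) next
    m <- confounder_footprint(cf, h, w)
    foot[[cf$kind]] <- if (is.null(foot[[cf$kind]])) m else foot[[cf$kind]] | m
    g <- cf$geometry
    if (cf$kind == "bright_reflection") {
      gg <- utils::modifyList(list(center = c(h / 2, w / 2), radius = 15,
                                   intensity = 0.9), g)
      rr <- matrix(seq_len(h), h, w)
      cc <- matrix(seq_len(w), h, w, byrow = TRUE)
      d2 <- (rr - gg$center[1])^2 + (cc - gg$center[2])^2
      wgt <- gg$intensity * clamp01(1 - d2 / gg$radius^2)
      for (k in 1:3) image[, , k] <- image[, , k] + (1 - image[, , k]) * wgt
    } else if (cf$kind == "particle") {
      for (k in 1:3) image[, , k][m] <- image[, , k][m] * 0.15
    } else if (cf$kind == "eyelash") {
      for (k in 1:3) image[, , k][m] <- image[, , k][m] * 0.25
    } else if (cf$kind == "eyelid") {
      for (k in 1:3) image[, , k][m] <- 0.02
    }
  }
  image <- clamp01(image)
  attr(image, "footprints") <- foot
  image
}

# Background patch class of a scene: explicit fringe confounder or a
# high-amplitude base field reads as Interference Fringe; otherwise Uniform.
scene_background_class <- function(spec, fringe_amplitude_threshold = 40) {
  has_fringe <- any(vapply(spec$confounders,
                           function(cf) cf$kind == "interference_fringe",
                           logical(1)))
  if (has_fringe || spec$base_field$amplitude >= fringe_amplitude_threshold)
    "interference_fringe" else "uniform"
}

#' Render a synthetic video with per-frame ground truth
#'
#' For each requested frame time: base thickness, breakup events applied at
#' that time, interference rendering, then confounder compositing. Ground
#' truth per frame records breakup presence (any rupture pixel inside the
#' central 384x384 region of interest) and the per-pattern rupture masks;
#' static confounder footprints are recorded once. Deterministic for a fixed
#' scene seed.
#'
#' @param spec A [scene_spec()].
#' @param model An [optical_model()].
#' @param times Frame times in seconds; default all `round(duration * fps)`
#'   frame times. Long videos are typically rendered only at the sampled
#'   evaluation times.
#' @param roi_size Region-of-interest side (px) used for the frame label.
#' @return An object of class `tbd_video`: `frames` (list of H x W x 3
#'   arrays), `truth` (per frame: `time`, `breakup`, `rupture_by_pattern`),
#'   `footprints`, `background_class`, `spec`.
#' @export
render_video <- function(spec, model = optical_model(), times = NULL,
                         roi_size = 384) {
  stopifnot(inherits(spec, "scene_spec"))
  if (is.null(times)) {
    n <- round(spec$duration * spec$fps)
    times <- (seq_len(n) - 1) / spec$fps
  }
  base <- sample_base_thickness(spec)
  h <- nrow(base$values); w <- ncol(base$values)
  roi <- roi_rect(h, w, min(roi_size, h, w))
  frames <- vector("list", length(times))
  truth <- vector("list", length(times))
  foot <- NULL
  for (i in seq_along(times)) {
    t <- times[i]
    th <- base
    pat_masks <- list()
    for (ev in spec$events) {
      fp <- event_footprint(ev, t, h, w)
      if (is.null(fp)) next
      vals <- th$values
      if (!is.null(fp$thin)) vals <- vals * fp$thin
      th <- thickness_map(vals, th$rupture_mask | fp$mask)
      pm <- pat_masks[[ev$pattern]]
      pat_masks[[ev$pattern]] <- if (is.null(pm)) fp$mask else pm | fp$mask
    }
    img <- render_interference(th, model,
                               noise_seed = derive_seed(spec$seed, "rupture"))
    img <- composite_confounders(img, spec$confounders)
    if (is.null(foot)) foot <- attr(img, "footprints")
    attr(img, "footprints") <- NULL
    frames[[i]] <- img
    in_roi <- th$rupture_mask[roi$rows, roi$cols]
    truth[[i]] <- list(time = t, breakup = any(in_roi),
                       rupture_by_pattern = pat_masks)
  }
  structure(list(spec = spec, frames = frames, truth = truth,
                 footprints = if (is.null(foot)) list() else foot,
                 background_class = scene_background_class(spec),
                 roi = roi),
            class = "tbd_video")
}

#' @export
print.tbd_video <- function(x, ...) {
  lab <- vapply(x$truth, function(tr) tr$breakup, logical(1))
  cat(sprintf("Synthetic video %s: %d frame(s), %d breakup-positive, %s background\n",
              x$spec$video_id, length(x$frames), sum(lab), x$background_class))
  invisible(x)
}

# Central ROI rows/cols (floor rounding of the centered origin).
roi_rect <- function(h, w, size) {
  r0 <- as.integer(floor((h - size) / 2))
  c0 <- as.integer(floor((w - size) / 2))
  list(rows = (r0 + 1):(r0 + size), cols = (c0 + 1):(c0 + size),
       origin = c(r0, c0), size = as.integer(size))
}

# Per-class footprint masks of one frame of a video (elements only;
# background classes are handled by exclusion).
frame_element_masks <- function(video, frame_index) {
  masks <- video$truth[[frame_index]]$rupture_by_pattern
  c(masks, video$footprints)
}

#' Extract labeled 96x96 patches from rendered videos
#'
#' Samples patches centered on scene elements. A patch receives a breakup
#' class only if that pattern's rupture pixels dominate every other element
#' in the window (ties resolved in favor of the breakup class); a
#' non-breakup element patch must contain zero rupture pixels; `uniform` /
#' `interference_fringe` patches contain no element pixels at all and take
#' the scene's background class. A shortfall for an unavailable class is
#' reported via warning and the `shortfall` attribute, never padded.
#'
#' @param videos A `tbd_video` or list of them.
#' @param patches_per_class Requested number of patches for each class.
#' @param classes Classes to sample (default all nine).
#' @param patch_size Patch side in px.
#' @param min_element_px Minimum element pixels inside a window for it to
#'   count as showing that element: a single number, or a named per-class
#'   vector. The default demands solid footprints for the large elements and
#'   proportionally less for intrinsically small ones (particles, lashes).
#' @param seed Integer seed for sampling.
#' @return A list of patch records (class `patch_set`): each has `image`,
#'   `label`, `video_id`, `eye_id`, `subject_id`, `frame_index`, `center`.
#' @export
emit_labeled_patches <- function(videos, patches_per_class,
                                 classes = tbd_classes(), patch_size = 96,
                                 min_element_px = NULL, seed = 1L) {
  if (inherits(videos, "tbd_video")) videos <- list(videos)
  min_px <- c(area = 150, spot = 150, line = 150, bright_reflection = 100,
              particle = 15, eyelash = 40, eyelid = 300)
  if (!is.null(min_element_px)) {
    if (is.null(names(min_element_px)))
      min_px[] <- min_element_px
    else min_px[names(min_element_px)] <- min_element_px
  }
  records <- list()
  shortfall <- stats::setNames(numeric(0), character(0))
  if (patches_per_class > 0) {
    with_local_seed(derive_seed(seed, "patches"), {
      for (cls in classes) {
        got <- sample_class_patches(videos, cls, patches_per_class,
                                    patch_size, min_px)
        if (length(got) < patches_per_class) {
          shortfall[cls] <- patches_per_class - length(got)
          warning(sprintf("class '%s': %d of %d requested patches available",
                          cls, length(got), patches_per_class),
                  call. = FALSE)
        }
        records <- c(records, got)
      }
    })
  }
  structure(records, class = "patch_set",
            shortfall = if (length(shortfall)) shortfall else NULL)
}

# Candidate-and-check sampler for one class across the videos.
sample_class_patches <- function(videos, cls, n_wanted, patch_size,
                                 min_px) {
  half <- patch_size %/% 2
  out <- list()
  budget <- n_wanted * 40L
  is_breakup <- cls %in% tbd_breakup_classes()
  is_background <- cls %in% c("uniform", "interference_fringe")
  vids <- sample(seq_along(videos))
  while (budget > 0 && length(out) < n_wanted) {
    for (vi in vids) {
      if (length(out) >= n_wanted || budget <= 0) break
      budget <- budget - 1L
      v <- videos[[vi]]
      if (is_background && v$background_class != cls) next
      h <- dim(v$frames[[1]])[1]; w <- dim(v$frames[[1]])[2]
      fi <- sample(length(v$frames), 1)
      masks <- frame_element_masks(v, fi)
      if (is_background) {
        r0 <- sample(seq_len(h - patch_size + 1), 1)
        c0 <- sample(seq_len(w - patch_size + 1), 1)
      } else {
        m <- masks[[cls]]
        if (is.null(m) || !any(m)) next
        px <- which(m, arr.ind = TRUE)
        ctr <- px[sample(nrow(px), 1), ]
        r0 <- min(max(ctr[1] - half, 1), h - patch_size + 1)
        c0 <- min(max(ctr[2] - half, 1), w - patch_size + 1)
      }
      rows <- r0:(r0 + patch_size - 1); cols <- c0:(c0 + patch_size - 1)
      counts <- vapply(masks, function(mm) sum(mm[rows, cols]), numeric(1))
      rupture_px <- sum(counts[names(counts) %in% tbd_breakup_classes()])
      # a competing element disqualifies the window only if it is itself
      # visible (>= its own pixel minimum) and strictly dominates the target
      dominated <- function() {
        others <- setdiff(names(counts), cls)
        any(counts[others] > counts[cls] &
              counts[others] >= min_px[others])
      }
      ok <- if (is_background) {
        sum(counts) == 0
      } else if (is_breakup) {
        counts[cls] >= min_px[cls] && !dominated()
      } else {
        rupture_px == 0 && counts[cls] >= min_px[cls] && !dominated()
      }
      if (!ok) next
      out[[length(out) + 1L]] <- list(
        image = v$frames[[fi]][rows, cols, , drop = FALSE],
        label = cls, video_id = v$spec$video_id, eye_id = v$spec$eye_id,
        subject_id = v$spec$subject_id, frame_index = fi,
        center = c(r0 + half, c0 + half))
    }
  }
  out
}

#' Extract labeled evaluation frames from rendered videos
#'
#' Samples at most `max_per_video` frames per video, stratified so both
#' labels are represented whenever both exist in the video; labels come from
#' the generator's ground truth.
#'
#' @param videos A `tbd_video` or list of them.
#' @param max_per_video Cap on sampled frames per video.
#' @param seed Integer sampling seed.
#' @return Data frame with columns `video_id`, `frame_index`, `time`,
#'   `breakup`; the frames themselves stay in the video objects.
#' @export
emit_labeled_frames <- function(videos, max_per_video = 40, seed = 1L) {
  if (inherits(videos, "tbd_video")) videos <- list(videos)
  rows <- list()
  with_local_seed(derive_seed(seed, "frames"), {
    for (v in videos) {
      lab <- vapply(v$truth, function(tr) tr$breakup, logical(1))
      n <- length(lab)
      pick <- function(x, k) x[sample.int(length(x), k)]
      take <- if (n <= max_per_video) seq_len(n) else {
        pos <- which(lab); neg <- which(!lab)
        if (length(pos) && length(neg)) {
          npos <- max(1L, round(max_per_video * length(pos) / n))
          npos <- min(npos, length(pos), max_per_video - 1L)
          nneg <- min(max_per_video - npos, length(neg))
          c(pick(pos, npos), pick(neg, nneg))
        } else pick(seq_len(n), max_per_video)
      }
      take <- sort(take)
      rows[[length(rows) + 1L]] <- data.frame(
        video_id = v$spec$video_id, frame_index = take,
        time = vapply(v$truth[take], function(tr) tr$time, numeric(1)),
        breakup = lab[take], stringsAsFactors = FALSE)
    }
  })
  if (!length(rows)) {
    return(data.frame(video_id = character(0), frame_index = integer(0),
                      time = numeric(0), breakup = logical(0)))
  }
  do.call(rbind, rows)
}
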