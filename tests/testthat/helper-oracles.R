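# Independent oracles and fixture builders shared across the test suite.
# Oracles deliberately avoid the package's own code paths.

# Multiple-beam (Airy) reflectance truncated at `n_terms` internal
# reflections: the reference against which the two-beam model is checked.
airy_reflectance <- function(d, lambda, n_air = 1.0, n_lipid = 1.48,
                             n_aqueous = 1.334, n_terms = 10) {
  r1 <- (n_air - n_lipid) / (n_air + n_lipid)
  r2 <- (n_lipid - n_aqueous) / (n_lipid + n_aqueous)
  phi <- 4 * pi * n_lipid * d / lambda
  r <- complex(real = r1)
  t1t1p <- 1 - r1^2
  for (m in seq_len(n_terms))
    r <- r + t1t1p * (-r1)^(m - 1) * r2^m * exp(1i * m * phi)
  Mod(r)^2
}

# O(n^2) pairwise Mann-Whitney AUC with midrank tie handling.
auc_pairwise_oracle <- function(scores, labels) {
  labels <- as.logical(labels)
  pos <- scores[labels]; neg <- scores[!labels]
  total <- 0
  for (p in pos) for (q in neg)
    total <- total + (p > q) + 0.5 * (p == q)
  total / (length(pos) * length(neg))
}

# A flat-color 96x96 patch (used to build well-separated toy classes).
flat_patch <- function(rgb, size = 96) {
  array(rep(rgb, each = size * size), c(size, size, 3))
}

# Well-separated toy patch set: each class a distinct flat color plus tiny
# seeded noise; n_per_class patches per class, split over two "videos".
toy_patch_set <- function(n_per_class = 3, seed = 99, noise = 0.01,
                          size = 96, n_videos = 2) {
  palette <- rbind(
    c(0.15, 0.15, 0.15), c(0.9, 0.1, 0.1), c(0.1, 0.9, 0.1),
    c(0.1, 0.1, 0.9), c(0.9, 0.9, 0.1), c(0.9, 0.1, 0.9),
    c(0.1, 0.9, 0.9), c(0.6, 0.6, 0.6), c(0.95, 0.6, 0.2))
  classes <- tbd_classes()
  set.seed(seed)
  recs <- list()
  for (ci in seq_along(classes)) for (j in seq_len(n_per_class)) {
    img <- flat_patch(palette[ci, ], size) +
      array(rnorm(size * size * 3, 0, noise), c(size, size, 3))
    img <- pmin(pmax(img, 0), 1)
    vid <- sprintf("T%d", (j %% n_videos) + 1)
    recs[[length(recs) + 1L]] <- list(
      image = img, label = classes[ci], video_id = vid, eye_id = vid,
      subject_id = vid, frame_index = j, center = c(48, 48))
  }
  structure(recs, class = "patch_set")
}

# A quick small scene for generator tests (about 0.2 s per rendered frame).
small_scene <- function(video_id = "V1", events = list(),
                        confounders = list(),
                        base_field = list(mean = 70, amplitude = 8,
                                          corr_len = 40),
                        frame_size = c(200, 160), duration = 10, fps = 1,
                        seed = 11) {
  scene_spec(video_id, duration = duration, fps = fps,
             frame_size = frame_size, base_field = base_field,
             events = events, confounders = confounders, seed = seed)
}

# Independent tally of manifest records per group label.
brute_group_sizes <- function(manifest, group_of_video, groups) {
  n <- 0
  for (i in seq_len(nrow(manifest)))
    if (group_of_video[[manifest$video_id[i]]] %in% groups) n <- n + 1
  n
}
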