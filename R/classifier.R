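# Nine-class patch classifier via transfer learning: a frozen convolutional
# feature extractor ("backbone") plus a trainable softmax head. The backbone
# is an interface: the shipped implementation is a small deterministic
# random-filter convolutional network (fixed seed), which keeps the full
# pipeline reproducible offline; any richer pretrained extractor can be
# plugged in behind the same surface. An identity backbone passes feature
# vectors straight through, for toy problems and oracle tests.

#' Identity backbone
#'
#' Flattens its input and returns it unchanged; used to route
#' already-extracted feature vectors (or tiny toy inputs) into the head.
#'
#' @param feature_dim Expected feature length (`NULL` to accept any).
#' @return An object of classes `identity_backbone`, `tbd_backbone`.
#' @export
identity_backbone <- function(feature_dim = NULL) {
  structure(list(name = "identity", input_size = NULL,
                 feature_dim = feature_dim, frozen = TRUE),
            class = c("identity_backbone", "tbd_backbone"))
}

# im2col linear-index matrix for an (h, w, cin) array: one row per output
# position (row-major over the output grid), one column per patch element.
im2col_index <- function(h, w, cin, kh, kw, stride) {
  oh <- (h - kh) %/% stride + 1L
  ow <- (w - kw) %/% stride + 1L
  pos_r <- rep(seq(0L, by = stride, length.out = oh), times = ow)
  pos_c <- rep(seq(0L, by = stride, length.out = ow), each = oh)
  base <- pos_r + pos_c * h                      # column-major over (oh, ow)
  off <- as.vector(outer(seq_len(kh) - 1L,
                         (seq_len(kw) - 1L) * h, `+`))
  off <- as.vector(outer(off, (seq_len(cin) - 1L) * h * w, `+`)) + 1L
  list(idx = outer(base, off, `+`), oh = oh, ow = ow)
}

#' Small deterministic convolutional backbone
#'
#' A compact fixed feature extractor: three convolution + ReLU stages with
#' random Gaussian filters drawn once from a fixed seed (He-scaled), followed
#' by spatial average pooling on a 3x3 grid. Random convolutional projections
#' preserve the color and local-texture statistics that separate the nine
#' patch classes, and the frozen random weights make extraction exactly
#' reproducible everywhere.
#'
#' @param seed Seed for the filter draw.
#' @param input_size Input side in px. The default 96 matches the native
#'   patch size (no resampling needed); 224 is supported for drop-in
#'   comparison with backbones that expect the larger input.
#' @return An object of classes `conv_backbone`, `tbd_backbone`.
#' @export
conv_backbone <- function(seed = 42L, input_size = 96) {
  arch <- list(
    list(k = 7L, stride = 4L, cout = 8L),
    list(k = 5L, stride = 2L, cout = 16L),
    list(k = 3L, stride = 2L, cout = 32L))
  layers <- list()
  h <- input_size; w <- input_size; cin <- 3L
  with_local_seed(seed, {
    for (sp in arch) {
      fan_in <- sp$k * sp$k * cin
      W <- matrix(stats::rnorm(fan_in * sp$cout, sd = sqrt(2 / fan_in)),
                  fan_in, sp$cout)
      ix <- im2col_index(h, w, cin, sp$k, sp$k, sp$stride)
      layers[[length(layers) + 1L]] <-
        list(W = W, idx = ix$idx, oh = ix$oh, ow = ix$ow, cout = sp$cout)
      h <- ix$oh; w <- ix$ow; cin <- sp$cout
    }
  })
  # average-pooling grid (up to 3x3) over the final (h, w) map
  bands <- function(n) {
    nb <- min(3L, n)
    split(seq_len(n), cut(seq_len(n), nb, labels = FALSE))
  }
  rb <- bands(h); cb <- bands(w)
  pool <- expand.grid(rb = seq_along(rb), cb = seq_along(cb))
  structure(list(name = sprintf("conv3-rand-%d-%d", seed, input_size),
                 seed = seed,
                 input_size = input_size, layers = layers,
                 pool_rows = rb, pool_cols = cb, pool_grid = pool,
                 feature_dim = nrow(pool) * cin, frozen = TRUE),
            class = c("conv_backbone", "tbd_backbone"))
}

#' @export
print.tbd_backbone <- function(x, ...) {
  cat(sprintf("Frozen backbone '%s'", x$name))
  if (!is.null(x$input_size))
    cat(sprintf(": input %dx%dx3, %d features", x$input_size, x$input_size,
                x$feature_dim))
  cat("\n")
  invisible(x)
}

#' Extract a feature vector from an image
#'
#' Deterministic (the backbone is frozen): identical inputs give identical
#' features.
#'
#' @param backbone A `tbd_backbone`.
#' @param image Input image (for the convolutional backbone, an
#'   `input_size` x `input_size` x 3 array); the identity backbone accepts
#'   any numeric input and flattens it.
#' @return Numeric feature vector of length `feature_dim`.
#' @export
extract_features <- function(backbone, image) UseMethod("extract_features")

#' @export
extract_features.identity_backbone <- function(backbone, image) {
  v <- as.numeric(image)
  if (!is.null(backbone$feature_dim) && length(v) != backbone$feature_dim)
    stop_invalid("expected %d features, got %d", backbone$feature_dim,
                 length(v))
  v
}

#' @export
extract_features.conv_backbone <- function(backbone, image) {
  assert_rgb(image)
  if (dim(image)[1] != backbone$input_size ||
      dim(image)[2] != backbone$input_size)
    stop_invalid("backbone expects %dx%dx3 input, got %dx%dx%d",
                 backbone$input_size, backbone$input_size,
                 dim(image)[1], dim(image)[2], dim(image)[3])
  x <- image
  for (ly in backbone$layers) {
    X <- matrix(x[ly$idx], nrow(ly$idx), ncol(ly$idx))
    x <- array(pmax(X %*% ly$W, 0), c(ly$oh, ly$ow, ly$cout))
  }
  feats <- numeric(0)
  for (i in seq_len(nrow(backbone$pool_grid))) {
    rs <- backbone$pool_rows[[backbone$pool_grid$rb[i]]]
    cs <- backbone$pool_cols[[backbone$pool_grid$cb[i]]]
    feats <- c(feats, apply(x[rs, cs, , drop = FALSE], 3, mean))
  }
  feats
}

# Prepare one 96x96 patch (or pre-extracted features) for the head.
patch_features <- function(backbone, image) {
  if (inherits(backbone, "identity_backbone"))
    return(extract_features(backbone, image))
  img <- if (dim(image)[1] != backbone$input_size)
    resize_to_input(image, backbone$input_size) else image
  extract_features(backbone, img)
}

softmax <- function(z) {
  if (is.null(dim(z))) z <- matrix(z, nrow = 1)
  z <- z - apply(z, 1, max)
  e <- exp(z)
  e / rowSums(e)
}

#' Training configuration for the softmax head
#'
#' @param batch_size Minibatch size (the protocol uses 20).
#' @param max_epochs Epoch budget. The clinical protocol ran 1000 epochs;
#'   the desk default is 30 -- selection by maximum validation accuracy makes
#'   the budget a runtime knob, not a semantic one.
#' @param learning_rate Adam step size (standard default).
#' @param policy [augmentation_policy()] applied on the fly to training
#'   patches each epoch; validation data is never augmented.
#' @param seed Seed controlling shuffling and augmentation streams.
#' @return An object of class `train_config`.
#' @export
train_config <- function(batch_size = 20, max_epochs = 30,
                         learning_rate = 1e-3,
                         policy = augmentation_policy(), seed = 1L) {
  if (batch_size < 1 || max_epochs < 1)
    stop_invalid("batch_size and max_epochs must be >= 1")
  structure(list(batch_size = as.integer(batch_size),
                 max_epochs = as.integer(max_epochs),
                 learning_rate = learning_rate, policy = policy,
                 seed = as.integer(seed)),
            class = "train_config")
}

# Normalise the accepted training-set shapes to (images list, labels).
training_records <- function(x) {
  if (inherits(x, "patch_set"))
    return(list(images = lapply(x, `[[`, "image"),
                labels = vapply(x, `[[`, "", "label")))
  if (inherits(x, "patch_manifest") || is.data.frame(x)) {
    imgs <- attr(x, "images")
    if (is.null(imgs)) imgs <- lapply(seq_len(nrow(x)),
                                      function(i) manifest_image(x, i))
    return(list(images = imgs, labels = x$class))
  }
  stop_invalid("unsupported training records object")
}

#' Train the nine-class softmax head on frozen backbone features
#'
#' Minimises categorical cross-entropy with Adam over minibatches of
#' augmented training patches (augment, resize to the backbone input,
#' extract features). Features are standardised using the unaugmented
#' training set. After every epoch, training and validation accuracy are
#' recorded (both on unaugmented patches) and the parameters from the epoch
#' with maximum validation accuracy are kept (earliest epoch on ties).
#' Deterministic for a fixed seed and backbone.
#'
#' @param train,validation Training and validation records: a `patch_set`
#'   or a `patch_manifest` (in-memory or on-disk patches).
#' @param backbone A `tbd_backbone`.
#' @param config A [train_config()].
#' @return An object of class `tbd_head` with the fitted weights, the
#'   per-epoch `history` data frame and the selected `best_epoch`.
#' @export
train_head <- function(train, validation, backbone = conv_backbone(),
                       config = train_config()) {
  tr <- training_records(train)
  va <- training_records(validation)
  if (!length(tr$images) || !length(va$images))
    stop_invalid("training and validation splits must be non-empty")
  classes <- tbd_classes()
  missing_cls <- setdiff(classes, unique(tr$labels))
  if (length(missing_cls))
    message("classes absent from training split: ",
            paste(missing_cls, collapse = ", "))
  y <- match(tr$labels, classes)
  yv <- match(va$labels, classes)
  if (anyNA(y) || anyNA(yv)) stop_invalid("unknown class label in records")

  n <- length(tr$images)
  feats_plain <- t(vapply(tr$images, function(im) patch_features(backbone, im),
                          numeric(length(patch_features(backbone,
                                                        tr$images[[1]])))))
  feats_val <- t(vapply(va$images, function(im) patch_features(backbone, im),
                        numeric(ncol(feats_plain))))
  mu <- colMeans(feats_plain)
  sdv <- apply(feats_plain, 2, stats::sd)
  sdv[!is.finite(sdv) | sdv < 1e-8] <- 1
  std <- function(M) sweep(sweep(M, 2, mu), 2, sdv, `/`)
  Xplain <- std(feats_plain); Xval <- std(feats_val)

  D <- ncol(feats_plain); K <- length(classes)
  W <- matrix(0, D, K); b <- numeric(K)
  mW <- vW <- matrix(0, D, K); mb <- vb <- numeric(K)
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8; step <- 0
  Y <- diag(K)[y, , drop = FALSE]
  acc <- function(X, yy) mean(max.col(cbind(X %*% W) + rep(b, each = nrow(X)),
                                      ties.method = "first") == yy)
  history <- data.frame(epoch = integer(0), train_accuracy = numeric(0),
                        validation_accuracy = numeric(0))
  best <- list(acc = -Inf, W = W, b = b, epoch = 0L)
  augmenting <- config$policy$scale_range[2] > config$policy$scale_range[1] ||
    config$policy$shift_range > 0 || config$policy$hflip_probability > 0
  for (epoch in seq_len(config$max_epochs)) {
    Xe <- if (augmenting) {
      with_local_seed(derive_seed(config$seed, paste0("augment", epoch)), {
        std(t(vapply(tr$images, function(im) {
          if (is_rgb_array(im)) im <- augment(im, config$policy)
          patch_features(backbone, im)
        }, numeric(D))))
      })
    } else Xplain
    ord <- with_local_seed(derive_seed(config$seed, paste0("shuffle", epoch)),
                           sample(n))
    for (start in seq(1, n, by = config$batch_size)) {
      idx <- ord[start:min(start + config$batch_size - 1, n)]
      Xb <- Xe[idx, , drop = FALSE]
      P <- softmax(Xb %*% W + rep(b, each = length(idx)))
      G <- (P - Y[idx, , drop = FALSE]) / length(idx)
      gW <- crossprod(Xb, G); gb <- colSums(G)
      step <- step + 1
      mW <- b1 * mW + (1 - b1) * gW; vW <- b2 * vW + (1 - b2) * gW^2
      mb <- b1 * mb + (1 - b1) * gb; vb <- b2 * vb + (1 - b2) * gb^2
      lr_t <- config$learning_rate * sqrt(1 - b2^step) / (1 - b1^step)
      W <- W - lr_t * mW / (sqrt(vW) + eps)
      b <- b - lr_t * mb / (sqrt(vb) + eps)
    }
    tr_acc <- acc(Xplain, y); va_acc <- acc(Xval, yv)
    history <- rbind(history, data.frame(epoch = epoch,
                                         train_accuracy = tr_acc,
                                         validation_accuracy = va_acc))
    if (va_acc > best$acc) best <- list(acc = va_acc, W = W, b = b,
                                        epoch = epoch)
  }
  structure(list(weights = best$W, bias = best$b, class_order = classes,
                 feature_mean = mu, feature_sd = sdv,
                 backbone_name = backbone$name,
                 input_size = backbone$input_size,
                 best_epoch = best$epoch, history = history,
                 config = config),
            class = "tbd_head")
}

#' @export
print.tbd_head <- function(x, ...) {
  cat(sprintf("Softmax head on frozen backbone '%s': %d features -> %d classes\n",
              x$backbone_name, nrow(x$weights), ncol(x$weights)))
  h <- x$history
  cat(sprintf("  %d epoch(s); selected epoch %d (validation accuracy %.3f)\n",
              nrow(h), x$best_epoch,
              h$validation_accuracy[x$best_epoch]))
  invisible(x)
}

#' @export
summary.tbd_head <- function(object, ...) {
  print(object)
  cat("training history (last 5 epochs):\n")
  print(utils::tail(object$history, 5), row.names = FALSE)
  invisible(object$history)
}

#' @export
coef.tbd_head <- function(object, ...) {
  out <- rbind(object$weights, bias = object$bias)
  colnames(out) <- object$class_order
  out
}

head_features <- function(model, backbone, patches) {
  if (is_rgb_array(patches) || !is.list(patches)) patches <- list(patches)
  M <- t(vapply(patches, function(p) patch_features(backbone, p),
                numeric(nrow(model$weights))))
  sweep(sweep(M, 2, model$feature_mean), 2, model$feature_sd, `/`)
}

#' Class probabilities for patches
#'
#' Pipeline: resize to the backbone input, extract frozen features,
#' standardise, affine head, softmax.
#'
#' @param model A `tbd_head`.
#' @param backbone The backbone the head was trained on.
#' @param patches One 96x96x3 patch or a list of them (the identity
#'   backbone accepts raw feature vectors).
#' @return An `n x 9` matrix of probabilities (rows sum to 1), columns in
#'   the canonical class order.
#' @export
predict_proba <- function(model, backbone, patches) {
  stopifnot(inherits(model, "tbd_head"))
  X <- head_features(model, backbone, patches)
  P <- softmax(X %*% model$weights + rep(model$bias, each = nrow(X)))
  colnames(P) <- model$class_order
  P
}

#' Predicted class labels for patches
#'
#' Argmax over [predict_proba()]; ties resolve to the earliest label in the
#' canonical class order.
#'
#' @inheritParams predict_proba
#' @return Character vector of class labels.
#' @export
predict_class <- function(model, backbone, patches) {
  P <- predict_proba(model, backbone, patches)
  model$class_order[max.col(P, ties.method = "first")]
}

#' @export
predict.tbd_head <- function(object, patches, backbone,
                             type = c("class", "prob"), ...) {
  type <- match.arg(type)
  if (type == "prob") predict_proba(object, backbone, patches)
  else predict_class(object, backbone, patches)
}

#' Serialise / restore a trained head
#'
#' The head is stored as JSON metadata (class order, backbone name, config,
#' selection) plus plain-text arrays, so models are portable and diffable.
#'
#' @param model A `tbd_head`.
#' @param path Output `.json` path.
#' @param history_csv Optional path to additionally write the per-epoch
#'   training history as CSV.
#' @return `path` invisibly, or the restored `tbd_head` for `read_head`.
#' @export
write_head <- function(model, path, history_csv = NULL) {
  stopifnot(inherits(model, "tbd_head"))
  if (!is.null(history_csv))
    utils::write.csv(model$history, history_csv, row.names = FALSE)
  payload <- list(
    class_order = model$class_order, backbone_name = model$backbone_name,
    input_size = model$input_size, best_epoch = model$best_epoch,
    feature_mean = model$feature_mean, feature_sd = model$feature_sd,
    bias = model$bias, weights = model$weights,
    history = model$history,
    config = list(batch_size = model$config$batch_size,
                  max_epochs = model$config$max_epochs,
                  learning_rate = model$config$learning_rate,
                  seed = model$config$seed))
  write_report_json(payload, path)
}

#' @rdname write_head
#' @export
read_head <- function(path) {
  p <- jsonlite::fromJSON(path)
  structure(list(weights = as.matrix(p$weights), bias = as.numeric(p$bias),
                 class_order = p$class_order,
                 feature_mean = as.numeric(p$feature_mean),
                 feature_sd = as.numeric(p$feature_sd),
                 backbone_name = p$backbone_name,
                 input_size = p$input_size, best_epoch = p$best_epoch,
                 history = as.data.frame(p$history),
                 config = do.call(train_config, p$config)),
            class = "tbd_head")
}
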