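# Thin-film interference optics: rendering lipid-layer thickness fields as
# the interference color images produced by white-light tear interferometry.
#
# Physical picture: white light reflects once at the air/lipid interface and
# once at the lipid/aqueous interface; the two reflected beams interfere with
# a path difference set by the local lipid thickness d, so the reflected
# spectrum -- and hence the perceived color -- encodes d.

#' Optical model for tear-film interference rendering
#'
#' Bundles the refractive indices of the three media, the wavelength grid and
#' illuminant spectrum used for spectral integration, the exposed-surface
#' (rupture) appearance, and a display exposure gain.
#'
#' @param n_air Refractive index of air (dimensionless).
#' @param n_lipid Refractive index of the lipid layer.
#' @param n_aqueous Refractive index of the aqueous layer beneath the lipid.
#' @param wavelengths Strictly increasing wavelength grid in nm within
#'   \[380, 780\]; the default samples every 5 nm.
#' @param illuminant Relative spectral power per wavelength (non-negative,
#'   not all zero). Default is the equal-energy illuminant.
#' @param gain Display exposure gain applied to the reflectance spectrum
#'   before color conversion. The two-beam film reflectance peaks near 6%,
#'   so unit gain would use only a small fraction of the display range; the
#'   default maps the physical range onto most of it.
#' @param rupture_gray Display-space gray level of exposed (broken-film)
#'   surface pixels.
#' @param rupture_noise Standard deviation of the multiplicative log-normal
#'   texture noise on exposed-surface pixels.
#'
#' @return An object of class `optical_model`.
#' @export
optical_model <- function(n_air = 1.0, n_lipid = 1.48, n_aqueous = 1.334,
                          wavelengths = seq(380, 780, by = 5),
                          illuminant = NULL,
                          gain = 12, rupture_gray = 0.20,
                          rupture_noise = 0.05) {
  for (n in c(n_air = n_air, n_lipid = n_lipid, n_aqueous = n_aqueous)) {
    if (!is.numeric(n) || length(n) != 1L || !is.finite(n) || n <= 0)
      stop_invalid("refractive indices must be positive finite scalars")
  }
  wavelengths <- as.numeric(wavelengths)
  if (length(wavelengths) < 2L || any(diff(wavelengths) <= 0))
    stop_invalid("wavelength grid must be strictly increasing")
  if (min(wavelengths) < 380 || max(wavelengths) > 780)
    stop_invalid("wavelength grid must lie within [380, 780] nm")
  if (is.null(illuminant)) illuminant <- rep(1, length(wavelengths))
  illuminant <- as.numeric(illuminant)
  if (length(illuminant) != length(wavelengths))
    stop_invalid("illuminant must have one entry per wavelength")
  if (any(illuminant < 0) || all(illuminant == 0))
    stop_invalid("illuminant must be non-negative and not all zero")
  if (gain <= 0) stop_invalid("gain must be positive")
  structure(
    list(n_air = n_air, n_lipid = n_lipid, n_aqueous = n_aqueous,
         wavelengths = wavelengths, illuminant = illuminant, gain = gain,
         rupture_gray = rupture_gray, rupture_noise = rupture_noise),
    class = "optical_model")
}

#' Read an optical model from a JSON or YAML config file
#'
#' Recognised fields: `n_air`, `n_lipid`, `n_aqueous`, `wavelengths`,
#' `illuminant`, `gain`, `rupture_gray`, `rupture_noise`; missing fields take
#' the [optical_model()] defaults.
#'
#' @param path Path to a `.json`, `.yaml` or `.yml` file.
#' @return An `optical_model`.
#' @export
read_optical_model <- function(path) {
  cfg <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE))
    yaml::read_yaml(path) else jsonlite::fromJSON(path)
  keep <- intersect(names(cfg), names(formals(optical_model)))
  do.call(optical_model, cfg[keep])
}

#' @export
print.optical_model <- function(x, ...) {
  cat("Tear-film optical model\n")
  cat(sprintf("  indices: air %.3f / lipid %.3f / aqueous %.3f\n",
              x$n_air, x$n_lipid, x$n_aqueous))
  cat(sprintf("  wavelengths: %d samples, %.0f-%.0f nm\n",
              length(x$wavelengths), min(x$wavelengths), max(x$wavelengths)))
  cat(sprintf("  gain %.1f, rupture gray %.2f (noise sd %.2f)\n",
              x$gain, x$rupture_gray, x$rupture_noise))
  invisible(x)
}

#' Lipid thickness map
#'
#' The simulator's latent state: per-pixel lipid-layer thickness in nm plus a
#' boolean rupture mask marking pixels where the film has broken and the
#' underlying surface is exposed.
#'
#' @param values Numeric matrix of thicknesses (nm), all non-negative.
#' @param rupture_mask Logical matrix of the same shape; default all `FALSE`.
#' @return An object of class `thickness_map`.
#' @export
thickness_map <- function(values, rupture_mask = NULL) {
  values <- as.matrix(values)
  if (any(values < 0)) stop_invalid("thickness values must be >= 0")
  if (is.null(rupture_mask))
    rupture_mask <- matrix(FALSE, nrow(values), ncol(values))
  rupture_mask <- as.matrix(rupture_mask)
  if (!identical(dim(rupture_mask), dim(values)))
    stop_invalid("rupture_mask and values must have identical shape")
  storage.mode(rupture_mask) <- "logical"
  structure(list(values = values, rupture_mask = rupture_mask),
            class = "thickness_map")
}

#' @export
print.thickness_map <- function(x, ...) {
  cat(sprintf("Thickness map %d x %d px, %.0f-%.0f nm, %d ruptured px\n",
              nrow(x$values), ncol(x$values), min(x$values), max(x$values),
              sum(x$rupture_mask)))
  invisible(x)
}

#' Normal-incidence Fresnel amplitude reflection coefficient
#'
#' @param n1,n2 Refractive indices on either side of the interface.
#' @return `(n1 - n2) / (n1 + n2)`: the signed amplitude coefficient, with the
#'   sign carrying the half-wave phase flip at a low-to-high index interface.
#' @export
fresnel_amplitude <- function(n1, n2) {
  if (any(n1 <= 0) || any(n2 <= 0))
    stop_invalid("refractive indices must be positive")
  (n1 - n2) / (n1 + n2)
}

#' Two-beam thin-film reflectance
#'
#' Reflectance of a film of thickness `d` at wavelength `lambda` under the
#' two-beam (first-order) approximation:
#' `R = r1^2 + r2^2 + 2 r1 r2 cos(4 pi n_lipid d / lambda)`,
#' where `r1` and `r2` are the Fresnel amplitudes of the front (air/lipid)
#' and back (lipid/aqueous) interfaces. Both interface coefficients are small
#' (< 0.2) for tear-film indices, so this agrees with the full multiple-beam
#' (Airy) summation to within about 1%.
#'
#' @param d Thickness in nm (scalar or vector, >= 0).
#' @param lambda Wavelength in nm; must lie within the model's grid range.
#' @param model An [optical_model()].
#' @return Reflectance fraction(s), clamped to \[0, 1\]; vectorised with the
#'   usual recycling over `d` and `lambda`.
#' @export
thin_film_reflectance <- function(d, lambda, model = optical_model()) {
  if (any(d < 0)) stop_invalid("thickness d must be >= 0")
  wl <- range(model$wavelengths)
  if (any(lambda < wl[1] | lambda > wl[2]))
    stop_invalid("lambda outside the model wavelength grid [%g, %g] nm",
                 wl[1], wl[2])
  r1 <- fresnel_amplitude(model$n_air, model$n_lipid)
  r2 <- fresnel_amplitude(model$n_lipid, model$n_aqueous)
  phase <- 4 * pi * model$n_lipid * d / lambda
  clamp01(r1^2 + r2^2 + 2 * r1 * r2 * cos(phase))
}

# CIE 1931 2-degree color-matching functions via the multi-lobe piecewise
# Gaussian analytic fit (accurate to ~1% of peak, ample for rendering).
cie_cmf <- function(lambda) {
  g <- function(x, mu, s1, s2) {
    s <- ifelse(x < mu, s1, s2)
    exp(-((x - mu)^2) / (2 * s^2))
  }
  xbar <- 1.056 * g(lambda, 599.8, 37.9, 31.0) +
    0.362 * g(lambda, 442.0, 16.0, 26.7) -
    0.065 * g(lambda, 501.1, 20.4, 26.2)
  ybar <- 0.821 * g(lambda, 568.8, 46.9, 40.5) +
    0.286 * g(lambda, 530.9, 16.3, 31.1)
  zbar <- 1.217 * g(lambda, 437.0, 11.8, 36.0) +
    0.681 * g(lambda, 459.0, 26.0, 13.8)
  cbind(x = xbar, y = ybar, z = zbar)
}

# XYZ of sRGB reference white (D65) and the XYZ -> linear sRGB matrix.
.d65_white <- c(0.95047, 1.0, 1.08883)
.xyz_to_rgb <- matrix(c(
  3.2406, -1.5372, -0.4986,
  -0.9689, 1.8758, 0.0415,
  0.0557, -0.2040, 1.0570), nrow = 3, byrow = TRUE)

srgb_gamma <- function(x) {
  ifelse(x <= 0.0031308, 12.92 * x, 1.055 * x^(1 / 2.4) - 0.055)
}

#' Convert a reflectance spectrum to display sRGB
#'
#' Integrates reflectance times illuminant against the CIE 1931 2-degree
#' color-matching functions, normalises by the illuminant white point (von
#' Kries adaptation to the sRGB D65 white, so a flat spectrum maps to a
#' neutral gray), converts through the standard XYZ-to-linear-sRGB matrix,
#' clips to gamut and applies the sRGB transfer curve. The model's exposure
#' `gain` scales the spectrum first.
#'
#' @param reflectances Numeric vector with one reflectance per model
#'   wavelength, or an `n x n_wavelengths` matrix of spectra (one per row).
#' @param model An [optical_model()].
#' @return An RGB triple in \[0,1\]^3, or an `n x 3` matrix for matrix input.
#' @export
spectrum_to_srgb <- function(reflectances, model = optical_model()) {
  vec_in <- is.null(dim(reflectances))
  R <- if (vec_in) matrix(reflectances, nrow = 1) else as.matrix(reflectances)
  nl <- length(model$wavelengths)
  if (ncol(R) != nl)
    stop_invalid("expected %d reflectance values per spectrum, got %d",
                 nl, ncol(R))
  cmf <- cie_cmf(model$wavelengths)
  wts <- cmf * model$illuminant            # per-wavelength XYZ weights
  white <- colSums(wts)                    # illuminant white point
  xyz <- (model$gain * R) %*% wts
  # von Kries scaling in XYZ: illuminant white -> D65 white -> sRGB (1,1,1)
  xyz <- sweep(xyz, 2, .d65_white / white, `*`)
  rgb_lin <- xyz %*% t(.xyz_to_rgb)
  out <- srgb_gamma(clamp01(rgb_lin))
  colnames(out) <- c("r", "g", "b")
  if (vec_in) drop(out) else out
}

#' Render a thickness map as an interference color image
#'
#' Applies [thin_film_reflectance()] and [spectrum_to_srgb()] per pixel.
#' Pixels under the rupture mask are drawn with the exposed-surface
#' appearance: a dark desaturated gray with multiplicative texture noise.
#'
#' @param thickness A [thickness_map()].
#' @param model An [optical_model()].
#' @param noise_seed Seed for the exposed-surface texture noise (the render
#'   is fully deterministic given `thickness`, `model` and this seed).
#' @return An H x W x 3 array with values in \[0, 1\].
#' @export
render_interference <- function(thickness, model = optical_model(),
                                noise_seed = 0L) {
  stopifnot(inherits(thickness, "thickness_map"))
  d <- thickness$values
  h <- nrow(d); w <- ncol(d)
  lam <- model$wavelengths
  r1 <- fresnel_amplitude(model$n_air, model$n_lipid)
  r2 <- fresnel_amplitude(model$n_lipid, model$n_aqueous)
  base <- r1^2 + r2^2
  k <- 4 * pi * model$n_lipid / lam        # phase per nm of thickness
  out <- matrix(0, h * w, 3)
  dv <- as.vector(d)
  # chunk rows of the (pixels x wavelengths) matrix to bound memory
  chunk <- max(1L, floor(4e6 / length(lam)))
  starts <- seq(1L, length(dv), by = chunk)
  for (s in starts) {
    idx <- s:min(s + chunk - 1L, length(dv))
    R <- clamp01(base + 2 * r1 * r2 * cos(outer(dv[idx], k)))
    out[idx, ] <- spectrum_to_srgb(R, model)
  }
  rupt <- as.vector(thickness$rupture_mask)
  if (any(rupt)) {
    noise <- with_local_seed(noise_seed,
      exp(stats::rnorm(sum(rupt), 0, model$rupture_noise)))
    gray <- clamp01(model$rupture_gray * noise)
    out[rupt, ] <- matrix(gray, ncol = 3, nrow = sum(rupt))
  }
  array(out, dim = c(h, w, 3))
}

#' Write an RGB image as an 8-bit PNG
#'
#' All color math in the package is floating point; quantisation to 8 bits
#' happens only here.
#'
#' @param img H x W x 3 array in \[0, 1\].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_image_png <- function(img, path) {
  assert_rgb(img)
  q <- round(clamp01(img) * 255) / 255
  png::writePNG(q, path)
  invisible(path)
}

#' Read an 8-bit RGB PNG as a \[0,1\] float array
#'
#' @param path PNG file path.
#' @return H x W x 3 array.
#' @export
read_image_png <- function(path) {
  img <- png::readPNG(path)
  if (length(dim(img)) == 2L) img <- array(rep(img, 3), c(dim(img), 3))
  if (dim(img)[3] == 4L) img <- img[, , 1:3, drop = FALSE]
  img
}
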