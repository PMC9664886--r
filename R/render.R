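#' Encode a colour parameter to an 8-bit channel value
#'
#' The ground-truth colour parameters lie in \[0.05, 0.95\] and are scaled
#' linearly to 8-bit integers with half-up rounding, giving the range
#' 13-242.
#'
#' @param value Numeric vector of colour parameters in \[0.05, 0.95\].
#' @return Integer vector of 8-bit levels.
#' @export
#' @examples
#' encode_channel(c(0.05, 0.5, 0.95))
encode_channel <- function(value) {
  if (any(!is.finite(value)) || any(value < 0.05 - 1e-12) ||
      any(value > 0.95 + 1e-12)) {
    stop("`value` must lie in [0.05, 0.95]", call. = FALSE)
  }
  as.integer(floor(value * 255 + 0.5))
}

# Linear re-map of normalised optical properties into the encodable
# colour-parameter range [0.05, 0.95].
property_to_colour <- function(frac) 0.05 + 0.9 * pmin(pmax(frac, 0), 1)
colour_to_property <- function(colour) (colour - 0.05) / 0.9

# Source-power gain: since Rd <= 1, the brightest possible material peaks
# at exactly `gain_target` of full scale at the nominal 3.5 W, so no
# material ever clips; linear in the scene's source power.
source_gain <- function(fx, calib, source_power = 3.5) {
  calib$gain_target * (source_power / 3.5)
}

# Per-material (Rd_dc, Rd_ac) for a rasterised scene; mu_s_prime is floored
# at a tiny value to keep the diffusion model defined for degenerate
# factor combinations.
material_reflectances <- function(materials, fx, calib) {
  props <- factors_to_properties(materials, calib)
  mu_s <- pmax(props$mu_s_prime, 1e-4 * calib$mu_s_max)
  list(rd_dc = diffuse_reflectance(props$mu_a, mu_s, 0, calib$n_rel),
       rd_ac = diffuse_reflectance(props$mu_a, mu_s, fx, calib$n_rel),
       props = props)
}

new_sfdi_image <- function(pixels, fx, phase, geometry, quantised = FALSE) {
  structure(list(pixels = pixels, fx = fx, phase = phase,
                 geometry = geometry, quantised = quantised),
            class = "sfdi_image")
}

quantise_image <- function(pixels) floor(pmin(pmax(pixels, 0), 1) * 255 + 0.5) / 255

# Optional seeded sensor-noise stage (off by default): additive Gaussian
# plus signal-dependent (Poisson-like) noise.
apply_noise <- function(pixels, noise, seed) {
  rng <- local_rng(seed)
  n <- length(pixels)
  out <- pixels +
    (noise$gaussian_sd %||% 0) * rng$norm(n) +
    sqrt(pmax(pixels, 0) * (noise$poisson_scale %||% 0)) * rng$norm(n)
  array(pmin(pmax(out, 0), 1), dim = dim(pixels))
}

#' Render the fringe-illuminated input image of a flat scene
#'
#' Telecentric sinusoidal illumination at the scene's spatial frequency:
#' each pixel with optical properties `(mu_a, mu_s')` receives
#' `I = g * (Rd(0)/2 + Rd(fx)/2 * cos(2 pi fx u + phase))`, with `u` the
#' lateral position in mm and `g` the normalised source gain. The three
#' colour channels carry the same intensity.
#'
#' @param scene A flat `scene_spec`.
#' @param res Output resolution in pixels (square image).
#' @param calib An `sfdi_calib`.
#' @param quantise Quantise intensities to 8-bit levels.
#' @param noise Optional list with `gaussian_sd` and/or `poisson_scale`;
#'   `NULL` (default) renders noiselessly.
#' @param noise_seed Seed for the noise stage.
#' @return An `sfdi_image` with pixel values in \[0, 1\].
#' @export
render_flat_sfdi <- function(scene, res = 256, calib = sfdi_calibration(),
                             quantise = FALSE, noise = NULL, noise_seed = 1L) {
  stopifnot(inherits(scene, "scene_spec"))
  if (scene$geometry != "flat") {
    stop("render_flat_sfdi() requires a flat scene", call. = FALSE)
  }
  ras <- rasterise_scene(scene, res, calib)
  fx <- scene$illumination$fx
  refl <- material_reflectances(ras$materials, fx, calib)
  g <- source_gain(fx, calib, scene$illumination$source_power)
  dc <- matrix(refl$rd_dc[ras$material], res, res)
  ac <- matrix(refl$rd_ac[ras$material], res, res)
  u <- matrix((seq_len(res) - 0.5) * ras$pixel_mm, res, res, byrow = TRUE)
  img <- g * (dc / 2 + ac / 2 * cos(2 * pi * fx * u + scene$illumination$phase))
  img <- pmin(pmax(img, 0), 1)
  pixels <- array(img, dim = c(res, res, 3))
  if (!is.null(noise)) pixels <- apply_noise(pixels, noise, noise_seed)
  if (quantise) pixels <- quantise_image(pixels)
  new_sfdi_image(pixels, fx, scene$illumination$phase, "flat", quantise)
}

#' Render the fringe-illuminated input image of a cylindrical scene
#'
#' Pinhole camera on the cylinder axis with the projector on the axis a
#' short baseline behind it. In the
#' default axial view the camera looks along the lumen: view rays intersect
#' the inner wall, the projected sinusoid's phase is evaluated at the 3-D
#' hit point, the local spatial frequency follows from the projection
#' geometry (finite differences of the fringe phase along the surface), and
#' intensity falls off with the squared distance — producing the distorted,
#' frequency-varying fringes characteristic of imaging inside a lumen. The
#' radial view looks at the wall perpendicular to the axis and converges to
#' the flat render as the radius grows.
#'
#' @param scene A cylinder `scene_spec`.
#' @param res Output resolution in pixels.
#' @param calib An `sfdi_calib`.
#' @param view `"axial"` (endoscopic, default) or `"radial"`.
#' @param focal Pinhole focal length in image-plane units.
#' @param proj_offset_mm Axial displacement of the projector behind the
#'   camera (axial view only). A non-zero baseline is what bends the
#'   projected fringes on the wall; a projector exactly co-located with
#'   the camera would image its own pattern undistorted.
#' @param quantise Quantise to 8-bit levels.
#' @return An `sfdi_image`; pixels beyond the cylinder length are 0.
#' @export
render_cylinder_sfdi <- function(scene, res = 256, calib = sfdi_calibration(),
                                 view = c("axial", "radial"), focal = 1.0,
                                 proj_offset_mm = 10, quantise = FALSE) {
  stopifnot(inherits(scene, "scene_spec"))
  view <- match.arg(view)
  if (scene$geometry != "cylinder") {
    stop("render_cylinder_sfdi() requires a cylinder scene", call. = FALSE)
  }
  ras <- rasterise_cylinder(scene, res, calib, view = view, focal = focal)
  fx <- scene$illumination$fx
  phase0 <- scene$illumination$phase
  R <- ras$radius
  if (view == "axial") {
    # vertical-stripe sinusoid in the image plane of a projector sitting
    # `proj_offset_mm` behind the camera on the axis; the baseline bends
    # the fringes on the wall. Angular frequency anchored so the local
    # frequency is ~fx at the mid-lumen side wall.
    k <- fx * (ras$length / 2 + proj_offset_mm)
    phi <- 2 * pi * k *
      (R * cos(ras$theta) / (ras$wall_z + proj_offset_mm)) + phase0
    d_ref <- if (any(ras$hit)) min(ras$distance[ras$hit]) else R
  } else {
    scale <- calib$fov_mm / focal / 2 / R
    u <- matrix((seq_len(res) - 0.5) / res - 0.5, res, res, byrow = TRUE)
    dy <- u * 2 * scale
    # wall coordinate R*dy + fov/2 matches the flat render's lateral origin
    phi <- 2 * pi * fx * (R * dy + calib$fov_mm / 2) + phase0
    d_ref <- R
  }
  fx_local <- local_frequency(phi, ras, res)
  refl <- material_reflectances(ras$materials, fx, calib)
  g <- source_gain(fx, calib, scene$illumination$source_power)
  props <- refl$props
  mu_a_px <- matrix(props$mu_a[ras$material], res, res)
  mu_s_px <- matrix(pmax(props$mu_s_prime, 1e-4 * calib$mu_s_max)[ras$material],
                    res, res)
  ok <- ras$hit & !is.na(ras$material)
  dc <- ac <- matrix(0, res, res)
  dc[ok] <- diffuse_reflectance(mu_a_px[ok], mu_s_px[ok], 0, calib$n_rel)
  ac[ok] <- diffuse_reflectance(mu_a_px[ok], mu_s_px[ok], fx_local[ok],
                                calib$n_rel)
  img <- matrix(0, res, res)
  falloff <- (d_ref / ras$distance)^2
  img[ok] <- g * falloff[ok] * (dc[ok] / 2 + ac[ok] / 2 * cos(phi[ok]))
  img <- pmin(pmax(img, 0), 1)
  pixels <- array(img, dim = c(res, res, 3))
  if (quantise) pixels <- quantise_image(pixels)
  new_sfdi_image(pixels, fx, phase0, "cylinder", quantise)
}

# Local spatial frequency (cycles/mm) of the projected fringe phase on the
# wall surface, by finite differences of phase over arc length between
# neighbouring pixels' 3-D hit points.
local_frequency <- function(phi, ras, res) {
  R <- ras$radius
  # 3-D hit points
  if (ras$view == "axial") {
    x <- R * cos(ras$theta); y <- R * sin(ras$theta); z <- ras$wall_z
  } else {
    x <- R * cos(ras$theta); y <- R * sin(ras$theta); z <- ras$wall_z
  }
  dphi_c <- phi[, -1] - phi[, -ncol(phi)]
  ds_c <- sqrt((x[, -1] - x[, -ncol(x)])^2 +
               (y[, -1] - y[, -ncol(y)])^2 +
               (z[, -1] - z[, -ncol(z)])^2)
  dphi_r <- phi[-1, ] - phi[-nrow(phi), ]
  ds_r <- sqrt((x[-1, ] - x[-nrow(x), ])^2 +
               (y[-1, ] - y[-nrow(y), ])^2 +
               (z[-1, ] - z[-nrow(z), ])^2)
  gc <- dphi_c / ds_c; gr <- dphi_r / ds_r
  gc[!is.finite(gc)] <- 0; gr[!is.finite(gr)] <- 0
  gc <- cbind(gc, gc[, ncol(gc)])     # replicate the trailing edge
  gr <- rbind(gr, gr[nrow(gr), ])
  f <- sqrt(gc^2 + gr^2) / (2 * pi)
  pmin(f, 0.5)  # cap below the sub-diffusive regime
}

#' Render the ground-truth optical property map of a scene
#'
#' Identical projection geometry to the paired fringe render but
#' flat-shaded: each pixel's colour depends only on its material's factors
#' (no fringes, no falloff). The red channel encodes absorption, green
#' encodes reduced scattering (both linearly re-mapped into \[0.05, 0.95\]
#' then 8-bit encoded to 13-242), and blue is identically 0. Pixels outside
#' the sample (beyond the cylinder length) are 0.
#'
#' @param scene A `scene_spec` (flat or cylinder).
#' @param res Resolution in pixels; must match the paired input render.
#' @param calib An `sfdi_calib`.
#' @param view,focal Camera parameters for cylinder scenes; must match the
#'   paired [render_cylinder_sfdi()] call.
#' @return A `ground_truth_map`: integer array (res x res x 3) of 8-bit
#'   values.
#' @export
render_ground_truth <- function(scene, res = 256, calib = sfdi_calibration(),
                                view = "axial", focal = 1.0) {
  stopifnot(inherits(scene, "scene_spec"))
  ras <- if (scene$geometry == "flat") {
    rasterise_flat(scene, res, calib)
  } else {
    rasterise_cylinder(scene, res, calib, view = view, focal = focal)
  }
  props <- factors_to_properties(ras$materials, calib)
  r_levels <- encode_channel(property_to_colour(props$mu_a / calib$mu_a_max))
  g_levels <- encode_channel(property_to_colour(props$mu_s_prime / calib$mu_s_max))
  idx <- ras$material
  rch <- matrix(0L, res, res); gch <- matrix(0L, res, res)
  okm <- !is.na(idx)
  rch[okm] <- r_levels[idx[okm]]
  gch[okm] <- g_levels[idx[okm]]
  pixels <- array(0L, dim = c(res, res, 3))
  pixels[, , 1] <- rch
  pixels[, , 2] <- gch
  structure(list(pixels = pixels, geometry = scene$geometry),
            class = "ground_truth_map")
}

#' Render a co-registered input/ground-truth image pair
#'
#' Convenience wrapper producing the quantised fringe input and its
#' ground-truth map for one scene, sharing geometry and camera parameters.
#'
#' @inheritParams render_ground_truth
#' @param noise,noise_seed Optional noise stage for the input render (flat
#'   scenes only).
#' @return A list with elements `input` (`sfdi_image`, quantised) and
#'   `truth` (`ground_truth_map`).
#' @export
render_scene_pair <- function(scene, res = 256, calib = sfdi_calibration(),
                              view = "axial", focal = 1.0, noise = NULL,
                              noise_seed = 1L) {
  input <- if (scene$geometry == "flat") {
    render_flat_sfdi(scene, res, calib, quantise = TRUE, noise = noise,
                     noise_seed = noise_seed)
  } else {
    render_cylinder_sfdi(scene, res, calib, view = view, focal = focal,
                         quantise = TRUE)
  }
  truth <- render_ground_truth(scene, res, calib, view = view, focal = focal)
  list(input = input, truth = truth)
}
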