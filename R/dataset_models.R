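#' Enumerate the flat-geometry dataset (four sample models)
#'
#' Builds the keyframe-swept scene lists for the four flat sample models —
#' a homogeneous rectangle, two materials along a curved boundary, three
#' materials along ragged boundaries, and the curved model with tumour
#' spheroids translated and re-scaled across frames. Material final factors
#' sweep 0.05-0.95 (moving each material from mostly absorbing to mostly
#' scattering); absorption and scattering factors can optionally sweep too,
#' expanding the covered region of optical property space.
#'
#' @param n_per_model Frames per model (50 each by default, 200 total).
#' @param final_range,abs_range,sct_range Sweep ranges for the three
#'   factors; a degenerate range (equal endpoints) holds the factor fixed.
#'   Defaults hold the absorbing component at full strength
#'   (`absorption_factor = 0`) and scattering at full strength
#'   (`scattering_factor = 1`), so the final-factor sweep traces the
#'   0.95:0.05 to 0.05:0.95 absorbing:scattering proportion path.
#' @param fx Illumination spatial frequency, mm^-1.
#' @param fov_mm Field of view, mm (spheroid placement scale).
#' @param seed Seed for the ragged boundaries.
#' @param models Subset of the four models to include.
#' @return A list of `scene_spec`, concatenated across models.
#' @export
flat_dataset_scenes <- function(n_per_model = 50,
                                final_range = c(0.05, 0.95),
                                abs_range = c(0, 0), sct_range = c(1, 1),
                                fx = 0.2, fov_mm = 51.2, seed = 1L,
                                models = c("rectangular", "curved", "ragged",
                                           "tumour")) {
  models <- match.arg(models, several.ok = TRUE)
  keys <- function(path, lo, hi) {
    if (lo == hi || n_per_model < 2) return(NULL)
    keyframe_track(path, c(1, n_per_model), c(lo, hi))
  }
  factor_tracks <- function(region_ids) {
    trs <- list()
    for (j in seq_along(region_ids)) {
      i <- region_ids[j]
      # stagger sweep directions so materials contrast within one frame
      rng <- if (j %% 2 == 1) final_range else rev(final_range)
      trs <- c(trs, list(keys(paste0("region.", i, ".final_factor"),
                              rng[1], rng[2])),
               list(keys(paste0("region.", i, ".absorption_factor"),
                         abs_range[1], abs_range[2])),
               list(keys(paste0("region.", i, ".scattering_factor"),
                         sct_range[1], sct_range[2])))
    }
    purrr::compact(trs)
  }
  start_factors <- function(n) {
    material_factors(
      final_factor = rep(final_range[1], n),
      absorption_factor = rep(abs_range[1], n),
      scattering_factor = rep(sct_range[1], n)
    )
  }
  out <- list()
  if ("rectangular" %in% models) {
    base <- flat_scene(start_factors(1), "none", seed = seed, fx = fx)
    out <- c(out, keyframe_sweep(base, factor_tracks(1), 1, n_per_model))
  }
  if ("curved" %in% models) {
    base <- flat_scene(start_factors(2), "curved", seed = seed + 1L, fx = fx)
    out <- c(out, keyframe_sweep(base, factor_tracks(1:2), 1, n_per_model))
  }
  if ("ragged" %in% models) {
    base <- flat_scene(start_factors(3), "ragged", seed = seed + 2L, fx = fx)
    out <- c(out, keyframe_sweep(base, factor_tracks(1:3), 1, n_per_model))
  }
  if ("tumour" %in% models) {
    base <- flat_scene(start_factors(2), "curved", seed = seed + 3L, fx = fx)
    mid <- mean(final_range)
    base <- add_spheroids(base, tibble::tibble(
      cx = 0.35 * fov_mm, cy = 0.4 * fov_mm, a = 0.08 * fov_mm,
      b = 0.08 * fov_mm, c = 0.08 * fov_mm,
      final_factor = mid, absorption_factor = abs_range[1],
      scattering_factor = sct_range[2]), fov_mm = fov_mm)
    trs <- c(factor_tracks(1:2), if (n_per_model >= 2) list(
      # XYZ-style translation and scale keyframes for the tumour
      keyframe_track("spheroid.1.cx", c(1, n_per_model),
                     c(0.25, 0.75) * fov_mm),
      keyframe_track("spheroid.1.cy", c(1, n_per_model),
                     c(0.65, 0.3) * fov_mm),
      keyframe_track("spheroid.1.a", c(1, n_per_model),
                     c(0.05, 0.14) * fov_mm),
      keyframe_track("spheroid.1.b", c(1, n_per_model),
                     c(0.12, 0.06) * fov_mm),
      keyframe_track("spheroid.1.final_factor", c(1, n_per_model),
                     rev(final_range))
    ))
    out <- c(out, keyframe_sweep(base, trs, 1, n_per_model))
  }
  out
}

#' Enumerate the cylindrical (lumen) dataset
#'
#' Two parts, mirroring the cylinder study design: a plain-lumen sweep of
#' the wall material factors, and a polyp part where short sweeps are run
#' over lumens with freshly scattered polyps of varying sizes, positions
#' and optical properties.
#'
#' @param n_sweep Frames of the plain-lumen material sweep.
#' @param n_polyp Frames of the polyp part.
#' @param radius,length Cylinder geometry, mm.
#' @param frames_per_polyp_scene Frames rendered per polyp arrangement.
#' @param n_polyps Polyps per arrangement.
#' @param final_range,abs_range,sct_range Factor sweep ranges as in
#'   [flat_dataset_scenes()].
#' @param fx Illumination spatial frequency, mm^-1.
#' @param seed Master seed (polyp scatter is reproducible from it).
#' @return A list of `scene_spec`.
#' @export
cylinder_dataset_scenes <- function(n_sweep = 200, n_polyp = 120,
                                    radius = 15, length = 80,
                                    frames_per_polyp_scene = 10,
                                    n_polyps = 4,
                                    final_range = c(0.05, 0.95),
                                    abs_range = c(0, 0), sct_range = c(1, 1),
                                    fx = 0.2, seed = 1L) {
  keys <- function(path, lo, hi, n) {
    if (lo == hi || n < 2) return(NULL)
    keyframe_track(path, c(1, n), c(lo, hi))
  }
  wall_tracks <- function(n) purrr::compact(list(
    keys("region.1.final_factor", final_range[1], final_range[2], n),
    keys("region.1.absorption_factor", abs_range[1], abs_range[2], n),
    keys("region.1.scattering_factor", sct_range[1], sct_range[2], n)
  ))
  wall0 <- material_factors(final_range[1], abs_range[1], sct_range[1])
  out <- list()
  if (n_sweep > 0) {
    base <- cylinder_scene(radius, length, wall0, seed = seed, fx = fx)
    out <- c(out, keyframe_sweep(base, wall_tracks(n_sweep), 1, n_sweep))
  }
  if (n_polyp > 0) {
    n_scenes <- ceiling(n_polyp / frames_per_polyp_scene)
    for (j in seq_len(n_scenes)) {
      nf <- min(frames_per_polyp_scene, n_polyp - (j - 1) * frames_per_polyp_scene)
      polyps <- random_polyps(n_polyps, radius, length,
                              size_range = c(0.1, 0.3) * radius,
                              factor_range = final_range,
                              seed = seed + 100L + j)
      base <- cylinder_scene(radius, length, wall0, polyps,
                             seed = seed + 100L + j, fx = fx)
      out <- c(out, keyframe_sweep(base, wall_tracks(nf), 1, nf))
    }
  }
  out
}
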