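#' Parametric sample scenes
#'
#' A scene specification describes one synthetic SFDI sample: a flat slab
#' whose surface is partitioned into 1-3 material regions (separated by
#' curved or ragged boundaries), optionally decorated with spheroidal
#' tumours, or a hollow cylinder (lumen) with polyp structures on the inner
#' wall. Scenes are plain lists so they serialise losslessly to YAML.
#'
#' @name scene_spec
#' @keywords internal
NULL

new_scene_spec <- function(geometry, regions, spheroids, illumination,
                           cylinder_params = NULL, seed = 1L,
                           frame_index = 1L) {
  structure(list(geometry = geometry, regions = regions,
                 spheroids = spheroids, illumination = illumination,
                 cylinder_params = cylinder_params, seed = as.integer(seed),
                 frame_index = as.integer(frame_index)),
            class = "scene_spec")
}

default_illumination <- function(fx = 0.2, phase = 0, source_power = 3.5) {
  list(fx = fx, phase = phase, source_power = source_power)
}

#' Construct a flat sample scene
#'
#' Builds one of the flat sample models: a single homogeneous material, two
#' materials meeting along a curved boundary (circular arc parametrised by
#' chord position and sagitta), or three materials meeting along ragged
#' boundaries (seeded smoothed random walks). Boundaries run top-to-bottom;
#' regions are ordered left to right.
#'
#' @param factors A data frame of material factors, one row per material
#'   (see [material_factors()]); 1, 2 or 3 rows.
#' @param boundary_style `"none"` (1 material), `"curved"` or `"ragged"`.
#' @param boundary_params For `"curved"`: list with `chord` (fractional
#'   boundary position(s) across the width) and `sagitta` (fractional bulge,
#'   0 = straight line). For `"ragged"`: list with `amplitude` (fractional
#'   walk scale) and `smooth` (moving-average half-width in pixels).
#' @param seed Integer seed controlling the ragged walks.
#' @param fx,phase Illumination spatial frequency (mm^-1) and phase (rad).
#' @param source_power Source power in W; enters rendering only as a
#'   normalised linear gain.
#' @return A `scene_spec`.
#' @export
#' @examples
#' flat_scene(material_factors(c(0.3, 0.7)), boundary_style = "curved")
flat_scene <- function(factors, boundary_style = c("none", "curved", "ragged"),
                       boundary_params = NULL, seed = 1L,
                       fx = 0.2, phase = 0, source_power = 3.5) {
  boundary_style <- match.arg(boundary_style)
  factors <- material_factors(factors$final_factor, factors$absorption_factor,
                              factors$scattering_factor)
  n <- nrow(factors)
  if (n < 1 || n > 3) stop("flat scenes support 1-3 materials", call. = FALSE)
  if ((boundary_style == "none") != (n == 1)) {
    stop("`boundary_style` must be \"none\" iff there is a single material",
         call. = FALSE)
  }
  if (is.null(boundary_params)) {
    boundary_params <- switch(boundary_style,
      none = list(),
      curved = list(chord = if (n == 2) 0.5 else c(1 / 3, 2 / 3),
                    sagitta = 0.15),
      ragged = list(chord = if (n == 2) 0.5 else c(1 / 3, 2 / 3),
                    amplitude = 0.08, smooth = 9)
    )
  }
  nb <- n - 1L
  if (nb > 0 && length(boundary_params$chord) != nb) {
    stop("need ", nb, " chord position(s) for ", n, " materials",
         call. = FALSE)
  }
  regions <- lapply(seq_len(n), function(i) {
    list(region_id = i, boundary_style = boundary_style,
         boundary_params = boundary_params, factors = factors[i, ])
  })
  new_scene_spec("flat", regions, spheroids = list(),
                 illumination = default_illumination(fx, phase, source_power),
                 seed = seed)
}

#' Attach tumour spheroids to a scene
#'
#' Spheroids are given in sample coordinates (mm; the flat sample spans
#' `[0, fov_mm]` in x and y). In projection, later spheroids occlude earlier
#' ones where they overlap. Spheroids fully outside the field of view are
#' retained in the specification with a warning.
#'
#' @param scene A `scene_spec`.
#' @param spheroids A data frame with columns `cx`, `cy` (mm), semi-axes
#'   `a`, `b`, `c` (mm) and the three material-factor columns.
#' @param fov_mm Field of view used for the visibility check (mm).
#' @return The scene with spheroids appended.
#' @export
add_spheroids <- function(scene, spheroids, fov_mm = 51.2) {
  stopifnot(inherits(scene, "scene_spec"))
  if (is.null(spheroids) || nrow(spheroids) == 0) return(scene)
  req <- c("cx", "cy", "a", "b", "c", "final_factor", "absorption_factor",
           "scattering_factor")
  if (!all(req %in% names(spheroids))) {
    stop("spheroid table must have columns: ", paste(req, collapse = ", "),
         call. = FALSE)
  }
  if (any(spheroids$a <= 0 | spheroids$b <= 0 | spheroids$c <= 0)) {
    stop("spheroid semi-axes must be positive", call. = FALSE)
  }
  outside <- spheroids$cx + spheroids$a < 0 | spheroids$cx - spheroids$a > fov_mm |
    spheroids$cy + spheroids$b < 0 | spheroids$cy - spheroids$b > fov_mm
  if (scene$geometry == "flat" && any(outside)) {
    warning(sum(outside), " spheroid(s) fall outside the field of view")
  }
  scene$spheroids <- c(scene$spheroids,
                       lapply(seq_len(nrow(spheroids)),
                              function(i) as.list(spheroids[i, ])))
  scene
}

#' Construct a cylindrical lumen scene
#'
#' Models imaging inside a tubular organ: a hollow cylinder of given radius
#' and length with the camera and projector on the axis. Polyps are
#' hemispheroids on the inner wall, specified in wall coordinates
#' (`theta` rad, `z` mm along the axis) with arc/axial semi-axes in mm.
#'
#' @param radius,length Cylinder radius and length, mm.
#' @param wall_factors One-row data frame of wall material factors.
#' @param polyps Optional data frame with columns `theta`, `z`, `a` (arc
#'   semi-axis, mm), `c` (axial semi-axis, mm) and the three factor columns.
#' @param seed Integer seed recorded for provenance.
#' @param fx,phase,source_power Illumination parameters as in [flat_scene()].
#' @return A `scene_spec` with geometry `"cylinder"`.
#' @export
cylinder_scene <- function(radius = 15, length = 80, wall_factors,
                           polyps = NULL, seed = 1L,
                           fx = 0.2, phase = 0, source_power = 3.5) {
  if (radius <= 0 || length <= 0) {
    stop("cylinder radius and length must be positive", call. = FALSE)
  }
  wall_factors <- material_factors(wall_factors$final_factor,
                                   wall_factors$absorption_factor,
                                   wall_factors$scattering_factor)
  if (nrow(wall_factors) != 1) stop("one wall material expected", call. = FALSE)
  sph <- list()
  if (!is.null(polyps) && nrow(polyps) > 0) {
    req <- c("theta", "z", "a", "c", "final_factor", "absorption_factor",
             "scattering_factor")
    if (!all(req %in% names(polyps))) {
      stop("polyp table must have columns: ", paste(req, collapse = ", "),
           call. = FALSE)
    }
    if (any(polyps$a > radius)) {
      stop("polyp semi-axis exceeds the cylinder radius", call. = FALSE)
    }
    sph <- lapply(seq_len(nrow(polyps)), function(i) as.list(polyps[i, ]))
  }
  regions <- list(list(region_id = 1L, boundary_style = "none",
                       boundary_params = list(), factors = wall_factors))
  new_scene_spec("cylinder", regions, spheroids = sph,
                 illumination = default_illumination(fx, phase, source_power),
                 cylinder_params = list(radius = radius, length = length),
                 seed = seed)
}

#' Scatter random polyps around a lumen wall
#'
#' Samples polyp positions uniformly in wall coordinates, sizes uniformly in
#' given ranges, and material factors uniformly in a factor range;
#' reproducible from the seed.
#'
#' @param n Number of polyps.
#' @param radius,length Cylinder geometry the polyps must fit (mm).
#' @param size_range Arc/axial semi-axis range, mm.
#' @param factor_range Range for the polyp final factor.
#' @param seed Integer seed.
#' @return A polyp data frame for [cylinder_scene()].
#' @export
random_polyps <- function(n, radius, length, size_range = c(2, 6),
                          factor_range = c(0.1, 0.9), seed = 1L) {
  rng <- local_rng(seed)
  tibble::tibble(
    theta = rng$unif(n, -pi, pi),
    z = rng$unif(n, 0.15 * length, 0.85 * length),
    a = rng$unif(n, size_range[1], min(size_range[2], radius)),
    c = rng$unif(n, size_range[1], size_range[2]),
    final_factor = rng$unif(n, factor_range[1], factor_range[2]),
    absorption_factor = rng$unif(n, 0, 0.3),
    scattering_factor = rng$unif(n, 0.7, 1)
  )
}

# Seeded RNG helper that does not disturb the global stream.
local_rng <- function(seed) {
  env <- new.env()
  env$state <- local({
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    set.seed(seed)
    s <- get(".Random.seed", globalenv())
    if (is.null(old)) rm(".Random.seed", envir = globalenv()) else assign(".Random.seed", old, globalenv())
    s
  })
  draw <- function(fun, ...) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    assign(".Random.seed", env$state, globalenv())
    out <- fun(...)
    env$state <- get(".Random.seed", globalenv())
    if (is.null(old)) rm(".Random.seed", envir = globalenv()) else assign(".Random.seed", old, globalenv())
    out
  }
  list(
    unif = function(n, min = 0, max = 1) draw(stats::runif, n, min, max),
    norm = function(n, mean = 0, sd = 1) draw(stats::rnorm, n, mean, sd),
    sample = function(x, size, replace = FALSE) draw(base::sample, x, size, replace),
    pois = function(n, lambda) draw(stats::rpois, n, lambda)
  )
}

# ---- rasterisation ---------------------------------------------------------

# Boundary x-position (fraction of width) as a function of the fractional
# row coordinate t in [0, 1].
boundary_position <- function(style, params, k, t, seed) {
  chord <- params$chord[k]
  if (style == "curved") {
    s <- params$sagitta %||% 0
    if (abs(s) < 1e-12) return(rep(chord, length(t)))
    # circular arc through (t=0, chord) and (t=1, chord), apex at chord + s
    r <- (0.25 + s^2) / (2 * abs(s))
    chord + s - sign(s) * r + sign(s) * sqrt(pmax(r^2 - (t - 0.5)^2, 0))
  } else if (style == "ragged") {
    amp <- params$amplitude %||% 0.08
    sm <- params$smooth %||% 9
    rng <- local_rng(seed * 131 + k)
    n <- length(t)
    walk <- cumsum(rng$norm(n)) / sqrt(n)
    kern <- rep(1, 2 * sm + 1)
    walk <- stats::filter(c(rep(walk[1], sm), walk, rep(walk[n], sm)),
                          kern / length(kern), sides = 2)
    walk <- as.numeric(walk)[sm + seq_len(n)]
    chord + amp * (walk - mean(walk))
  } else {
    stop("unknown boundary style: ", style, call. = FALSE)
  }
}

#' Rasterise a scene to per-pixel material indices
#'
#' Produces the material-index map underlying both the fringe render and the
#' ground-truth map, guaranteeing pixel-exact co-registration of the pair.
#' Every pixel is assigned exactly one material: base regions partition the
#' surface and spheroids/polyps overwrite them in order (later entries
#' occlude earlier ones).
#'
#' @param scene A `scene_spec`.
#' @param res Image resolution (pixels per side).
#' @param calib An `sfdi_calib` (supplies the field of view).
#' @return A list: `material` (res x res integer matrix), `materials`
#'   (tibble of factor rows indexed by material id), and for cylinder scenes
#'   the per-pixel geometry (`distance`, `wall_z`, `theta`, `hit`).
#' @export
rasterise_scene <- function(scene, res = 256, calib = sfdi_calibration()) {
  stopifnot(inherits(scene, "scene_spec"))
  switch(scene$geometry,
         flat = rasterise_flat(scene, res, calib),
         cylinder = rasterise_cylinder(scene, res, calib),
         stop("unknown geometry: ", scene$geometry, call. = FALSE))
}

rasterise_flat <- function(scene, res, calib) {
  n <- length(scene$regions)
  mat <- matrix(1L, res, res)
  t_row <- (seq_len(res) - 0.5) / res
  x_col <- matrix((seq_len(res) - 0.5) / res, res, res, byrow = TRUE)
  if (n > 1) {
    style <- scene$regions[[1]]$boundary_style
    params <- scene$regions[[1]]$boundary_params
    for (k in seq_len(n - 1)) {
      xb <- boundary_position(style, params, k, t_row, scene$seed)
      mat[x_col >= matrix(xb, res, res)] <- k + 1L
    }
  }
  factors <- dplyr::bind_rows(lapply(scene$regions, `[[`, "factors"))
  # spheroids occlude base regions; later spheroids occlude earlier ones
  px_mm <- calib$fov_mm / res
  x_mm <- x_col * calib$fov_mm
  y_mm <- matrix(t_row * calib$fov_mm, res, res)
  for (sp in scene$spheroids) {
    inside <- ((x_mm - sp$cx) / sp$a)^2 + ((y_mm - sp$cy) / sp$b)^2 <= 1
    id <- nrow(factors) + 1L
    factors <- dplyr::bind_rows(
      factors, tibble::tibble(final_factor = sp$final_factor,
                              absorption_factor = sp$absorption_factor,
                              scattering_factor = sp$scattering_factor))
    mat[inside] <- id
  }
  list(material = mat, materials = factors, pixel_mm = px_mm)
}

# Pinhole camera on the cylinder axis. `view = "axial"` looks along the
# axis (the endoscopic geometry); `view = "radial"` looks at the wall
# perpendicular to the axis and converges to the flat geometry as the
# radius grows.
rasterise_cylinder <- function(scene, res, calib, view = "axial",
                               focal = 1.0) {
  cp <- scene$cylinder_params
  R <- cp$radius; L <- cp$length
  u <- matrix((seq_len(res) - 0.5) / res - 0.5, res, res, byrow = TRUE)
  v <- matrix((seq_len(res) - 0.5) / res - 0.5, res, res)
  if (view == "axial") {
    # rays (u, v, focal) from the origin; wall at x^2 + y^2 = R^2
    rr <- sqrt(u^2 + v^2)
    rr[rr < 1e-9] <- 1e-9
    t_hit <- R / rr
    z <- t_hit * focal
    hit <- z <= L & z > 0
    theta <- atan2(v, u)
    dist <- sqrt(R^2 + z^2)
  } else {
    # optical axis along +x; image plane spans fov at distance R
    scale <- calib$fov_mm / focal / 2 / R  # half-FOV tan at distance R
    dx <- 1; dy <- u * 2 * scale; dz_ <- v * 2 * scale
    # intersect x^2 + y^2 = R^2 with ray t*(1, dy, dz_)
    t_hit <- R / sqrt(1 + dy^2)
    z <- t_hit * dz_ + L / 2
    hit <- z >= 0 & z <= L
    theta <- atan2(t_hit * dy, t_hit * dx)
    dist <- t_hit * sqrt(1 + dy^2 + dz_^2)
  }
  # wall material map: base wall = 1, polyps overwrite
  mat <- matrix(1L, res, res)
  factors <- dplyr::bind_rows(lapply(scene$regions, `[[`, "factors"))
  arc <- R * theta
  for (sp in scene$spheroids) {
    dtheta <- (theta - sp$theta + pi) %% (2 * pi) - pi
    inside <- ((R * dtheta) / sp$a)^2 + ((z - sp$z) / sp$c)^2 <= 1 & hit
    id <- nrow(factors) + 1L
    factors <- dplyr::bind_rows(
      factors, tibble::tibble(final_factor = sp$final_factor,
                              absorption_factor = sp$absorption_factor,
                              scattering_factor = sp$scattering_factor))
    mat[inside] <- id
  }
  mat[!hit] <- NA_integer_
  list(material = mat, materials = factors, distance = dist, wall_z = z,
       theta = theta, hit = hit, view = view, focal = focal,
       radius = R, length = L)
}

# ---- keyframe sweeps -------------------------------------------------------

#' Define a keyframe track
#'
#' A track names one scalar scene parameter and a set of (frame, value)
#' keyframes; values are linearly interpolated between keyframes, mirroring
#' animation-style dataset enumeration.
#'
#' Parameter paths are dotted strings: `"region.<i>.<factor>"`,
#' `"spheroid.<i>.<field>"`, `"illumination.fx"`, `"illumination.phase"`,
#' `"cylinder.radius"`, `"cylinder.length"`.
#'
#' @param parameter_path Dotted path naming the target field.
#' @param frames Integer keyframe positions, strictly increasing.
#' @param values Values at the keyframes.
#' @return A tibble of class `keyframe_track`.
#' @export
#' @examples
#' keyframe_track("region.1.final_factor", c(1, 100), c(0.05, 0.95))
keyframe_track <- function(parameter_path, frames, values) {
  stopifnot(length(frames) == length(values), length(frames) >= 1)
  if (is.unsorted(frames, strictly = TRUE)) {
    stop("keyframe frames must be strictly increasing", call. = FALSE)
  }
  structure(tibble::tibble(parameter_path = parameter_path,
                           frame = as.integer(frames), value = values),
            class = c("keyframe_track", class(tibble::tibble())))
}

#' Interpolate a keyframe track at a frame
#'
#' Piecewise-linear interpolation between keyframes; exact at keyframes.
#'
#' @param track A `keyframe_track`.
#' @param frame Integer frame within the keyframe range.
#' @return The interpolated value.
#' @export
interpolate_track <- function(track, frame) {
  rng <- range(track$frame)
  if (any(frame < rng[1] | frame > rng[2])) {
    stop("frame outside the keyframe range [", rng[1], ", ", rng[2], "]",
         call. = FALSE)
  }
  stats::approx(track$frame, track$value, xout = frame)$y
}

set_scene_param <- function(scene, path, value) {
  parts <- strsplit(path, ".", fixed = TRUE)[[1]]
  bad <- function() stop("track targets unknown field: ", path, call. = FALSE)
  head <- parts[1]
  if (head == "illumination") {
    if (length(parts) != 2 || !parts[2] %in% names(scene$illumination)) bad()
    scene$illumination[[parts[2]]] <- value
  } else if (head == "cylinder") {
    if (is.null(scene$cylinder_params) || length(parts) != 2 ||
        !parts[2] %in% names(scene$cylinder_params)) bad()
    scene$cylinder_params[[parts[2]]] <- value
  } else if (head == "region") {
    i <- suppressWarnings(as.integer(parts[2]))
    if (length(parts) != 3 || is.na(i) || i > length(scene$regions)) bad()
    if (!parts[3] %in% names(scene$regions[[i]]$factors)) bad()
    scene$regions[[i]]$factors[[parts[3]]] <- value
  } else if (head == "spheroid") {
    i <- suppressWarnings(as.integer(parts[2]))
    if (length(parts) != 3 || is.na(i) || i > length(scene$spheroids)) bad()
    if (!parts[3] %in% names(scene$spheroids[[i]])) bad()
    scene$spheroids[[i]][[parts[3]]] <- value
  } else bad()
  scene
}

#' Enumerate a dataset by sweeping keyframe tracks
#'
#' Produces one scene per frame between `start` and `end`, with every
#' tracked parameter linearly interpolated — the animation-style mechanism
#' used to enumerate training datasets.
#'
#' @param base_scene A `scene_spec`.
#' @param tracks A list of [keyframe_track()] objects (possibly empty).
#' @param start,end First and last frame (inclusive); `end - start + 1`
#'   scenes are returned.
#' @return A list of `scene_spec`, each with `frame_index` set.
#' @export
keyframe_sweep <- function(base_scene, tracks = list(), start = 1L,
                           end = 100L) {
  stopifnot(inherits(base_scene, "scene_spec"), start <= end)
  if (inherits(tracks, "keyframe_track")) tracks <- list(tracks)
  lapply(seq.int(start, end), function(fr) {
    sc <- base_scene
    for (tr in tracks) {
      sc <- set_scene_param(sc, tr$parameter_path[1],
                            interpolate_track(tr, fr))
    }
    sc$frame_index <- as.integer(fr)
    sc
  })
}

# ---- scene serialisation ---------------------------------------------------

#' Write / read a scene specification as YAML
#'
#' Round-trips every field of a `scene_spec` for provenance.
#'
#' @param scene A `scene_spec`.
#' @param path File path.
#' @return `read_scene()` returns the `scene_spec`; `write_scene()` returns
#'   `path` invisibly.
#' @export
write_scene <- function(scene, path) {
  ser <- unclass(scene)
  ser$regions <- lapply(ser$regions, function(r) {
    r$factors <- as.list(r$factors); r
  })
  ser$spheroids <- lapply(ser$spheroids, function(s) lapply(s, identity))
  yaml::write_yaml(ser, path)
  invisible(path)
}

#' @rdname write_scene
#' @export
read_scene <- function(path) {
  raw <- yaml::read_yaml(path)
  regions <- lapply(raw$regions, function(r) {
    r$factors <- tibble::as_tibble(r$factors); r
  })
  new_scene_spec(raw$geometry, regions, raw$spheroids %||% list(),
                 raw$illumination, raw$cylinder_params, raw$seed %||% 1L,
                 raw$frame_index %||% 1L)
}
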