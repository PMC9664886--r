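#' Calibration constants for the synthetic SFDI pipeline
#'
#' Bundles the constants that tie the unitless material factors to physical
#' optical properties and the image-formation model: the property-space
#' extents mapped to the 8-bit colour scale (255 corresponds to
#' `mu_a_max` for absorption and `mu_s_max` for reduced scattering), the
#' relative refractive index of the medium, the lateral field of view of a
#' rendered image, and the source-power normalisation target.
#'
#' @param mu_a_max Maximum absorption coefficient, mm^-1 (default 0.25).
#' @param mu_s_max Maximum reduced scattering coefficient, mm^-1 (default 2.5).
#' @param n_rel Relative refractive index of the turbid medium (default 1.43).
#' @param fov_mm Lateral field of view of a rendered image in mm
#'   (default 51.2 mm, ~10 fringe periods at 0.2 mm^-1).
#' @param gain_target Peak image intensity (fraction of full scale) reached by
#'   a mid-range material under the source gain; absolute radiometry is
#'   irrelevant after 8-bit normalisation, only this anchor matters.
#' @return An object of class `sfdi_calib` (a named list).
#' @export
#' @examples
#' sfdi_calibration()
sfdi_calibration <- function(mu_a_max = 0.25, mu_s_max = 2.5, n_rel = 1.43,
                             fov_mm = 51.2, gain_target = 0.8) {
  stopifnot(mu_a_max > 0, mu_s_max > 0, n_rel >= 1, fov_mm > 0,
            gain_target > 0, gain_target <= 1)
  structure(list(mu_a_max = mu_a_max, mu_s_max = mu_s_max, n_rel = n_rel,
                 fov_mm = fov_mm, gain_target = gain_target),
            class = "sfdi_calib")
}

#' Read calibration constants from a YAML config file
#'
#' Missing keys fall back to the defaults of [sfdi_calibration()].
#'
#' @param path Path to a YAML file with any of the keys `mu_a_max`,
#'   `mu_s_max`, `n_rel`, `fov_mm`, `gain_target`.
#' @return An `sfdi_calib` object.
#' @export
read_calibration <- function(path) {
  cfg <- yaml::read_yaml(path)
  keep <- intersect(names(cfg),
                    c("mu_a_max", "mu_s_max", "n_rel", "fov_mm", "gain_target"))
  do.call(sfdi_calibration, cfg[keep])
}

#' Construct a table of material factors
#'
#' A material is controlled by three unitless factors in \[0, 1\]: the
#' `final_factor` mixes an absorbing component (0) with a scattering
#' component (1); the `absorption_factor` runs from fully absorbing (0) to
#' transparent (1); the `scattering_factor` runs from transparent (0) to
#' fully scattering (1).
#'
#' @param final_factor,absorption_factor,scattering_factor Numeric vectors
#'   in \[0, 1\], recycled to a common length.
#' @return A tibble with one row per material and the three factor columns.
#' @export
#' @examples
#' material_factors(final_factor = c(0.05, 0.95))
material_factors <- function(final_factor, absorption_factor = 1,
                             scattering_factor = 1) {
  n <- max(length(final_factor), length(absorption_factor),
           length(scattering_factor))
  out <- tibble::tibble(
    final_factor = rep_len(final_factor, n),
    absorption_factor = rep_len(absorption_factor, n),
    scattering_factor = rep_len(scattering_factor, n)
  )
  for (f in names(out)) {
    v <- out[[f]]
    if (any(!is.finite(v)) || any(v < 0) || any(v > 1)) {
      stop("`", f, "` must lie in [0, 1]", call. = FALSE)
    }
  }
  out
}

#' Map material factors to proxy optical properties
#'
#' The bilinear product map taking the three material factors to the proxy
#' absorption and reduced scattering coefficients:
#' `mu_a = mu_a_max * (1 - final) * (1 - absorption)` and
#' `mu_s_prime = mu_s_max * final * scattering`. The map is monotone
#' (mu_a non-increasing in the final and absorption factors, mu_s_prime
#' non-decreasing in the final and scattering factors) and spans the full
#' property rectangle boundary-to-boundary.
#'
#' @param factors A data frame with columns `final_factor`,
#'   `absorption_factor`, `scattering_factor` (e.g. from
#'   [material_factors()]).
#' @param calib An `sfdi_calib` object.
#' @return The input tibble with `mu_a` and `mu_s_prime` columns (mm^-1)
#'   appended.
#' @export
#' @examples
#' factors_to_properties(material_factors(0.5, 0.5, 1.0))
factors_to_properties <- function(factors, calib = sfdi_calibration()) {
  f <- material_factors(factors$final_factor, factors$absorption_factor,
                        factors$scattering_factor)
  dplyr::mutate(
    tibble::as_tibble(factors),
    mu_a = calib$mu_a_max * (1 - f$final_factor) * (1 - f$absorption_factor),
    mu_s_prime = calib$mu_s_max * f$final_factor * f$scattering_factor
  )
}

# Effective internal-reflection coefficient (Groenhuis polynomial in n) and
# the derived boundary parameter A of the diffusion approximation.
internal_reflection_A <- function(n_rel) {
  r_eff <- 0.0636 * n_rel + 0.668 + 0.710 / n_rel - 1.440 / n_rel^2
  (1 - r_eff) / (2 * (1 + r_eff))
}

#' Diffuse reflectance of a semi-infinite turbid medium
#'
#' Closed-form diffusion-approximation reflectance at spatial frequency `fx`
#' for a semi-infinite homogeneous medium: with `mu_tr = mu_a + mu_s_prime`,
#' transport albedo `a' = mu_s_prime / mu_tr` and
#' `mu_eff' = sqrt(3 mu_a mu_tr + (2 pi fx)^2)`,
#' `Rd = 3 A a' / ((mu_eff'/mu_tr + 1) (mu_eff'/mu_tr + 3A))`,
#' where `A` is the internal-reflection boundary parameter for the relative
#' refractive index. This analytic model stands in for ray-traced image
#' formation; it is monotone decreasing in `mu_a` and `fx` and increasing in
#' `mu_s_prime`.
#'
#' @param mu_a Absorption coefficient(s), mm^-1, >= 0.
#' @param mu_s_prime Reduced scattering coefficient(s), mm^-1, > 0.
#' @param fx Spatial frequency, mm^-1 (cycles per mm), >= 0.
#' @param n_rel Relative refractive index, >= 1.
#' @return Diffuse reflectance fraction(s) in \[0, 1\]; vectorised over all
#'   numeric arguments.
#' @export
#' @examples
#' diffuse_reflectance(0.02, 1.0, fx = 0.2)
diffuse_reflectance <- function(mu_a, mu_s_prime, fx = 0, n_rel = 1.43) {
  if (any(fx < 0)) stop("`fx` must be non-negative", call. = FALSE)
  if (any(mu_s_prime <= 0)) {
    stop("diffusion approximation requires `mu_s_prime` > 0", call. = FALSE)
  }
  if (any(mu_a < 0)) stop("`mu_a` must be non-negative", call. = FALSE)
  if (any(n_rel < 1)) stop("`n_rel` must be >= 1", call. = FALSE)
  A <- internal_reflection_A(n_rel)
  mu_tr <- mu_a + mu_s_prime
  a_p <- mu_s_prime / mu_tr
  mu_eff <- sqrt(3 * mu_a * mu_tr + (2 * pi * fx)^2)
  r <- mu_eff / mu_tr
  3 * A * a_p / ((r + 1) * (r + 3 * A))
}

#' Tabulate (DC, AC) diffuse reflectance over a property grid
#'
#' Builds the lookup table used by the SSOP baseline: for every node of a
#' regular (mu_a, mu_s_prime) grid it stores the planar (fx = 0) reflectance
#' `rd_dc` and the modulated reflectance `rd_ac` at the AC spatial frequency.
#'
#' @param fx_ac AC spatial frequency, mm^-1, > 0.
#' @param n_mu_a,n_mu_s Grid resolution along each property axis.
#' @param mu_a_range,mu_s_range Property ranges covered (defaults: 4% and
#'   10% of the calibrated maxima up to the maxima — the region where the
#'   diffusion forward model is valid and its inversion well conditioned).
#' @param calib An `sfdi_calib` object.
#' @return A `reflectance_lut` object: grid vectors plus `rd_dc`/`rd_ac`
#'   matrices (rows = mu_a nodes, columns = mu_s_prime nodes).
#' @export
build_inversion_lut <- function(fx_ac, n_mu_a = 101, n_mu_s = 101,
                                mu_a_range = NULL, mu_s_range = NULL,
                                calib = sfdi_calibration()) {
  if (fx_ac <= 0) stop("`fx_ac` must be positive", call. = FALSE)
  if (is.null(mu_a_range)) mu_a_range <- c(0.04, 1) * calib$mu_a_max
  if (is.null(mu_s_range)) mu_s_range <- c(0.1, 1) * calib$mu_s_max
  mu_a <- seq(mu_a_range[1], mu_a_range[2], length.out = n_mu_a)
  mu_s <- seq(mu_s_range[1], mu_s_range[2], length.out = n_mu_s)
  rd_dc <- outer(mu_a, mu_s, diffuse_reflectance, fx = 0, n_rel = calib$n_rel)
  rd_ac <- outer(mu_a, mu_s, diffuse_reflectance, fx = fx_ac,
                 n_rel = calib$n_rel)
  structure(list(fx_ac = fx_ac, mu_a = mu_a, mu_s_prime = mu_s,
                 rd_dc = rd_dc, rd_ac = rd_ac, n_rel = calib$n_rel),
            class = "reflectance_lut")
}

#' Invert (DC, AC) reflectance pairs to optical properties
#'
#' Recovers `(mu_a, mu_s_prime)` from measured `(rd_dc, rd_ac)` reflectance
#' pairs by locating the best-matching node of the lookup table and then
#' inverting the bilinear interpolant of the surrounding grid cell with a
#' few Newton steps, so the inverse is continuous in its inputs. Queries
#' falling outside the tabulated reflectance gamut are clamped to the
#' nearest node and flagged.
#'
#' @param lut A `reflectance_lut` from [build_inversion_lut()].
#' @param rd_dc,rd_ac Numeric vectors of equal length: planar and modulated
#'   reflectance fractions.
#' @return A tibble with columns `mu_a`, `mu_s_prime`, `out_of_gamut`.
#' @export
invert_reflectance <- function(lut, rd_dc, rd_ac) {
  stopifnot(inherits(lut, "reflectance_lut"), length(rd_dc) == length(rd_ac))
  na <- length(lut$mu_a); ns <- length(lut$mu_s_prime)
  nq <- length(rd_dc)
  # scale the two reflectance axes comparably before nearest-node search
  s_dc <- stats::sd(lut$rd_dc); s_ac <- stats::sd(lut$rd_ac)
  node_best <- find_nearest_node(lut$rd_dc / s_dc, lut$rd_ac / s_ac,
                                 rd_dc / s_dc, rd_ac / s_ac)
  ia <- ((node_best - 1) %% na) + 1
  is <- ((node_best - 1) %/% na) + 1
  out <- invert_bilinear_cells(lut$rd_dc, lut$rd_ac, ia, is, rd_dc, rd_ac)
  ga <- out[, 1]; gs <- out[, 2]; resid <- out[, 3]
  tol <- 1e-3
  oog <- ga < 1 - tol | ga > na + tol | gs < 1 - tol | gs > ns + tol |
    resid > 1e-6 * (s_dc + s_ac)
  ga <- pmin(pmax(ga, 1), na); gs <- pmin(pmax(gs, 1), ns)
  da <- lut$mu_a[2] - lut$mu_a[1]; ds <- lut$mu_s_prime[2] - lut$mu_s_prime[1]
  tibble::tibble(
    mu_a = lut$mu_a[1] + (ga - 1) * da,
    mu_s_prime = lut$mu_s_prime[1] + (gs - 1) * ds,
    out_of_gamut = oog
  )
}

#' Serialise a reflectance lookup table to a plain-text file
#'
#' Writes a commented header (AC frequency, refractive index, grid spec)
#' followed by one whitespace-separated row per node:
#' `mu_a mu_s_prime rd_dc rd_ac`.
#'
#' @param lut A `reflectance_lut`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_lut <- function(lut, path) {
  hdr <- c(
    sprintf("# fx_ac %.10g", lut$fx_ac),
    sprintf("# n_rel %.10g", lut$n_rel),
    sprintf("# grid %d %d", length(lut$mu_a), length(lut$mu_s_prime)),
    "# mu_a mu_s_prime rd_dc rd_ac"
  )
  grid <- expand.grid(mu_a = lut$mu_a, mu_s_prime = lut$mu_s_prime)
  body <- sprintf("%.10g %.10g %.10g %.10g", grid$mu_a, grid$mu_s_prime,
                  as.vector(lut$rd_dc), as.vector(lut$rd_ac))
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read a reflectance lookup table written by [write_lut()]
#'
#' @param path File path.
#' @return A `reflectance_lut`.
#' @export
read_lut <- function(path) {
  lines <- readLines(path)
  hdr <- lines[startsWith(lines, "#")]
  val <- function(key) strsplit(hdr[grepl(paste0("^# ", key, " "), hdr)],
                                " +")[[1]][-(1:2)]
  fx_ac <- as.numeric(val("fx_ac")[1])
  n_rel <- as.numeric(val("n_rel")[1])
  dims <- as.integer(val("grid"))
  body <- utils::read.table(text = lines[!startsWith(lines, "#")],
                            col.names = c("mu_a", "mu_s_prime", "rd_dc",
                                          "rd_ac"))
  structure(list(
    fx_ac = fx_ac,
    mu_a = unique(body$mu_a)[seq_len(dims[1])],
    mu_s_prime = unique(body$mu_s_prime)[seq_len(dims[2])],
    rd_dc = matrix(body$rd_dc, dims[1], dims[2]),
    rd_ac = matrix(body$rd_ac, dims[1], dims[2]),
    n_rel = n_rel
  ), class = "reflectance_lut")
}
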