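#' Normalised mean absolute error
#'
#' `sum(|pred - ref|) / sum(ref)` over all pixels: the per-image error
#' metric used throughout; smaller is better. Scale identity:
#' `nmae(c * ref, ref) = |c - 1|`.
#'
#' @param pred,ref Numeric vectors/matrices of identical shape; `ref` must
#'   have a positive sum.
#' @return The NMAE as a fraction (multiply by 100 for %).
#' @export
#' @examples
#' nmae(c(110, 90, 100, 100), c(100, 100, 100, 100))  # 0.05
nmae <- function(pred, ref) {
  if (!identical(dim(pred), dim(ref)) || length(pred) != length(ref)) {
    stop("`pred` and `ref` shapes differ", call. = FALSE)
  }
  s <- sum(ref)
  if (s <= 0) stop("undefined metric: reference sums to zero", call. = FALSE)
  sum(abs(pred - ref)) / s
}

#' Per-pixel percentage difference map
#'
#' `|pred - ref| / ref * 100` per pixel where the reference is positive;
#' zero-reference pixels are masked (NA) rather than infinite.
#'
#' @param pred,ref Numeric matrices of identical shape.
#' @return A `difference_map`: list with `map` (percent, NA where masked)
#'   and `mask` (TRUE where the reference is zero).
#' @export
difference_map <- function(pred, ref) {
  if (!identical(dim(pred), dim(ref))) {
    stop("`pred` and `ref` shapes differ", call. = FALSE)
  }
  mask <- ref == 0
  map <- abs(pred - ref) / ifelse(mask, NA, ref) * 100
  structure(list(map = map, mask = mask), class = "difference_map")
}

#' Decode a 3-channel 8-bit map to optical properties
#'
#' Linear channel scaling: the 8-bit maximum 255 corresponds to
#' `mu_a_max` (red) and `mu_s_max` (green).
#'
#' @param output An integer array `H x W x 3` of 8-bit values.
#' @param calib An `sfdi_calib`.
#' @return List with matrices `mu_a` and `mu_s_prime` (mm^-1).
#' @export
#' @examples
#' decode_optical_maps(array(c(255L, 0L, 0L), dim = c(1, 1, 3)))
decode_optical_maps <- function(output, calib = sfdi_calibration()) {
  stopifnot(length(dim(output)) == 3, dim(output)[3] >= 2)
  list(mu_a = output[, , 1] / 255 * calib$mu_a_max,
       mu_s_prime = output[, , 2] / 255 * calib$mu_s_max)
}

# Encode property maps on the ground-truth colour scale (13-242 8-bit),
# so SSOP output is comparable with GAN output and ground truth.
properties_to_map8 <- function(mu_a, mu_s_prime, calib = sfdi_calibration()) {
  h <- dim(mu_a)[1]; w <- dim(mu_a)[2]
  px <- array(0L, dim = c(h, w, 3))
  px[, , 1] <- encode_channel(property_to_colour(mu_a / calib$mu_a_max))
  px[, , 2] <- encode_channel(property_to_colour(mu_s_prime / calib$mu_s_max))
  px
}

# ---- SSOP baseline ---------------------------------------------------------

# Gaussian low-pass along rows with normalised (edge-corrected) convolution.
row_lowpass <- function(m, sigma_px) {
  half <- max(3L, ceiling(3 * sigma_px))
  k <- stats::dnorm(seq(-half, half), sd = sigma_px)
  k <- k / sum(k)
  W <- ncol(m)
  filt <- function(v) {
    padded <- c(rep(v[1], half), v, rep(v[W], half))
    stats::filter(padded, k, sides = 2)[half + seq_len(W)]
  }
  t(apply(m, 1, filt))
}

#' Single-snapshot optical property (SSOP) demodulation
#'
#' The conventional analytic baseline: spatial-frequency filtering splits
#' one fringe image into its DC level and AC modulation amplitude
#' (quadrature demodulation at `fx` with a Gaussian low-pass envelope),
#' the two are converted to calibrated diffuse reflectances, and each
#' pixel's `(Rd_dc, Rd_ac)` pair is inverted through the lookup table to
#' `(mu_a, mu_s')`. Boundary artefacts localise within the filter support.
#'
#' @param image An `sfdi_image` (fringes along the horizontal axis) or a
#'   numeric matrix of intensities in \[0, 1\].
#' @param fx Fringe spatial frequency, mm^-1.
#' @param lut A `reflectance_lut` built at `fx` (see
#'   [build_inversion_lut()]).
#' @param calib An `sfdi_calib`.
#' @param source_power Source power of the render (sets the gain).
#' @param sigma_periods Gaussian filter width in fringe periods.
#' @return List of matrices `mu_a`, `mu_s_prime`, logical `out_of_gamut`,
#'   plus the intermediate `rd_dc`, `rd_ac`.
#' @export
ssop_predict <- function(image, fx, lut, calib = sfdi_calibration(),
                         source_power = 3.5, sigma_periods = 0.8) {
  m <- if (inherits(image, "sfdi_image")) image$pixels[, , 1] else image
  W <- ncol(m)
  px_mm <- calib$fov_mm / W
  period_px <- 1 / (fx * px_mm)
  if (period_px < 2) {
    stop("fx above the resolvable band (fringe period < 2 px)", call. = FALSE)
  }
  if (W / period_px < 2) {
    stop("fx below the resolvable band (< 2 fringe periods in view)",
         call. = FALSE)
  }
  sigma_px <- sigma_periods * period_px
  u <- (seq_len(W) - 0.5) * px_mm
  carrier <- exp(-2i * pi * fx * u)
  zr <- sweep(m, 2, Re(carrier), `*`)
  zi <- sweep(m, 2, Im(carrier), `*`)
  ac <- 2 * sqrt(row_lowpass(zr, sigma_px)^2 + row_lowpass(zi, sigma_px)^2)
  dc <- row_lowpass(m, sigma_px)
  g <- source_gain(fx, calib, source_power)
  # I = g (Rd_dc/2 + Rd_ac/2 cos): DC level g Rd_dc / 2, amplitude g Rd_ac / 2
  rd_dc <- 2 * dc / g
  rd_ac <- 2 * ac / g
  inv <- invert_reflectance(lut, as.vector(rd_dc), as.vector(rd_ac))
  list(mu_a = matrix(inv$mu_a, nrow(m), W),
       mu_s_prime = matrix(inv$mu_s_prime, nrow(m), W),
       out_of_gamut = matrix(inv$out_of_gamut, nrow(m), W),
       rd_dc = rd_dc, rd_ac = rd_ac)
}

# ---- per-image evaluation --------------------------------------------------

#' Per-image NMAE report for a trained generator
#'
#' Runs the generator over the selected samples and computes the NMAE of
#' the absorption (red) and scattering (green) channels against the
#' ground-truth half, on the 8-bit encoded scale.
#'
#' @param fit A `ganpop_fit`.
#' @param samples List of `paired_sample`s.
#' @param manifest Optional manifest aligned with `samples`; with
#'   `split = "val"` (default) only validation rows are scored.
#' @param split Which split to score; `NULL` scores everything.
#' @return An `nmae_report` tibble: `sample_id`, `nmae_abs`, `nmae_sct`
#'   (fractions).
#' @export
evaluate_fit <- function(fit, samples, manifest = NULL, split = "val") {
  idx <- seq_along(samples)
  if (!is.null(manifest) && !is.null(split)) {
    idx <- which(manifest$split == split)
  }
  rows <- purrr::map(idx, function(i) {
    truth <- unpair_sample(samples[[i]])$truth
    pred <- predict(fit, samples[[i]])
    tibble::tibble(sample_id = samples[[i]]$sample_id,
                   nmae_abs = nmae(pred[, , 1], truth[, , 1]),
                   nmae_sct = nmae(pred[, , 2], truth[, , 2]))
  })
  structure(dplyr::bind_rows(rows),
            class = c("nmae_report", class(tibble::tibble())))
}

#' Per-image NMAE report for the SSOP baseline
#'
#' Demodulates each sample's fringe half with [ssop_predict()], re-encodes
#' the recovered properties on the ground-truth colour scale and scores
#' them like [evaluate_fit()].
#'
#' @param samples List of `paired_sample`s.
#' @param lut A `reflectance_lut` at the dataset's fx.
#' @param calib An `sfdi_calib`.
#' @param manifest,split As in [evaluate_fit()].
#' @return An `nmae_report` tibble.
#' @export
evaluate_ssop <- function(samples, lut, calib = sfdi_calibration(),
                          manifest = NULL, split = "val") {
  idx <- seq_along(samples)
  if (!is.null(manifest) && !is.null(split)) {
    idx <- which(manifest$split == split)
  }
  rows <- purrr::map(idx, function(i) {
    halves <- unpair_sample(samples[[i]])
    fx <- samples[[i]]$fx
    maps <- ssop_predict(halves$input[, , 1] / 255, fx, lut, calib)
    pred <- properties_to_map8(maps$mu_a, maps$mu_s_prime, calib)
    tibble::tibble(sample_id = samples[[i]]$sample_id,
                   nmae_abs = nmae(pred[, , 1], halves$truth[, , 1]),
                   nmae_sct = nmae(pred[, , 2], halves$truth[, , 2]))
  })
  structure(dplyr::bind_rows(rows),
            class = c("nmae_report", class(tibble::tibble())))
}

#' Summarise an NMAE report
#'
#' Mean and envelope (maximum) per channel, in percent.
#'
#' @param report An `nmae_report`.
#' @return A one-row tibble: `n`, `mean_abs_pct`, `mean_sct_pct`,
#'   `env_abs_pct`, `env_sct_pct`.
#' @export
nmae_summary <- function(report) {
  tibble::tibble(
    n = nrow(report),
    mean_abs_pct = 100 * mean(report$nmae_abs),
    mean_sct_pct = 100 * mean(report$nmae_sct),
    env_abs_pct = 100 * max(report$nmae_abs),
    env_sct_pct = 100 * max(report$nmae_sct)
  )
}

# ---- experiment runners ----------------------------------------------------

#' Run a scaled replication of one of the study designs
#'
#' Four experiment kinds are supported:
#' \describe{
#'   \item{`rect`}{train on the four flat models, score the validation
#'     split (NMAE scatter).}
#'   \item{`cylinder`}{train on the lumen dataset (plain sweep + polyp
#'     part), score the validation split.}
#'   \item{`sf_sweep`}{evaluate a trained model on fresh validation sets
#'     rendered 10% above and 10% below the training spatial frequency.}
#'   \item{`factor_grid`}{train/evaluate over the four factor-range
#'     combinations (final factor swept; absorption/scattering factors
#'     fixed or swept).}
#' }
#' All sizes are configurable so runs scale from desk checks to the full
#' protocol.
#'
#' @param kind Experiment kind.
#' @param res Image resolution.
#' @param n_per_model Frames per flat model (`rect`, `factor_grid`).
#' @param n_sweep,n_polyp Cylinder dataset sizes.
#' @param n_val_sf Validation images per spatial frequency (`sf_sweep`).
#' @param train A [train_config()].
#' @param fit A pre-trained `ganpop_fit` (`sf_sweep` only; trained fresh
#'   when `NULL`).
#' @param train_fraction Train split fraction.
#' @param fx Base spatial frequency, mm^-1.
#' @param seed Dataset/split seed.
#' @param calib An `sfdi_calib`.
#' @return An `sfdi_experiment`: list with the per-image `report` (incl.
#'   a `condition` column), `summary`, and the fitted model(s).
#' @export
run_experiment <- function(kind = c("rect", "cylinder", "sf_sweep",
                                    "factor_grid"),
                           res = 64, n_per_model = 50, n_sweep = 40,
                           n_polyp = 24, n_val_sf = 50,
                           train = train_config(), fit = NULL,
                           train_fraction = 0.7, fx = 0.2, seed = 1L,
                           calib = sfdi_calibration()) {
  kind <- match.arg(kind)
  train_eval <- function(samples, frac, condition) {
    manifest <- split_dataset(sample_manifest(samples), frac,
                              seed = seed + 17L)
    f <- train_ganpop(samples, manifest, train)
    rep <- evaluate_fit(f, samples, manifest, "val")
    rep$condition <- condition
    list(fit = f, report = rep)
  }
  if (kind == "rect") {
    scenes <- flat_dataset_scenes(n_per_model, fx = fx, fov_mm = calib$fov_mm,
                                  seed = seed)
    samples <- render_dataset(scenes, res, calib)
    out <- train_eval(samples, train_fraction, "rect")
    fits <- list(rect = out$fit); report <- out$report
  } else if (kind == "cylinder") {
    scenes <- cylinder_dataset_scenes(n_sweep, n_polyp, fx = fx, seed = seed)
    samples <- render_dataset(scenes, res, calib)
    out <- train_eval(samples, 0.8, "cylinder")
    fits <- list(cylinder = out$fit); report <- out$report
  } else if (kind == "sf_sweep") {
    if (is.null(fit)) {
      scenes <- flat_dataset_scenes(n_per_model, fx = fx,
                                    fov_mm = calib$fov_mm, seed = seed)
      samples <- render_dataset(scenes, res, calib)
      manifest <- split_dataset(sample_manifest(samples), train_fraction,
                                seed = seed + 17L)
      fit <- train_ganpop(samples, manifest, train)
    }
    report <- dplyr::bind_rows(purrr::map(c(0.9, 1.1), function(mult) {
      fx_val <- mult * fx
      scenes <- flat_dataset_scenes(n_val_sf, fx = fx_val,
                                    fov_mm = calib$fov_mm,
                                    seed = seed + round(100 * mult),
                                    models = "tumour")
      vs <- render_dataset(scenes, res, calib)
      r <- evaluate_fit(fit, vs, manifest = NULL, split = NULL)
      r$condition <- sprintf("fx=%.3f", fx_val)
      r
    }))
    fits <- list(base = fit)
  } else {  # factor_grid
    # four rows: final factor always swept; absorption/scattering factors
    # either held at full component strength or swept too
    grid <- tibble::tibble(
      abs_lo = c(0, 0.05, 0, 0.05), abs_hi = c(0, 0.95, 0, 0.95),
      sct_lo = c(1, 1, 0.05, 0.05), sct_hi = c(1, 1, 0.95, 0.95)
    )
    rows <- purrr::pmap(grid, function(abs_lo, abs_hi, sct_lo, sct_hi) {
      label <- sprintf("final=0.05-0.95 abs=%s sct=%s",
                       if (abs_lo == abs_hi) "fixed" else paste0(abs_lo, "-", abs_hi),
                       if (sct_lo == sct_hi) "fixed" else paste0(sct_lo, "-", sct_hi))
      scenes <- flat_dataset_scenes(n_per_model, abs_range = c(abs_lo, abs_hi),
                                    sct_range = c(sct_lo, sct_hi), fx = fx,
                                    fov_mm = calib$fov_mm, seed = seed)
      samples <- render_dataset(scenes, res, calib)
      train_eval(samples, train_fraction, label)
    })
    report <- dplyr::bind_rows(purrr::map(rows, "report"))
    fits <- purrr::map(rows, "fit")
  }
  summary <- report |>
    dplyr::group_by(.data$condition) |>
    dplyr::group_modify(~ nmae_summary(.x)) |>
    dplyr::ungroup()
  structure(list(kind = kind, report = report, summary = summary,
                 fits = fits),
            class = "sfdi_experiment")
}
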