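#' Pair an input render with its ground-truth map
#'
#' Concatenates the 8-bit quantised fringe image (left half) with the
#' ground-truth optical property map (right half) into the single
#' `H x 2H` RGB image the GAN consumes. Lossless: both halves are copied
#' bit-exactly.
#'
#' @param input An `sfdi_image` (quantised or in \[0,1\]; quantised on the
#'   fly if needed).
#' @param truth A `ground_truth_map` of identical height and width.
#' @param sample_id Identifier recorded in the sample.
#' @param frame_index Frame index recorded for provenance.
#' @param scene_hash Provenance hash of the generating scene.
#' @return A `paired_sample`: integer pixel array `H x 2W x 3` (0-255) plus
#'   metadata.
#' @export
pair_sample <- function(input, truth, sample_id = 1L, frame_index = 1L,
                        scene_hash = NA_character_) {
  stopifnot(inherits(input, "sfdi_image"), inherits(truth, "ground_truth_map"))
  din <- dim(input$pixels); dtr <- dim(truth$pixels)
  if (!identical(din, dtr)) {
    stop("input and ground truth shapes differ (",
         paste(din, collapse = "x"), " vs ", paste(dtr, collapse = "x"), ")",
         call. = FALSE)
  }
  left <- array(as.integer(floor(pmin(pmax(input$pixels, 0), 1) * 255 + 0.5)),
                dim = din)
  h <- din[1]; w <- din[2]
  px <- array(0L, dim = c(h, 2L * w, 3L))
  px[, seq_len(w), ] <- left
  px[, w + seq_len(w), ] <- truth$pixels
  structure(list(pixels = px, sample_id = sample_id,
                 frame_index = as.integer(frame_index),
                 geometry = input$geometry, fx = input$fx,
                 scene_hash = scene_hash),
            class = "paired_sample")
}

#' Split a paired sample back into its two halves
#'
#' Inverse of [pair_sample()]: returns the 8-bit input and ground-truth
#' halves bit-exactly.
#'
#' @param sample A `paired_sample`.
#' @return A list with integer arrays `input` and `truth` (each `H x W x 3`).
#' @export
unpair_sample <- function(sample) {
  stopifnot(inherits(sample, "paired_sample"))
  w <- dim(sample$pixels)[2] / 2
  list(input = sample$pixels[, seq_len(w), , drop = FALSE],
       truth = sample$pixels[, w + seq_len(w), , drop = FALSE])
}

#' Render a list of scenes into paired samples
#'
#' Runs the forward renderer over every scene (flat or cylindrical) and
#' pairs each fringe image with its co-registered ground truth.
#'
#' @param scenes A list of `scene_spec` (e.g. from [keyframe_sweep()]).
#' @param res Image resolution per half.
#' @param calib An `sfdi_calib`.
#' @param view,focal Cylinder camera parameters.
#' @param noise,noise_seed Optional noise stage, see [render_flat_sfdi()].
#' @return A list of `paired_sample`s, ids numbered in order.
#' @export
render_dataset <- function(scenes, res = 256, calib = sfdi_calibration(),
                           view = "axial", focal = 1.0, noise = NULL,
                           noise_seed = 1L) {
  purrr::imap(scenes, function(sc, i) {
    pr <- render_scene_pair(sc, res, calib, view = view, focal = focal,
                            noise = noise, noise_seed = noise_seed + i)
    pair_sample(pr$input, pr$truth, sample_id = i,
                frame_index = sc$frame_index, scene_hash = rlang::hash(sc))
  })
}

#' Build a manifest tibble for in-memory paired samples
#'
#' One row per sample with its id, frame index, geometry, spatial
#' frequency and provenance hash; the `split` column starts unset (see
#' [split_dataset()]).
#'
#' @param samples A list of `paired_sample`s.
#' @param files Optional file paths to record.
#' @return A manifest tibble.
#' @export
sample_manifest <- function(samples, files = NA_character_) {
  tibble::tibble(
    sample_id = purrr::map_int(samples, ~ as.integer(.x$sample_id)),
    file = rep_len(files, length(samples)),
    frame_index = purrr::map_int(samples, "frame_index"),
    geometry = purrr::map_chr(samples, "geometry"),
    fx = purrr::map_dbl(samples, "fx"),
    scene_hash = purrr::map_chr(samples, "scene_hash"),
    split = NA_character_
  )
}

#' Assign train/validation splits to a dataset manifest
#'
#' Seeded uniform random split: a permutation of the rows is drawn under
#' the seed and the first `round(train_fraction * n)` samples are labelled
#' `"train"`, the rest `"val"`. Deterministic given the seed; the two
#' splits are disjoint and exhaustive.
#'
#' @param manifest A manifest tibble (from [write_dataset()] or
#'   [sample_manifest()]).
#' @param train_fraction Fraction of samples used for training, in (0, 1).
#' @param seed Integer split seed, recorded in the result.
#' @return The manifest with its `split` column filled in and attributes
#'   `split_seed`/`train_fraction` set.
#' @export
#' @examples
#' m <- tibble::tibble(sample_id = 1:200, file = NA, frame_index = 1:200,
#'                     geometry = "flat", fx = 0.2, scene_hash = "",
#'                     split = NA_character_)
#' table(split_dataset(m, 0.7, seed = 1)$split)
split_dataset <- function(manifest, train_fraction = 0.7, seed = 1L) {
  n <- nrow(manifest)
  if (n == 0) stop("empty dataset", call. = FALSE)
  if (train_fraction <= 0 || train_fraction >= 1) {
    stop("`train_fraction` must lie strictly between 0 and 1", call. = FALSE)
  }
  rng <- local_rng(seed)
  perm <- rng$sample(n, n)
  n_train <- round(train_fraction * n)
  split <- rep("val", n)
  split[perm[seq_len(n_train)]] <- "train"
  manifest$split <- split
  attr(manifest, "split_seed") <- as.integer(seed)
  attr(manifest, "train_fraction") <- train_fraction
  manifest
}

#' Write a dataset of paired samples to disk
#'
#' Lossless layout: `images/NNNN.png` (8-bit RGB, `H x 2H`), a
#' `manifest.csv` with one row per sample, and a `meta.json` header with
#' counts, resolution and provenance.
#'
#' @param samples A list of `paired_sample`s.
#' @param directory Output directory (created if missing).
#' @param manifest Optional pre-split manifest matching `samples`.
#' @return The manifest tibble, invisibly.
#' @export
write_dataset <- function(samples, directory, manifest = NULL) {
  dir.create(file.path(directory, "images"), recursive = TRUE,
             showWarnings = FALSE)
  files <- sprintf("images/%04d.png", seq_along(samples))
  for (i in seq_along(samples)) {
    png::writePNG(samples[[i]]$pixels / 255,
                  file.path(directory, files[i]))
  }
  if (is.null(manifest)) manifest <- sample_manifest(samples)
  manifest$file <- files
  utils::write.csv(manifest, file.path(directory, "manifest.csv"),
                   row.names = FALSE)
  h <- dim(samples[[1]]$pixels)[1]
  meta <- list(n = length(samples), height = h, width = 2L * h,
               split_seed = attr(manifest, "split_seed"),
               train_fraction = attr(manifest, "train_fraction"))
  jsonlite::write_json(meta, file.path(directory, "meta.json"),
                       auto_unbox = TRUE, null = "null")
  invisible(manifest)
}

#' Read a dataset written by [write_dataset()]
#'
#' PNG round trips are bit-exact. Files whose width is not twice their
#' height, or that disagree with the recorded resolution, raise a format
#' error naming the file.
#'
#' @param directory Dataset directory.
#' @return A list with `samples` (list of `paired_sample`) and `manifest`.
#' @export
read_dataset <- function(directory) {
  manifest <- tibble::as_tibble(
    utils::read.csv(file.path(directory, "manifest.csv"),
                    stringsAsFactors = FALSE))
  meta <- jsonlite::read_json(file.path(directory, "meta.json"))
  samples <- purrr::pmap(manifest, function(sample_id, file, frame_index,
                                            geometry, fx, scene_hash, split,
                                            ...) {
    px <- png::readPNG(file.path(directory, file))
    d <- dim(px)
    if (length(d) < 3) d <- c(d, 1)
    if (d[2] != 2 * d[1] || (!is.null(meta$height) && d[1] != meta$height)) {
      stop("malformed sample image ", file, ": ", d[1], "x", d[2],
           " (expected ", meta$height, "x", meta$width, ")", call. = FALSE)
    }
    px <- array(as.integer(floor(px[, , 1:3] * 255 + 0.5)), dim = c(d[1], d[2], 3))
    structure(list(pixels = px, sample_id = sample_id,
                   frame_index = frame_index, geometry = geometry, fx = fx,
                   scene_hash = scene_hash),
              class = "paired_sample")
  })
  list(samples = samples, manifest = manifest)
}
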