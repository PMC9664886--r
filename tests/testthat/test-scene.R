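test_that("single-material flat scene rasterises to one region covering every pixel", {
  sc <- fixture_flat_scene()
  ras <- rasterise_scene(sc, res = 64)
  expect_true(all(ras$material == 1L))
  expect_equal(nrow(ras$materials), 1)
})

test_that("region masks partition the image exactly once", {
  for (sc in list(fixture_two_material_scene(),
                  flat_scene(material_factors(c(0.2, 0.5, 0.8)), "ragged",
                             seed = 7))) {
    ras <- rasterise_scene(sc, res = 48)
    expect_false(any(is.na(ras$material)))
    expect_true(all(ras$material %in% seq_len(nrow(ras$materials))))
  }
})

test_that("zero-sagitta curved boundary is a straight split at the chord", {
  sc <- flat_scene(material_factors(c(0.3, 0.7)), "curved",
                   boundary_params = list(chord = 0.25, sagitta = 0))
  ras <- rasterise_scene(sc, res = 256)
  # every row splits at the same column; left fraction = chord
  split_cols <- apply(ras$material, 1, function(r) sum(r == 1L))
  expect_true(all(split_cols == split_cols[1]))
  expect_equal(split_cols[1] / 256, 0.25, tolerance = 1 / 256)
})

test_that("curved boundary bulges by the sagitta at mid-height", {
  sc <- flat_scene(material_factors(c(0.3, 0.7)), "curved",
                   boundary_params = list(chord = 0.5, sagitta = 0.2))
  ras <- rasterise_scene(sc, res = 200)
  left <- apply(ras$material, 1, function(r) sum(r == 1L)) / 200
  expect_equal(left[1], 0.5, tolerance = 0.02)      # chord at the ends
  expect_equal(left[100], 0.7, tolerance = 0.02)    # chord + sagitta mid-way
})

test_that("ragged boundaries are reproducible from the seed and differ across seeds", {
  f <- material_factors(c(0.2, 0.5, 0.8))
  r1 <- rasterise_scene(flat_scene(f, "ragged", seed = 5), res = 64)
  r2 <- rasterise_scene(flat_scene(f, "ragged", seed = 5), res = 64)
  r3 <- rasterise_scene(flat_scene(f, "ragged", seed = 6), res = 64)
  expect_identical(r1$material, r2$material)
  expect_false(identical(r1$material, r3$material))
})

test_that("spheroids project to discs, occlude in order, and warn when invisible", {
  sc <- fixture_flat_scene()
  fov <- 51.2
  sph <- tibble::tibble(cx = fov / 2, cy = fov / 2, a = 10, b = 10, c = 5,
                        final_factor = 0.9, absorption_factor = 0,
                        scattering_factor = 1)
  ras <- rasterise_scene(add_spheroids(sc, sph), res = 128)
  area <- mean(ras$material == 2L) * fov^2
  expect_equal(area, pi * 100, tolerance = 0.03 * pi * 100)
  # second overlapping spheroid wins in the overlap
  sph2 <- dplyr::mutate(sph, cx = cx + 5, final_factor = 0.1)
  ras2 <- rasterise_scene(add_spheroids(add_spheroids(sc, sph), sph2),
                          res = 128)
  centre_right <- ras2$material[64, 96]  # inside both projections
  expect_equal(centre_right, 3L)
  expect_warning(add_spheroids(sc, dplyr::mutate(sph, cx = 200)),
                 "outside")
  # empty list leaves the scene unchanged
  expect_identical(add_spheroids(sc, sph[0, ]), sc)
})

test_that("cylinder scenes validate geometry and polyp size", {
  wall <- material_factors(0.5, 0.2, 1)
  expect_error(cylinder_scene(-1, 10, wall), "positive")
  bad_polyp <- tibble::tibble(theta = 0, z = 5, a = 99, c = 2,
                              final_factor = 0.5, absorption_factor = 0,
                              scattering_factor = 1)
  expect_error(cylinder_scene(15, 80, wall, bad_polyp), "radius")
})

test_that("homogeneous cylinder wall map is uniform; a polyp forms one component at its angle", {
  sc <- fixture_cylinder_scene()
  ras <- rasterise_scene(sc, res = 64)
  expect_true(all(ras$material[ras$hit] == 1L))
  theta0 <- 1.1
  polyp <- tibble::tibble(theta = theta0, z = 30, a = 4, c = 4,
                          final_factor = 0.9, absorption_factor = 0,
                          scattering_factor = 1)
  sc2 <- fixture_cylinder_scene(polyps = polyp)
  ras2 <- rasterise_scene(sc2, res = 96)
  on_polyp <- ras2$material == 2L & ras2$hit
  expect_gt(sum(on_polyp, na.rm = TRUE), 0)
  # circular mean of polyp pixel angles matches the placement angle
  ang <- atan2(mean(sin(ras2$theta[which(on_polyp)])),
               mean(cos(ras2$theta[which(on_polyp)])))
  expect_lt(abs(ang - theta0), 0.15)
})

test_that("random polyp scatter is seed-reproducible", {
  p1 <- random_polyps(5, 15, 80, seed = 3)
  p2 <- random_polyps(5, 15, 80, seed = 3)
  p3 <- random_polyps(5, 15, 80, seed = 4)
  expect_identical(p1, p2)
  expect_false(identical(p1, p3))
  expect_true(all(p1$a <= 15))
})

test_that("keyframe tracks interpolate linearly and reject out-of-range frames", {
  tr <- keyframe_track("region.1.final_factor", c(1, 100), c(0.05, 0.95))
  expect_equal(interpolate_track(tr, 1), 0.05)
  expect_equal(interpolate_track(tr, 100), 0.95)
  expect_equal(interpolate_track(tr, 50), 0.05 + 0.9 * 49 / 99)
  expect_error(interpolate_track(tr, 101), "range")
  expect_error(keyframe_track("x", c(5, 5), c(0, 1)), "increasing")
})

test_that("keyframe sweeps enumerate one scene per frame and honour tracks", {
  base <- fixture_flat_scene()
  tr <- keyframe_track("region.1.final_factor", c(1, 100), c(0.05, 0.95))
  scenes <- keyframe_sweep(base, list(tr), 1, 100)
  expect_length(scenes, 100)
  expect_equal(scenes[[1]]$regions[[1]]$factors$final_factor, 0.05)
  expect_equal(scenes[[100]]$regions[[1]]$factors$final_factor, 0.95)
  # empty track list: all scenes equal the base apart from frame_index
  same <- keyframe_sweep(base, list(), 1, 5)
  for (s in same) {
    s$frame_index <- base$frame_index
    expect_identical(s, base)
  }
  expect_error(keyframe_sweep(base, list(keyframe_track("nope.1.z", 1, 0)),
                              1, 2), "unknown field")
})

test_that("final-factor sweep moves monotonically from absorbing to scattering", {
  base <- flat_scene(material_factors(0.05, 0, 1), "none")
  tr <- keyframe_track("region.1.final_factor", c(1, 50), c(0.05, 0.95))
  scenes <- keyframe_sweep(base, list(tr), 1, 50)
  props <- dplyr::bind_rows(lapply(scenes, function(s) {
    factors_to_properties(s$regions[[1]]$factors)
  }))
  ratio <- props$mu_s_prime / props$mu_a
  expect_true(all(diff(ratio) > 0))
  # proportion path: 0.95:0.05 absorbing:scattering at the start
  expect_equal(props$mu_a[1] / 0.25, 0.95)
  expect_equal(props$mu_s_prime[1] / 2.5, 0.05)
  expect_equal(props$mu_a[50] / 0.25, 0.05)
  expect_equal(props$mu_s_prime[50] / 2.5, 0.95)
})

test_that("scene specs round-trip through YAML", {
  sc <- fixture_two_material_scene()
  sc <- add_spheroids(sc, tibble::tibble(
    cx = 20, cy = 20, a = 5, b = 4, c = 3, final_factor = 0.7,
    absorption_factor = 0.1, scattering_factor = 0.9))
  path <- withr::local_tempfile(fileext = ".yaml")
  write_scene(sc, path)
  sc2 <- read_scene(path)
  r1 <- rasterise_scene(sc, res = 32)
  r2 <- rasterise_scene(sc2, res = 32)
  expect_identical(r1$material, r2$material)
  expect_equal(r1$materials, r2$materials, tolerance = 1e-12)
})

test_that("standard dataset enumerations have the documented sizes", {
  flat <- flat_dataset_scenes(n_per_model = 5, seed = 1)
  expect_length(flat, 20)  # four models
  cyl <- cylinder_dataset_scenes(n_sweep = 6, n_polyp = 7,
                                 frames_per_polyp_scene = 3, seed = 1)
  expect_length(cyl, 13)
  expect_true(all(vapply(cyl, function(s) s$geometry, "") == "cylinder"))
})
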