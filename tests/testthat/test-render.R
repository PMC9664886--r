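test_that("channel encoding matches the 8-bit scale with half-up rounding", {
  expect_identical(encode_channel(0.05), 13L)
  expect_identical(encode_channel(0.95), 242L)
  expect_identical(encode_channel(0.5), 128L)
  expect_error(encode_channel(0.04), "0.05")
  expect_error(encode_channel(0.96), "0.05")
})

test_that("homogeneous flat render is a pure sinusoid along the fringe axis", {
  sc <- fixture_flat_scene(fx = 0.2)
  img <- render_flat_sfdi(sc, res = 64)
  px <- img$pixels
  expect_equal(dim(px), c(64, 64, 3))
  expect_true(all(px >= 0 & px <= 1))
  # rows identical (no variation perpendicular to fringes)
  expect_lt(max(abs(sweep(px[, , 1], 2, px[1, , 1]))), 1e-12)
  # profile matches g * (Rd0/2 + Rdfx/2 cos(2 pi fx u))
  calib <- fixture_calib()
  pr <- factors_to_properties(material_factors(0.6, 0.2, 0.9), calib)
  g <- sfdigan:::source_gain(0.2, calib, 3.5)
  u <- (seq_len(64) - 0.5) * calib$fov_mm / 64
  expected <- g * (diffuse_reflectance(pr$mu_a, pr$mu_s_prime, 0) / 2 +
                   diffuse_reflectance(pr$mu_a, pr$mu_s_prime, 0.2) / 2 *
                     cos(2 * pi * 0.2 * u))
  expect_equal(px[1, , 1], pmin(expected, 1), tolerance = 1e-12)
})

test_that("zero spatial frequency renders a constant image at the DC level", {
  sc <- fixture_flat_scene(fx = 1e-9)
  img <- render_flat_sfdi(sc, res = 32)
  expect_lt(diff(range(img$pixels)), 1e-6)
})

test_that("fringe amplitude ratio between regions matches the forward model", {
  sc <- fixture_two_material_scene(sagitta = 0)
  img <- render_flat_sfdi(sc, res = 128)
  calib <- fixture_calib()
  pr <- factors_to_properties(material_factors(c(0.25, 0.8), 0.1, 1), calib)
  rd <- diffuse_reflectance(pr$mu_a, pr$mu_s_prime, 0.2)
  amp <- function(cols) {
    prof <- img$pixels[1, cols, 1]
    (max(prof) - min(prof)) / 2
  }
  # interior windows covering full periods away from the boundary
  ratio <- amp(5:55) / amp(74:124)
  expect_equal(ratio, rd[1] / rd[2], tolerance = 0.05)
})

test_that("image intensity is non-increasing in absorption", {
  imgs <- lapply(c(0.1, 0.3, 0.6), function(af) {
    render_flat_sfdi(fixture_flat_scene(final = 0.4, absf = af), res = 32)
  })
  # higher absorption_factor means lower mu_a, so intensity must not drop
  expect_true(all(imgs[[2]]$pixels >= imgs[[1]]$pixels - 1e-12))
  expect_true(all(imgs[[3]]$pixels >= imgs[[2]]$pixels - 1e-12))
})

test_that("optional render noise is seeded and off by default", {
  sc <- fixture_flat_scene()
  a <- render_flat_sfdi(sc, res = 32)
  b <- render_flat_sfdi(sc, res = 32)
  expect_identical(a$pixels, b$pixels)
  n1 <- render_flat_sfdi(sc, res = 32, noise = list(gaussian_sd = 0.01),
                         noise_seed = 9)
  n2 <- render_flat_sfdi(sc, res = 32, noise = list(gaussian_sd = 0.01),
                         noise_seed = 9)
  n3 <- render_flat_sfdi(sc, res = 32, noise = list(gaussian_sd = 0.01),
                         noise_seed = 10)
  expect_identical(n1$pixels, n2$pixels)
  expect_false(identical(n1$pixels, n3$pixels))
  expect_false(identical(a$pixels, n1$pixels))
})

test_that("ground truth maps encode properties in R/G with zero blue", {
  sc <- fixture_flat_scene(final = 0.6, absf = 0.2, sct = 0.9)
  gt <- render_ground_truth(sc, res = 32)
  expect_true(all(gt$pixels[, , 3] == 0L))
  calib <- fixture_calib()
  pr <- factors_to_properties(material_factors(0.6, 0.2, 0.9), calib)
  r_exp <- encode_channel(0.05 + 0.9 * pr$mu_a / calib$mu_a_max)
  g_exp <- encode_channel(0.05 + 0.9 * pr$mu_s_prime / calib$mu_s_max)
  expect_true(all(gt$pixels[, , 1] == r_exp))
  expect_true(all(gt$pixels[, , 2] == g_exp))
  expect_true(all(gt$pixels[, , 1:2] >= 13L & gt$pixels[, , 1:2] <= 242L))
})

test_that("input and ground truth are pixel-exactly co-registered", {
  sc <- fixture_two_material_scene()
  sph <- tibble::tibble(cx = 20, cy = 30, a = 6, b = 6, c = 4,
                        final_factor = 0.9, absorption_factor = 0,
                        scattering_factor = 1)
  sc <- add_spheroids(sc, sph)
  ras <- rasterise_scene(sc, res = 64)
  gt <- render_ground_truth(sc, res = 64)
  # pixels sharing a material share a colour and vice versa
  ids <- ras$material
  for (id in unique(as.vector(ids))) {
    expect_equal(length(unique(gt$pixels[, , 1][ids == id])), 1)
  }
  tumour_mask_input <- ids == 3L
  tumour_colour <- unique(gt$pixels[, , 1][tumour_mask_input])
  other_colours <- unique(gt$pixels[, , 1][!tumour_mask_input])
  expect_false(tumour_colour %in% other_colours)
})

test_that("cylinder render dims toward the lumen centre and stretches fringes near the camera", {
  sc <- cylinder_scene(15, 120, material_factors(0.6, 0.2, 0.9), seed = 4,
                       fx = 0.4)
  img <- render_cylinder_sfdi(sc, res = 160, proj_offset_mm = 20)
  px <- img$pixels[, , 1]
  # ring-averaged intensity decreases toward the image centre (farther
  # wall, 1/d^2 falloff); fringe wobble rides on the trend
  centre <- 80.5
  rads <- seq(22, 78, 4)
  prof <- sapply(rads, function(r) {
    ring <- abs(sqrt(outer((1:160 - centre)^2,
                           (1:160 - centre)^2, `+`)) - r) < 1.5
    mean(px[ring])
  })
  expect_gt(cor(rads, prof), 0.95)
  # apparent fringe period along the horizontal mid-line shrinks from the
  # border (wall near the camera) toward the centre (wall far away)
  row <- px[81, 1:78]
  minima <- which(diff(sign(diff(row))) == 2) + 1
  spacing <- diff(minima)
  expect_gte(length(spacing), 3)
  expect_true(all(diff(spacing) <= 0))
  expect_gt(spacing[1], spacing[length(spacing)])
})

test_that("rays beyond the cylinder length render as background zero", {
  sc <- cylinder_scene(15, 60, material_factors(0.6, 0.2, 0.9))
  img <- render_cylinder_sfdi(sc, res = 64)
  expect_equal(img$pixels[32, 32, 1], 0)  # centre looks past the far end
  expect_gt(max(img$pixels[56, , 1]), 0)  # ring with z within the lumen
})

test_that("radial-view cylinder render converges to the flat render for large radii", {
  f <- material_factors(0.6, 0.2, 0.9)
  flat <- render_flat_sfdi(flat_scene(f, "none"), res = 48)
  cyl <- cylinder_scene(radius = 5e4, length = 2e5, wall_factors = f)
  curved <- render_cylinder_sfdi(cyl, res = 48, view = "radial")
  expect_lt(max(abs(curved$pixels - flat$pixels)), 0.01)
})

test_that("quantisation maps to exact 8-bit levels", {
  img <- render_flat_sfdi(fixture_flat_scene(), res = 32, quantise = TRUE)
  lv <- img$pixels * 255
  expect_equal(lv, round(lv), tolerance = 1e-12)
})
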