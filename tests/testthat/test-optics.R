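test_that("factor-to-property map hits its boundary values and hand-computed interior", {
  p <- factors_to_properties(material_factors(
    final_factor = c(1, 0, 0.5),
    absorption_factor = c(1, 0, 0.5),
    scattering_factor = c(1, 1, 1)
  ))
  expect_equal(p$mu_a, c(0, 0.25, 0.0625))
  expect_equal(p$mu_s_prime, c(2.5, 0, 1.25))
})

test_that("factor map is monotone and spans the property rectangle", {
  f <- seq(0, 1, length.out = 21)
  p_final <- factors_to_properties(material_factors(f, 0.3, 0.8))
  expect_true(all(diff(p_final$mu_a) <= 0))
  expect_true(all(diff(p_final$mu_s_prime) >= 0))
  p_abs <- factors_to_properties(material_factors(0.3, f, 0.8))
  expect_true(all(diff(p_abs$mu_a) <= 0))
  p_sct <- factors_to_properties(material_factors(0.3, 0.3, f))
  expect_true(all(diff(p_sct$mu_s_prime) >= 0))
  # corners of the rectangle are reachable
  corners <- factors_to_properties(material_factors(
    c(0, 1, 0, 1), c(0, 1, 0, 1), c(1, 1, 0, 0)))
  expect_equal(corners$mu_a, c(0.25, 0, 0.25, 0))
  expect_equal(corners$mu_s_prime, c(0, 2.5, 0, 0))
})

test_that("factor validation names the offending field", {
  expect_error(material_factors(1.2), "final_factor")
  expect_error(material_factors(0.5, -0.1), "absorption_factor")
  expect_error(material_factors(0.5, 0.5, 2), "scattering_factor")
})

test_that("diffuse reflectance matches the frozen closed-form evaluation", {
  # independently evaluated: Reff(1.43) = 0.551261, A = 0.144637
  expect_equal(diffuse_reflectance(0.02, 1.0, fx = 0.2, n_rel = 1.43),
               0.11162408128184415, tolerance = 1e-10)
  expect_equal(diffuse_reflectance(0.02, 1.0, fx = 0, n_rel = 1.43),
               0.506125392627784, tolerance = 1e-10)
})

test_that("diffuse reflectance limits and monotonicity hold", {
  # fully absorbing limit
  expect_lt(diffuse_reflectance(1e4, 1.0, fx = 0), 1e-3)
  # decreasing in fx
  r <- diffuse_reflectance(0.03, 1.2, fx = c(0, 0.18, 0.22))
  expect_true(all(diff(r) < 0))
  # grid monotonicity over the calibrated range: decreasing in mu_a,
  # increasing in mu_s'. (Below mu_s' ~ 2*pi*fx the AC reflectance is
  # genuinely non-monotone in mu_a — the degeneracy that the LUT inversion
  # flags as out-of-gamut.)
  mu_a <- seq(0.01, 0.25, length.out = 9)
  mu_s <- seq(0.6, 2.5, length.out = 9)
  for (fx in c(0, 0.2)) {
    m <- outer(mu_a, mu_s, diffuse_reflectance, fx = fx)
    expect_true(all(apply(m, 2, diff) < 0))
    expect_true(all(apply(m, 1, diff) > 0))
    expect_true(all(m >= 0 & m <= 1))
  }
})

test_that("diffuse reflectance rejects invalid inputs", {
  expect_error(diffuse_reflectance(0.02, 0, fx = 0.2), "mu_s_prime")
  expect_error(diffuse_reflectance(0.02, 1, fx = -0.1), "fx")
})

test_that("diffusion reflectance agrees with a Monte-Carlo photon oracle", {
  # isotropic random-walk MC in a semi-infinite medium with Fresnel
  # boundary (independent of the closed form): planar total diffuse
  # reflectance at two albedos
  mc_rd <- function(mu_a, mu_s, n_rel, n_photon = 20000, seed = 99) {
    set.seed(seed)
    mu_t <- mu_a + mu_s
    albedo <- mu_s / mu_t
    # critical angle and Fresnel reflectance (unpolarised) leaving medium
    fresnel <- function(cos_i) {
      sin_t2 <- n_rel^2 * (1 - cos_i^2)   # Snell into the rarer medium
      r <- numeric(length(cos_i))
      tir <- sin_t2 >= 1
      r[tir] <- 1
      ct <- sqrt(pmax(1 - sin_t2[!tir], 0))
      ci <- cos_i[!tir]
      rs <- ((n_rel * ci - ct) / (n_rel * ci + ct))^2
      rp <- ((n_rel * ct - ci) / (n_rel * ct + ci))^2
      r[!tir] <- (rs + rp) / 2
      r
    }
    escaped <- 0
    weight_out <- 0
    for (p in seq_len(n_photon)) {
      z <- 0; uz <- 1  # launched straight down from the surface
      ux <- 0; uy <- 0
      w <- 1
      for (step in 1:200) {
        s <- -log(runif(1)) / mu_t
        z <- z + uz * s
        if (z < 0) {
          # hits surface: Fresnel decides escape
          rf <- fresnel(abs(uz))
          weight_out <- weight_out + w * (1 - rf)
          w <- w * rf
          z <- -z; uz <- -uz  # reflected back in
        }
        w <- w * albedo
        if (w < 1e-4) break
        # isotropic rescatter
        cz <- 2 * runif(1) - 1
        phi <- 2 * pi * runif(1)
        sz <- sqrt(1 - cz^2)
        ux <- sz * cos(phi); uy <- sz * sin(phi); uz <- cz
      }
    }
    weight_out / n_photon
  }
  for (pars in list(c(0.02, 1.0), c(0.05, 1.5))) {
    mc <- mc_rd(pars[1], pars[2], 1.43)
    da <- diffuse_reflectance(pars[1], pars[2], fx = 0, n_rel = 1.43)
    expect_lt(abs(mc - da) / mc, 0.15)
  }
})

test_that("inversion LUT tabulates the forward model and respects Rd_ac <= Rd_dc", {
  lut <- build_inversion_lut(0.2, n_mu_a = 21, n_mu_s = 21)
  expect_equal(lut$rd_dc[5, 9],
               diffuse_reflectance(lut$mu_a[5], lut$mu_s_prime[9], 0))
  expect_equal(lut$rd_ac[5, 9],
               diffuse_reflectance(lut$mu_a[5], lut$mu_s_prime[9], 0.2))
  expect_true(all(lut$rd_ac <= lut$rd_dc))
  expect_true(all(lut$rd_dc >= 0 & lut$rd_dc <= 1))
  expect_error(build_inversion_lut(0), "fx_ac")
})

test_that("interior nodes of a 21x21 LUT invert back exactly", {
  lut <- build_inversion_lut(0.2, 21, 21, mu_a_range = c(0.01, 0.25),
                             mu_s_range = c(0.1, 2.5))
  g <- expand.grid(a = lut$mu_a[2:20], s = lut$mu_s_prime[2:20])
  inv <- invert_reflectance(lut,
                            diffuse_reflectance(g$a, g$s, 0),
                            diffuse_reflectance(g$a, g$s, 0.2))
  expect_lt(max(abs(inv$mu_a - g$a) / g$a), 0.01)
  expect_lt(max(abs(inv$mu_s_prime - g$s) / g$s), 0.01)
})

test_that("LUT inversion round-trips 100 random property pairs within 2%", {
  lut <- build_inversion_lut(0.2)
  set.seed(11)
  mu_a <- runif(300, 0.01, 0.25)
  mu_s <- runif(300, 0.25, 2.5)
  keep <- mu_s / (mu_a + mu_s) >= 0.6  # diffusion-valid albedo range
  mu_a <- mu_a[keep][1:100]; mu_s <- mu_s[keep][1:100]
  inv <- invert_reflectance(lut,
                            diffuse_reflectance(mu_a, mu_s, 0),
                            diffuse_reflectance(mu_a, mu_s, 0.2))
  expect_lt(max(abs(inv$mu_a - mu_a) / mu_a), 0.02)
  expect_lt(max(abs(inv$mu_s_prime - mu_s) / mu_s), 0.02)
})

test_that("inversion is monotone and flags out-of-gamut queries", {
  lut <- build_inversion_lut(0.2)
  # larger rd_dc at fixed rd_ac implies weakly smaller mu_a
  rd_ac0 <- diffuse_reflectance(0.1, 1.5, 0.2)
  rd_dc <- seq(diffuse_reflectance(0.12, 1.5, 0),
               diffuse_reflectance(0.08, 1.5, 0), length.out = 15)
  inv <- invert_reflectance(lut, rd_dc, rep(rd_ac0, 15))
  expect_true(all(diff(inv$mu_a) < 1e-9))
  # a reflectance pair far outside the gamut is flagged
  far <- invert_reflectance(lut, 0.99, 0.98)
  expect_true(far$out_of_gamut)
})

test_that("off-node queries interpolate between adjacent nodes", {
  lut <- build_inversion_lut(0.2, 41, 41)
  i <- 15; j <- 20
  # midpoint of two mu_a-adjacent nodes in reflectance space
  qdc <- (lut$rd_dc[i, j] + lut$rd_dc[i + 1, j]) / 2
  qac <- (lut$rd_ac[i, j] + lut$rd_ac[i + 1, j]) / 2
  inv <- invert_reflectance(lut, qdc, qac)
  expect_gt(inv$mu_a, lut$mu_a[i])
  expect_lt(inv$mu_a, lut$mu_a[i + 1])
  expect_equal(inv$mu_s_prime, lut$mu_s_prime[j], tolerance = 0.01)
})

test_that("LUT round-trips through its plain-text serialisation", {
  lut <- build_inversion_lut(0.2, 11, 13)
  path <- withr::local_tempfile(fileext = ".txt")
  write_lut(lut, path)
  lut2 <- read_lut(path)
  expect_equal(lut2$fx_ac, lut$fx_ac)
  expect_equal(lut2$mu_a, lut$mu_a, tolerance = 1e-9)
  expect_equal(lut2$rd_dc, lut$rd_dc, tolerance = 1e-9)
  expect_equal(lut2$rd_ac, lut$rd_ac, tolerance = 1e-9)
})

test_that("calibration constants read from YAML with defaults filled in", {
  path <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("mu_a_max: 0.3", "n_rel: 1.4"), path)
  cal <- read_calibration(path)
  expect_equal(cal$mu_a_max, 0.3)
  expect_equal(cal$n_rel, 1.4)
  expect_equal(cal$mu_s_max, 2.5)
})
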