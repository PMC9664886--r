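# Shared fixtures: built in code at test time, sized for desk-scale runs.

fixture_calib <- function() sfdi_calibration()

# Homogeneous flat scene with mid-range optical properties.
fixture_flat_scene <- function(final = 0.6, absf = 0.2, sct = 0.9,
                               fx = 0.2) {
  flat_scene(material_factors(final, absf, sct), "none", fx = fx)
}

# Two-material curved-boundary scene with a clear property contrast.
fixture_two_material_scene <- function(sagitta = 0.15) {
  flat_scene(material_factors(c(0.25, 0.8), c(0.1, 0.1), c(1, 1)),
             "curved", boundary_params = list(chord = 0.5, sagitta = sagitta))
}

fixture_cylinder_scene <- function(radius = 15, length = 80, polyps = NULL) {
  cylinder_scene(radius, length, material_factors(0.6, 0.2, 0.9),
                 polyps = polyps, seed = 4L)
}

# Small paired dataset of homogeneous flat scenes spanning the final-factor
# sweep; cheap enough for training smoke tests.
fixture_flat_samples <- function(n = 16, res = 32, seed = 1L) {
  scenes <- flat_dataset_scenes(n_per_model = n, seed = seed,
                                models = "rectangular")
  render_dataset(scenes, res = res, calib = fixture_calib())
}

fixture_lut <- function(fx = 0.2) build_inversion_lut(fx)
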