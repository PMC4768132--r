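test_that("a bare cylinder renders to exactly the apparent height", {
  sp <- scene_spec(orientation_deg = 90, corrugation_amplitude_nm = 0,
                   substrate_rms_nm = 0, aggregate_density_per_um2 = 0,
                   image_size_px = c(256L, 128L), seed = 1)
  m <- suppressWarnings(render_scene(sp))
  expect_equal(max(m$values), 14)
  expect_equal(min(m$values), 0)
})

test_that("the default scene peaks near the compressed 14 nm height", {
  m <- render_noiseless_vertical(seed = 2)
  expect_lt(abs(max(m$values) - 14), 0.5)
})

test_that("rendering is deterministic given the scene seed", {
  sp <- scene_spec(seed = 11, image_size_px = 128L,
                   helix = helix_parameters(length_nm = 60))
  expect_identical(render_scene(sp)$values, render_scene(sp)$values)
})

test_that("crest-line autocorrelation shows the three-turn repeat", {
  m <- render_noiseless_vertical(seed = 1)
  crest <- which.max(apply(m$values, 2, stats::median))
  prof <- m$values[, crest] - mean(m$values[, crest])
  ac <- stats::acf(prof, lag.max = 20, plot = FALSE)$acf[-1]
  side_max <- which(diff(sign(diff(ac))) == -2)[1] + 1
  # first non-trivial maximum at the 6.9 nm lattice translation (lag in px)
  expect_lt(abs(side_max * m$pixel_size_nm - 6.9), 2 * m$pixel_size_nm)
})

test_that("substrate-only regions carry the specified roughness", {
  sp <- scene_spec(orientation_deg = 90, aggregate_density_per_um2 = 0,
                   seed = 3)
  m <- suppressWarnings(render_scene(sp))
  bg <- m$values[, 1:120]  # far from the centred virion
  expect_lt(abs(sqrt(mean(bg^2)) - 0.4), 0.05)
})

test_that("the pixel size must resolve the single-turn pitch", {
  expect_error(scene_spec(pixel_size_nm = 1.2), "Nyquist")
  expect_silent(scene_spec(pixel_size_nm = 1.1,
                           helix = helix_parameters(length_nm = 100),
                           image_size_px = 256L))
})

test_that("a virion longer than the frame warns and is clipped", {
  expect_warning(render_scene(scene_spec(image_size_px = 128L, seed = 1)),
                 "clipped")
})

test_that("noise stages are reproducible, additive and optional", {
  m <- height_map(matrix(0, 256, 256), 0.5)
  expect_identical(add_noise(m, noise_spec()), m)

  n <- noise_spec(white_rms_nm = 0.4, seed = 9)
  a <- add_noise(m, n)
  expect_identical(a$values, add_noise(m, n)$values)
  expect_lt(abs(sqrt(mean(a$values^2)) - 0.4) / 0.4, 0.05)

  lo <- add_noise(m, noise_spec(line_offset_rms_nm = 0.3, seed = 4))
  expect_equal(apply(lo$values, 1, function(r) diff(range(r))), rep(0, 256))
  expect_gt(stats::sd(lo$values[, 1]), 0)
})

test_that("axial jitter shifts lines by interpolation without changing flat maps", {
  flat <- height_map(matrix(5, 64, 64), 0.5)
  j <- add_noise(flat, noise_spec(axial_jitter_rms_nm = 1, seed = 2))
  expect_equal(j$values, flat$values)  # constant lines are shift-invariant

  ramp <- height_map(matrix(seq(0, 1, length.out = 64), 64, 64, byrow = TRUE), 0.5)
  jr <- add_noise(ramp, noise_spec(axial_jitter_rms_nm = 1, seed = 2))
  expect_false(identical(jr$values, ramp$values))
  # a linear ramp shifts by a constant per line away from the edges
  mid <- jr$values[, 20] - ramp$values[, 20]
  expect_equal(jr$values[, 30] - ramp$values[, 30], mid, tolerance = 1e-10)
})

test_that("channels are co-registered and degrade gracefully to identity", {
  sp <- scene_spec(image_size_px = 128L, seed = 5,
                   helix = helix_parameters(length_nm = 60))
  zero <- noise_spec()
  ch <- make_channels(sp, topo_noise = zero, mode2_noise = zero)
  expect_identical(ch$topography$values, ch$mode2$values)
  expect_identical(ch$topography$channel_label, "topography")
  expect_identical(ch$mode2$channel_label, "mode2-like")

  expect_error(
    make_channels(sp, topo_noise = noise_spec(axial_jitter_rms_nm = 0.1),
                  mode2_noise = noise_spec(axial_jitter_rms_nm = 0.5)),
    "jitter"
  )
})

test_that("orientation 0 and 90 give the same spectrum along the particle axis", {
  mk <- function(orient) {
    sp <- scene_spec(orientation_deg = orient, substrate_rms_nm = 0,
                     aggregate_density_per_um2 = 0, image_size_px = 256L,
                     seed = 1)
    suppressWarnings(render_scene(sp))
  }
  mv <- mk(90); mh <- mk(0)
  # rotating the scene by 90 deg transposes the frame and mirrors the
  # transverse axis about the on-pixel origin; tiny trigonometric residue can
  # move a bump-center rounding by one pixel, hence the loose tolerance
  n <- ncol(mh$values)
  expect_equal(mv$values[, 1:(n - 1)], t(mh$values)[, (n - 1):1],
               tolerance = 1e-7)
  pv <- averaged_psdf(mv, crest_box(mv, "columns"))
  ph <- averaged_psdf(mh, crest_box(mh, "rows"))
  expect_equal(pv$power, ph$power, tolerance = 1e-5)
})
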