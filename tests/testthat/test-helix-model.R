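test_that("subunit lattice places proteins on the cylinder with the stated rise and twist", {
  p <- helix_parameters()
  lat <- subunit_lattice(p, 50)

  expect_equal(lat$axial_nm[1], 0)
  expect_equal(lat$azimuth_deg[1], 0)

  # three full turns: subunit 49 sits exactly 6.9 nm above subunit 0, same azimuth
  expect_equal(lat$axial_nm[50] - lat$axial_nm[1], 6.9)
  expect_equal(lat$azimuth_deg[50] %% 360, 0, tolerance = 1e-10)

  # direct-multiplication oracle for subunit 16
  expect_equal(lat$axial_nm[17], 16 * 2.3 * 3 / 49)
  expect_equal(lat$azimuth_deg[17], (16 * 360 * 3 / 49) %% 360)

  # all points exactly on the outer cylinder
  expect_equal(sqrt(lat$x_nm^2 + lat$y_nm^2), rep(9, 50))

  expect_error(subunit_lattice(p, 0), "positive integer")
})

test_that("off-axis angles reproduce the near-axial repeat geometry", {
  p <- helix_parameters()
  rv <- repeat_vectors(p, 6)

  expect_equal(rv$offaxis_angle_rounded_deg, c(27, -14, 0, 7, -6, 0))
  # exactly axial whenever n * s is an integer
  expect_identical(rv$offaxis_angle_deg[c(3, 6)], c(0, 0))
  # four turns: the ~9.2 nm vector
  expect_equal(rv$axial_distance_nm[4], 9.153, tolerance = 1e-3)

  # brute-force partner oracle
  for (n in 1:8) {
    expect_identical(repeat_vector(p, n)$partner_index,
                     as.integer(oracle_partner(p, n)))
  }

  expect_error(repeat_vector(p, 0), "integer >= 1")
})

test_that("wavenumber conversions follow k = 2 pi / l and round-trip exactly", {
  expect_equal(round(wavenumber_of(c(9.2, 6.9, 2.3)), 2), c(0.68, 0.91, 2.73))
  expect_equal(wavenumber_of(2 * pi), 1.0)
  expect_equal(distance_of(2 * wavenumber_of(6.9)), 3.45)

  ds <- exp(runif(50, log(0.1), log(100)))
  expect_equal(distance_of(wavenumber_of(ds)), ds, tolerance = 1e-14)

  expect_error(wavenumber_of(0), "positive")
  expect_error(distance_of(-1), "positive")
})

test_that("predicted peaks weight vectors by off-axis angle and append harmonics", {
  p <- helix_parameters()
  pred <- predicted_peaks(p, max_turns = 6, attenuation_deg = 10)

  expect_false(is.unsorted(pred$wavenumber_inv_nm))
  w <- function(n) pred$visibility_weight[which(pred$n_turns == n)]
  expect_equal(w(3), 1)
  expect_equal(w(6), 1)
  # the 4.6 nm (n = 2, -14 deg) vector is more suppressed than 9.2 nm (n = 4, 7 deg)
  for (att in c(3, 10, 30)) {
    pa <- predicted_peaks(p, 6, attenuation_deg = att)
    expect_lt(pa$visibility_weight[which(pa$n_turns == 2)],
              pa$visibility_weight[which(pa$n_turns == 4)])
  }
  # direct evaluation of the chosen attenuation model
  th1 <- repeat_vector(p, 1)$offaxis_angle_deg
  expect_equal(w(1) / w(3), exp(-(th1 / 10)^2))

  harm <- pred[!is.na(pred$harmonic), ]
  expect_equal(harm$wavenumber_inv_nm, harm$harmonic * wavenumber_of(6.9))
})

test_that("parameter invariants are enforced", {
  expect_error(helix_parameters(pitch_nm = -1))
  expect_error(helix_parameters(subunits_per_three_turns = 2))
  expect_error(helix_parameters(outer_radius_nm = 1, channel_radius_nm = 2))
})
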