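test_that("peak detection finds injected lines and nothing on flat spectra", {
  # flat spectrum: no local maxima survive the SNR threshold
  flat <- synthetic_psdf(rep(1, 100), 0.02)
  expect_identical(nrow(detect_peaks(flat, 3)$peaks), 0L)

  # two sinusoids injected into lines of a height map
  d <- 0.5; L <- 256
  x <- (seq_len(L) - 1) * d
  line <- 0.5 * sin(wavenumber_of(6.9) * x) + 0.2 * sin(wavenumber_of(2.3) * x)
  set.seed(8)
  v <- t(matrix(line, L, 16)) + matrix(rnorm(16 * L, 0, 0.02), 16, L)
  ps <- averaged_psdf(height_map(v, d), box_selection(c(1, 16), c(1, L), "rows"))
  pk <- detect_peaks(ps, 3)
  expect_identical(nrow(pk$peaks), 2L)
  expect_identical(pk$peaks$index,
                   vapply(c(6.9, 2.3), function(l)
                     which.min(abs(ps$wavenumbers - wavenumber_of(l))), 1L))

  expect_error(detect_peaks(ps, 1), "> 1")
})

test_that("harmonic assignment reports present and missing orders", {
  # constructed peak set at m = 1 and m = 3 of the three-turn fundamental
  pw <- rep(0.01, 200); dk <- 0.02
  i1 <- round(0.91 / dk); i3 <- round(2.73 / dk)
  pw[i1] <- 5; pw[i3] <- 1
  pk <- detect_peaks(synthetic_psdf(pw, dk), 3)
  hm <- assign_harmonics(pk, 0.91, max_m = 3)
  expect_setequal(hm$assigned$m, c(1L, 3L))
  expect_identical(hm$missing, 2L)

  # empty peak set: everything missing
  hm0 <- assign_harmonics(detect_peaks(synthetic_psdf(rep(1, 64), dk), 3),
                          0.91, max_m = 3)
  expect_identical(hm0$missing, 1:3)
  expect_true(all(is.na(hm0$harmonic_power_ratios)))

  # exact harmonics 1..4: none missing, ratios well defined
  pw <- rep(0.001, 400)
  for (mm in 1:4) pw[round(mm * 0.91 / dk)] <- 2 / mm
  hm4 <- assign_harmonics(detect_peaks(synthetic_psdf(pw, dk), 3), 0.91,
                          max_m = 4)
  expect_identical(hm4$missing, integer(0))
  expect_equal(unname(hm4$harmonic_power_ratios), c(1, 1/2, 1/3, 1/4),
               tolerance = 1e-12)

  # stability: a one-bin shift of on-grid harmonics changes no assignment
  k0 <- 45 * dk
  for (shift in c(-1L, 0L, 1L)) {
    pw_s <- rep(0.001, 400)
    for (mm in 1:4) pw_s[mm * 45L + shift] <- 2 / mm
    hm_s <- assign_harmonics(detect_peaks(synthetic_psdf(pw_s, dk), 3),
                             k0, max_m = 4)
    expect_identical(sort(hm_s$assigned$m), 1:4)
    expect_identical(hm_s$missing, integer(0))
  }
})

test_that("correlation length is recovered from a two-slope knee spectrum", {
  dk <- 0.02
  k <- (1:150) * dk
  pw <- ifelse(k < 1.25, 1, (k / 1.25)^-3)
  fit <- correlation_length(synthetic_psdf(pw, dk))
  expect_lt(abs(fit$breakpoint_k - 1.25) / 1.25, 0.10)
  expect_lt(abs(fit$correlation_length_nm - 2 * pi / 1.25), 0.5)
  expect_equal(unname(fit$slopes), c(0, -3), tolerance = 1e-6)

  # a pure power law has no knee
  expect_error(correlation_length(synthetic_psdf(k^-2.5, dk)), "degenerate")
  # too few usable bins
  expect_error(correlation_length(synthetic_psdf(rep(1, 6), dk)), "8 usable")
})

test_that("knee recovery is unbiased over noisy replicates", {
  dk <- 0.02
  k <- (1:150) * dk
  pw <- ifelse(k < 1.25, 1, (k / 1.25)^-3)
  set.seed(31)
  est <- replicate(100, {
    noisy <- pw * exp(rnorm(length(pw), 0, 0.2))
    correlation_length(synthetic_psdf(noisy, dk))$breakpoint_k
  })
  expect_lt(abs(stats::median(est) - 1.25), dk)
})

test_that("axis estimation recovers the particle orientation from moments", {
  mv <- render_noiseless_vertical(seed = 1)
  expect_lt(min(abs(estimate_axis(mv) - 90), abs(estimate_axis(mv) + 90)), 2)

  sp <- scene_spec(orientation_deg = 0, substrate_rms_nm = 0,
                   aggregate_density_per_um2 = 0, seed = 1)
  mh <- suppressWarnings(render_scene(sp))
  expect_lt(abs(estimate_axis(mh)), 2)

  expect_error(estimate_axis(height_map(matrix(0, 32, 32), 0.5)), "threshold")
})

test_that("the lattice pitch is recovered across seeded noisy scenes", {
  hits <- vapply(1:20, function(s) {
    sp <- scene_spec(orientation_deg = 90, seed = s)
    base <- suppressWarnings(render_scene(sp))
    base <- tip_dilate(base, build_tip("sphere", 2, base$pixel_size_nm))
    m <- add_noise(base, noise_preset("mode2", seed = s + 500L))
    sig <- crest_box(m, "columns")
    ps <- averaged_psdf(m, sig)
    cmp <- compare_background(ps, averaged_psdf(m, background_box(m, sig)),
                              ps$wavenumbers, snr_threshold = 3)
    band <- which(ps$wavenumbers >= 0.7 & ps$wavenumbers <= 1.1 &
                    cmp$flag == "signal-specific")
    if (!length(band)) return(FALSE)
    kbest <- ps$wavenumbers[band[which.max(ps$power[band])]]
    abs(kbest - k0_three_turn) <= ps$dk
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})
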