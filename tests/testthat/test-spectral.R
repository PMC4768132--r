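test_that("the averaged PSDF satisfies Parseval under the stated convention", {
  set.seed(21)
  v <- matrix(rnorm(32 * 64), 32, 64)
  m <- height_map(v, 0.5)
  box <- box_selection(c(1, 32), c(1, 64), "rows")
  ps <- averaged_psdf(m, box)

  line_var <- apply(v, 1, function(r) mean((r - mean(r))^2))
  expect_equal(sum(ps$power) * ps$dk, mean(line_var), tolerance = 1e-9)

  # invariant to adding a constant and to line order
  expect_equal(averaged_psdf(height_map(v + 11, 0.5), box)$power, ps$power)
  perm <- height_map(v[sample(32), ], 0.5)
  expect_equal(averaged_psdf(perm, box)$power, ps$power)
})

test_that("a constant map has zero power in every bin", {
  m <- height_map(matrix(4.2, 16, 32), 0.5)
  ps <- averaged_psdf(m, box_selection(c(1, 16), c(1, 32), "rows"))
  expect_equal(ps$power, rep(0, 16))
})

test_that("an on-grid cosine concentrates all its variance in one bin", {
  d <- 0.5; L <- 64
  x <- seq_len(L) - 1
  v <- t(matrix(cos(2 * pi * x / 8), L, 8))        # 8 identical lines
  m <- height_map(v, d)
  ps <- averaged_psdf(m, box_selection(c(1, 8), c(1, L), "rows"))

  k_true <- 2 * pi / (8 * d)
  i <- which.max(ps$power)
  expect_equal(ps$wavenumbers[i], k_true)
  expect_equal(sum(ps$power) * ps$dk, 0.5, tolerance = 1e-12)  # cosine variance
  expect_equal(sum(ps$power > 1e-12), 1L)
})

test_that("an off-grid sinusoid peaks at the analytically nearest bin", {
  d <- 0.5; L <- 128
  x <- (seq_len(L) - 1) * d
  for (lambda in c(6.9, 2.3, 9.2)) {
    v <- t(matrix(sin(2 * pi * x / lambda), L, 8))
    ps <- averaged_psdf(height_map(v, d), box_selection(c(1, 8), c(1, L), "rows"))
    expect_identical(which.max(ps$power),
                     which.min(abs(ps$wavenumbers - 2 * pi / lambda)))
  }
})

test_that("white-noise spectra are flat with the right total power", {
  set.seed(5)
  sigma <- 0.4
  v <- matrix(rnorm(512 * 512, 0, sigma), 512, 512)
  ps <- averaged_psdf(height_map(v, 0.5),
                      box_selection(c(1, 512), c(1, 512), "rows"))
  expect_lt(abs(sum(ps$power) * ps$dk - sigma^2) / sigma^2, 0.05)
  # flat: lower and upper halves of the band carry similar power
  n <- length(ps$power)
  expect_lt(abs(mean(ps$power[1:(n / 2)]) / mean(ps$power[(n / 2 + 1):n]) - 1), 0.1)
})

test_that("box validation rejects degenerate selections", {
  m <- height_map(matrix(0, 32, 32), 0.5)
  expect_error(averaged_psdf(m, box_selection(c(1, 40), c(1, 32), "rows")),
               "outside")
  expect_error(averaged_psdf(m, box_selection(c(1, 3), c(1, 32), "rows")),
               "4 lines")
  expect_error(averaged_psdf(m, box_selection(c(1, 32), c(1, 10), "rows")),
               "16 samples")
})

test_that("background comparison flags shared and specific peaks", {
  m <- render_noiseless_vertical(seed = 4)
  m <- add_noise(m, noise_spec(white_rms_nm = 0.03, seed = 4))
  sig <- crest_box(m, "columns")
  bg <- background_box(m, sig)
  ps_s <- averaged_psdf(m, sig)
  ps_b <- averaged_psdf(m, bg)

  cmp <- compare_background(ps_s, ps_b, k0_three_turn)
  expect_identical(cmp$flag, "signal-specific")

  # identical boxes: everything the signal shows, the "background" shows too
  cmp2 <- compare_background(ps_s, ps_s, k0_three_turn)
  expect_identical(cmp2$flag, "also-in-background")

  # inject the same ripple into the background region
  ripple <- m
  x <- (seq_len(nrow(ripple$values)) - 1) * ripple$pixel_size_nm
  ripple$values <- ripple$values + 0.3 * sin(k0_three_turn * x)
  ps_b2 <- averaged_psdf(ripple, bg)
  cmp3 <- compare_background(averaged_psdf(ripple, sig), ps_b2, k0_three_turn)
  expect_identical(cmp3$flag, "also-in-background")

  # incompatible grids are a hard error
  short <- averaged_psdf(m, box_selection(c(1, 256), sig$cols, "columns"))
  expect_error(compare_background(ps_s, short, k0_three_turn), "incompatible")
})

test_that("greedy box optimization improves the target SNR and respects bounds", {
  sp <- scene_spec(orientation_deg = 90, seed = 5)
  m <- suppressWarnings(render_scene(sp))
  m <- add_noise(m, noise_spec(white_rms_nm = 0.03, seed = 6))

  seed_box <- box_selection(c(3, 510), c(230, 270), "columns")  # straddles the edge
  opt <- optimize_box(m, seed_box, k0_three_turn)
  snr0 <- psdf_snr(averaged_psdf(m, seed_box), k = k0_three_turn)
  snr1 <- psdf_snr(averaged_psdf(m, opt), k = k0_three_turn)
  expect_gte(snr1, snr0)

  # a pure on-grid single-frequency map is already a fixed point
  d <- 0.5
  x <- (seq_len(64) - 1) * d
  v <- t(matrix(sin(2 * pi * x / (64 * d / 9)), 64, 32))
  pure <- height_map(v, d)
  b0 <- box_selection(c(1, 32), c(1, 64), "rows")
  expect_identical(optimize_box(pure, b0, 2 * pi * 9 / (64 * d)), b0)

  # the minimum box never shrinks below the invariants
  tiny <- box_selection(c(1, 4), c(1, 16), "rows")
  opt2 <- optimize_box(m, tiny, k0_three_turn, max_iter = 3)
  expect_gte(diff(opt2$rows) + 1, 4)
  expect_gte(diff(opt2$cols) + 1, 16)

  expect_error(optimize_box(m, seed_box, 7), "Nyquist")
})

test_that("the Hann window preserves approximate broadband levels", {
  set.seed(9)
  v <- matrix(rnorm(32 * 128, 0, 0.5), 32, 128)
  m <- height_map(v, 0.5)
  box <- box_selection(c(1, 32), c(1, 128), "rows")
  p0 <- averaged_psdf(m, box)
  ph <- averaged_psdf(m, box, window = "hann")
  expect_lt(abs(sum(ph$power) / sum(p0$power) - 1), 0.15)
})
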