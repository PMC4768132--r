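# Independent oracles and small fixture builders used across the suite.

# Brute-force search for the lattice partner after n turns: scan subunit
# indices around n * s and return the one minimizing the absolute azimuthal
# offset (wrapped to [-180, 180)).
oracle_partner <- function(params, n_turns) {
  s <- helixpsd::subunits_per_turn(params)
  cand <- floor(n_turns * s) + (-2:3)
  wrap <- function(a) ((a + 180) %% 360) - 180
  off <- abs(wrap((cand - n_turns * s) * (360 / s)))
  cand[which.min(off)]
}

# Naive O(N * |tip|) greyscale dilation with edge replication.
oracle_dilate <- function(v, tip_profile) {
  nr <- nrow(v); nc <- ncol(v)
  ctr <- (dim(tip_profile) + 1L) %/% 2L
  out <- matrix(-Inf, nr, nc)
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    for (a in seq_len(nrow(tip_profile))) for (b in seq_len(ncol(tip_profile))) {
      h <- tip_profile[a, b]
      if (is.na(h)) next
      ii <- min(max(i + a - ctr[1L], 1L), nr)
      jj <- min(max(j + b - ctr[2L], 1L), nc)
      out[i, j] <- max(out[i, j], v[ii, jj] + h)
    }
  }
  out
}

# Assemble a psdf object directly from a power vector (for fit/peak tests
# that need a spectrum with known analytic structure).
synthetic_psdf <- function(power, dk, pixel_size_nm = 0.5) {
  structure(list(
    wavenumbers = seq_along(power) * dk,
    power = power,
    dk = dk,
    n_lines_averaged = 16L,
    line_length_samples = 2L * length(power),
    box = helixpsd::box_selection(c(1L, 16L), c(1L, 2L * length(power)), "rows"),
    source_channel = "synthetic",
    pixel_size_nm = pixel_size_nm,
    window = "none"
  ), class = "psdf")
}

# Default noiseless vertical virion used by several spectral tests;
# clipping of the 300 nm particle by the 256 nm frame is expected.
render_noiseless_vertical <- function(seed = 1L, ...) {
  sp <- helixpsd::scene_spec(orientation_deg = 90, substrate_rms_nm = 0,
                             aggregate_density_per_um2 = 0, seed = seed, ...)
  suppressWarnings(helixpsd::render_scene(sp))
}

k0_three_turn <- helixpsd::wavenumber_of(3 * 2.3)
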