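#!/usr/bin/env Rscript
# Channel-contrast emulation: over seeded replicates of the default scene,
# the 6.9 nm lattice peak must be signal-specific in the low-noise
# second-mode-like channel and buried by line jitter in the topography
# channel. Writes results/channel_contrast.csv.

suppressPackageStartupMessages(library(helixpsd))
dir.create("results", showWarnings = FALSE)

k0 <- wavenumber_of(6.9)
rows <- lapply(1:20, function(s) {
  sp <- scene_spec(orientation_deg = 90, seed = s)
  base <- suppressWarnings(render_scene(sp))
  base <- tip_dilate(base, build_tip("sphere", 2, sp$pixel_size_nm))
  ch <- make_channels(sp, base = base)
  eval_channel <- function(map) {
    sig <- crest_box(map, "columns")
    ps <- averaged_psdf(map, sig)
    cmp <- compare_background(ps, averaged_psdf(map, background_box(map, sig)),
                              k0, snr_threshold = 3)
    c(snr = cmp$snr_signal, flag = cmp$flag)
  }
  m2 <- eval_channel(ch$mode2); tp <- eval_channel(ch$topography)
  data.frame(seed = s,
             mode2_snr = as.numeric(m2["snr"]), mode2_flag = m2["flag"],
             topo_snr = as.numeric(tp["snr"]), topo_flag = tp["flag"])
})
tab <- do.call(rbind, rows)
print(tab, row.names = FALSE, digits = 3)
write.csv(tab, "results/channel_contrast.csv", row.names = FALSE)

cat(sprintf("\nmode2-like: %d/20 signal-specific at 0.91 nm^-1; topography: %d/20 undetected.\n",
            sum(tab$mode2_flag == "signal-specific"),
            sum(tab$topo_flag == "not-detected")))
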