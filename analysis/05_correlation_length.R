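#!/usr/bin/env Rscript
# Correlation length by two-slope log-log fitting: recovery on a constructed
# knee spectrum (flat below k_c = 1.25 nm^-1, power-law above), and bias over
# noisy replicates. Writes results/correlation_length.csv.

suppressPackageStartupMessages(library(helixpsd))
dir.create("results", showWarnings = FALSE)

mk_psdf <- function(power, dk) structure(list(
  wavenumbers = seq_along(power) * dk, power = power, dk = dk,
  n_lines_averaged = 16L, line_length_samples = 2L * length(power),
  box = box_selection(c(1L, 16L), c(1L, 2L * length(power)), "rows"),
  source_channel = "synthetic", pixel_size_nm = 0.5, window = "none"
), class = "psdf")

dk <- 0.02
k <- (1:150) * dk
kc_true <- 1.25
pw <- ifelse(k < kc_true, 1, (k / kc_true)^-3)

fit <- correlation_length(mk_psdf(pw, dk))
print(fit)

set.seed(2026)
est <- replicate(200, {
  noisy <- pw * exp(rnorm(length(pw), 0, 0.2))
  correlation_length(mk_psdf(noisy, dk))$breakpoint_k
})
out <- data.frame(
  kc_true = kc_true,
  kc_noiseless = fit$breakpoint_k,
  length_noiseless_nm = fit$correlation_length_nm,
  kc_noisy_median = median(est),
  kc_noisy_iqr = IQR(est),
  n_replicates = length(est)
)
print(out, row.names = FALSE, digits = 4)
write.csv(out, "results/correlation_length.csv", row.names = FALSE)
cat(sprintf("\nKnee at k = %.3f nm^-1 -> correlation length %.2f nm (truth %.2f nm); noisy-replicate median %.3f nm^-1.\n",
            fit$breakpoint_k, fit$correlation_length_nm, 2 * pi / kc_true,
            median(est)))
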