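#' Detect spectral peaks above a signal-to-noise threshold
#'
#' Local maxima of the averaged spectrum (ties broken towards the
#' lower-wavenumber bin) whose SNR (see [psdf_snr()]) reaches the threshold.
#' Maxima in adjacent bins are merged, keeping the higher-power bin. The
#' detection is descriptive; no multiplicity correction is applied.
#'
#' @param psdf A [averaged_psdf()] result.
#' @param snr_threshold Detection threshold (must exceed 1; default 3).
#' @return An object of class `peak_set`: a list with `peaks` (data frame
#'   with `index`, `wavenumber_inv_nm`, `power`, `snr`, `distance_nm`),
#'   `noise_floor` (per-bin floor implied by the SNR window), `dk`,
#'   `snr_threshold`.
#' @export
detect_peaks <- function(psdf, snr_threshold = 3) {
  stopifnot(inherits(psdf, "psdf"), snr_threshold > 1)
  p <- psdf$power
  n <- length(p)
  idx <- which(vapply(seq_len(n), function(i) {
    left <- if (i == 1L) -Inf else p[i - 1L]
    right <- if (i == n) -Inf else p[i + 1L]
    p[i] > left && p[i] >= right && p[i] > 0
  }, logical(1)))
  snr_all <- psdf_snr(psdf, index = seq_len(n))
  idx <- idx[snr_all[idx] >= snr_threshold]
  # merge maxima in adjacent bins, keeping the higher power
  if (length(idx) > 1L) {
    keep <- logical(length(idx))
    i <- 1L
    while (i <= length(idx)) {
      j <- i
      while (j < length(idx) && idx[j + 1L] - idx[j] <= 1L) j <- j + 1L
      grp <- idx[i:j]
      keep[i:j] <- grp == grp[which.max(p[grp])]
      i <- j + 1L
    }
    idx <- idx[keep]
  }
  peaks <- data.frame(
    index = idx,
    wavenumber_inv_nm = psdf$wavenumbers[idx],
    power = p[idx],
    snr = snr_all[idx],
    distance_nm = if (length(idx)) distance_of(psdf$wavenumbers[idx]) else numeric(0)
  )
  structure(list(
    peaks = peaks[order(peaks$wavenumber_inv_nm), , drop = FALSE],
    noise_floor = p / pmax(snr_all, .Machine$double.eps),
    dk = psdf$dk,
    snr_threshold = snr_threshold
  ), class = "peak_set")
}

#' @export
print.peak_set <- function(x, ...) {
  cat(sprintf("<peak_set> %d peaks (SNR >= %.3g)\n",
              nrow(x$peaks), x$snr_threshold))
  if (nrow(x$peaks)) print(x$peaks, row.names = FALSE)
  invisible(x)
}

#' Assign detected peaks to harmonics of a fundamental
#'
#' Tests the one-dimensional-crystal picture of the lattice: each detected
#' peak is assigned the integer `m` minimizing `|k - m * k0|`, accepted when
#' the residual is within the tolerance (one bin by default, the physical
#' resolution of the spectrum). Harmonics up to `max_m` with no assigned peak
#' are reported missing.
#'
#' @param peaks A [detect_peaks()] result.
#' @param fundamental_k Fundamental wavenumber `k0` (nm^-1), e.g.
#'   `wavenumber_of(3 * pitch)` for the three-turn building block.
#' @param max_m Highest harmonic considered.
#' @param tol_inv_nm Assignment tolerance; default one bin spacing.
#' @return An object of class `harmonic_model`: `fundamental_k`, `assigned`
#'   (data frame `wavenumber_inv_nm`, `power`, `m`, `residual_inv_nm`),
#'   `missing` (integer vector), `harmonic_power_ratios` (power relative to
#'   `m = 1`, `NA` when the fundamental is missing).
#' @export
assign_harmonics <- function(peaks, fundamental_k, max_m = 3L,
                             tol_inv_nm = NULL) {
  stopifnot(inherits(peaks, "peak_set"), fundamental_k > 0, max_m >= 1)
  if (is.null(tol_inv_nm)) tol_inv_nm <- peaks$dk
  pk <- peaks$peaks
  if (nrow(pk) == 0L) {
    return(structure(list(
      fundamental_k = fundamental_k,
      assigned = data.frame(wavenumber_inv_nm = numeric(0),
                            power = numeric(0), m = integer(0),
                            residual_inv_nm = numeric(0)),
      missing = seq_len(max_m),
      harmonic_power_ratios = stats::setNames(rep(NA_real_, max_m),
                                              paste0("m", seq_len(max_m))),
      tol_inv_nm = tol_inv_nm
    ), class = "harmonic_model"))
  }
  m <- pmax(1L, as.integer(round(pk$wavenumber_inv_nm / fundamental_k)))
  resid <- pk$wavenumber_inv_nm - m * fundamental_k
  # inclusive tolerance with a guard against floating-point ties at the bin edge
  ok <- abs(resid) <= tol_inv_nm * (1 + 1e-9) & m <= max_m
  assigned <- data.frame(
    wavenumber_inv_nm = pk$wavenumber_inv_nm[ok],
    power = pk$power[ok],
    m = m[ok],
    residual_inv_nm = resid[ok]
  )
  # if several peaks claim one harmonic, keep the closer one
  if (nrow(assigned) > 1L) {
    assigned <- assigned[order(assigned$m, abs(assigned$residual_inv_nm)), ]
    assigned <- assigned[!duplicated(assigned$m), ]
  }
  missing <- setdiff(seq_len(max_m), assigned$m)
  ratios <- stats::setNames(rep(NA_real_, max_m), paste0("m", seq_len(max_m)))
  if (1L %in% assigned$m) {
    p1 <- assigned$power[assigned$m == 1L]
    ratios[assigned$m] <- assigned$power / p1
  }
  structure(list(
    fundamental_k = fundamental_k,
    assigned = assigned,
    missing = as.integer(missing),
    harmonic_power_ratios = ratios,
    tol_inv_nm = tol_inv_nm
  ), class = "harmonic_model")
}

#' @export
print.harmonic_model <- function(x, ...) {
  cat(sprintf("<harmonic_model> k0 = %.4g nm^-1, tol %.3g nm^-1\n",
              x$fundamental_k, x$tol_inv_nm))
  if (nrow(x$assigned)) print(x$assigned, row.names = FALSE)
  cat("missing harmonics:",
      if (length(x$missing)) paste(x$missing, collapse = ", ") else "none",
      "\n")
  invisible(x)
}

# closed-form OLS of y on x; returns c(intercept, slope, sse)
.ols <- function(x, y) {
  mx <- mean(x); my <- mean(y)
  sxx <- sum((x - mx)^2)
  slope <- sum((x - mx) * (y - my)) / sxx
  intercept <- my - slope * mx
  resid <- y - intercept - slope * x
  c(intercept, slope, sum(resid^2))
}

#' Correlation length from a two-slope log-log fit
#'
#' For rough surfaces without strict periodicity, the log-log averaged
#' spectrum shows two power-law regimes; the wavenumber where two fitted
#' lines intersect defines a correlation length `2 * pi / k_c`. The
#' breakpoint is found by exhaustive search over all splits of the fitted
#' bins (at least 4 bins per segment), minimizing the total squared residual
#' of the two least-squares lines in (log k, log power). Bins adjacent to DC
#' (the first bin) and beyond 0.8 of the Nyquist wavenumber are excluded by
#' default, as leakage and pixelation contaminate the extremes.
#'
#' @param psdf A [averaged_psdf()] result.
#' @param k_range Optional `c(kmin, kmax)` restricting the fit.
#' @param min_slope_difference Below this difference of slopes the knee is
#'   considered absent and an error is raised (default 0.1).
#' @return An object of class `slope_fit`: `breakpoint_k`, `slopes`,
#'   `intercepts`, `correlation_length_nm`, `residual`, `k_used`.
#' @export
correlation_length <- function(psdf, k_range = NULL,
                               min_slope_difference = 0.1) {
  stopifnot(inherits(psdf, "psdf"))
  k <- psdf$wavenumbers
  p <- psdf$power
  k_nyq <- pi / psdf$pixel_size_nm
  sel <- k > psdf$dk * 1.5 & k <= 0.8 * k_nyq   # drop first bin and the top
  if (!is.null(k_range)) {
    stopifnot(length(k_range) == 2L, k_range[1] < k_range[2])
    sel <- sel & k >= k_range[1] & k <= k_range[2]
  }
  sel <- sel & p > 0
  k <- k[sel]; p <- p[sel]
  n <- length(k)
  if (n < 8L) stop("need at least 8 usable bins in the fitted range")
  lx <- log(k); ly <- log(p)
  best <- NULL
  for (b in 4:(n - 4L)) {
    f1 <- .ols(lx[1:b], ly[1:b])
    f2 <- .ols(lx[(b + 1L):n], ly[(b + 1L):n])
    sse <- f1[3] + f2[3]
    if (is.null(best) || sse < best$sse) {
      best <- list(b = b, f1 = f1, f2 = f2, sse = sse)
    }
  }
  s1 <- best$f1[2]; s2 <- best$f2[2]
  if (abs(s1 - s2) < min_slope_difference) {
    stop("degenerate fit: the two slopes are indistinguishable (no knee)")
  }
  log_kc <- (best$f2[1] - best$f1[1]) / (s1 - s2)
  kc <- exp(log_kc)
  if (kc <= min(k) || kc >= max(k)) {
    stop("fitted breakpoint falls outside the fitted wavenumber range")
  }
  structure(list(
    breakpoint_k = kc,
    slopes = c(low_k = s1, high_k = s2),
    intercepts = c(low_k = best$f1[1], high_k = best$f2[1]),
    correlation_length_nm = 2 * pi / kc,
    residual = best$sse,
    split_index = best$b,
    k_used = k
  ), class = "slope_fit")
}

#' @export
print.slope_fit <- function(x, ...) {
  cat(sprintf(
    "<slope_fit> knee at k = %.4g nm^-1 (length %.3g nm); slopes %.3g / %.3g, SSE %.3g\n",
    x$breakpoint_k, x$correlation_length_nm, x$slopes[1], x$slopes[2],
    x$residual
  ))
  invisible(x)
}

#' Estimate the in-plane axis orientation of an elongated particle
#'
#' Thresholds the box region above the background (median plus a quarter of
#' the median-to-maximum range) and takes the orientation of the principal
#' axis of the second central moments of the mask. Angles are reported in
#' degrees versus the horizontal (fast-scan) direction, in `[-90, 90)`, with
#' the same screen convention as rendering (row index increasing downwards).
#'
#' @param map A [height_map()].
#' @param box A [box_selection()] containing the particle, or `NULL` for the
#'   whole image.
#' @return Orientation in degrees.
#' @export
estimate_axis <- function(map, box = NULL) {
  stopifnot(inherits(map, "height_map"))
  v <- map$values
  if (!is.null(box)) {
    stopifnot(inherits(box, "box_selection"))
    if (box$rows[2] > nrow(v) || box$cols[2] > ncol(v)) {
      stop("box extends outside the image")
    }
    v <- v[box$rows[1]:box$rows[2], box$cols[1]:box$cols[2], drop = FALSE]
  }
  thr <- stats::median(v) + 0.25 * (max(v) - stats::median(v))
  mask <- which(v > thr, arr.ind = TRUE)
  if (nrow(mask) == 0L) stop("no pixels above the foreground threshold")
  x <- mask[, 2L]; y <- mask[, 1L]
  mu20 <- mean((x - mean(x))^2)
  mu02 <- mean((y - mean(y))^2)
  mu11 <- mean((x - mean(x)) * (y - mean(y)))
  ang <- 0.5 * atan2(2 * mu11, mu20 - mu02) * 180 / pi
  if (ang >= 90) ang <- ang - 180
  if (ang < -90) ang <- ang + 180
  ang
}
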