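#' Axis-aligned box of scan lines
#'
#' Selects a rectangular region of a height map and the direction along which
#' spectra are taken. Ranges are 1-based and inclusive (the R convention;
#' stated in every output header). Lines run along rows (each row of the box
#' is one line) or along columns.
#'
#' @param rows,cols Length-2 integer vectors `c(first, last)`.
#' @param line_direction `"rows"` or `"columns"`.
#' @return An object of class `box_selection`.
#' @export
box_selection <- function(rows, cols, line_direction = c("rows", "columns")) {
  line_direction <- match.arg(line_direction)
  stopifnot(length(rows) == 2L, length(cols) == 2L,
            all(rows == round(rows)), all(cols == round(cols)),
            rows[1] >= 1, cols[1] >= 1,
            rows[2] >= rows[1], cols[2] >= cols[1])
  structure(list(rows = as.integer(rows), cols = as.integer(cols),
                 line_direction = line_direction), class = "box_selection")
}

#' @export
print.box_selection <- function(x, ...) {
  cat(sprintf("<box_selection> rows %d:%d, cols %d:%d, lines along %s\n",
              x$rows[1], x$rows[2], x$cols[1], x$cols[2], x$line_direction))
  invisible(x)
}

.box_dims <- function(box) {
  nr <- box$rows[2] - box$rows[1] + 1L
  nc <- box$cols[2] - box$cols[1] + 1L
  if (box$line_direction == "rows") {
    c(n_lines = nr, line_length = nc)
  } else {
    c(n_lines = nc, line_length = nr)
  }
}

.check_box <- function(box, map) {
  stopifnot(inherits(box, "box_selection"), inherits(map, "height_map"))
  if (box$rows[2] > nrow(map$values) || box$cols[2] > ncol(map$values)) {
    stop("box extends outside the image")
  }
  bd <- .box_dims(box)
  if (bd["n_lines"] < 4L) stop("box must contain at least 4 lines")
  if (bd["line_length"] < 16L) stop("lines must be at least 16 samples long")
  invisible(bd)
}

#' Line-averaged power spectral density of a box
#'
#' The averaged PSDF: every scan line in the box is mean-subtracted, Fourier
#' transformed, its squared modulus taken per frequency bin (discarding
#' phase), and the result averaged over all lines. The one-sided spectrum is
#' returned with the DC bin excluded, on the angular-wavenumber grid
#' `k_m = 2 * pi * m / (L * dx)`. Normalization is chosen so that
#' `sum(power) * dk` equals the mean per-line variance (Parseval, with the
#' 1/L variance convention); power is in nm^3 (nm^2 per unit wavenumber).
#' No detrending beyond per-line mean removal is applied, and the default
#' boxcar (no window) preserves peak positions; a Hann window is available,
#' scaled so broadband levels remain comparable (Parseval is then only
#' approximate).
#'
#' @param map A [height_map()].
#' @param box A [box_selection()] (at least 4 lines of at least 16 samples).
#' @param window `"none"` (default) or `"hann"`.
#' @return An object of class `psdf`: `wavenumbers`, `power`, `dk`,
#'   `n_lines_averaged`, `line_length_samples`, `box`, `source_channel`,
#'   `pixel_size_nm`, `window`.
#' @export
averaged_psdf <- function(map, box, window = c("none", "hann")) {
  window <- match.arg(window)
  .check_box(box, map)
  sub <- map$values[box$rows[1]:box$rows[2], box$cols[1]:box$cols[2],
                    drop = FALSE]
  lines <- if (box$line_direction == "rows") sub else t(sub)
  L <- ncol(lines)
  lines <- lines - rowMeans(lines)
  wcorr <- 1
  if (window == "hann") {
    w <- 0.5 - 0.5 * cos(2 * pi * seq.int(0, L - 1) / (L - 1))
    lines <- sweep(lines, 2L, w, `*`)
    wcorr <- mean(w^2)
  }
  X <- stats::mvfft(t(lines))              # L x n_lines
  P <- Mod(X)^2 / L^2                      # per line, per bin
  m <- seq_len(L %/% 2L)
  mult <- rep(2, length(m))
  if (L %% 2L == 0L) mult[length(m)] <- 1  # Nyquist bin is not doubled
  dk <- 2 * pi / (L * map$pixel_size_nm)
  power <- rowMeans(P)[m + 1L] * mult / dk / wcorr
  structure(list(
    wavenumbers = m * dk,
    power = power,
    dk = dk,
    n_lines_averaged = nrow(lines),
    line_length_samples = L,
    box = box,
    source_channel = map$channel_label,
    pixel_size_nm = map$pixel_size_nm,
    window = window
  ), class = "psdf")
}

#' @export
print.psdf <- function(x, ...) {
  cat(sprintf(
    "<psdf> %d bins, dk = %.4g nm^-1 (k up to %.3g), %d lines of %d samples, channel \"%s\", window %s\n",
    length(x$power), x$dk, max(x$wavenumbers), x$n_lines_averaged,
    x$line_length_samples, x$source_channel, x$window
  ))
  invisible(x)
}

#' Signal-to-noise ratio of spectrum bins
#'
#' SNR of a bin is its power divided by the median power of the 9 surrounding
#' bins at offsets -6..-2 and +2..+5 (the three central bins, the peak and
#' its immediate neighbours, are excluded so a narrow peak does not inflate
#' its own floor). Offsets are clipped to the spectrum range. A zero floor
#' gives `Inf`.
#'
#' @param psdf A [averaged_psdf()] result.
#' @param k Wavenumbers at which to evaluate (nearest bin is used), or `NULL`
#'   to use `index`.
#' @param index Bin indices (used when `k` is `NULL`).
#' @return Numeric vector of SNR values.
#' @export
psdf_snr <- function(psdf, k = NULL, index = NULL) {
  stopifnot(inherits(psdf, "psdf"))
  if (!is.null(k)) {
    index <- vapply(k, function(kk) which.min(abs(psdf$wavenumbers - kk)), 1L)
  }
  stopifnot(!is.null(index), all(index >= 1), all(index <= length(psdf$power)))
  offs <- c(-6:-2, 2:5)
  vapply(index, function(i) {
    nb <- unique(pmin(pmax(i + offs, 1L), length(psdf$power)))
    nb <- setdiff(nb, (i - 1L):(i + 1L))
    floor_ <- stats::median(psdf$power[nb])
    if (floor_ <= 0) {
      if (psdf$power[i] > 0) Inf else 0
    } else {
      psdf$power[i] / floor_
    }
  }, numeric(1))
}

#' Compare spectral peaks against a background box
#'
#' Confirms that analysed peaks are specific to the signal region: a peak is
#' `signal-specific` when its SNR in the signal box reaches the threshold
#' while its SNR in the background box does not; it is `also-in-background`
#' when the background shows it too, and `not-detected` when even the signal
#' box does not reach the threshold. Both spectra must share the bin grid
#' (same line length and pixel size).
#'
#' @param signal,background [averaged_psdf()] results on the same bin grid.
#' @param peak_ks Wavenumbers of the peaks to check (nm^-1).
#' @param snr_threshold Detection threshold (default 3).
#' @return A data frame with `k`, `snr_signal`, `snr_background`, `flag`.
#' @export
compare_background <- function(signal, background, peak_ks,
                               snr_threshold = 3) {
  stopifnot(inherits(signal, "psdf"), inherits(background, "psdf"))
  if (signal$line_length_samples != background$line_length_samples ||
      abs(signal$dk - background$dk) > 1e-12) {
    stop("signal and background spectra are on incompatible bin grids")
  }
  snr_s <- psdf_snr(signal, k = peak_ks)
  snr_b <- psdf_snr(background, k = peak_ks)
  flag <- ifelse(snr_s < snr_threshold, "not-detected",
                 ifelse(snr_b >= snr_threshold, "also-in-background",
                        "signal-specific"))
  data.frame(k = peak_ks, snr_signal = snr_s, snr_background = snr_b,
             flag = flag)
}

#' Greedy SNR optimization of a box
#'
#' Starting from a seed box, repeatedly moves each of the four box edges by
#' `step` pixels in either direction and keeps the move that most improves
#' the SNR of the bin nearest `target_k`, until no move improves it (a local
#' maximum). Boxes never shrink below 4 lines or 16 samples and never leave
#' the image; the search is deterministic.
#'
#' @param map A [height_map()].
#' @param seed_box A valid [box_selection()].
#' @param target_k Wavenumber whose SNR is maximized; must be below the
#'   Nyquist wavenumber `pi / pixel_size`.
#' @param step Edge step in pixels (default 2).
#' @param max_iter Safety cap on greedy iterations.
#' @param window Spectral window passed to [averaged_psdf()].
#' @return The optimized `box_selection`.
#' @export
optimize_box <- function(map, seed_box, target_k, step = 2L, max_iter = 50L,
                         window = "none") {
  stopifnot(inherits(map, "height_map"))
  if (target_k >= pi / map$pixel_size_nm) {
    stop("`target_k` is at or beyond the Nyquist wavenumber")
  }
  .check_box(seed_box, map)
  objective <- function(box) {
    ps <- averaged_psdf(map, box, window = window)
    psdf_snr(ps, k = target_k)
  }
  candidate <- function(box, edge, delta) {
    r <- box$rows; c <- box$cols
    if (edge == 1L) r[1] <- r[1] + delta
    if (edge == 2L) r[2] <- r[2] + delta
    if (edge == 3L) c[1] <- c[1] + delta
    if (edge == 4L) c[2] <- c[2] + delta
    if (r[1] < 1 || c[1] < 1 || r[2] > nrow(map$values) ||
        c[2] > ncol(map$values) || r[2] < r[1] || c[2] < c[1]) {
      return(NULL)
    }
    b <- box_selection(r, c, box$line_direction)
    bd <- .box_dims(b)
    if (bd["n_lines"] < 4L || bd["line_length"] < 16L) return(NULL)
    b
  }
  best <- seed_box
  best_val <- objective(best)
  for (it in seq_len(max_iter)) {
    improved <- FALSE
    for (edge in 1:4) {
      for (delta in c(-step, step)) {
        cand <- candidate(best, edge, delta)
        if (is.null(cand)) next
        val <- objective(cand)
        if (is.finite(val) && val > best_val ||
            (is.infinite(val) && is.finite(best_val))) {
          best <- cand; best_val <- val; improved <- TRUE
        }
      }
    }
    if (!improved) break
  }
  best
}
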