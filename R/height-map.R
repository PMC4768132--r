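#' Height map container
#'
#' A raster of surface heights in nm on a square-pixel grid, plus the pixel
#' size and a channel label. Rows are fast-scan lines (the fast scan is
#' horizontal); row 1 is the top of the image.
#'
#' @param values Numeric matrix of heights (nm). All values must be finite.
#' @param pixel_size_nm Positive pixel size (nm).
#' @param channel_label Free-text channel name, e.g. `"topography"` or
#'   `"mode2-like"`.
#' @param metadata Named list of arbitrary metadata (seed, generator spec, ...).
#' @return An object of class `height_map`.
#' @export
height_map <- function(values, pixel_size_nm, channel_label = "topography",
                       metadata = list()) {
  if (!is.matrix(values) || !is.numeric(values)) {
    stop("`values` must be a numeric matrix")
  }
  if (any(!is.finite(values))) stop("height values must all be finite")
  if (!is.numeric(pixel_size_nm) || length(pixel_size_nm) != 1L ||
      !is.finite(pixel_size_nm) || pixel_size_nm <= 0) {
    stop("`pixel_size_nm` must be a single positive number")
  }
  stopifnot(is.character(channel_label), length(channel_label) == 1L,
            is.list(metadata))
  structure(list(
    values = values,
    pixel_size_nm = pixel_size_nm,
    channel_label = channel_label,
    metadata = metadata
  ), class = "height_map")
}

#' @export
print.height_map <- function(x, ...) {
  cat(sprintf(
    "<height_map> %d x %d px, %.4g nm/px (%.4g x %.4g nm), channel \"%s\", z range [%.3g, %.3g] nm\n",
    nrow(x$values), ncol(x$values), x$pixel_size_nm,
    nrow(x$values) * x$pixel_size_nm, ncol(x$values) * x$pixel_size_nm,
    x$channel_label, min(x$values), max(x$values)
  ))
  invisible(x)
}

#' @export
dim.height_map <- function(x) dim(x$values)

#' Per-line flattening (destroys axial periodicities)
#'
#' Subtracts the median from every fast-scan line, the common first step of
#' AFM topography display. Line-wise flattening removes exactly the per-line
#' phase information that the averaged line spectrum needs, so maps flagged as
#' flattened are refused by [run_pipeline()]; the function exists so that the
#' refusal can be exercised and so users can see the effect.
#'
#' @param map A [height_map()].
#' @return A `height_map` with `metadata$flattened = TRUE`.
#' @export
flatten_lines <- function(map) {
  stopifnot(inherits(map, "height_map"))
  v <- map$values - apply(map$values, 1, stats::median)
  md <- map$metadata
  md$flattened <- TRUE
  height_map(v, map$pixel_size_nm, map$channel_label, md)
}
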