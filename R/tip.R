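#' Build a parametric tip profile
#'
#' Radial tip shape sampled on an odd-sized, apex-centred pixel grid, stored
#' as non-positive heights with the apex at 0: a spherical cap
#' `-(R - sqrt(R^2 - r^2))` truncated at `r = R`, a paraboloid `-r^2 / (2R)`
#' truncated at depth `R`, or a single-pixel point probe. Pixels outside the
#' finite support are `NA` and ignored by dilation.
#'
#' @param model `"sphere"`, `"paraboloid"` or `"point"`.
#' @param radius_nm Apex curvature radius (nm); ignored for `"point"`.
#'   A radius smaller than one pixel degenerates to a point probe.
#' @param pixel_size_nm Pixel size (nm); must match the map the tip is used
#'   on.
#' @return An object of class `tip_shape` with fields `profile` (matrix, nm),
#'   `pixel_size_nm`, `radius_nm`, `model`.
#' @export
#' @examples
#' t2 <- build_tip("sphere", 2, 0.5)
#' max(t2$profile, na.rm = TRUE) # 0 at the apex
build_tip <- function(model = c("sphere", "paraboloid", "point"),
                      radius_nm = 2, pixel_size_nm = 0.5) {
  model <- match.arg(model)
  stopifnot(radius_nm >= 0, pixel_size_nm > 0)
  if (model == "point" || radius_nm < pixel_size_nm) {
    prof <- matrix(0, 1L, 1L)
    return(structure(list(profile = prof, pixel_size_nm = pixel_size_nm,
                          radius_nm = if (model == "point") 0 else radius_nm,
                          model = "point"), class = "tip_shape"))
  }
  support <- if (model == "sphere") radius_nm else sqrt(2) * radius_nm
  n <- floor(support / pixel_size_nm)
  off <- (-n:n) * pixel_size_nm
  r2 <- outer(off^2, off^2, `+`)
  prof <- matrix(NA_real_, 2L * n + 1L, 2L * n + 1L)
  inside <- r2 <= support^2 + 1e-12
  if (model == "sphere") {
    prof[inside] <- -(radius_nm - sqrt(pmax(radius_nm^2 - r2[inside], 0)))
  } else {
    prof[inside] <- -r2[inside] / (2 * radius_nm)
  }
  structure(list(profile = prof, pixel_size_nm = pixel_size_nm,
                 radius_nm = radius_nm, model = model), class = "tip_shape")
}

#' @export
print.tip_shape <- function(x, ...) {
  cat(sprintf("<tip_shape> %s, R = %.3g nm, %d x %d px @ %.3g nm\n",
              x$model, x$radius_nm, nrow(x$profile), ncol(x$profile),
              x$pixel_size_nm))
  invisible(x)
}

#' Image a surface with a finite tip (greyscale dilation)
#'
#' Simulates probe broadening: the imaged height at `x` is
#' `max over tip support u of surface(x + u) + profile(u)`, the greyscale
#' dilation of the surface by the (inverted) tip. The output is everywhere
#' `>=` the input; a point tip is the identity. Image borders are handled by
#' edge replication, which avoids spurious rim artifacts in spectral boxes
#' that touch the frame.
#'
#' @param map A [height_map()].
#' @param tip A [build_tip()] object with the same pixel size as `map`
#'   (hard error otherwise).
#' @return A `height_map` of the imaged surface.
#' @export
tip_dilate <- function(map, tip) {
  .tip_morph(map, tip, erode = FALSE)
}

#' Morphological surface reconstruction (erosion by the tip)
#'
#' The inverse check to [tip_dilate()]: the greyscale erosion
#' `min over u of imaged(x + u) - profile(u)` recovers the tightest surface
#' consistent with the imaged one. Erosion after dilation never overshoots
#' the original surface. Provided as a verification tool, not a pipeline
#' stage.
#'
#' @inheritParams tip_dilate
#' @return A `height_map`.
#' @export
tip_erode <- function(map, tip) {
  .tip_morph(map, tip, erode = TRUE)
}

.tip_morph <- function(map, tip, erode) {
  stopifnot(inherits(map, "height_map"), inherits(tip, "tip_shape"))
  if (abs(map$pixel_size_nm - tip$pixel_size_nm) > 1e-9) {
    stop("tip and map pixel sizes differ")
  }
  v <- map$values
  nr <- nrow(v); nc <- ncol(v)
  tp <- tip$profile
  if (nrow(tp) > nr || ncol(tp) > nc) {
    stop("tip support is larger than the image")
  }
  ctr <- (dim(tp) + 1L) %/% 2L
  sup <- which(!is.na(tp), arr.ind = TRUE)
  out <- matrix(if (erode) Inf else -Inf, nr, nc)
  ri <- seq_len(nr); ci <- seq_len(nc)
  for (p in seq_len(nrow(sup))) {
    du <- sup[p, 1L] - ctr[1L]
    dv <- sup[p, 2L] - ctr[2L]
    h <- tp[sup[p, 1L], sup[p, 2L]]
    rs <- pmin(pmax(ri + du, 1L), nr)   # edge replication
    cs <- pmin(pmax(ci + dv, 1L), nc)
    out <- if (erode) pmin(out, v[rs, cs] - h) else pmax(out, v[rs, cs] + h)
  }
  md <- map$metadata
  md$tip <- list(model = tip$model, radius_nm = tip$radius_nm,
                 operation = if (erode) "erode" else "dilate")
  height_map(out, map$pixel_size_nm, map$channel_label, md)
}
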