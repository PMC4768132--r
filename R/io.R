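#' Read and write height maps
#'
#' Two plain interchange formats are supported, chosen by file extension:
#'
#' * **Text matrix** (`.txt`, `.dat`): whitespace-separated rows of heights
#'   in nm, preceded by comment header lines beginning with `#` of the form
#'   `# key: value`. The header must state `# pixel_size_nm: <value>`;
#'   a missing pixel size is a hard error (a pixel size is never guessed for
#'   real data). `# channel: <label>` is honoured when present.
#' * **Float TIFF** (`.tif`, `.tiff`): a 32-bit float TIFF holding heights
#'   rescaled to `[0, 1]`, with a JSON sidecar `<path>.json` carrying
#'   `pixel_size_nm`, `channel_label`, the z range used for rescaling, and
#'   any metadata. Reading without the sidecar is an error.
#'
#' `read_heightmap(write_heightmap(m))` reproduces values to 32-bit float
#' precision and the pixel size exactly.
#'
#' @param map A [height_map()].
#' @param path Output/input path; the extension selects the format.
#' @return `write_heightmap` returns `path` invisibly; `read_heightmap`
#'   returns a [height_map()].
#' @export
write_heightmap <- function(map, path) {
  stopifnot(inherits(map, "height_map"))
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("txt", "dat")) {
    .write_text_map(map, path)
  } else if (ext %in% c("tif", "tiff")) {
    .write_tiff_map(map, path)
  } else {
    stop(sprintf("unsupported height-map extension '%s'", ext))
  }
  invisible(path)
}

#' @rdname write_heightmap
#' @export
read_heightmap <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("txt", "dat")) {
    .read_text_map(path)
  } else if (ext %in% c("tif", "tiff")) {
    .read_tiff_map(path)
  } else {
    stop(sprintf("unsupported height-map extension '%s'", ext))
  }
}

.write_text_map <- function(map, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# pixel_size_nm: %.10g", map$pixel_size_nm), con)
  writeLines(sprintf("# channel: %s", map$channel_label), con)
  if (!is.null(map$metadata$seed)) {
    writeLines(sprintf("# seed: %d", map$metadata$seed), con)
  }
  if (isTRUE(map$metadata$flattened)) writeLines("# flattened: TRUE", con)
  writeLines(sprintf("# rows: %d", nrow(map$values)), con)
  writeLines("# units: nm; rows are fast-scan lines, row 1 at the top", con)
  body <- apply(map$values, 1L, function(r) {
    paste(formatC(r, digits = 9, format = "g"), collapse = " ")
  })
  writeLines(body, con)
}

.read_text_map <- function(path) {
  txt <- readLines(path)
  is_hdr <- grepl("^\\s*#", txt)
  hdr <- txt[is_hdr]
  keys <- sub("^\\s*#\\s*([^:]+):\\s*(.*)$", "\\1", hdr)
  vals <- sub("^\\s*#\\s*([^:]+):\\s*(.*)$", "\\2", hdr)
  named <- stats::setNames(vals, trimws(keys))
  if (!"pixel_size_nm" %in% names(named)) {
    stop("text height map has no '# pixel_size_nm:' header; refusing to guess")
  }
  px <- suppressWarnings(as.numeric(named[["pixel_size_nm"]]))
  if (!is.finite(px) || px <= 0) stop("invalid pixel_size_nm header value")
  body_idx <- which(!is_hdr & nzchar(trimws(txt)))
  if (!length(body_idx)) stop("text height map has no data rows")
  rows <- strsplit(trimws(txt[body_idx]), "\\s+")
  nfield <- lengths(rows)
  if (length(unique(nfield)) != 1L) {
    bad <- body_idx[which(nfield != nfield[1])[1]]
    stop(sprintf("malformed matrix: line %d has %d fields, expected %d",
                 bad, nfield[which(nfield != nfield[1])[1]], nfield[1]))
  }
  vals <- suppressWarnings(vapply(rows, as.numeric, numeric(nfield[1])))
  if (any(!is.finite(vals))) {
    bad_col <- which(apply(!is.finite(vals), 2L, any))[1]
    stop(sprintf("malformed matrix: non-numeric value on line %d",
                 body_idx[bad_col]))
  }
  channel <- if ("channel" %in% names(named)) named[["channel"]] else "topography"
  md <- as.list(named[setdiff(names(named), c("pixel_size_nm", "channel"))])
  if (!is.null(md$flattened)) md$flattened <- toupper(md$flattened) == "TRUE"
  height_map(t(vals), px, channel_label = channel, metadata = md)
}

.write_tiff_map <- function(map, path) {
  v <- map$values
  zmin <- min(v); zmax <- max(v)
  norm <- if (zmax > zmin) (v - zmin) / (zmax - zmin) else v * 0
  tiff::writeTIFF(norm, path, bits.per.sample = 32L, compression = "none")
  sidecar <- paste0(path, ".json")
  jsonlite::write_json(list(
    pixel_size_nm = map$pixel_size_nm,
    channel_label = map$channel_label,
    z_min_nm = zmin,
    z_max_nm = zmax,
    metadata = .jsonable(map$metadata)
  ), sidecar, auto_unbox = TRUE, digits = NA, pretty = TRUE)
}

.read_tiff_map <- function(path) {
  sidecar <- paste0(path, ".json")
  if (!file.exists(sidecar)) {
    stop(sprintf("TIFF height map '%s' has no JSON sidecar '%s'; the pixel size is unknown",
                 path, sidecar))
  }
  meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  if (is.null(meta$pixel_size_nm)) stop("sidecar lacks pixel_size_nm")
  v <- tiff::readTIFF(path)
  if (is.array(v) && length(dim(v)) == 3L) v <- v[, , 1L]
  values <- v * (meta$z_max_nm - meta$z_min_nm) + meta$z_min_nm
  height_map(values, meta$pixel_size_nm,
             channel_label = if (is.null(meta$channel_label)) "topography"
                             else meta$channel_label,
             metadata = if (is.null(meta$metadata)) list()
                        else as.list(meta$metadata))
}

# nested S3 specs become plain lists for JSON serialization
.jsonable <- function(x) {
  if (is.list(x)) lapply(unclass(x), .jsonable) else x
}
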