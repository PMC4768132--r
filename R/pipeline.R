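#' Pipeline run configuration
#'
#' Bundles everything one end-to-end analysis needs: the input source (a
#' simulation preset plus seed, or height-map files), the channel to analyse,
#' the spectral boxes (explicit or automatic), spectral and detection
#' options, and the lattice parameters used for the predicted-peak overlay.
#'
#' Presets:
#' * `"paper-default"` / `"vertical"`: vertical virion, default scene,
#'   frozen channel-noise presets, 2 nm spherical tip.
#' * `"horizontal"`: the same with the virion along the fast-scan direction.
#' * `"noiseless"`: vertical virion, no substrate roughness, no aggregates,
#'   no measurement noise, 2 nm spherical tip.
#' * `"files"`: read `input_topography` / `input_mode2` instead of
#'   simulating.
#'
#' @param preset One of `"paper-default"`, `"noiseless"`, `"horizontal"`,
#'   `"vertical"`, `"files"`.
#' @param seed Integer seed driving all simulation randomness.
#' @param channel `"mode2-like"` or `"topography"`.
#' @param input_topography,input_mode2 File paths (preset `"files"` only).
#' @param signal_box,background_box Optional explicit [box_selection()]s;
#'   `NULL` selects them automatically ([crest_box()] / [background_box()]).
#'   Explicit boxes must be disjoint.
#' @param snr_threshold Peak detection threshold.
#' @param window Spectral window (`"none"` or `"hann"`).
#' @param tip `NULL` for the preset default, a [build_tip()] object, or
#'   `"none"` to skip tip broadening.
#' @param helix [helix_parameters()] used for simulation and prediction.
#' @param max_harmonic Highest harmonic reported by [assign_harmonics()].
#' @param out_dir Output directory, or `NULL` to write nothing.
#' @return An object of class `run_config`.
#' @export
run_config <- function(preset = c("paper-default", "noiseless", "horizontal",
                                  "vertical", "files"),
                       seed = 1L,
                       channel = c("mode2-like", "topography"),
                       input_topography = NULL, input_mode2 = NULL,
                       signal_box = NULL, background_box = NULL,
                       snr_threshold = 3, window = "none",
                       tip = NULL, helix = helix_parameters(),
                       max_harmonic = 3L, out_dir = NULL) {
  preset <- match.arg(preset)
  channel <- match.arg(channel)
  stopifnot(seed == round(seed), snr_threshold > 1,
            inherits(helix, "helix_parameters"))
  if (preset == "files") {
    paths <- c(input_topography, input_mode2)
    if (!length(paths)) stop("preset 'files' needs at least one input path")
    missing <- paths[!file.exists(paths)]
    if (length(missing)) {
      stop(sprintf("input file(s) not found: %s",
                   paste(missing, collapse = ", ")))
    }
  }
  if (!is.null(signal_box) && !is.null(background_box)) {
    if (.boxes_overlap(signal_box, background_box)) {
      stop("signal and background boxes must be disjoint")
    }
  }
  structure(list(
    preset = preset, seed = as.integer(seed), channel = channel,
    input_topography = input_topography, input_mode2 = input_mode2,
    signal_box = signal_box, background_box = background_box,
    snr_threshold = snr_threshold, window = window, tip = tip,
    helix = helix, max_harmonic = as.integer(max_harmonic),
    out_dir = out_dir
  ), class = "run_config")
}

.boxes_overlap <- function(a, b) {
  stopifnot(inherits(a, "box_selection"), inherits(b, "box_selection"))
  a$rows[1] <= b$rows[2] && b$rows[1] <= a$rows[2] &&
    a$cols[1] <= b$cols[2] && b$cols[1] <= a$cols[2]
}

# deterministic short hash of the resolved configuration (polynomial hash
# over the deparsed config, reported as 8 hex digits)
.config_hash <- function(x) {
  s <- paste(deparse(x, control = "all"), collapse = "\n")
  h <- 0
  for (b in utf8ToInt(s)) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", as.integer(h))
}

#' Automatic crest box over the particle
#'
#' Finds the column (or row) of maximal median height — the cylinder crest —
#' and selects a band of the given width around it, with full-length lines
#' along the particle axis (trimmed by a small margin at the frame edge).
#'
#' @param map A [height_map()].
#' @param line_direction `"columns"` for a vertical particle (lines along the
#'   axis run down columns) or `"rows"` for a horizontal one.
#' @param width_nm Width of the crest band (nm).
#' @param margin_px Pixels trimmed from the line ends.
#' @return A [box_selection()].
#' @export
crest_box <- function(map, line_direction = c("columns", "rows"),
                      width_nm = 6, margin_px = 2L) {
  line_direction <- match.arg(line_direction)
  stopifnot(inherits(map, "height_map"))
  v <- map$values
  d <- map$pixel_size_nm
  half <- max(2L, round(width_nm / 2 / d))
  if (line_direction == "columns") {
    prof <- apply(v, 2L, stats::median)
    ctr <- which.max(prof)
    cols <- c(max(1L, ctr - half), min(ncol(v), ctr + half))
    rows <- c(1L + margin_px, nrow(v) - margin_px)
  } else {
    prof <- apply(v, 1L, stats::median)
    ctr <- which.max(prof)
    rows <- c(max(1L, ctr - half), min(nrow(v), ctr + half))
    cols <- c(1L + margin_px, ncol(v) - margin_px)
  }
  box_selection(rows, cols, line_direction)
}

#' Automatic background box matched to a signal box
#'
#' Chooses a substrate region with the same line grid as the signal box (so
#' the two spectra share wavenumber bins): a band of equal width over columns
#' (or rows) whose 90th height percentile stays below `max_height_nm`,
#' as far from the signal box as possible.
#'
#' @param map A [height_map()].
#' @param signal_box The [box_selection()] being compared against.
#' @param max_height_nm Maximum 90th-percentile height of background lines.
#' @return A [box_selection()] disjoint from `signal_box`.
#' @export
background_box <- function(map, signal_box, max_height_nm = 2) {
  stopifnot(inherits(map, "height_map"), inherits(signal_box, "box_selection"))
  v <- map$values
  if (signal_box$line_direction == "columns") {
    stat <- apply(v, 2L, stats::quantile, probs = 0.9, names = FALSE)
    span <- signal_box$cols
    n_all <- ncol(v)
  } else {
    stat <- apply(v, 1L, stats::quantile, probs = 0.9, names = FALSE)
    span <- signal_box$rows
    n_all <- nrow(v)
  }
  w <- span[2] - span[1] + 1L
  ok <- stat < max_height_nm
  runs <- rle(ok)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  cand <- which(runs$values & runs$lengths >= w)
  if (!length(cand)) stop("no background region wide enough for comparison")
  ctr_sig <- mean(span)
  best <- NULL; best_dist <- -1
  for (i in cand) {
    # position the window inside the run, as far from the signal box as possible
    lo <- starts[i]; hi <- ends[i] - w + 1L
    pos <- if (abs(lo - ctr_sig) > abs(hi - ctr_sig)) lo else hi
    dist <- abs(pos + (w - 1) / 2 - ctr_sig)
    if (dist > best_dist) { best <- pos; best_dist <- dist }
  }
  rng <- c(best, best + w - 1L)
  if (signal_box$line_direction == "columns") {
    box_selection(signal_box$rows, rng, "columns")
  } else {
    box_selection(rng, signal_box$cols, "rows")
  }
}

.preset_scene <- function(config) {
  orient <- if (config$preset == "horizontal") 0 else 90
  if (config$preset == "noiseless") {
    scene_spec(helix = config$helix, orientation_deg = orient,
               substrate_rms_nm = 0, aggregate_density_per_um2 = 0,
               seed = config$seed)
  } else {
    scene_spec(helix = config$helix, orientation_deg = orient,
               seed = config$seed)
  }
}

#' Run the full analysis pipeline
#'
#' Orchestrates: simulate (or load) height maps, pick a channel, choose the
#' signal (crest) and background boxes, compute the line-averaged spectra,
#' detect peaks and confirm them against the background, assign harmonics of
#' the three-turn building block, and tabulate predicted versus observed
#' peaks. The run is deterministic given the seeds; when `out_dir` is set,
#' spectra (CSV), a peak/harmonic report (JSON), the predicted-peak table
#' (CSV), the resolved configuration and a log of every decision are written,
#' each carrying the configuration hash and seed.
#'
#' Maps flagged as line-flattened (`metadata$flattened`) are refused:
#' per-line flattening destroys the periodicities this analysis measures.
#'
#' @param config A [run_config()].
#' @return A report (list, class `pipeline_report`), invisibly also written
#'   to `config$out_dir` when set.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  log <- character(0)
  note <- function(fmt, ...) {
    log[[length(log) + 1L]] <<- sprintf(fmt, ...)
  }

  # --- stage: input -------------------------------------------------------
  if (config$preset == "files") {
    maps <- list()
    if (!is.null(config$input_topography)) {
      maps$topography <- read_heightmap(config$input_topography)
    }
    if (!is.null(config$input_mode2)) {
      maps$mode2 <- read_heightmap(config$input_mode2)
    }
    note("loaded %d height map(s) from files", length(maps))
  } else {
    spec <- .preset_scene(config)
    base <- render_scene(spec)
    tip <- config$tip
    if (is.null(tip)) tip <- build_tip("sphere", 2, spec$pixel_size_nm)
    if (inherits(tip, "tip_shape")) {
      base <- tip_dilate(base, tip)
      note("tip broadening: %s, R = %.3g nm", tip$model, tip$radius_nm)
    } else {
      note("tip broadening skipped")
    }
    if (config$preset == "noiseless") {
      zero <- noise_spec(seed = config$seed)
      maps <- make_channels(spec, topo_noise = zero, mode2_noise = zero,
                            base = base)
    } else {
      maps <- make_channels(spec, base = base)
    }
    note("simulated preset '%s', seed %d, orientation %g deg",
         config$preset, config$seed, spec$orientation_deg)
  }
  map <- if (config$channel == "topography") maps$topography else maps$mode2
  if (is.null(map)) stop(sprintf("channel '%s' not available", config$channel))
  if (isTRUE(map$metadata$flattened)) {
    stop("refusing to compute the averaged PSDF of a line-flattened map: flattening removes the sample periodicities")
  }
  note("channel: %s", map$channel_label)

  # --- stage: box selection ----------------------------------------------
  orient <- if (config$preset == "files") {
    estimate_axis(map)
  } else if (config$preset == "horizontal") 0 else 90
  dir <- if (abs(orient) >= 45) "columns" else "rows"
  note("axis orientation %g deg -> lines along %s", orient, dir)
  sig_box <- config$signal_box
  if (is.null(sig_box)) sig_box <- crest_box(map, dir)
  bg_box <- config$background_box
  if (is.null(bg_box)) bg_box <- background_box(map, sig_box)
  if (.boxes_overlap(sig_box, bg_box)) {
    stop("signal and background boxes overlap")
  }
  note("signal box rows %d:%d cols %d:%d; background rows %d:%d cols %d:%d (1-based inclusive)",
       sig_box$rows[1], sig_box$rows[2], sig_box$cols[1], sig_box$cols[2],
       bg_box$rows[1], bg_box$rows[2], bg_box$cols[1], bg_box$cols[2])

  # --- stage: spectra, peaks, harmonics ----------------------------------
  ps_sig <- averaged_psdf(map, sig_box, window = config$window)
  ps_bg <- averaged_psdf(map, bg_box, window = config$window)
  note("PSDF: %d bins, dk = %.4g nm^-1, window %s",
       length(ps_sig$power), ps_sig$dk, config$window)
  peaks <- detect_peaks(ps_sig, config$snr_threshold)
  note("detected %d peak(s) at SNR >= %.3g", nrow(peaks$peaks),
       config$snr_threshold)
  cmp <- if (nrow(peaks$peaks)) {
    compare_background(ps_sig, ps_bg, peaks$peaks$wavenumber_inv_nm,
                       config$snr_threshold)
  } else {
    data.frame(k = numeric(0), snr_signal = numeric(0),
               snr_background = numeric(0), flag = character(0))
  }
  k0 <- wavenumber_of(3 * config$helix$pitch_nm)
  harm <- assign_harmonics(peaks, k0, max_m = config$max_harmonic)
  note("harmonics of k0 = %.4g nm^-1: %d assigned, missing {%s}",
       k0, nrow(harm$assigned), paste(harm$missing, collapse = ", "))
  predicted <- predicted_peaks(config$helix)

  report <- structure(list(
    preset = config$preset, seed = config$seed,
    channel = map$channel_label, orientation_deg = orient,
    signal_box = sig_box, background_box = bg_box,
    psdf_signal = ps_sig, psdf_background = ps_bg,
    peaks = peaks, background_comparison = cmp, harmonics = harm,
    predicted = predicted,
    config_hash = .config_hash(config), log = log
  ), class = "pipeline_report")
  if (!is.null(config$out_dir)) .write_report(report, config)
  report
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat(sprintf("<pipeline_report> preset %s, seed %d, channel %s (hash %s)\n",
              x$preset, x$seed, x$channel, x$config_hash))
  cat("peaks:\n")
  print(x$background_comparison, row.names = FALSE)
  print(x$harmonics)
  invisible(x)
}

.write_report <- function(report, config) {
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  hdr <- function(extra = character(0)) {
    c(sprintf("# config_hash: %s", report$config_hash),
      sprintf("# seed: %d", report$seed),
      "# coordinates: 1-based inclusive box ranges, row 1 at the top",
      extra)
  }
  wcsv <- function(ps, file) {
    box <- ps$box
    lines <- c(
      hdr(sprintf("# box: rows %d:%d cols %d:%d, lines along %s, channel %s",
                  box$rows[1], box$rows[2], box$cols[1], box$cols[2],
                  box$line_direction, ps$source_channel)),
      "k_inv_nm,power_nm3",
      sprintf("%.10g,%.10g", ps$wavenumbers, ps$power)
    )
    writeLines(lines, file.path(config$out_dir, file))
  }
  wcsv(report$psdf_signal, "spectrum_signal.csv")
  wcsv(report$psdf_background, "spectrum_background.csv")
  pred <- report$predicted
  lines <- c(hdr(), paste(colnames(pred), collapse = ","),
             do.call(paste, c(lapply(pred, function(col) {
               if (is.numeric(col) && !is.integer(col)) sprintf("%.10g", col)
               else as.character(col)
             }), sep = ",")))
  writeLines(lines, file.path(config$out_dir, "predicted_peaks.csv"))
  jsonlite::write_json(list(
    config_hash = report$config_hash,
    seed = report$seed,
    channel = report$channel,
    peaks = report$peaks$peaks,
    background_comparison = report$background_comparison,
    harmonics = list(
      fundamental_k = report$harmonics$fundamental_k,
      assigned = report$harmonics$assigned,
      missing = report$harmonics$missing,
      power_ratios = as.list(report$harmonics$harmonic_power_ratios)
    )
  ), file.path(config$out_dir, "report.json"),
  auto_unbox = TRUE, digits = NA, pretty = TRUE)
  write_run_config(config, file.path(config$out_dir, "config_resolved.txt"),
                   hash = report$config_hash)
  writeLines(c(hdr(), report$log), file.path(config$out_dir, "log.txt"))
  invisible(NULL)
}

#' Write / read a flat key-value run configuration
#'
#' The resolved configuration of every run is written as `key: value` lines
#' so a run can be repeated from its output directory. Boxes serialize as
#' `rows r1:r2 cols c1:c2 dir`; the tip as `model radius_nm`.
#'
#' @param config A [run_config()].
#' @param path File path.
#' @param hash Optional config hash to embed as a comment.
#' @return `write_run_config` returns `path` invisibly; `read_run_config`
#'   returns a [run_config()].
#' @export
write_run_config <- function(config, path, hash = NULL) {
  stopifnot(inherits(config, "run_config"))
  fmt_box <- function(b) {
    if (is.null(b)) "auto"
    else sprintf("rows %d:%d cols %d:%d %s", b$rows[1], b$rows[2],
                 b$cols[1], b$cols[2], b$line_direction)
  }
  fmt_tip <- function(t) {
    if (is.null(t)) "preset-default"
    else if (inherits(t, "tip_shape")) sprintf("%s %.10g", t$model, t$radius_nm)
    else "none"
  }
  lines <- c(
    if (!is.null(hash)) sprintf("# config_hash: %s", hash),
    sprintf("preset: %s", config$preset),
    sprintf("seed: %d", config$seed),
    sprintf("channel: %s", config$channel),
    sprintf("snr_threshold: %.10g", config$snr_threshold),
    sprintf("window: %s", config$window),
    sprintf("signal_box: %s", fmt_box(config$signal_box)),
    sprintf("background_box: %s", fmt_box(config$background_box)),
    sprintf("tip: %s", fmt_tip(config$tip)),
    sprintf("max_harmonic: %d", config$max_harmonic),
    sprintf("helix_pitch_nm: %.10g", config$helix$pitch_nm),
    sprintf("helix_subunits_per_three_turns: %d",
            config$helix$subunits_per_three_turns),
    sprintf("helix_outer_radius_nm: %.10g", config$helix$outer_radius_nm),
    sprintf("helix_length_nm: %.10g", config$helix$length_nm),
    if (!is.null(config$input_topography))
      sprintf("input_topography: %s", config$input_topography),
    if (!is.null(config$input_mode2))
      sprintf("input_mode2: %s", config$input_mode2)
  )
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  txt <- readLines(path)
  txt <- txt[!grepl("^\\s*#", txt) & nzchar(trimws(txt))]
  keys <- trimws(sub(":.*$", "", txt))
  vals <- trimws(sub("^[^:]*:\\s*", "", txt))
  kv <- stats::setNames(vals, keys)
  parse_box <- function(s) {
    s <- unname(s)
    if (is.na(s) || identical(s, "auto")) return(NULL)
    m <- regmatches(s, regexec(
      "rows (\\d+):(\\d+) cols (\\d+):(\\d+) (rows|columns)", s))[[1]]
    if (length(m) != 6L) stop(sprintf("cannot parse box spec '%s'", s))
    box_selection(as.integer(m[2:3]), as.integer(m[4:5]), m[6])
  }
  tip <- NULL
  if (!is.na(kv["tip"]) && !kv["tip"] %in% c("preset-default")) {
    if (kv["tip"] == "none") {
      tip <- "none"
    } else {
      parts <- strsplit(kv[["tip"]], "\\s+")[[1]]
      px <- if (!is.na(kv["pixel_size_nm"])) as.numeric(kv[["pixel_size_nm"]]) else 0.5
      tip <- build_tip(parts[1], as.numeric(parts[2]), px)
    }
  }
  helix <- helix_parameters(
    pitch_nm = as.numeric(kv[["helix_pitch_nm"]]),
    subunits_per_three_turns = as.integer(kv[["helix_subunits_per_three_turns"]]),
    outer_radius_nm = as.numeric(kv[["helix_outer_radius_nm"]]),
    length_nm = as.numeric(kv[["helix_length_nm"]])
  )
  run_config(
    preset = kv[["preset"]],
    seed = as.integer(kv[["seed"]]),
    channel = kv[["channel"]],
    input_topography = if (!is.na(kv["input_topography"])) kv[["input_topography"]],
    input_mode2 = if (!is.na(kv["input_mode2"])) kv[["input_mode2"]],
    signal_box = parse_box(kv["signal_box"]),
    background_box = parse_box(kv["background_box"]),
    snr_threshold = as.numeric(kv[["snr_threshold"]]),
    window = kv[["window"]],
    tip = tip,
    helix = helix,
    max_harmonic = as.integer(kv[["max_harmonic"]])
  )
}
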