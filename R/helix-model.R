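#' Helical lattice parameters of a rod-shaped virion
#'
#' Container for the geometry of the coat-protein helix of a rigid rod virus.
#' The defaults describe tobacco mosaic virus: 49 subunits form exactly three
#' helix turns, the axial rise per turn (the pitch) is 2.3 nm, and the
#' particle is an 18 nm diameter cylinder with a 4 nm inner channel. The
#' shortest truly axial lattice translation is therefore three turns,
#' `3 * pitch_nm` = 6.9 nm.
#'
#' @param pitch_nm Axial rise per helix turn (nm). Must be positive.
#' @param subunits_per_three_turns Integer number of subunits completing three
#'   turns; the non-integer number of subunits per turn is this value / 3.
#' @param outer_radius_nm Outer cylinder radius (nm).
#' @param channel_radius_nm Inner channel radius (nm); informational only.
#' @param length_nm Particle length (nm).
#' @param handedness `+1` or `-1`; sense of azimuth advance per subunit. No
#'   reported quantity depends on it (angles are compared by magnitude and a
#'   fixed sign convention), so the default `+1` is arbitrary but documented.
#' @return An object of class `helix_parameters`.
#' @export
#' @examples
#' p <- helix_parameters()
#' subunits_per_turn(p) # 16.33...
helix_parameters <- function(pitch_nm = 2.3, subunits_per_three_turns = 49L,
                             outer_radius_nm = 9, channel_radius_nm = 2,
                             length_nm = 300, handedness = 1L) {
  stopifnot(
    is.numeric(pitch_nm), length(pitch_nm) == 1L, pitch_nm > 0,
    length(subunits_per_three_turns) == 1L,
    subunits_per_three_turns == round(subunits_per_three_turns),
    subunits_per_three_turns >= 3,
    outer_radius_nm > channel_radius_nm, channel_radius_nm >= 0,
    length_nm > 0, handedness %in% c(-1, 1)
  )
  structure(list(
    pitch_nm = pitch_nm,
    subunits_per_three_turns = as.integer(subunits_per_three_turns),
    outer_radius_nm = outer_radius_nm,
    channel_radius_nm = channel_radius_nm,
    length_nm = length_nm,
    handedness = as.integer(handedness)
  ), class = "helix_parameters")
}

#' @rdname helix_parameters
#' @param params A `helix_parameters` object.
#' @export
subunits_per_turn <- function(params) {
  stopifnot(inherits(params, "helix_parameters"))
  params$subunits_per_three_turns / 3
}

#' @export
print.helix_parameters <- function(x, ...) {
  cat(sprintf(
    "<helix_parameters> pitch %.3g nm, %d subunits / 3 turns (%.4g per turn),\n  outer radius %.3g nm, length %.4g nm, handedness %+d\n",
    x$pitch_nm, x$subunits_per_three_turns, subunits_per_turn(x),
    x$outer_radius_nm, x$length_nm, x$handedness
  ))
  invisible(x)
}

#' Subunit positions on the helical lattice
#'
#' Places coat-protein centers on the outer cylinder. Subunit `j` (counting
#' from 0) sits at axial position `j * pitch / s` and azimuth
#' `j * (360 / s) * handedness` degrees (mod 360), where `s` is the number of
#' subunits per turn. Cartesian coordinates put the cylinder axis along `z`.
#'
#' @param params A [helix_parameters()] object.
#' @param n_subunits Number of subunits to generate (indices `0:(n_subunits-1)`).
#' @return A data frame with columns `index`, `axial_nm`, `azimuth_deg`,
#'   `x_nm`, `y_nm`, `z_nm`.
#' @export
subunit_lattice <- function(params, n_subunits) {
  stopifnot(inherits(params, "helix_parameters"))
  if (!is.numeric(n_subunits) || length(n_subunits) != 1L || n_subunits < 1 ||
      n_subunits != round(n_subunits)) {
    stop("`n_subunits` must be a positive integer")
  }
  s <- subunits_per_turn(params)
  j <- seq_len(n_subunits) - 1L
  axial <- j * params$pitch_nm / s
  az <- (j * (360 / s) * params$handedness) %% 360
  R <- params$outer_radius_nm
  data.frame(
    index = j,
    axial_nm = axial,
    azimuth_deg = az,
    x_nm = R * cos(az * pi / 180),
    y_nm = R * sin(az * pi / 180),
    z_nm = axial
  )
}

#' Near-axial repeat vector after n helix turns
#'
#' After `n_turns` turns, the lattice point closest in azimuth to the starting
#' subunit is subunit `round(n_turns * s)`. The vector joining the two protein
#' centers is exactly axial only when `n_turns * s` is an integer (every three
#' turns for the 49/3 lattice); otherwise it is tilted off the particle axis
#' by `atan(arc offset / axial distance)`, with the arc offset measured on the
#' outer cylinder. The sign convention is positive when the partner subunit
#' lags in azimuth, which makes the one-turn vector positive.
#'
#' @param params A [helix_parameters()] object.
#' @param n_turns Number of helix turns (integer >= 1).
#' @return An object of class `repeat_vector`: a list with `n_turns`,
#'   `partner_index`, `axial_distance_nm`, `arc_offset_nm`,
#'   `offaxis_angle_deg` (signed, unrounded) and `offaxis_angle_rounded_deg`.
#' @export
#' @examples
#' repeat_vector(helix_parameters(), 1)$offaxis_angle_rounded_deg # 27
#' repeat_vector(helix_parameters(), 3)$offaxis_angle_deg         # exactly 0
repeat_vector <- function(params, n_turns) {
  stopifnot(inherits(params, "helix_parameters"))
  if (!is.numeric(n_turns) || length(n_turns) != 1L || n_turns < 1 ||
      n_turns != round(n_turns)) {
    stop("`n_turns` must be an integer >= 1")
  }
  s <- subunits_per_turn(params)
  partner <- round(n_turns * s)
  axial <- partner * params$pitch_nm / s
  # azimuthal mismatch of the partner subunit relative to n full turns
  dphi_deg <- (partner - n_turns * s) * (360 / s)
  arc <- params$outer_radius_nm * dphi_deg * pi / 180
  angle <- atan2(abs(arc), axial) * 180 / pi
  # positive when the partner lags in azimuth (mismatch negative)
  sgn <- if (dphi_deg == 0) 1 else -sign(dphi_deg)
  angle <- sgn * angle
  structure(list(
    n_turns = as.integer(n_turns),
    partner_index = as.integer(partner),
    axial_distance_nm = axial,
    arc_offset_nm = arc,
    offaxis_angle_deg = angle,
    offaxis_angle_rounded_deg = round(angle)
  ), class = "repeat_vector")
}

#' @export
print.repeat_vector <- function(x, ...) {
  cat(sprintf(
    "<repeat_vector> n = %d turns -> subunit %d: axial %.3f nm, off-axis %+.2f deg (%+d)\n",
    x$n_turns, x$partner_index, x$axial_distance_nm,
    x$offaxis_angle_deg, x$offaxis_angle_rounded_deg
  ))
  invisible(x)
}

#' Table of repeat vectors for n = 1..max_turns
#'
#' @inheritParams repeat_vector
#' @param max_turns Largest number of turns tabulated.
#' @return A data frame with one row per `n_turns`.
#' @export
repeat_vectors <- function(params, max_turns = 6L) {
  stopifnot(max_turns >= 1)
  rows <- lapply(seq_len(max_turns), function(n) {
    rv <- repeat_vector(params, n)
    data.frame(
      n_turns = rv$n_turns,
      partner_index = rv$partner_index,
      axial_distance_nm = rv$axial_distance_nm,
      arc_offset_nm = rv$arc_offset_nm,
      offaxis_angle_deg = rv$offaxis_angle_deg,
      offaxis_angle_rounded_deg = rv$offaxis_angle_rounded_deg
    )
  })
  do.call(rbind, rows)
}

#' Convert between real-space distance and wavenumber
#'
#' Uses the angular-wavenumber convention `k = 2 * pi / l` throughout, so a
#' 6.9 nm repeat appears at 0.91 nm^-1. The two functions are mutual inverses.
#'
#' @param distance_nm,wavenumber_inv_nm Positive numeric vectors.
#' @return Numeric vector of wavenumbers (nm^-1) or distances (nm).
#' @export
wavenumber_of <- function(distance_nm) {
  if (!is.numeric(distance_nm) || any(!is.finite(distance_nm)) ||
      any(distance_nm <= 0)) {
    stop("`distance_nm` must be positive and finite")
  }
  2 * pi / distance_nm
}

#' @rdname wavenumber_of
#' @export
distance_of <- function(wavenumber_inv_nm) {
  if (!is.numeric(wavenumber_inv_nm) || any(!is.finite(wavenumber_inv_nm)) ||
      any(wavenumber_inv_nm <= 0)) {
    stop("`wavenumber_inv_nm` must be positive and finite")
  }
  2 * pi / wavenumber_inv_nm
}

#' Predicted spectral peaks of the helical lattice
#'
#' Predicts where an axis-aligned line spectrum of the particle surface should
#' show peaks: one entry per repeat vector (n turns), down-weighted by how far
#' the vector tilts off the axis, plus the harmonics of the three-turn
#' building-block fundamental. Off-axis attenuation is modelled as a Gaussian
#' in the off-axis angle, `exp(-(theta / attenuation_deg)^2)`; the width is a
#' free parameter because only the ordering (near-axial vectors strong,
#' strongly tilted ones suppressed) is physically constrained.
#'
#' @inheritParams repeat_vector
#' @param max_turns Repeat vectors for `n = 1..max_turns` are predicted.
#' @param attenuation_deg Positive width (degrees) of the visibility Gaussian.
#' @param max_harmonic Harmonics `m = 1..max_harmonic` of the three-turn
#'   fundamental are appended (visibility 1: they are exactly axial).
#' @return A data frame sorted by wavenumber with columns `source`, `n_turns`,
#'   `harmonic`, `distance_nm`, `wavenumber_inv_nm`, `offaxis_angle_deg`,
#'   `visibility_weight`.
#' @export
predicted_peaks <- function(params, max_turns = 6L, attenuation_deg = 10,
                            max_harmonic = 3L) {
  stopifnot(inherits(params, "helix_parameters"),
            max_turns >= 1, attenuation_deg > 0, max_harmonic >= 0)
  rv <- repeat_vectors(params, max_turns)
  turns <- data.frame(
    source = sprintf("n=%d turns", rv$n_turns),
    n_turns = rv$n_turns,
    harmonic = NA_integer_,
    distance_nm = rv$axial_distance_nm,
    wavenumber_inv_nm = wavenumber_of(rv$axial_distance_nm),
    offaxis_angle_deg = rv$offaxis_angle_deg,
    visibility_weight = exp(-(rv$offaxis_angle_deg / attenuation_deg)^2)
  )
  out <- turns
  if (max_harmonic >= 1) {
    l3 <- 3 * params$pitch_nm
    m <- seq_len(max_harmonic)
    harm <- data.frame(
      source = sprintf("harmonic m=%d", m),
      n_turns = NA_integer_,
      harmonic = m,
      distance_nm = l3 / m,
      wavenumber_inv_nm = m * wavenumber_of(l3),
      offaxis_angle_deg = 0,
      visibility_weight = 1
    )
    out <- rbind(out, harm)
  }
  out[order(out$wavenumber_inv_nm), , drop = FALSE]
}
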