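#' QRS duration
#'
#' @param window A `qrs_window`.
#' @return Duration in ms (`end_time - start_time`).
#' @export
qrs_duration <- function(window) {
  stopifnot(inherits(window, "qrs_window"))
  window$end_time - window$start_time
}

#' QRS area of the VCG loop
#'
#' Per component, the signed trapezoidal integral of the component (minus a
#' 0 mV baseline, the simulated signal being isoelectric outside the QRS)
#' over the QRS window; the combined area is the Euclidean norm of the three
#' signed component areas, so that
#' `qrs_area^2 = area_x^2 + area_y^2 + area_z^2`.
#'
#' @param vcg A `vcg_trace`.
#' @param window A `qrs_window`.
#' @param baseline Baseline level subtracted per component, mV. Either a
#'   single value (default 0) or `"onset"` to use the component values at
#'   the QRS onset sample.
#' @return Named vector `area_x`, `area_y`, `area_z`, `qrs_area` in mV.ms.
#' @export
qrs_area <- function(vcg, window, baseline = 0) {
  idx <- window$start_index:window$end_index
  t <- vcg$t[idx]
  xyz <- vcg$xyz[idx, , drop = FALSE]
  b <- if (identical(baseline, "onset")) vcg$xyz[window$start_index, ] else
    rep(baseline, 3)
  areas <- vapply(1:3, function(j) trapz(t, xyz[, j] - b[j]), numeric(1))
  c(area_x = areas[1], area_y = areas[2], area_z = areas[3],
    qrs_area = sqrt(sum(areas^2)))
}

trapz <- function(t, y) {
  n <- length(t)
  sum((y[-1] + y[-n]) * diff(t)) / 2
}

#' Magnitude-weighted average azimuth and elevation of the QRS dipole
#'
#' Per sample, the azimuth is `atan2(y, x)` on the transverse (xy) plane and
#' the elevation is the angle between the full 3-vector and the +y axis.
#' Weights are the dipole magnitudes. The azimuth is averaged circularly
#' (direction of the weighted resultant on the unit circle); the elevation,
#' which lives on \[0, 180\] degrees, is averaged arithmetically with the
#' same weights.
#'
#' @param vcg A `vcg_trace`.
#' @param window A `qrs_window`.
#' @return Named vector `waa`, `wae` in degrees.
#' @export
weighted_angles <- function(vcg, window) {
  xyz <- vcg$xyz[window$start_index:window$end_index, , drop = FALSE]
  mag <- sqrt(rowSums(xyz^2))
  if (all(mag == 0)) stop("undefined angle: all-zero dipole in QRS window",
                          call. = FALSE)
  az <- atan2(xyz[, "y"], xyz[, "x"])
  waa <- atan2(sum(mag * sin(az)), sum(mag * cos(az))) * 180 / pi
  el <- acos(pmin(1, pmax(-1, xyz[, "y"] / pmax(mag, .Machine$double.xmin)))) *
    180 / pi
  wae <- sum(mag * el) / sum(mag)
  c(waa = waa, wae = wae)
}

#' Dipole magnitude summaries and landmark dipoles over the QRS
#'
#' Computes the mean and maximum dipole magnitude over the window, the time
#' of the maximum (first occurrence wins ties), the dipole vectors at the
#' QRS start, mid-point (`floor((start_index + end_index)/2)`) and end, the
#' maximum-magnitude dipole vector, and the mean weighted dipole: the
#' normalised vector sum over the window of either the raw per-sample
#' dipoles (`weighting = "magnitude"`, default: large dipoles dominate) or
#' the per-sample unit vectors (`weighting = "unit"`).
#'
#' @param vcg A `vcg_trace`.
#' @param window A `qrs_window`.
#' @param weighting `"magnitude"` or `"unit"`.
#' @return List with `vcg_mean_mag`, `vcg_max_mag`, `t_vcg_max`,
#'   `max_dipole`, `mean_weighted_dipole`, `dipole_at_start`,
#'   `dipole_at_mid`, `dipole_at_end`.
#' @export
dipole_extrema <- function(vcg, window, weighting = c("magnitude", "unit")) {
  weighting <- match.arg(weighting)
  idx <- window$start_index:window$end_index
  xyz <- vcg$xyz[idx, , drop = FALSE]
  mag <- sqrt(rowSums(xyz^2))
  imax <- which.max(mag)
  mid <- floor((window$start_index + window$end_index) / 2)
  wsum <- if (weighting == "magnitude") colSums(xyz) else
    colSums(xyz / pmax(mag, .Machine$double.xmin))
  nw <- sqrt(sum(wsum^2))
  list(
    vcg_mean_mag = mean(mag),
    vcg_max_mag = mag[imax],
    t_vcg_max = vcg$t[idx[imax]],
    max_dipole = xyz[imax, ],
    mean_weighted_dipole = if (nw > 0) wsum / nw else wsum,
    dipole_at_start = vcg$xyz[window$start_index, ],
    dipole_at_mid = vcg$xyz[mid, ],
    dipole_at_end = vcg$xyz[window$end_index, ])
}

#' Angle between two dipole vectors
#'
#' @param a,b Nonzero 3-vectors.
#' @return Angle in degrees, in \[0, 180\]: the arccos of the clipped
#'   normalised dot product, evaluated as `atan2(|a x b|, a . b)` so that
#'   identical (0 deg) and antiparallel (180 deg) inputs are exact.
#' @export
angular_difference <- function(a, b) {
  a <- as.numeric(a); b <- as.numeric(b)
  if (all(a == 0) || all(b == 0)) {
    stop("undefined angle: zero vector", call. = FALSE)
  }
  cr <- c(a[2] * b[3] - a[3] * b[2],
          a[3] * b[1] - a[1] * b[3],
          a[1] * b[2] - a[2] * b[1])
  atan2(sqrt(sum(cr^2)), sum(a * b)) * 180 / pi
}

#' Compute the full single-rate VCG metric set
#'
#' Delimits the QRS (unless a window is supplied) and evaluates QRS
#' duration, component and combined QRS areas, weighted average azimuth and
#' elevation, dipole magnitude summaries, and the landmark dipole vectors.
#'
#' @param vcg A `vcg_trace`.
#' @param window Optional precomputed `qrs_window`.
#' @param threshold_fraction,filter Passed to [detect_qrs()].
#' @param baseline Passed to [qrs_area()].
#' @param weighting Passed to [dipole_extrema()].
#' @return A `vcg_metrics` list with fields `qrsd`, `qrs_area_x/y/z`,
#'   `qrs_area`, `waa`, `wae`, `vcg_mean_mag`, `vcg_max_mag`, `t_vcg_max`,
#'   the landmark vectors, and the `window`.
#' @export
vcg_metrics <- function(vcg, window = NULL, threshold_fraction = 0.15,
                        filter = filter_config(), baseline = 0,
                        weighting = "magnitude") {
  if (is.null(window)) {
    window <- detect_qrs(vcg, threshold_fraction, filter)
  }
  area <- qrs_area(vcg, window, baseline)
  ang <- weighted_angles(vcg, window)
  ext <- dipole_extrema(vcg, window, weighting)
  structure(
    c(list(qrsd = qrs_duration(window),
           qrs_area_x = unname(area["area_x"]),
           qrs_area_y = unname(area["area_y"]),
           qrs_area_z = unname(area["area_z"]),
           qrs_area = unname(area["qrs_area"]),
           waa = unname(ang["waa"]), wae = unname(ang["wae"])),
      ext, list(window = window)),
    class = "vcg_metrics")
}

#' @export
print.vcg_metrics <- function(x, ...) {
  cat(sprintf(
    "<vcg_metrics> QRSd %.1f ms | QRSarea %.1f mV.ms | WAA %.1f deg WAE %.1f deg | |VCG| mean %.3f max %.3f mV @ %.1f ms\n",
    x$qrsd, x$qrs_area, x$waa, x$wae, x$vcg_mean_mag, x$vcg_max_mag,
    x$t_vcg_max))
  invisible(x)
}
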