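#' Construct a VCG trace
#'
#' @param xyz Numeric matrix, time by 3 (columns x, y, z, mV). Axis
#'   convention: z = long axis of the body, x = anterior-posterior, so the
#'   xy-plane is the transverse plane.
#' @param sampling_rate Sampling rate, Hz.
#' @return A `vcg_trace` with fields `xyz`, `sampling_rate`, `t` (ms).
#' @export
vcg_trace <- function(xyz, sampling_rate) {
  xyz <- as.matrix(xyz)
  stopifnot(ncol(xyz) == 3, sampling_rate > 0)
  colnames(xyz) <- c("x", "y", "z")
  structure(
    list(xyz = xyz, sampling_rate = sampling_rate,
         t = (seq_len(nrow(xyz)) - 1) * 1000 / sampling_rate),
    class = "vcg_trace")
}

#' @export
print.vcg_trace <- function(x, ...) {
  cat(sprintf("<vcg_trace> %d samples @ %g Hz (%.1f ms)\n",
              nrow(x$xyz), x$sampling_rate, max(x$t)))
  invisible(x)
}

#' Reconstruct the VCG from a 12-lead ECG (Kors transform)
#'
#' Applies a 3 x 8 lead transform to the 8 independent leads
#' (I, II, V1-V6): `xyz(t) = matrix %*% leads(t)`.
#'
#' @param ecg An `ecg_recording`.
#' @param transform A `lead_transform`; defaults to the Kors matrix.
#' @return A `vcg_trace` at the recording's sampling rate.
#' @export
kors_transform <- function(ecg, transform = kors_matrix()) {
  stopifnot(inherits(ecg, "ecg_recording"))
  leads <- ecg$samples[, independent_leads(), drop = FALSE]
  vcg_trace(leads %*% t(unclass(transform)), ecg$sampling_rate)
}

#' Filtering configuration for QRS delimitation
#'
#' The VCG components are low-pass filtered before differentiation with a
#' zero-phase (forward-backward) Butterworth filter; default order 2,
#' cut-off 40 Hz — the standard QRS bandwidth. Filtering can be disabled
#' for analytic work.
#'
#' @param enabled Apply the filter?
#' @param cutoff_hz,order Butterworth design parameters.
#' @return A `filter_config` list.
#' @export
filter_config <- function(enabled = TRUE, cutoff_hz = 40, order = 2) {
  stopifnot(cutoff_hz > 0, order >= 1)
  structure(list(enabled = enabled, cutoff_hz = cutoff_hz, order = order),
            class = "filter_config")
}

apply_lowpass <- function(xyz, sampling_rate, config) {
  if (!config$enabled) return(xyz)
  wn <- config$cutoff_hz / (sampling_rate / 2)
  if (wn >= 1) return(xyz)
  bf <- signal::butter(config$order, wn, type = "low")
  apply(xyz, 2, function(col) signal::filtfilt(bf, col))
}

#' Spatial velocity of a VCG trace
#'
#' Each component is (optionally) low-pass filtered, differentiated by
#' central differences (one-sided at the boundaries), and the spatial
#' velocity is the Euclidean norm of the three component velocities:
#' `sv(t) = sqrt(vx^2 + vy^2 + vz^2)`, in mV/ms.
#'
#' @param vcg A `vcg_trace` with at least 3 samples.
#' @param filter A `filter_config`.
#' @return Numeric vector, one nonnegative value per sample.
#' @export
spatial_velocity <- function(vcg, filter = filter_config()) {
  stopifnot(inherits(vcg, "vcg_trace"))
  n <- nrow(vcg$xyz)
  if (n < 3) stop("invalid input: spatial velocity needs >= 3 samples",
                  call. = FALSE)
  xyz <- apply_lowpass(vcg$xyz, vcg$sampling_rate, filter)
  dt <- 1000 / vcg$sampling_rate
  deriv <- function(x) {
    c(x[2] - x[1], (x[3:n] - x[1:(n - 2)]) / 2, x[n] - x[n - 1]) / dt
  }
  v <- apply(xyz, 2, deriv)
  sqrt(rowSums(v^2))
}

#' Delimit the QRS complex by spatial-velocity thresholding
#'
#' The QRS onset is the first sample (scanning forward) at which the
#' spatial velocity of the filtered VCG strictly exceeds
#' `threshold_fraction` of its maximum; the QRS end is found the same way
#' scanning backward from the end of the trace. The window is closed,
#' 1-based, and invariant to uniform scaling of the VCG.
#'
#' @param vcg A `vcg_trace`.
#' @param threshold_fraction Fraction of the maximum spatial velocity
#'   (default 0.15).
#' @param filter A `filter_config` used for the spatial velocity.
#' @return A `qrs_window` with `start_index`, `end_index` (1-based sample
#'   indices), `start_time`, `end_time` (ms) and `threshold_fraction`.
#' @export
detect_qrs <- function(vcg, threshold_fraction = 0.15,
                       filter = filter_config()) {
  stopifnot(threshold_fraction >= 0, threshold_fraction < 1)
  sv <- spatial_velocity(vcg, filter)
  if (max(sv) <= 0) stop("no QRS: spatial velocity is identically zero",
                         call. = FALSE)
  thr <- threshold_fraction * max(sv)
  above <- sv > thr
  start <- which(above)[1]
  end <- which(above)[sum(above)]
  if (is.na(start) || is.na(end) || start >= end) {
    stop("degenerate QRS window", call. = FALSE)
  }
  qrs_window(start, end, vcg$t, threshold_fraction)
}

qrs_window <- function(start_index, end_index, t, threshold_fraction) {
  stopifnot(start_index >= 1, start_index < end_index,
            end_index <= length(t))
  structure(
    list(start_index = as.integer(start_index),
         end_index = as.integer(end_index),
         start_time = t[start_index], end_time = t[end_index],
         threshold_fraction = threshold_fraction),
    class = "qrs_window")
}

#' @export
print.qrs_window <- function(x, ...) {
  cat(sprintf("<qrs_window> [%.1f, %.1f] ms (samples %d..%d, threshold %.2f)\n",
              x$start_time, x$end_time, x$start_index, x$end_index,
              x$threshold_fraction))
  invisible(x)
}

#' Export a VCG trace as delimited text
#'
#' Same dialect as [write_ecg()]: tab-separated, header
#' `time_ms`, `x`, `y`, `z`.
#'
#' @param vcg A `vcg_trace`.
#' @param path File path.
#' @export
write_vcg <- function(vcg, path) {
  df <- data.frame(time_ms = vcg$t, vcg$xyz, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
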