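#' Construct a 12-lead ECG recording
#'
#' Holds a uniformly sampled multi-lead ECG of ventricular depolarisation.
#' Only the 8 independent leads carry information; III, aVR, aVL and aVF obey
#' their exact linear relations to leads I and II:
#' III = II - I, aVR = -(I + II)/2, aVL = I - II/2, aVF = II - I/2.
#'
#' @param samples Numeric matrix, time by lead, in mV. Columns must be the 12
#'   standard leads in the order I, II, III, aVR, aVL, aVF, V1-V6 (column
#'   names, when present, are checked).
#' @param sampling_rate Sampling rate in Hz.
#' @return An `ecg_recording` with fields `samples`, `sampling_rate`,
#'   `lead_names` and `t` (time in ms, starting at 0).
#' @export
ecg_recording <- function(samples, sampling_rate) {
  samples <- as.matrix(samples)
  if (ncol(samples) != 12L) {
    stop("an ECG recording requires 12 lead columns", call. = FALSE)
  }
  if (!is.null(colnames(samples)) && !identical(colnames(samples), all_leads())) {
    stop("lead columns must be ordered ", paste(all_leads(), collapse = ", "),
         call. = FALSE)
  }
  colnames(samples) <- all_leads()
  stopifnot(is.numeric(sampling_rate), sampling_rate > 0)
  structure(
    list(samples = samples,
         sampling_rate = sampling_rate,
         lead_names = all_leads(),
         t = (seq_len(nrow(samples)) - 1) * 1000 / sampling_rate),
    class = "ecg_recording")
}

#' @export
print.ecg_recording <- function(x, ...) {
  cat(sprintf("<ecg_recording> %d samples x 12 leads @ %g Hz (%.1f ms)\n",
              nrow(x$samples), x$sampling_rate, max(x$t)))
  invisible(x)
}

# Derive the 4 dependent limb leads from I and II.
derive_limb_leads <- function(I, II) {
  cbind(III = II - I, aVR = -(I + II) / 2, aVL = I - II / 2, aVF = II - I / 2)
}

check_limb_leads <- function(samples, tol = 1e-6) {
  expected <- derive_limb_leads(samples[, "I"], samples[, "II"])
  dev <- max(abs(samples[, colnames(expected), drop = FALSE] - expected))
  scale <- max(abs(samples), 1e-12)
  if (dev > tol * max(1, scale)) {
    warning(sprintf(
      "limb leads violate their linear relations to I and II (max deviation %.3g mV); data accepted as-is",
      dev), call. = FALSE)
  }
  invisible(dev)
}

#' Read / write an ECG recording as delimited text
#'
#' The on-disk dialect is tab-separated text with a header row: the first
#' column `time_ms`, then the 12 leads in standard order, values in mV.
#' Reading validates that all leads are present, that the time column is
#' uniform, and (with a warning only) that the dependent limb leads obey their
#' linear relations to leads I and II.
#'
#' @param path File path.
#' @param recording An `ecg_recording`.
#' @param digits Significant digits written (default 10).
#' @return `read_ecg` returns an `ecg_recording`; `write_ecg` returns `path`
#'   invisibly.
#' @export
read_ecg <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE)
  if (!"time_ms" %in% names(df)) {
    stop("parse error: missing column time_ms", call. = FALSE)
  }
  missing <- setdiff(all_leads(), names(df))
  if (length(missing)) {
    stop("parse error: missing lead ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  t <- df[["time_ms"]]
  dt <- diff(t)
  if (length(dt) < 1L || any(dt <= 0)) {
    stop("parse error: time column must be strictly increasing", call. = FALSE)
  }
  if (max(abs(dt - dt[1])) > 1e-6 * dt[1]) {
    bad <- which(abs(dt - dt[1]) > 1e-6 * dt[1])[1] + 1L
    stop(sprintf("parse error: non-uniform time column at row %d", bad),
         call. = FALSE)
  }
  samples <- as.matrix(df[, all_leads()])
  check_limb_leads(samples, tol = 1e-4)
  ecg_recording(samples, sampling_rate = 1000 / dt[1])
}

#' @rdname read_ecg
#' @export
write_ecg <- function(recording, path, digits = 10) {
  stopifnot(inherits(recording, "ecg_recording"))
  df <- data.frame(time_ms = recording$t,
                   recording$samples, check.names = FALSE)
  out <- vapply(df, function(col) formatC(col, digits = digits, format = "g"),
                character(nrow(df)))
  out <- rbind(names(df), out)
  writeLines(apply(out, 1, paste, collapse = "\t"), path)
  invisible(path)
}
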