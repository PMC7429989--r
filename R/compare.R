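#' Paired slow/fast rate-dependent metric differences
#'
#' Forms the rate-comparison ("delta") metric set from single-rate metric
#' sets computed at slow and rapid pacing with identical configuration.
#' Sign conventions (recorded in the `conventions` field of the result):
#' \itemize{
#'   \item percentage deltas `100 * (fast - slow) / slow` for the maximum
#'     dipole magnitude (`d_vcg_max`), combined QRS area (`d_qrs_area`) and
#'     mean dipole magnitude (`d_vcg_mean_mag`);
#'   \item `d_qrsd = qrsd_slow - qrsd_fast` in ms (negative when rapid
#'     pacing prolongs the QRS);
#'   \item `d_t_vcg_max = t_slow - t_fast` in ms;
#'   \item `d_waa`, `d_wae`: absolute circular difference of the weighted
#'     average angles, degrees, in \[0, 180\];
#'   \item `dt_vcg_mean`, `dt_vcg_max`, `dt_qrs_start`, `dt_qrs_mid`,
#'     `dt_qrs_end`: angle between the corresponding fast- and slow-pacing
#'     dipole vectors ([angular_difference()]), degrees, in \[0, 180\].
#' }
#'
#' @param slow,fast `vcg_metrics` at slow and rapid pacing.
#' @return A `rate_comparison` list of the 12 delta metrics plus
#'   `conventions`.
#' @export
compare_rates <- function(slow, fast) {
  stopifnot(inherits(slow, "vcg_metrics"), inherits(fast, "vcg_metrics"))
  pct <- function(field) {
    s <- slow[[field]]
    if (s == 0) stop("undefined percentage: slow-pacing ", field, " is zero",
                     call. = FALSE)
    100 * (fast[[field]] - s) / s
  }
  circ_abs <- function(a, b) {
    d <- abs(a - b) %% 360
    min(d, 360 - d)
  }
  structure(
    list(
      d_vcg_max = pct("vcg_max_mag"),
      d_qrsd = slow$qrsd - fast$qrsd,
      d_qrs_area = pct("qrs_area"),
      d_vcg_mean_mag = pct("vcg_mean_mag"),
      d_waa = circ_abs(slow$waa, fast$waa),
      d_wae = abs(slow$wae - fast$wae),
      d_t_vcg_max = slow$t_vcg_max - fast$t_vcg_max,
      dt_vcg_mean = angular_difference(slow$mean_weighted_dipole,
                                       fast$mean_weighted_dipole),
      dt_vcg_max = angular_difference(slow$max_dipole, fast$max_dipole),
      dt_qrs_start = angular_difference(slow$dipole_at_start,
                                        fast$dipole_at_start),
      dt_qrs_mid = angular_difference(slow$dipole_at_mid,
                                      fast$dipole_at_mid),
      dt_qrs_end = angular_difference(slow$dipole_at_end,
                                      fast$dipole_at_end),
      conventions = list(
        percent = "100 * (fast - slow) / slow",
        d_qrsd = "slow - fast (ms)",
        d_t_vcg_max = "slow - fast (ms)",
        angles = "absolute difference in [0, 180] degrees")),
    class = "rate_comparison")
}

#' Names of the delta-metric feature columns
#' @return Character vector of the 12 rate-comparison metric names.
#' @export
rate_metric_names <- function() {
  c("d_vcg_max", "d_qrsd", "d_qrs_area", "d_vcg_mean_mag", "d_waa", "d_wae",
    "d_t_vcg_max", "dt_vcg_mean", "dt_vcg_max", "dt_qrs_start", "dt_qrs_mid",
    "dt_qrs_end")
}

#' @export
print.rate_comparison <- function(x, ...) {
  cat("<rate_comparison>\n")
  for (nm in rate_metric_names()) cat(sprintf("  %-14s %8.3f\n", nm, x[[nm]]))
  invisible(x)
}

#' Simulate scenario pairs and assemble the cohort feature table
#'
#' Runs every pair (slow and fast member), computes single-rate metrics and
#' their rate-dependent differences, and stacks them into the feature table
#' used for ROC analysis and random-forest classification: one row per
#' scenario pair, one column per delta metric, plus `id` and the `location`
#' label.
#'
#' @param pairs A `vcg_cohort`, or a named list of `scenario_pair`s.
#' @param threshold_fraction,filter,baseline,weighting Metric configuration,
#'   shared by both members of every pair (see [vcg_metrics()]).
#' @param model Optional prebuilt `patch_model` shared across pairs (built
#'   once from the first pair's settings when omitted).
#' @return A `feature_table` data frame.
#' @export
cohort_features <- function(pairs, threshold_fraction = 0.15,
                            filter = filter_config(), baseline = 0,
                            weighting = "magnitude", model = NULL) {
  if (inherits(pairs, "vcg_cohort")) pairs <- pairs$pairs
  stopifnot(length(pairs) >= 1)
  if (is.null(model)) {
    model <- build_patch_model(pairs[[1]]$slow$n_patches,
                               seed = pairs[[1]]$slow$seed)
  }
  rows <- lapply(pairs, function(pair) {
    ecgs <- simulate_pair(pair, model = model)
    met <- lapply(ecgs, function(e) {
      vcg_metrics(kors_transform(e), threshold_fraction = threshold_fraction,
                  filter = filter, baseline = baseline, weighting = weighting)
    })
    cmp <- compare_rates(met$slow, met$fast)
    cbind(data.frame(id = pair$id, location = pair$label,
                     stringsAsFactors = FALSE),
          as.data.frame(cmp[rate_metric_names()]))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("feature_table", "data.frame")
  out
}

#' Validate a feature table
#'
#' @param table A data frame with `location` and the delta-metric columns.
#' @param require_two_classes Require >= 2 distinct labels?
#' @return The validated table (invisibly re-classed to `feature_table`).
#' @export
validate_feature_table <- function(table, require_two_classes = TRUE) {
  need <- c("location", rate_metric_names())
  missing <- setdiff(need, names(table))
  if (length(missing)) {
    stop("invalid feature table: missing columns ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  vals <- table[, rate_metric_names()]
  if (any(!is.finite(as.matrix(vals)))) {
    stop("invalid feature table: missing or non-finite metric values",
         call. = FALSE)
  }
  if (require_two_classes && length(unique(table$location)) < 2) {
    stop("invalid feature table: need >= 2 distinct location labels",
         call. = FALSE)
  }
  if (!inherits(table, "feature_table")) {
    class(table) <- c("feature_table", class(table))
  }
  invisible(table)
}
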