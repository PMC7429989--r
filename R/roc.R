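#' ROC curve and AUC for a single metric
#'
#' Sweeps a decision threshold over the observed metric values (plus
#' infinite endpoints), labelling each observation positive when its value
#' strictly exceeds the threshold, and accumulates true- and false-positive
#' rates. The AUC is obtained by trapezoidal integration over the
#' (FPR, TPR) points and equals the Mann-Whitney pairwise concordance
#' probability (ties counted 1/2). The curve orientation is fixed — higher
#' value = predicted positive — so an uninformative-or-inverted metric may
#' legitimately score below 0.5.
#'
#' @param values Numeric metric values, one per observation.
#' @param labels Logical (or 0/1) vector; `TRUE` = positive class
#'   (conventionally: scar in the LV free wall).
#' @return A `roc_result` with `thresholds` (decreasing), `tpr`, `fpr`
#'   (nondecreasing along the sweep) and `auc`.
#' @export
roc_curve <- function(values, labels) {
  labels <- as.logical(labels)
  stopifnot(length(values) == length(labels), !anyNA(values), !anyNA(labels))
  if (!any(labels) || all(labels)) {
    stop("invalid input: ROC needs at least one positive and one negative",
         call. = FALSE)
  }
  thresholds <- c(Inf, sort(unique(values), decreasing = TRUE), -Inf)
  npos <- sum(labels)
  nneg <- sum(!labels)
  tpr <- vapply(thresholds, function(th) sum(values > th & labels) / npos,
                numeric(1))
  fpr <- vapply(thresholds, function(th) sum(values > th & !labels) / nneg,
                numeric(1))
  auc <- sum(diff(fpr) * (tpr[-1] + tpr[-length(tpr)]) / 2)
  structure(list(thresholds = thresholds, tpr = tpr, fpr = fpr, auc = auc),
            class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("<roc_result> AUC %.3f over %d thresholds\n",
              x$auc, length(x$thresholds)))
  invisible(x)
}

#' Per-metric ROC sweep over a feature table
#'
#' Computes [roc_curve()] for every delta metric, discriminating LV
#' free-wall from septal scar (positive class = LV; control rows are
#' dropped).
#'
#' @param table A feature table (see [cohort_features()]).
#' @return Data frame with columns `metric`, `auc`, ordered as
#'   [rate_metric_names()].
#' @export
roc_table <- function(table) {
  table <- validate_feature_table(table)
  scar <- table[table$location != "none", , drop = FALSE]
  labels <- scar$location == "lv_free_wall"
  data.frame(
    metric = rate_metric_names(),
    auc = vapply(rate_metric_names(),
                 function(m) roc_curve(scar[[m]], labels)$auc, numeric(1)),
    row.names = NULL)
}
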