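#' Default pipeline configuration
#'
#' A flat, documented key-value configuration covering every stage:
#' \describe{
#'   \item{seed}{Global integer seed.}
#'   \item{out_dir}{Output directory.}
#'   \item{cohort}{Generator settings, see [default_cohort_config()].}
#'   \item{qrs}{`threshold_fraction`, `filter_enabled`, `filter_cutoff_hz`,
#'     `filter_order`.}
#'   \item{metrics}{`baseline` (mV, or `"onset"`), `weighting`
#'     (`"magnitude"` or `"unit"`).}
#'   \item{classifier}{`n_trees`, `cv_scheme`, `seed`, `include_control`.}
#' }
#'
#' @param seed Global seed.
#' @param out_dir Output directory.
#' @return Nested configuration list.
#' @export
default_pipeline_config <- function(seed = 1, out_dir = "vcgscar-run") {
  list(seed = seed, out_dir = out_dir,
       cohort = default_cohort_config(),
       qrs = list(threshold_fraction = 0.15, filter_enabled = TRUE,
                  filter_cutoff_hz = 40, filter_order = 2),
       metrics = list(baseline = 0, weighting = "magnitude"),
       classifier = list(n_trees = 1000, cv_scheme = "n_fold", seed = 42,
                         include_control = FALSE))
}

#' Read / validate a pipeline configuration
#'
#' Configurations are stored as YAML; unknown keys are rejected and missing
#' keys filled from [default_pipeline_config()]. Validation runs before any
#' stage executes.
#'
#' @param path YAML file path.
#' @param config Configuration list to validate.
#' @return The validated configuration.
#' @export
read_pipeline_config <- function(path) {
  validate_pipeline_config(yaml::read_yaml(path))
}

#' @rdname read_pipeline_config
#' @export
validate_pipeline_config <- function(config) {
  def <- default_pipeline_config()
  unknown <- setdiff(names(config), names(def))
  if (length(unknown)) {
    stop("invalid configuration: unknown keys ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  config <- merge_config(def, config)
  qrs <- config$qrs
  if (qrs$threshold_fraction < 0 || qrs$threshold_fraction >= 1) {
    stop("invalid configuration: qrs.threshold_fraction must be in [0, 1)",
         call. = FALSE)
  }
  if (!config$metrics$weighting %in% c("magnitude", "unit")) {
    stop("invalid configuration: metrics.weighting must be 'magnitude' or 'unit'",
         call. = FALSE)
  }
  if (!config$classifier$cv_scheme %in% c("five_fold", "n_fold")) {
    stop("invalid configuration: classifier.cv_scheme must be 'five_fold' or 'n_fold'",
         call. = FALSE)
  }
  nsweep <- length(cohort_scars(config$cohort))
  if (nsweep == 0) {
    stop("invalid configuration: empty cohort sweep", call. = FALSE)
  }
  config
}

#' Run the full analysis pipeline
#'
#' Executes cohort generation, ECG simulation, VCG metric extraction,
#' rate comparison, per-metric ROC analysis and random-forest
#' classification, persisting every intermediate artifact under
#' `config$out_dir`:
#' cohort manifest (`cohort_manifest.tsv`), per-scenario ECGs
#' (`ecg/<id>_<bcl>.tsv`), per-scenario single-rate metrics
#' (`metrics/<id>_<bcl>.json`), the feature table (`feature_table.tsv`),
#' the ROC table (`roc_table.json`), forest reports (`forest_lv.json`,
#' `forest_septum.json`, `importance_report.json`) and a run manifest
#' (`manifest.json`: configuration hash, seeds, per-stage row counts).
#' Rerunning with the same configuration reproduces every numeric output.
#'
#' @param config A (validated) pipeline configuration.
#' @param write_ecgs Persist per-scenario ECG traces (the largest artifact)?
#' @param quiet Suppress per-stage progress messages?
#' @return The run manifest, invisibly; its `feature_table` element holds
#'   the in-memory feature table.
#' @export
run_pipeline <- function(config = default_pipeline_config(),
                         write_ecgs = TRUE, quiet = FALSE) {
  config <- validate_pipeline_config(config)
  out <- config$out_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  dir.create(file.path(out, "ecg"), showWarnings = FALSE)
  dir.create(file.path(out, "metrics"), showWarnings = FALSE)
  say <- function(...) if (!quiet) message(sprintf(...))

  filt <- filter_config(config$qrs$filter_enabled, config$qrs$filter_cutoff_hz,
                        config$qrs$filter_order)

  say("stage cohort: expanding sweep (seed %d)", config$seed)
  cohort <- make_cohort(config$cohort, seed = config$seed)
  utils::write.table(cohort$manifest, file.path(out, "cohort_manifest.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)

  say("stage simulate+metrics: %d scenario pairs", length(cohort$pairs))
  model <- build_patch_model(config$cohort$n_patches,
                             seed = cohort$pairs[[1]]$slow$seed)
  rows <- vector("list", length(cohort$pairs))
  for (i in seq_along(cohort$pairs)) {
    pair <- cohort$pairs[[i]]
    ecgs <- tryCatch(simulate_pair(pair, model = model), error = function(e) {
      stop(sprintf("stage simulate failed for scenario '%s': %s",
                   pair$id, conditionMessage(e)), call. = FALSE)
    })
    met <- lapply(names(ecgs), function(rate) {
      e <- ecgs[[rate]]
      bcl <- pair[[rate]]$bcl
      if (write_ecgs) {
        write_ecg(e, file.path(out, "ecg", sprintf("%s_bcl%d.tsv", pair$id, bcl)))
      }
      m <- tryCatch(
        vcg_metrics(kors_transform(e),
                    threshold_fraction = config$qrs$threshold_fraction,
                    filter = filt, baseline = config$metrics$baseline,
                    weighting = config$metrics$weighting),
        error = function(err) {
          stop(sprintf("stage metrics failed for scenario '%s' (BCL %d): %s",
                       pair$id, bcl, conditionMessage(err)), call. = FALSE)
        })
      jsonlite::write_json(
        metrics_as_list(m),
        file.path(out, "metrics", sprintf("%s_bcl%d.json", pair$id, bcl)),
        auto_unbox = TRUE, digits = NA)
      m
    })
    cmp <- compare_rates(met[[1]], met[[2]])
    rows[[i]] <- cbind(data.frame(id = pair$id, location = pair$label,
                                  stringsAsFactors = FALSE),
                       as.data.frame(cmp[rate_metric_names()]))
  }
  features <- do.call(rbind, rows)
  rownames(features) <- NULL
  class(features) <- c("feature_table", "data.frame")
  utils::write.table(features, file.path(out, "feature_table.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)

  say("stage roc: per-metric AUC sweep")
  roc <- roc_table(features)
  jsonlite::write_json(roc, file.path(out, "roc_table.json"), digits = NA)

  say("stage forest: %d trees, %s CV", config$classifier$n_trees,
      config$classifier$cv_scheme)
  forests <- lapply(c(lv = "lv", septum = "septum"), function(tgt) {
    res <- forest_classify(features, target = tgt,
                           n_trees = config$classifier$n_trees,
                           cv_scheme = config$classifier$cv_scheme,
                           seed = config$classifier$seed,
                           include_control = config$classifier$include_control)
    jsonlite::write_json(forest_as_list(res),
                         file.path(out, sprintf("forest_%s.json", tgt)),
                         auto_unbox = TRUE, digits = NA)
    res
  })
  rep <- importance_report(forests$lv, forests$septum)
  jsonlite::write_json(list(table = rep$table,
                            rank_correlation = rep$rank_correlation),
                       file.path(out, "importance_report.json"),
                       auto_unbox = TRUE, digits = NA)

  manifest <- list(
    config_hash = config_hash(config),
    seed = config$seed,
    classifier_seed = config$classifier$seed,
    n_pairs = length(cohort$pairs),
    n_feature_rows = nrow(features),
    n_metric_columns = length(rate_metric_names()),
    forest_accuracy = list(lv = forests$lv$accuracy_mean,
                           septum = forests$septum$accuracy_mean))
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  manifest$feature_table <- features
  manifest$roc_table <- roc
  manifest$forests <- forests
  invisible(manifest)
}

metrics_as_list <- function(m) {
  keep <- setdiff(names(m), "window")
  out <- lapply(m[keep], function(v) if (is.numeric(v)) unname(v) else v)
  out$qrs_start_ms <- m$window$start_time
  out$qrs_end_ms <- m$window$end_time
  out
}

forest_as_list <- function(res) {
  res <- unclass(res)
  res$importances <- as.list(res$importances)
  res
}

# Fill missing keys from the defaults: recurse into named lists, replace
# everything else (including unnamed lists such as density sweeps and empty
# lists, which disable a sweep arm) wholesale.
merge_config <- function(def, cfg) {
  named_list <- function(x) {
    is.list(x) && length(x) > 0 && !is.null(names(x)) && all(names(x) != "")
  }
  out <- def
  for (nm in names(cfg)) {
    out[[nm]] <- if (named_list(def[[nm]]) && named_list(cfg[[nm]])) {
      merge_config(def[[nm]], cfg[[nm]])
    } else {
      cfg[[nm]]
    }
  }
  out
}

# Stable hash of the scientific configuration (output location excluded):
# serialised canonical text, summed by a small rolling checksum (avoids a
# digest dependency).
config_hash <- function(config) {
  config$out_dir <- NULL
  txt <- paste(utils::capture.output(utils::str(config, digits.d = 15)),
               collapse = "\n")
  h <- 0
  for (ch in utf8ToInt(txt)) h <- (h * 31 + ch) %% 2147483647
  sprintf("%08x", h)
}
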