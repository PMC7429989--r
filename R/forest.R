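#' Random-forest scar-location classification with cross-validation
#'
#' Trains random forests (unrestricted tree depth, Gini split criterion,
#' bootstrap sampling) on the delta-metric feature table to answer one of
#' two independent binary questions: is the scar in the LV free wall, or is
#' it in the septum. Evaluation uses either stratified 5-fold
#' cross-validation or n-fold (leave-one-out) cross-validation; feature
#' importances are the normalised total Gini impurity decreases of a forest
#' trained on the full table. Control (scar-free) rows are excluded by
#' default. Deterministic for a fixed seed.
#'
#' @param table A feature table (see [cohort_features()]).
#' @param target `"lv"` or `"septum"`: the positive class.
#' @param n_trees Number of trees (>= 1); the reference analysis uses 20
#'   and 1000.
#' @param cv_scheme `"five_fold"` (stratified) or `"n_fold"`
#'   (leave-one-out).
#' @param seed Integer seed (default 42).
#' @param include_control Keep control rows (as negatives for both
#'   questions)? Default `FALSE`.
#' @param mtry Features tried at each split; default `floor(sqrt(p))`, the
#'   usual classification heuristic.
#' @return A `forest_result`: `n_trees`, `cv_scheme`, `fold_accuracies`
#'   (percent), `accuracy_mean`, `accuracy_std` (percent), `importances`
#'   (named, nonnegative, summing to 1), `seed`, `target`, `n`.
#' @export
forest_classify <- function(table, target = c("lv", "septum"),
                            n_trees = 1000,
                            cv_scheme = c("five_fold", "n_fold"),
                            seed = 42, include_control = FALSE,
                            mtry = NULL) {
  target <- match.arg(target)
  cv_scheme <- match.arg(cv_scheme)
  if (n_trees < 1) stop("invalid configuration: n_trees must be >= 1",
                        call. = FALSE)
  table <- validate_feature_table(table)
  if (!include_control) {
    table <- table[table$location != "none", , drop = FALSE]
  }
  positive <- if (target == "lv") "lv_free_wall" else "septum"
  y <- factor(table$location == positive, levels = c(FALSE, TRUE))
  x <- as.matrix(table[, rate_metric_names()])
  n <- nrow(x)
  if (is.null(mtry)) mtry <- max(1L, floor(sqrt(ncol(x))))
  if (cv_scheme == "five_fold" && n < 5) {
    stop("invalid configuration: fewer rows than folds", call. = FALSE)
  }
  folds <- switch(cv_scheme,
                  five_fold = stratified_folds(y, k = 5, seed = seed),
                  n_fold = as.list(seq_len(n)))
  acc <- withr::with_seed(as.integer(seed), {
    vapply(folds, function(test) {
      fit <- randomForest::randomForest(x[-test, , drop = FALSE],
                                        y[-test], ntree = n_trees,
                                        mtry = mtry)
      pred <- stats::predict(fit, x[test, , drop = FALSE])
      100 * mean(pred == y[test])
    }, numeric(1))
  })
  imp <- withr::with_seed(as.integer(seed), {
    fit <- randomForest::randomForest(x, y, ntree = n_trees, mtry = mtry,
                                      importance = FALSE)
    gi <- randomForest::importance(fit, type = 2)[, 1]
    if (sum(gi) > 0) gi / sum(gi) else rep(1 / length(gi), length(gi))
  })
  structure(
    list(n_trees = n_trees, cv_scheme = cv_scheme, fold_accuracies = acc,
         accuracy_mean = mean(acc), accuracy_std = stats::sd(acc),
         importances = imp, seed = seed, target = target, n = n),
    class = "forest_result")
}

# Seeded stratified k-fold assignment: within each class, shuffled row
# indices are dealt round-robin to the folds.
stratified_folds <- function(y, k, seed) {
  assign <- integer(length(y))
  withr::with_seed(as.integer(seed), {
    for (cls in levels(y)) {
      idx <- sample(which(y == cls))
      assign[idx] <- rep_len(seq_len(k), length(idx))
    }
  })
  folds <- lapply(seq_len(k), function(f) which(assign == f))
  Filter(length, folds)
}

#' @export
print.forest_result <- function(x, ...) {
  cat(sprintf(
    "<forest_result> target %s: %.2f +/- %.2f %% accuracy (%s, %d trees, n = %d, seed %d)\n",
    x$target, x$accuracy_mean, x$accuracy_std,
    ifelse(x$cv_scheme == "five_fold", "5-fold CV", "leave-one-out CV"),
    x$n_trees, x$n, x$seed))
  invisible(x)
}

#' Ranked feature-importance report across both location questions
#'
#' @param lv,septum `forest_result`s for the two binary questions.
#' @return List with `table` (data frame: metric, importance and rank per
#'   target, joint mean importance and joint rank, sorted by joint rank)
#'   and `rank_correlation` (Spearman correlation of the two rankings).
#' @export
importance_report <- function(lv, septum) {
  stopifnot(inherits(lv, "forest_result"), inherits(septum, "forest_result"))
  metrics <- names(lv$importances)
  stopifnot(identical(sort(metrics), sort(names(septum$importances))))
  ilv <- lv$importances[metrics]
  isep <- septum$importances[metrics]
  joint <- (ilv + isep) / 2
  tab <- data.frame(
    metric = metrics,
    importance_lv = ilv,
    importance_septum = isep,
    rank_lv = rank(-ilv, ties.method = "min"),
    rank_septum = rank(-isep, ties.method = "min"),
    importance_joint = joint,
    rank_joint = rank(-joint, ties.method = "min"),
    row.names = NULL)
  tab <- tab[order(tab$rank_joint), ]
  rho <- if (length(metrics) > 1 &&
             stats::sd(ilv) > 0 && stats::sd(isep) > 0) {
    stats::cor(ilv, isep, method = "spearman")
  } else 1
  list(table = tab, rank_correlation = rho)
}
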