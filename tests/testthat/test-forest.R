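# Feature table with a perfectly separating end-angle feature and pure
# noise elsewhere.
separable_table <- function(n_per_class = 10, seed = 1) {
  set.seed(seed)
  n <- 2 * n_per_class
  tab <- as.data.frame(matrix(stats::rnorm(n * 12), n, 12,
                              dimnames = list(NULL, rate_metric_names())))
  tab$location <- rep(c("lv_free_wall", "septum"), each = n_per_class)
  tab$dt_qrs_end <- ifelse(tab$location == "lv_free_wall",
                           stats::runif(n, 5, 15), stats::runif(n, 40, 60))
  tab$id <- sprintf("s%02d", seq_len(n))
  tab
}

test_that("a perfectly separating feature gives perfect folds and top importance", {
  # with every feature available at each split, each tree roots on the
  # separating end-angle feature exactly as a decision stump would
  tab <- separable_table()
  for (scheme in c("five_fold", "n_fold")) {
    res <- forest_classify(tab, target = "lv", n_trees = 100,
                           cv_scheme = scheme, seed = 42,
                           mtry = length(rate_metric_names()))
    expect_true(all(res$fold_accuracies == 100))
    expect_equal(res$accuracy_mean, 100)
    expect_equal(which.max(res$importances),
                 c(dt_qrs_end = which(rate_metric_names() == "dt_qrs_end")))
  }
})

test_that("importances are a probability vector and results deterministic", {
  tab <- separable_table(seed = 3)
  r1 <- forest_classify(tab, "septum", n_trees = 50, cv_scheme = "five_fold",
                        seed = 42)
  r2 <- forest_classify(tab, "septum", n_trees = 50, cv_scheme = "five_fold",
                        seed = 42)
  expect_identical(r1, r2)
  expect_true(all(r1$importances >= 0))
  expect_equal(sum(r1$importances), 1, tolerance = 1e-9)
  r3 <- forest_classify(tab, "septum", n_trees = 50, cv_scheme = "five_fold",
                        seed = 43)
  expect_false(identical(r1$fold_accuracies, r3$fold_accuracies) &&
                 identical(r1$importances, r3$importances))
})

test_that("leave-one-out yields exactly n folds", {
  tab <- separable_table(n_per_class = 6)
  res <- forest_classify(tab, "lv", n_trees = 20, cv_scheme = "n_fold",
                         seed = 42)
  expect_length(res$fold_accuracies, nrow(tab))
  expect_true(all(res$fold_accuracies %in% c(0, 100)))
})

test_that("permuted labels score at chance level", {
  set.seed(99)
  n <- 16
  accs <- replicate(60, {
    tab <- as.data.frame(matrix(stats::rnorm(n * 12), n, 12,
                                dimnames = list(NULL, rate_metric_names())))
    tab$location <- sample(rep(c("lv_free_wall", "septum"), each = n / 2))
    tab$id <- seq_len(n)
    forest_classify(tab, "lv", n_trees = 30, cv_scheme = "five_fold",
                    seed = sample.int(1e6, 1))$accuracy_mean
  })
  # mean fold accuracy within 3 standard errors of 50%
  se <- stats::sd(accs) / sqrt(length(accs))
  expect_lt(abs(mean(accs) - 50), 3 * se + 1e-9)
})

test_that("degenerate configurations are rejected", {
  tab <- separable_table(n_per_class = 2)
  expect_error(forest_classify(tab[1:3, ], "lv", n_trees = 10,
                               cv_scheme = "five_fold"), "fewer rows")
  expect_error(forest_classify(tab, "lv", n_trees = 0), "n_trees")
  one_class <- separable_table()
  one_class$location <- "lv_free_wall"
  expect_error(forest_classify(one_class, "lv"), "location labels")
})

test_that("importance report ranks and correlates targets", {
  tab <- separable_table(seed = 5)
  mtry_all <- length(rate_metric_names())
  lv <- forest_classify(tab, "lv", n_trees = 100, seed = 42, mtry = mtry_all)
  sep <- forest_classify(tab, "septum", n_trees = 100, seed = 42,
                         mtry = mtry_all)
  rep <- importance_report(lv, sep)
  expect_equal(rep$table$metric[1], "dt_qrs_end")
  expect_true(all(diff(rep$table$importance_joint) <= 0))
  # the two questions are complements of one table: identical importances
  ident <- importance_report(lv, lv)
  expect_equal(ident$rank_correlation, 1)
})
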