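test_that("baseline predictors return training constants", {
  f <- baseline_predictor("regression", c(1, 2, 3))
  expect_identical(f(matrix(0, 5, 2)), rep(2, 5))
  expect_error(baseline_predictor("regression", numeric(0)), "empty")
  # majority class with ties toward the lexicographically smaller label
  g <- baseline_predictor("classification", c("b", "a", "b", "a"))
  expect_identical(attr(g, "constant"), "a")
  g2 <- baseline_predictor("classification",
                           c(rep("neg", 7), rep("pos", 3)))
  expect_identical(g2(1:4), rep("neg", 4))
})

test_that("baseline metrics behave as the protocol defines", {
  # R^2 of the mean predictor on its own training set is 0 by definition
  y <- c(0.5, 1.5, 4, -2, 3)
  f <- baseline_predictor("regression", y)
  expect_identical(qapair:::.metric_r2(y, f(y)), 0)
  # constant majority prediction on a test set with both classes:
  # sensitivity 0, specificity 1 -> balanced accuracy 0.5
  obs <- c("neg", "neg", "pos")
  expect_identical(qapair:::.metric_balanced_accuracy(obs, rep("neg", 3)), 0.5)
})

test_that("regression metrics agree with closed forms", {
  obs <- c(1, 2, 3, 4); pred <- c(1.5, 2, 2.5, 4.5)
  expect_equal(qapair:::.metric_rmse(obs, pred),
               sqrt(mean(c(.5, 0, -.5, .5)^2)), tolerance = 1e-15)
  expect_equal(qapair:::.metric_r2(obs, pred),
               1 - sum((obs - pred)^2) / sum((obs - mean(obs))^2),
               tolerance = 1e-15)
  expect_equal(qapair:::.metric_pearson_r2(obs, pred),
               cor(obs, pred)^2, tolerance = 1e-15)
  # AUC: perfect separation -> 1; label-independent scores -> 0.5
  expect_identical(qapair:::.metric_roc_auc(c("a","a","b","b"),
                                            c(.1,.2,.8,.9), c("a","b")), 1)
  expect_identical(qapair:::.metric_roc_auc(c("a","b","a","b"),
                                            c(.5,.5,.5,.5), c("a","b")), 0.5)
})

test_that("fold partitions are deterministic, exhaustive and stratified", {
  y <- c(rep("maj", 45), rep("min", 5))
  f1 <- qapair:::.make_folds(y, 10L, seed = 7, stratify = TRUE)
  f2 <- qapair:::.make_folds(y, 10L, seed = 7, stratify = TRUE)
  expect_identical(f1, f2)
  expect_identical(sort(unique(f1)), 1:10)
  # per-class round-robin: each class spread across folds to within one row
  maj_counts <- tabulate(f1[y == "maj"], 10L)
  min_counts <- tabulate(f1[y == "min"], 10L)
  expect_lte(diff(range(maj_counts)), 1L)
  expect_lte(diff(range(min_counts)), 1L)
  expect_identical(sum(maj_counts), 45L)
  expect_identical(sum(min_counts), 5L)
  f3 <- qapair:::.make_folds(rnorm(25), 5L, seed = 1, stratify = FALSE)
  expect_identical(as.integer(table(f3)), rep(5L, 5L))
})

test_that("repeated_cv produces the full protocol shape deterministically", {
  set.seed(123)
  x <- matrix(rnorm(60 * 3), 60, 3,
              dimnames = list(NULL, paste0("f", 1:3)))
  y <- x[, 1] + rnorm(60, sd = 0.1)
  cfg <- benchmark_config("regression", n_folds = 5, n_repeats = 3,
                          n_estimators = 50, random_seed = 9)
  r1 <- repeated_cv(x, y, cfg, representation = "x")
  r2 <- repeated_cv(x, y, cfg, representation = "x")
  expect_identical(r1, r2)  # bit-identical under the same config
  expect_identical(nrow(r1$per_fold), 3L * 5L * 3L)  # repeats*folds*metrics
  for (m in cfg$metrics) {
    expect_identical(sum(r1$per_fold$metric == m), 15L)
  }
  expect_error(repeated_cv(x, y[-1], cfg), "misaligned")
  expect_error(repeated_cv(x[1:3, ], y[1:3], cfg), "fewer rows")
})

test_that("a perfectly predictive feature yields near-perfect cross-validated R2", {
  set.seed(5)
  x <- matrix(rnorm(200), 200, 1, dimnames = list(NULL, "f"))
  y <- as.numeric(x[, 1])
  cfg <- benchmark_config("regression", n_folds = 10, n_repeats = 2,
                          random_seed = 31)
  r <- repeated_cv(x, y, cfg, representation = "oracle")
  expect_gte(r$summary$mean[r$summary$metric == "r2"], 0.99)
})

test_that("the mean-predicting baseline scores at or below zero held-out R2", {
  set.seed(6)
  x <- matrix(rnorm(150 * 2), 150, 2)
  y <- rnorm(150)
  cfg <- benchmark_config("regression", n_folds = 10, n_repeats = 2,
                          random_seed = 17)
  r <- repeated_cv(x, y, cfg, model = "baseline", representation = "base")
  expect_lte(r$summary$mean[r$summary$metric == "r2"], 0.01)
  expect_gte(min(r$per_fold$value[r$per_fold$metric == "rmse"]), 0)
})

test_that("classification CV reports sane balanced accuracy and AUC", {
  set.seed(8)
  x <- matrix(rnorm(160 * 2), 160, 2)
  y <- ifelse(x[, 1] + rnorm(160, sd = 0.4) > 0, "pos", "neg")
  cfg <- benchmark_config("classification", n_folds = 8, n_repeats = 1,
                          n_estimators = 100, random_seed = 3)
  r <- repeated_cv(x, y, cfg, representation = "x")
  s <- r$summary
  auc <- s$mean[s$metric == "roc_auc"]
  ba <- s$mean[s$metric == "balanced_accuracy"]
  expect_gte(auc, 0.8); expect_lte(auc, 1)
  expect_gte(ba, 0.7); expect_lte(ba, 1)
  # label-independent features hover at chance AUC
  r0 <- repeated_cv(x, sample(y), cfg, representation = "null")
  expect_lt(abs(r0$summary$mean[r0$summary$metric == "roc_auc"] - 0.5), 0.1)
})

test_that("relative_metric pairs folds and handles self-comparison and errors", {
  set.seed(11)
  x <- matrix(rnorm(80 * 2), 80, 2)
  y <- x[, 1] + rnorm(80, sd = 0.3)
  cfg <- benchmark_config("regression", n_folds = 5, n_repeats = 2,
                          n_estimators = 50, random_seed = 2)
  ra <- repeated_cv(x, y, cfg, representation = "a")
  cmp <- relative_metric(ra, ra, "r2")
  expect_identical(length(cmp$per_fold_relative), 10L)
  expect_true(all(cmp$per_fold_relative == 0))
  # plain arithmetic on a doctored pair of reports
  rb <- ra
  rb$per_fold$value[rb$per_fold$metric == "r2"] <-
    ra$per_fold$value[ra$per_fold$metric == "r2"] / 1.06
  cmp2 <- relative_metric(ra, rb, "r2")
  expect_equal(unique(round(cmp2$per_fold_relative, 10)), 0.06,
               tolerance = 1e-9)
  # structural mismatch
  cfg3 <- benchmark_config("regression", n_folds = 5, n_repeats = 1,
                           n_estimators = 50, random_seed = 2)
  rc <- repeated_cv(x, y, cfg3, representation = "c")
  expect_error(relative_metric(ra, rc, "r2"), "structure")
  # zero denominators are dropped and counted
  rd <- ra
  rd$per_fold$value[rd$per_fold$metric == "r2"][1] <- 0
  expect_warning(cmp3 <- relative_metric(ra, rd, "r2"), "zero")
  expect_identical(cmp3$n_dropped, 1L)
  expect_identical(length(cmp3$per_fold_relative), 9L)
})

test_that("Mann-Whitney comparison matches exact enumeration and honors alpha", {
  set.seed(13)
  x <- matrix(rnorm(60), 60, 1)
  y <- x[, 1] + rnorm(60, sd = 0.5)
  cfg <- benchmark_config("regression", n_folds = 5, n_repeats = 2,
                          n_estimators = 30, random_seed = 4)
  ra <- repeated_cv(x, y, cfg, representation = "a")
  # identical samples: p = 1, never significant
  same <- compare_mannwhitney(ra, ra, "r2")
  expect_identical(same$p_value, 1)
  expect_false(same$significant)
  # fully separated samples of size 10 vs 10: exact two-sided p = 2/C(20,10)
  rb <- ra
  rb$per_fold$value[rb$per_fold$metric == "r2"] <-
    ra$per_fold$value[ra$per_fold$metric == "r2"] + 10
  cmp <- compare_mannwhitney(rb, ra, "r2")
  expect_equal(cmp$p_value, 2 / choose(20, 10), tolerance = 1e-12)
  expect_true(cmp$significant)
  expect_identical(cmp$significant, cmp$p_value < 0.05)
  expect_identical(cmp$u_statistic, 100)
})

test_that("cv reports plot as bars with confidence whiskers", {
  set.seed(14)
  x <- matrix(rnorm(50), 50, 1)
  y <- x[, 1]
  cfg <- benchmark_config("regression", n_folds = 5, n_repeats = 1,
                          n_estimators = 20, random_seed = 6)
  r <- repeated_cv(x, y, cfg, representation = "r")
  grDevices::pdf(NULL)
  on.exit(grDevices::dev.off())
  expect_no_error(plot_cv_reports(list(r, r), "rmse"))
})
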