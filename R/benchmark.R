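#' Benchmark configuration
#'
#' Bundles the modeling protocol settings: random forest with 500 trees and
#' `mtry = floor(0.3 * p)` features per split, evaluated by 10 times repeated
#' 10-fold cross-validation. Regression is scored by the coefficient of
#' determination (`r2`), the squared Pearson correlation (`pearson_r2`) and
#' RMSE; classification by balanced accuracy and probability-based ROC AUC.
#'
#' @param task `"regression"` or `"classification"`.
#' @param n_estimators number of trees (default 500).
#' @param max_features_fraction fraction of features tried at each split
#'   (default 0.3).
#' @param n_folds folds per repeat (default 10).
#' @param n_repeats repeats (default 10).
#' @param random_seed base seed; repeat `r` draws its fold partition from
#'   `random_seed + r` and the forest for fold `f` of repeat `r` is seeded
#'   with `random_seed + 1000 * r + f`.
#' @param metrics metric names; defaults per task.
#' @return A `qap_bench_config` list.
#' @export
benchmark_config <- function(task = c("regression", "classification"),
                             n_estimators = 500L,
                             max_features_fraction = 0.3,
                             n_folds = 10L, n_repeats = 10L,
                             random_seed = 1L, metrics = NULL) {
  task <- match.arg(task)
  stopifnot(n_folds >= 2L, n_repeats >= 1L,
            max_features_fraction > 0, max_features_fraction <= 1)
  if (is.null(metrics)) {
    metrics <- if (task == "regression") c("r2", "pearson_r2", "rmse")
               else c("balanced_accuracy", "roc_auc")
  }
  structure(list(task = task, n_estimators = as.integer(n_estimators),
                 max_features_fraction = max_features_fraction,
                 n_folds = as.integer(n_folds),
                 n_repeats = as.integer(n_repeats),
                 random_seed = as.integer(random_seed), metrics = metrics),
            class = "qap_bench_config")
}

#' Baseline predictor
#'
#' The regression baseline always predicts the mean of the training targets;
#' the classification baseline always predicts the majority training class
#' (ties broken toward the lexicographically smaller label). For ROC scoring
#' the classification baseline emits a constant positive-class probability
#' equal to the training prevalence.
#'
#' @param task `"regression"` or `"classification"`.
#' @param training_targets numeric vector (regression) or factor/character
#'   (classification); non-empty.
#' @return A function `f(newdata)` returning constant predictions; for
#'   classification it carries a `"prob"` attribute function as well.
#' @export
baseline_predictor <- function(task = c("regression", "classification"),
                               training_targets) {
  task <- match.arg(task)
  if (length(training_targets) == 0L) stop("empty training targets",
                                           call. = FALSE)
  if (task == "regression") {
    mu <- mean(as.numeric(training_targets))
    f <- function(newdata) rep(mu, NROW(newdata))
    attr(f, "constant") <- mu
    return(f)
  }
  y <- as.character(training_targets)
  tab <- table(y)
  top <- names(tab)[tab == max(tab)]
  label <- sort(top)[1L]  # tie toward lexicographically smaller label
  lev <- sort(unique(y))
  prev <- if (length(lev) == 2L) mean(y == lev[2L]) else NA_real_
  f <- function(newdata) rep(label, NROW(newdata))
  attr(f, "constant") <- label
  attr(f, "prob") <- function(newdata) rep(prev, NROW(newdata))
  f
}

# ---- metrics ----------------------------------------------------------------

# Coefficient of determination on held-out data: 1 - SS_res / SS_tot with
# SS_tot about the held-out mean; may be negative.
.metric_r2 <- function(obs, pred) {
  ss_tot <- sum((obs - mean(obs))^2)
  if (ss_tot == 0) return(NA_real_)
  1 - sum((obs - pred)^2) / ss_tot
}

.metric_pearson_r2 <- function(obs, pred) {
  if (stats::sd(pred) == 0 || stats::sd(obs) == 0) return(NA_real_)
  stats::cor(obs, pred)^2
}

.metric_rmse <- function(obs, pred) sqrt(mean((obs - pred)^2))

# Balanced accuracy = mean of per-class recalls over classes present in obs.
.metric_balanced_accuracy <- function(obs, pred_label) {
  obs <- as.character(obs); pred_label <- as.character(pred_label)
  classes <- sort(unique(obs))
  mean(vapply(classes, function(cl) {
    mean(pred_label[obs == cl] == cl)
  }, numeric(1)))
}

# ROC AUC from positive-class probabilities; positive class = larger level.
.metric_roc_auc <- function(obs, prob_pos, levels) {
  if (length(unique(obs)) < 2L) return(NA_real_)
  r <- pROC::roc(response = factor(obs, levels = levels),
                 predictor = prob_pos, levels = levels, direction = "<",
                 quiet = TRUE)
  as.numeric(pROC::auc(r))
}

.eval_metrics <- function(metrics, obs, pred, prob_pos = NULL, levels = NULL) {
  vapply(metrics, function(m) {
    switch(m,
           r2 = .metric_r2(as.numeric(obs), as.numeric(pred)),
           pearson_r2 = .metric_pearson_r2(as.numeric(obs), as.numeric(pred)),
           rmse = .metric_rmse(as.numeric(obs), as.numeric(pred)),
           balanced_accuracy = .metric_balanced_accuracy(obs, pred),
           roc_auc = .metric_roc_auc(obs, prob_pos, levels),
           stop("unknown metric: ", m))
  }, numeric(1))
}

# ---- fold generation --------------------------------------------------------

# Deterministic fold assignment for one repeat. Regression: a seeded random
# permutation dealt into n_folds groups. Classification: stratified -- each
# class is permuted and dealt round-robin so every fold sees both classes
# whenever counts allow.
.make_folds <- function(y, n_folds, seed, stratify) {
  n <- length(y)
  folds <- integer(n)
  rs <- .seeded_rng(seed)
  if (!stratify) {
    perm <- rs$sample(n)
    folds[perm] <- rep_len(seq_len(n_folds), n)
  } else {
    for (cl in sort(unique(as.character(y)))) {
      idx <- which(as.character(y) == cl)
      perm <- idx[rs$sample(length(idx))]
      start <- rs$sample_int(n_folds)  # rotate so small classes spread evenly
      folds[perm] <- ((start + seq_along(perm) - 2L) %% n_folds) + 1L
    }
  }
  folds
}

# Small local RNG wrapper: isolates seeding from the global RNG state.
.seeded_rng <- function(seed) {
  env <- new.env(parent = emptyenv())
  env$state <- local({
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                        globalenv()) else NULL
    set.seed(seed)
    s <- get(".Random.seed", globalenv())
    if (!is.null(old)) assign(".Random.seed", old, globalenv())
    s
  })
  run <- function(expr_fn) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                        globalenv()) else NULL
    assign(".Random.seed", env$state, globalenv())
    on.exit({
      env$state <- get(".Random.seed", globalenv())
      if (is.null(old)) rm(".Random.seed", envir = globalenv())
      else assign(".Random.seed", old, globalenv())
    })
    expr_fn()
  }
  list(
    sample = function(n) run(function() sample.int(n)),
    sample_int = function(n) run(function() sample.int(n, 1L)),
    norm = function(n, mean = 0, sd = 1) run(function() stats::rnorm(n, mean, sd)),
    unif = function(n) run(function() stats::runif(n)),
    choice = function(x, size, replace = FALSE, prob = NULL)
      run(function() sample(x, size, replace = replace, prob = prob))
  )
}

#' Repeated k-fold cross-validation of a random forest (or baseline)
#'
#' Runs the full evaluation protocol: for each repeat a fresh (seeded) fold
#' partition, stratified for classification; per fold a random forest with
#' the configured tree count and feature fraction (or the mean/majority
#' baseline) is fitted on the training rows and scored on the held-out rows.
#'
#' @param features numeric matrix, rows aligned with `targets`.
#' @param targets numeric vector (regression) or binary factor/character
#'   (classification).
#' @param config a [benchmark_config()].
#' @param model `"forest"` (default) or `"baseline"`.
#' @param representation label stored in the report.
#' @return A `qap_cv_report`: `per_fold` data.frame (`rep`, `fold`, `metric`,
#'   `value`) with `n_folds * n_repeats` rows per metric, and `summary` with
#'   mean and t-based 95% confidence interval per metric.
#' @export
repeated_cv <- function(features, targets, config,
                        model = c("forest", "baseline"),
                        representation = deparse(substitute(features))) {
  model <- match.arg(model)
  stopifnot(inherits(config, "qap_bench_config"))
  features <- as.matrix(features)
  if (is.null(colnames(features))) {
    colnames(features) <- paste0("x", seq_len(ncol(features)))
  }
  n <- nrow(features)
  if (n != length(targets)) stop("features and targets are misaligned",
                                 call. = FALSE)
  if (n < config$n_folds) stop("fewer rows (", n, ") than folds (",
                               config$n_folds, ")", call. = FALSE)
  classify <- config$task == "classification"
  if (classify) {
    targets <- as.character(targets)
    lev <- sort(unique(targets))
    if (length(lev) != 2L) stop("classification targets must be binary",
                                call. = FALSE)
  }
  mtry <- max(1L, floor(config$max_features_fraction * ncol(features)))
  recs <- vector("list", config$n_repeats * config$n_folds)
  k <- 0L
  for (r in seq_len(config$n_repeats)) {
    folds <- .make_folds(targets, config$n_folds,
                         seed = config$random_seed + r, stratify = classify)
    for (f in seq_len(config$n_folds)) {
      test <- folds == f
      x_tr <- features[!test, , drop = FALSE]
      y_tr <- targets[!test]
      x_te <- features[test, , drop = FALSE]
      y_te <- targets[test]
      fit_seed <- config$random_seed + 1000L * r + f
      if (model == "baseline") {
        bp <- baseline_predictor(config$task, y_tr)
        pred <- bp(x_te)
        prob <- if (classify) attr(bp, "prob")(x_te) else NULL
      } else if (!classify) {
        fit <- ranger::ranger(x = x_tr, y = as.numeric(y_tr),
                              num.trees = config$n_estimators, mtry = mtry,
                              seed = fit_seed, num.threads = 1L)
        pred <- stats::predict(fit, data = x_te,
                               num.threads = 1L)$predictions
        prob <- NULL
      } else {
        fit <- ranger::ranger(x = x_tr, y = factor(y_tr, levels = lev),
                              num.trees = config$n_estimators, mtry = mtry,
                              seed = fit_seed, num.threads = 1L,
                              probability = TRUE)
        pm <- stats::predict(fit, data = x_te, num.threads = 1L)$predictions
        prob <- pm[, lev[2L]]
        pred <- ifelse(pm[, lev[2L]] > pm[, lev[1L]], lev[2L], lev[1L])
      }
      vals <- .eval_metrics(config$metrics, y_te, pred, prob,
                            if (classify) lev else NULL)
      k <- k + 1L
      recs[[k]] <- data.frame(rep = r, fold = f,
                              metric = names(vals), value = unname(vals),
                              stringsAsFactors = FALSE)
    }
  }
  per_fold <- do.call(rbind, recs)
  rownames(per_fold) <- NULL
  structure(list(representation = representation, task = config$task,
                 model = model, config = config, per_fold = per_fold,
                 summary = .cv_summary(per_fold)),
            class = "qap_cv_report")
}

.cv_summary <- function(per_fold) {
  out <- do.call(rbind, lapply(split(per_fold, per_fold$metric), function(d) {
    v <- d$value[is.finite(d$value)]
    m <- mean(v)
    half <- if (length(v) > 1L)
      stats::qt(0.975, length(v) - 1L) * stats::sd(v) / sqrt(length(v)) else 0
    data.frame(metric = d$metric[1L], mean = m,
               ci_lo = m - half, ci_hi = m + half, n = length(v),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' @export
print.qap_cv_report <- function(x, ...) {
  cat("<cv report> ", x$representation, " (", x$model, ", ", x$task, ", ",
      x$config$n_repeats, "x", x$config$n_folds, "-fold)\n", sep = "")
  s <- x$summary
  for (i in seq_len(nrow(s))) {
    cat(sprintf("  %-18s %.4f  [95%% CI %.4f, %.4f]\n",
                s$metric[i], s$mean[i], s$ci_lo[i], s$ci_hi[i]))
  }
  invisible(x)
}

#' @export
summary.qap_cv_report <- function(object, ...) object$summary

#' Per-fold relative metric between two representations
#'
#' For reports produced with identical fold partitions (same seed and data
#' size), computes `value_a / value_b - 1` for every paired (repeat, fold)
#' cell of the chosen metric. Pairs where the denominator is exactly zero are
#' dropped and counted.
#'
#' @param report_a,report_b `qap_cv_report` objects with matching fold
#'   structure.
#' @param metric metric name present in both reports.
#' @return A `qap_comparison` with `per_fold_relative`, `n_dropped`, and
#'   summary statistics; the Mann-Whitney fields are `NA` (see
#'   [compare_mannwhitney()]).
#' @export
relative_metric <- function(report_a, report_b, metric) {
  va <- .fold_values(report_a, metric)
  vb <- .fold_values(report_b, metric)
  if (!identical(va$key, vb$key)) {
    stop("fold structures differ between reports (repeats x folds must match)",
         call. = FALSE)
  }
  zero <- vb$value == 0
  if (any(zero)) {
    warning(sum(zero), " fold pair(s) dropped: zero denominator value")
  }
  rel <- va$value[!zero] / vb$value[!zero] - 1
  structure(list(metric = metric,
                 representation_a = report_a$representation,
                 representation_b = report_b$representation,
                 per_fold_relative = rel, n_dropped = sum(zero),
                 mean_relative = mean(rel),
                 u_statistic = NA_real_, p_value = NA_real_,
                 alpha = NA_real_, significant = NA),
            class = "qap_comparison")
}

.fold_values <- function(report, metric) {
  stopifnot(inherits(report, "qap_cv_report"))
  d <- report$per_fold[report$per_fold$metric == metric, , drop = FALSE]
  if (nrow(d) == 0L) stop("metric '", metric, "' not found in report for ",
                          report$representation, call. = FALSE)
  d <- d[order(d$rep, d$fold), ]
  list(key = paste(d$rep, d$fold, sep = "."), value = d$value)
}

#' Mann-Whitney comparison of per-fold metric values
#'
#' Two-sided Mann-Whitney U test on the pooled per-fold metric values of two
#' representations (unpaired). The exact null distribution is used for small
#' untied samples; otherwise the normal approximation with tie correction.
#'
#' @inheritParams relative_metric
#' @param alpha significance level (default 0.05).
#' @return A `qap_comparison` with `u_statistic`, `p_value`, `significant`,
#'   plus the paired relative metrics when the fold structures match.
#' @export
compare_mannwhitney <- function(report_a, report_b, metric, alpha = 0.05) {
  va <- .fold_values(report_a, metric)$value
  vb <- .fold_values(report_b, metric)$value
  if (length(va) < 2L || length(vb) < 2L) {
    stop("need at least 2 per-fold values per side", call. = FALSE)
  }
  if (all(va == vb[1L]) && all(vb == vb[1L])) {
    u <- length(va) * length(vb) / 2
    p <- 1
  } else {
    wt <- suppressWarnings(stats::wilcox.test(va, vb,
                                              alternative = "two.sided"))
    u <- unname(wt$statistic)
    p <- wt$p.value
  }
  rel <- tryCatch(relative_metric(report_a, report_b, metric),
                  error = function(e) NULL, warning = function(w) NULL)
  structure(list(metric = metric,
                 representation_a = report_a$representation,
                 representation_b = report_b$representation,
                 per_fold_relative = if (is.null(rel)) numeric(0)
                                     else rel$per_fold_relative,
                 n_dropped = if (is.null(rel)) NA_integer_ else rel$n_dropped,
                 mean_relative = if (is.null(rel)) NA_real_
                                 else rel$mean_relative,
                 u_statistic = u, p_value = p, alpha = alpha,
                 significant = p < alpha),
            class = "qap_comparison")
}

#' @export
print.qap_comparison <- function(x, ...) {
  cat("<comparison> ", x$representation_a, " vs ", x$representation_b,
      " on ", x$metric, "\n", sep = "")
  if (length(x$per_fold_relative) > 0L) {
    cat(sprintf("  mean relative difference: %+.4f (%d fold pairs%s)\n",
                x$mean_relative, length(x$per_fold_relative),
                if (isTRUE(x$n_dropped > 0L))
                  paste0(", ", x$n_dropped, " dropped") else ""))
  }
  if (is.finite(x$p_value)) {
    cat(sprintf("  Mann-Whitney U = %.1f, p = %.4g (%ssignificant at %.2f)\n",
                x$u_statistic, x$p_value,
                if (isTRUE(x$significant)) "" else "not ", x$alpha))
  }
  invisible(x)
}

#' Bar chart of cross-validated metric means with 95% CI whiskers
#'
#' @param reports list of `qap_cv_report` objects.
#' @param metric metric to display.
#' @param ... passed to [graphics::barplot()].
#' @export
plot_cv_reports <- function(reports, metric, ...) {
  stats_ <- lapply(reports, function(r) {
    s <- r$summary[r$summary$metric == metric, ]
    if (nrow(s) == 0L) stop("metric '", metric, "' missing for ",
                            r$representation, call. = FALSE)
    s
  })
  means <- vapply(stats_, `[[`, numeric(1), "mean")
  lo <- vapply(stats_, `[[`, numeric(1), "ci_lo")
  hi <- vapply(stats_, `[[`, numeric(1), "ci_hi")
  labs <- vapply(reports, `[[`, character(1), "representation")
  ylim <- range(0, lo, hi)
  bp <- graphics::barplot(means, names.arg = labs, ylab = metric,
                          ylim = ylim + c(0, 0.08 * diff(ylim)), ...)
  graphics::arrows(bp, lo, bp, hi, angle = 90, code = 3, length = 0.06)
  invisible(bp)
}
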