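#' Bootstrapped random-forest structure-function model
#'
#' Fits the voxel-level feature table to the chosen visual-function outcome
#' with random-forest regression under repeated patient-level evaluation:
#' each replicate resamples patients with replacement (bootstrap), splits
#' the resampled patients 80/20 with all eyes of a patient on one side,
#' trains a forest on the training eyes and scores the held-out eyes with
#' the coefficient of determination (r^2) and mean absolute error (MAE, in
#' ETDRS letters). Per-predictor impurity importances (variance reduction,
#' averaged over the ensemble) are retained per replicate, averaged, and
#' renormalised to percentage contributions.
#'
#' @param table a [build_feature_table()] result.
#' @param n_replicates bootstrap replicate count.
#' @param train_frac fraction of split units assigned to training.
#' @param split_unit `"patient"` (all eyes of a patient stay together,
#'   default) or `"eye"`.
#' @param scheme `"bootstrap"` (resample units with replacement, then
#'   partition the resampled set; default) or `"split_only"` (plain repeated
#'   80/20 splits without resampling).
#' @param seed master seed; the result is a deterministic function of table
#'   and seed.
#' @param num_trees,mtry,min_node_size forest hyperparameters. Defaults
#'   follow the common regression-forest convention of 100 trees with all
#'   predictors considered at every split (`mtry = NULL` means all);
#'   `min_node_size = 5` is the usual regression leaf size.
#' @param point how the single reported r^2 / MAE is aggregated across
#'   replicates (`"median"` default, `"mean"` available).
#' @return object of class `structfunc_fit` with elements `replicates`
#'   (per-replicate r^2, MAE, n_train, n_test, excluded flag), `summary`
#'   (point r^2, MAE median and quartiles), `importance` (per-predictor
#'   percentages, see [importance_by_cell()]), `splits` (per-replicate unit
#'   assignments, for leakage auditing), `final_fit` (forest trained on all
#'   rows, used by [predict.structfunc_fit()]), and provenance
#'   (hyperparameters, seed, outcome, column info).
#' @export
fit_structfunc <- function(table, n_replicates = 100, train_frac = 0.8,
                           split_unit = c("patient", "eye"),
                           scheme = c("bootstrap", "split_only"),
                           seed = 1, num_trees = 100, mtry = NULL,
                           min_node_size = 5,
                           point = c("median", "mean")) {
  split_unit <- match.arg(split_unit)
  scheme <- match.arg(scheme)
  point <- match.arg(point)
  stopifnot(inherits(table, "feature_table"))
  preds <- predictor_columns(table)
  unit_col <- if (split_unit == "patient") "patient_id" else "eye_id"
  units <- unique(table[[unit_col]])
  if (split_unit == "patient" && length(units) < 10)
    stop("need at least 10 distinct patients", call. = FALSE)
  if (is.null(mtry)) mtry <- length(preds)

  x <- as.matrix(table[, preds, drop = FALSE])
  y <- table$outcome
  rep_stats <- data.frame(r2 = rep(NA_real_, n_replicates),
                          mae = NA_real_, n_train = NA_integer_,
                          n_test = NA_integer_, excluded = FALSE)
  imp <- matrix(NA_real_, n_replicates, length(preds),
                dimnames = list(NULL, preds))
  splits <- vector("list", n_replicates)

  for (r in seq_len(n_replicates)) {
    rep_seed <- derive_seed(seed, r, 5L)
    set.seed(rep_seed)
    for (draw in 1:20) {   # redraw until the test side is non-empty
      if (scheme == "bootstrap") {
        res <- sample(units, replace = TRUE)
        distinct <- unique(res)
        n_test <- max(1L, round((1 - train_frac) * length(distinct)))
        test_units <- sample(distinct, n_test)
        train_multiset <- res[!(res %in% test_units)]
      } else {
        shuffled <- sample(units)
        n_test <- max(1L, round((1 - train_frac) * length(units)))
        test_units <- shuffled[seq_len(n_test)]
        train_multiset <- shuffled[-seq_len(n_test)]
      }
      if (length(train_multiset) > 0L) break
    }
    train_rows <- unlist(lapply(train_multiset,
                                function(u) which(table[[unit_col]] == u)))
    test_rows <- which(table[[unit_col]] %in% test_units)
    splits[[r]] <- list(train_units = unique(train_multiset),
                        test_units = test_units)
    rep_stats$n_train[r] <- length(train_rows)
    rep_stats$n_test[r] <- length(test_rows)

    ytr <- y[train_rows]; yte <- y[test_rows]
    if (length(ytr) < 2L || length(yte) < 2L ||
        stats::sd(ytr) == 0 || stats::var(yte) == 0) {
      rep_stats$excluded[r] <- TRUE
      next
    }
    fit <- ranger::ranger(x = x[train_rows, , drop = FALSE], y = ytr,
                          num.trees = num_trees, mtry = mtry,
                          min.node.size = min_node_size,
                          importance = "impurity",
                          seed = rep_seed, num.threads = 1)
    pred <- stats::predict(fit, data = x[test_rows, , drop = FALSE],
                           num.threads = 1)$predictions
    rep_stats$r2[r] <- 1 - sum((yte - pred)^2) / sum((yte - mean(yte))^2)
    rep_stats$mae[r] <- mean(abs(yte - pred))
    imp[r, ] <- fit$variable.importance
  }

  ok <- !rep_stats$excluded
  if (sum(!ok) > 0) message(sum(!ok), " replicate(s) excluded from summary")
  agg <- if (point == "median") stats::median else mean
  summ <- list(
    r2 = agg(rep_stats$r2[ok]),
    mae = stats::median(rep_stats$mae[ok]),
    mae_q25 = unname(stats::quantile(rep_stats$mae[ok], 0.25)),
    mae_q75 = unname(stats::quantile(rep_stats$mae[ok], 0.75)),
    n_replicates = n_replicates, n_excluded = sum(!ok))

  imp_pct <- average_importance(imp[ok, , drop = FALSE])

  final_fit <- ranger::ranger(x = x, y = y, num.trees = num_trees,
                              mtry = mtry, min.node.size = min_node_size,
                              importance = "impurity",
                              seed = derive_seed(seed, 0L, 6L),
                              num.threads = 1)

  structure(list(replicates = rep_stats, summary = summ,
                 importance = imp_pct, importance_replicates = imp,
                 splits = splits, final_fit = final_fit,
                 n_eyes = nrow(table),
                 n_patients = length(unique(table$patient_id)),
                 outcome = attr(table, "outcome_name"),
                 column_info = attr(table, "column_info"),
                 block_dim = attr(table, "block_dim"),
                 extent_mm = attr(table, "extent_mm"),
                 hyperparameters = list(num_trees = num_trees, mtry = mtry,
                                        min_node_size = min_node_size,
                                        train_frac = train_frac,
                                        split_unit = split_unit,
                                        scheme = scheme, point = point),
                 seed = seed),
            class = "structfunc_fit")
}

#' Repeat the evaluation with one eye per patient
#'
#' Keeps a single eye per patient (random, seeded, or the first in table
#' order) and reruns [fit_structfunc()]; used as a sensitivity analysis for
#' the within-patient correlation of bilateral eyes.
#'
#' @param table a [build_feature_table()] result.
#' @param rule `"random"` or `"first"`.
#' @param seed master seed (drives the selection and the refit).
#' @param ... passed to [fit_structfunc()].
#' @return a `structfunc_fit` on the reduced table.
#' @export
sensitivity_one_eye <- function(table, rule = c("random", "first"),
                                seed = 1, ...) {
  rule <- match.arg(rule)
  stopifnot(inherits(table, "feature_table"))
  keep <- unlist(lapply(split(seq_len(nrow(table)), table$patient_id),
                        function(idx) {
                          if (rule == "first" || length(idx) == 1L) idx[1]
                          else {
                            set.seed(derive_seed(seed, idx[1], 7L))
                            sample(idx, 1L)
                          }
                        }))
  sub <- table[sort(unname(keep)), , drop = FALSE]
  attributes(sub)[c("column_info", "block_dim", "outcome_name", "extent_mm")] <-
    attributes(table)[c("column_info", "block_dim", "outcome_name", "extent_mm")]
  class(sub) <- class(table)
  fit_structfunc(sub, seed = seed, ...)
}

#' @export
print.structfunc_fit <- function(x, ...) {
  s <- x$summary
  cat(sprintf("<structfunc_fit> outcome = %s, %d bootstrap replicates\n",
              x$outcome, s$n_replicates))
  cat(sprintf("  r2 %.2f  MAE %.1f (%.1f-%.1f) ETDRS letters\n",
              s$r2, s$mae, s$mae_q25, s$mae_q75))
  invisible(x)
}

#' @export
summary.structfunc_fit <- function(object, labels = NULL, ...) {
  print(object)
  labels <- labels %||% etdrs_labels(object$block_dim,
                                     extent_mm = object$extent_mm)
  ri <- aggregate_by_region(object, labels)
  print(ri)
  invisible(list(fit = object, region_importance = ri))
}

#' @export
coef.structfunc_fit <- function(object, ...) object$importance

#' @export
predict.structfunc_fit <- function(object, newdata, ...) {
  if (inherits(newdata, "feature_table") || is.data.frame(newdata))
    newdata <- as.matrix(newdata[, predictor_columns(newdata), drop = FALSE])
  stats::predict(object$final_fit, data = newdata,
                 num.threads = 1)$predictions
}

#' @export
residuals.structfunc_fit <- function(object, table, ...) {
  table$outcome - predict(object, table)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Replicate-averaged normalised importance: average raw impurity importances
# across replicates first, then renormalise to percentages summing to 100.
average_importance <- function(imp_matrix) {
  mean_imp <- colMeans(imp_matrix)
  tot <- sum(mean_imp)
  if (tot > 0) 100 * mean_imp / tot else mean_imp * 0
}
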