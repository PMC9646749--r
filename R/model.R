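#' Fit z-score scaling statistics on training features
#'
#' Column means and population standard deviations (divide by `n`). Test
#' data must be standardised with the *training* statistics, so fit and
#' apply are separate steps.
#'
#' @param features A numeric feature tibble/matrix (no id column).
#' @return A tibble with columns `feature`, `mean`, `sd`.
#' @export
zscore_fit <- function(features) {
  m <- as.matrix(features)
  n <- nrow(m)
  mu <- colMeans(m)
  sigma <- sqrt(colMeans(sweep(m, 2, mu)^2))
  tibble(feature = colnames(m), mean = unname(mu), sd = unname(sigma))
}

#' Apply z-score scaling statistics
#'
#' `z = (x - mean) / sd` per column. Constant training columns (`sd = 0`)
#' map to 0 so degenerate features stay finite.
#'
#' @param features A numeric feature tibble/matrix with the same columns
#'   the statistics were fitted on.
#' @param stats Scaling statistics from [zscore_fit()].
#' @return A tibble of standardised features.
#' @export
zscore_apply <- function(features, stats) {
  m <- as.matrix(features)
  idx <- match(colnames(m), stats$feature)
  if (anyNA(idx)) {
    stop("no scaling statistics for column(s): ",
         paste(colnames(m)[is.na(idx)], collapse = ", "), call. = FALSE)
  }
  centred <- sweep(m, 2, stats$mean[idx])
  sd_safe <- ifelse(stats$sd[idx] == 0, 1, stats$sd[idx])
  out <- sweep(centred, 2, sd_safe, "/")
  out[, stats$sd[idx] == 0] <- 0
  as_tibble(out)
}

#' Balance classes by SMOTE minority over-sampling
#'
#' Synthesises new minority-class rows on the segments joining each sampled
#' minority instance to one of its `k` nearest minority neighbours
#' (`x_new = x + u * (x_nn - x)`, `u ~ U(0, 1)`), until both classes have
#' the same count. Original rows of both classes are preserved verbatim;
#' synthetic rows are appended. Already-balanced input is returned
#' unchanged.
#'
#' @param features A numeric feature tibble/matrix.
#' @param labels Character/factor vector of two classes, one per row.
#' @param k_neighbors Number of nearest minority neighbours to draw from
#'   (reduced, with a warning, when the minority class is too small).
#' @param seed Integer seed for reproducibility.
#' @return A list with `features` (tibble), `labels`, and `n_synthetic`.
#' @export
smote_balance <- function(features, labels, k_neighbors = 5L, seed = 1L) {
  m <- as.matrix(features)
  labels <- as.character(labels)
  stopifnot(nrow(m) == length(labels))
  tab <- table(labels)
  if (length(tab) != 2L) stop("SMOTE needs exactly two classes", call. = FALSE)
  if (tab[[1]] == tab[[2]]) {
    return(list(features = as_tibble(m), labels = labels, n_synthetic = 0L))
  }
  minority <- names(tab)[which.min(tab)]
  n_new <- abs(tab[[1]] - tab[[2]])
  min_rows <- which(labels == minority)
  x <- m[min_rows, , drop = FALSE]
  n_min <- nrow(x)
  if (n_min <= k_neighbors) {
    k_neighbors <- max(1L, n_min - 1L)
    warning("minority class has only ", n_min,
            " instances; using k = ", k_neighbors)
  }
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(seed)
  synth <- matrix(0, nrow = n_new, ncol = ncol(m), dimnames = list(NULL, colnames(m)))
  if (n_min == 1L) {
    # a single minority point has no neighbours; replicate it
    synth[] <- rep(x[1L, ], each = n_new)
  } else {
    d <- as.matrix(stats::dist(x))
    diag(d) <- Inf
    nn <- do.call(rbind, lapply(seq_len(n_min), function(i) {
      order(d[i, ])[seq_len(k_neighbors)]
    }))
    base_i <- sample.int(n_min, n_new, replace = TRUE)
    pick <- sample.int(k_neighbors, n_new, replace = TRUE)
    u <- runif(n_new)
    for (s in seq_len(n_new)) {
      a <- x[base_i[s], ]
      b <- x[nn[base_i[s], pick[s]], ]
      synth[s, ] <- a + u[s] * (b - a)
    }
  }
  list(
    features = as_tibble(rbind(m, synth)),
    labels = c(labels, rep(minority, n_new)),
    n_synthetic = n_new
  )
}

# stratified fold assignment, seeded and reproducible
make_folds <- function(labels, folds, seed) {
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(seed)
  fold <- integer(length(labels))
  for (cl in unique(labels)) {
    idx <- sample(which(labels == cl))
    fold[idx] <- rep_len(seq_len(folds), length(idx))
  }
  fold
}

default_xgb_params <- function(max_depth = 6L, eta = 0.1) {
  list(
    objective = "binary:logistic", eval_metric = "error",
    max_depth = max_depth, eta = eta, nthread = 1
  )
}

fit_xgb <- function(m, y, params, nrounds, seed) {
  dtrain <- xgboost::xgb.DMatrix(m, label = y)
  set.seed(seed)
  xgboost::xgb.train(params = params, data = dtrain, nrounds = nrounds, verbose = 0)
}

cv_accuracy <- function(m, y, params, nrounds, folds, seed) {
  fold <- make_folds(y, folds, seed)
  acc <- vapply(seq_len(folds), function(f) {
    tr <- fold != f
    fit <- fit_xgb(m[tr, , drop = FALSE], y[tr], params, nrounds, seed)
    p <- predict(fit, xgboost::xgb.DMatrix(m[!tr, , drop = FALSE]))
    mean((p >= 0.5) == (y[!tr] == 1))
  }, numeric(1))
  mean(acc)
}

#' Recursive feature elimination with cross-validation
#'
#' Starting from all columns, repeatedly fits the boosted-tree model,
#' ranks features by gain importance, and drops the single least-important
#' feature, recording the mean stratified k-fold cross-validation accuracy
#' of every subset size. The returned subset is the one at peak accuracy;
#' ties go to the smaller subset.
#'
#' @param features A standardised numeric feature tibble/matrix.
#' @param labels Two-class label vector (`"lncRNA"` is the positive class).
#' @param folds Number of cross-validation folds.
#' @param seed Integer seed controlling folds and model fits.
#' @param nrounds Boosting rounds per fit (kept modest: RFECV refits the
#'   model once per eliminated feature).
#' @param params XGBoost parameter list.
#' @return A list with `features` (the selected subset, in retained order)
#'   and `trace`, a tibble of `size` and `cv_accuracy` per subset size.
#' @export
rfecv_select <- function(features, labels, folds = 10L, seed = 1L,
                         nrounds = 50L, params = default_xgb_params()) {
  m <- as.matrix(features)
  y <- as.integer(labels == "lncRNA")
  stopifnot(min(table(labels)) >= folds)
  current <- colnames(m)
  trace <- list()
  while (TRUE) {
    msub <- m[, current, drop = FALSE]
    acc <- cv_accuracy(msub, y, params, nrounds, folds, seed)
    trace[[length(trace) + 1L]] <- tibble(size = length(current), cv_accuracy = acc,
                                          features = list(current))
    if (length(current) == 1L) break
    fit <- fit_xgb(msub, y, params, nrounds, seed)
    imp <- xgboost::xgb.importance(model = fit)
    gain <- setNames(rep(0, length(current)), current)
    gain[imp$Feature] <- imp$Gain
    # drop the single lowest-gain feature (first of the ties, deterministic)
    drop_feat <- names(gain)[which.min(gain)]
    current <- setdiff(current, drop_feat)
  }
  trace <- dplyr::bind_rows(trace)
  best <- trace[order(-trace$cv_accuracy, trace$size), ][1L, ]
  list(features = best$features[[1]], trace = trace[, c("size", "cv_accuracy")])
}

#' Tune XGBoost hyperparameters by cross-validated accuracy
#'
#' Evaluates a small grid of tree counts, depths and learning rates by mean
#' stratified k-fold cross-validation accuracy and returns the winning
#' configuration. The default grid is deliberately small; the package's
#' default training parameters are already sensible for feature sets of
#' this size, so tuning is opt-in.
#'
#' @param features Standardised numeric feature tibble/matrix.
#' @param labels Two-class label vector.
#' @param grid A data frame with columns `nrounds`, `max_depth`, `eta`.
#' @param folds Number of cross-validation folds.
#' @param seed Integer seed.
#' @return The grid with an extra `cv_accuracy` column, sorted best-first.
#' @export
tune_classifier <- function(features, labels,
                            grid = expand.grid(nrounds = c(100L, 300L, 500L),
                                               max_depth = c(4L, 6L, 8L),
                                               eta = c(0.05, 0.1, 0.3)),
                            folds = 10L, seed = 1L) {
  m <- as.matrix(features)
  y <- as.integer(labels == "lncRNA")
  grid$cv_accuracy <- vapply(seq_len(nrow(grid)), function(i) {
    params <- default_xgb_params(grid$max_depth[i], grid$eta[i])
    cv_accuracy(m, y, params, grid$nrounds[i], folds, seed)
  }, numeric(1))
  as_tibble(grid[order(-grid$cv_accuracy, grid$nrounds, grid$max_depth), ])
}

#' Compute binary classification metrics
#'
#' Sensitivity, specificity, precision, accuracy, F-score and Matthews
#' correlation coefficient from true and predicted labels, with lncRNA as
#' the positive class. A zero denominator yields 0 for that metric and a
#' `degenerate` flag.
#'
#' @param truth,predicted Character vectors of `"lncRNA"`/`"mRNA"` labels.
#' @return An object of class `lnc_metrics`: a list with the confusion
#'   counts and the six metrics.
#' @examples
#' compute_metrics(c("lncRNA", "mRNA"), c("lncRNA", "mRNA"))$accuracy  # 1
#' @export
compute_metrics <- function(truth, predicted) {
  stopifnot(length(truth) == length(predicted))
  if (length(truth) == 0L) stop("cannot compute metrics on empty input", call. = FALSE)
  tp <- sum(truth == "lncRNA" & predicted == "lncRNA")
  fn <- sum(truth == "lncRNA" & predicted == "mRNA")
  tn <- sum(truth == "mRNA" & predicted == "mRNA")
  fp <- sum(truth == "mRNA" & predicted == "lncRNA")
  safe_div <- function(num, den) if (den == 0) 0 else num / den
  sn <- safe_div(tp, tp + fn)
  sp <- safe_div(tn, tn + fp)
  prec <- safe_div(tp, tp + fp)
  acc <- (tp + tn) / (tp + fp + tn + fn)
  f <- safe_div(2 * prec * sn, prec + sn)
  mcc_den <- sqrt(tp + fp) * sqrt(tp + fn) * sqrt(tn + fp) * sqrt(tn + fn)
  mcc <- if (mcc_den == 0) 0 else (tp * tn - fp * fn) / mcc_den
  degenerate <- any(c(tp + fn, tn + fp, tp + fp, prec + sn) == 0) || mcc_den == 0
  structure(
    list(tp = tp, fp = fp, tn = tn, fn = fn,
         sensitivity = sn, specificity = sp, precision = prec,
         accuracy = acc, f_score = f, mcc = mcc, degenerate = degenerate),
    class = "lnc_metrics"
  )
}

#' @export
print.lnc_metrics <- function(x, ...) {
  cat(sprintf("confusion: TP=%d FP=%d TN=%d FN=%d\n", x$tp, x$fp, x$tn, x$fn))
  cat(sprintf("Sn=%.4f Sp=%.4f Prec=%.4f Acc=%.4f F=%.4f MCC=%.4f\n",
              x$sensitivity, x$specificity, x$precision, x$accuracy,
              x$f_score, x$mcc))
  if (x$degenerate) cat("(degenerate confusion matrix: some metrics reported as 0)\n")
  invisible(x)
}

#' ROC curve and AUC
#'
#' Sweeps the decision threshold over the unique scores, records the true-
#' and false-positive rates, and integrates the curve by the trapezoid
#' rule. The result equals the rank-statistic (Mann--Whitney) formulation
#' of the AUC.
#'
#' @param truth Character vector of `"lncRNA"`/`"mRNA"` labels.
#' @param scores Numeric lncRNA scores (higher means more lncRNA-like).
#' @return An object of class `lnc_roc`: list with `points` (tibble of
#'   `threshold`, `fpr`, `tpr`) and `auc`.
#' @export
roc_auc <- function(truth, scores) {
  stopifnot(length(truth) == length(scores), length(truth) > 0L)
  pos <- truth == "lncRNA"
  n_pos <- sum(pos)
  n_neg <- sum(!pos)
  thresholds <- sort(unique(scores), decreasing = TRUE)
  tpr <- vapply(thresholds, function(t) sum(scores >= t & pos) / n_pos, numeric(1))
  fpr <- vapply(thresholds, function(t) sum(scores >= t & !pos) / n_neg, numeric(1))
  points <- tibble(
    threshold = c(Inf, thresholds),
    fpr = c(0, fpr),
    tpr = c(0, tpr)
  )
  auc <- sum(diff(points$fpr) * (head(points$tpr, -1) + tail(points$tpr, -1)) / 2)
  structure(list(points = points, auc = auc), class = "lnc_roc")
}

#' @export
print.lnc_roc <- function(x, ...) {
  cat(sprintf("ROC with %d points, AUC = %.4f\n", nrow(x$points), x$auc))
  invisible(x)
}
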