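test_that("z-score uses population sd and training statistics only", {
  x <- tibble::tibble(a = c(1, 2, 3), b = c(5, 5, 5))
  st <- zscore_fit(x)
  expect_equal(st$sd[st$feature == "a"], sqrt(2 / 3))
  z <- zscore_apply(x, st)
  expect_equal(z$a, c(-1.2247449, 0, 1.2247449), tolerance = 1e-6)
  expect_equal(z$b, c(0, 0, 0))  # constant column maps to zero
  expect_equal(colMeans(as.matrix(z))[["a"]], 0, tolerance = 1e-12)
  # applying train stats to new data uses the train mean/sd
  z2 <- zscore_apply(tibble::tibble(a = 4, b = 9), st)
  expect_equal(z2$a, (4 - 2) / sqrt(2 / 3), tolerance = 1e-9)
  expect_error(zscore_apply(tibble::tibble(c = 1), st), "no scaling statistics")
})

test_that("SMOTE balances classes without touching original rows", {
  set.seed(414)
  maj <- matrix(rnorm(200), ncol = 2)
  mnr <- matrix(rnorm(60, mean = 5), ncol = 2)
  x <- rbind(maj, mnr)
  colnames(x) <- c("f1", "f2")
  labels <- c(rep("mRNA", 100), rep("lncRNA", 30))
  out <- smote_balance(x, labels, seed = 9)
  expect_equal(unname(table(out$labels)[["lncRNA"]]), 100)
  expect_equal(as.matrix(out$features[1:130, ]), x, ignore_attr = TRUE)
  expect_equal(out$n_synthetic, 70)
  # every synthetic row lies on a segment between a minority row and one of
  # its k nearest minority neighbours
  synth <- as.matrix(out$features[131:200, ])
  d <- as.matrix(dist(mnr)); diag(d) <- Inf
  nn <- t(apply(d, 1, function(r) order(r)[1:5]))
  on_segment <- vapply(seq_len(nrow(synth)), function(s) {
    any(vapply(seq_len(nrow(mnr)), function(i) {
      any(vapply(nn[i, ], function(j) {
        v <- mnr[j, ] - mnr[i, ]
        w <- synth[s, ] - mnr[i, ]
        if (sum(v^2) == 0) return(sum(w^2) < 1e-18)
        u <- sum(w * v) / sum(v^2)
        u >= -1e-9 && u <= 1 + 1e-9 && sum((w - u * v)^2) < 1e-18
      }, logical(1)))
    }, logical(1)))
  }, logical(1))
  expect_true(all(on_segment))
  # seeded reproducibility
  out2 <- smote_balance(x, labels, seed = 9)
  expect_equal(out2$features, out$features)
})

test_that("SMOTE edge cases: balanced input unchanged, tiny minority handled", {
  x <- matrix(1:8, ncol = 2, dimnames = list(NULL, c("a", "b")))
  lab <- c("mRNA", "mRNA", "lncRNA", "lncRNA")
  out <- smote_balance(x, lab)
  expect_equal(as.matrix(out$features), x, ignore_attr = TRUE)
  expect_equal(out$n_synthetic, 0L)
  # two identical minority points: synthetics are identical copies
  x2 <- rbind(matrix(rnorm(20), ncol = 2), c(1, 1), c(1, 1))
  colnames(x2) <- c("a", "b")
  lab2 <- c(rep("mRNA", 10), "lncRNA", "lncRNA")
  expect_warning(out2 <- smote_balance(x2, lab2, k_neighbors = 5, seed = 2),
                 "using k = 1")
  synth <- as.matrix(out2$features[13:20, ])
  expect_true(all(abs(synth - 1) < 1e-12))
})

test_that("RFECV recovers planted signal and traces every subset size", {
  set.seed(415)
  n <- 160
  signal <- matrix(rnorm(n * 3), ncol = 3)
  y <- ifelse(rowSums(signal) > 0, "lncRNA", "mRNA")
  x <- cbind(signal, matrix(rnorm(n * 7), ncol = 7))
  colnames(x) <- c(paste0("sig", 1:3), paste0("noise", 1:7))
  sel <- rfecv_select(x, y, folds = 5, seed = 3, nrounds = 40)
  expect_equal(nrow(sel$trace), 10)  # one accuracy point per subset size
  expect_setequal(intersect(sel$features, paste0("sig", 1:3)), paste0("sig", 1:3))
  sel2 <- rfecv_select(x, y, folds = 5, seed = 3, nrounds = 40)
  expect_equal(sel2$trace, sel$trace)  # reproducible under a fixed seed
  expect_equal(sel2$features, sel$features)
})

test_that("metric formulas match hand evaluation on a fixed confusion matrix", {
  truth <- c(rep("lncRNA", 100), rep("mRNA", 100))
  pred <- c(rep("lncRNA", 98), rep("mRNA", 2), rep("lncRNA", 3), rep("mRNA", 97))
  m <- compute_metrics(truth, pred)
  expect_equal(c(m$tp, m$fn, m$fp, m$tn), c(98, 2, 3, 97))
  expect_equal(m$sensitivity, 0.98)
  expect_equal(m$specificity, 0.97)
  expect_equal(m$precision, 98 / 101, tolerance = 1e-9)
  expect_equal(m$accuracy, 0.975)
  expect_equal(m$f_score, 2 * (98 / 101) * 0.98 / (98 / 101 + 0.98), tolerance = 1e-9)
  expect_equal(m$mcc, (98 * 97 - 3 * 2) / sqrt(101 * 100 * 100 * 99), tolerance = 1e-9)

  perfect <- compute_metrics(truth, truth)
  expect_equal(perfect$mcc, 1)
  expect_equal(perfect$f_score, 1)

  allpos <- compute_metrics(truth, rep("lncRNA", 200))
  expect_equal(allpos$sensitivity, 1)
  expect_equal(allpos$specificity, 0)
  expect_equal(allpos$mcc, 0)
  expect_true(allpos$degenerate)
  expect_error(compute_metrics(character(0), character(0)), "empty")
})

test_that("ROC/AUC equals the rank-statistic oracle", {
  truth <- c(rep("lncRNA", 3), rep("mRNA", 3))
  expect_equal(roc_auc(truth, c(0.9, 0.8, 0.7, 0.3, 0.2, 0.1))$auc, 1)
  expect_equal(roc_auc(truth, c(0.1, 0.2, 0.3, 0.7, 0.8, 0.9))$auc, 0)
  set.seed(416)
  for (i in 1:20) {
    n <- 80
    tr <- sample(c("lncRNA", "mRNA"), n, replace = TRUE, prob = c(0.4, 0.6))
    if (length(unique(tr)) < 2) next
    sc <- round(runif(n), 2)  # ties on purpose
    expect_equal(roc_auc(tr, sc)$auc, oracle_auc(tr, sc), tolerance = 1e-9)
  }
  # random scores on balanced classes hover around 0.5
  set.seed(417)
  tr <- rep(c("lncRNA", "mRNA"), each = 1000)
  expect_equal(roc_auc(tr, runif(2000))$auc, 0.5, tolerance = 0.05)
})

test_that("pROC agrees with the in-package AUC", {
  skip_if_not_installed("pROC")
  set.seed(418)
  tr <- sample(c("lncRNA", "mRNA"), 200, replace = TRUE)
  sc <- rnorm(200) + (tr == "lncRNA")
  want <- as.numeric(pROC::auc(pROC::roc(response = tr, predictor = sc,
                                         levels = c("mRNA", "lncRNA"),
                                         direction = "<", quiet = TRUE)))
  expect_equal(roc_auc(tr, sc)$auc, want, tolerance = 1e-9)
})

test_that("training is deterministic and prediction is order-invariant", {
  rec <- shared_training_records()
  m1 <- shared_model()
  m2 <- train_model(rec, seed = 5L)
  te <- shared_test_records()
  p1 <- predict(m1, te)
  p2 <- predict(m2, te)
  expect_equal(p1, p2)  # same seed, same data -> identical model behaviour
  expect_identical(xgboost::xgb.save.raw(m1$classifier),
                   xgboost::xgb.save.raw(m2$classifier))
  shuffled <- te[rev(seq_len(nrow(te))), ]
  p3 <- predict(m1, shuffled)
  expect_equal(p3[match(p1$id, p3$id), ]$lncRNA_probability, p1$lncRNA_probability)
})

test_that("a training lncRNA is scored as lncRNA with high probability", {
  rec <- shared_training_records()
  m <- shared_model()
  one <- rec[rec$label == "lncRNA", ][1, ]
  expect_gt(predict(m, one)$lncRNA_probability, 0.5)
})

test_that("tidy and glance expose importance and metadata", {
  m <- shared_model()
  td <- tidy(m)
  expect_setequal(td$feature, feature_schema("top28"))
  expect_true(all(td$gain >= 0))
  gl <- glance(m)
  expect_equal(gl$n_features, 28L)
  expect_equal(gl$n_lncrna, 100L)
  expect_true(gl$with_structure)
})

test_that("model bundles survive a save/load round trip", {
  m <- shared_model()
  dir <- withr::local_tempdir()
  save_model(m, dir)
  expect_true(file.exists(file.path(dir, "manifest.json")))
  m2 <- load_model(dir)
  te <- shared_test_records()
  expect_equal(predict(m2, te), predict(m, te), tolerance = 1e-7)
  expect_equal(m2$features, m$features)
  expect_error(load_model(withr::local_tempdir()), "not a model bundle")
})

test_that("hyperparameter tuning returns a ranked grid", {
  set.seed(419)
  x <- matrix(rnorm(200), ncol = 2, dimnames = list(NULL, c("a", "b")))
  y <- ifelse(x[, 1] + rnorm(100, sd = 0.3) > 0, "lncRNA", "mRNA")
  grid <- expand.grid(nrounds = c(10L, 30L), max_depth = c(2L, 4L), eta = 0.3)
  tuned <- tune_classifier(x, y, grid = grid, folds = 3, seed = 1)
  expect_equal(nrow(tuned), 4L)
  expect_true(all(diff(tuned$cv_accuracy) <= 0))
  expect_true(all(tuned$cv_accuracy > 0.7))
})
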