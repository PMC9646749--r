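#' Train a lncRNA/mRNA classifier
#'
#' Runs the full training pipeline on labelled transcripts: builds the
#' hexamer table from the mRNAs' annotated CDS and the lncRNA sequences,
#' builds the five SASS tables from the records' structures (unless
#' `with_structure = FALSE`), extracts the full feature matrix,
#' standardises it by z-score, balances classes with SMOTE, optionally
#' runs recursive feature elimination, and fits the gradient-boosted tree
#' classifier. Everything needed for prediction is captured in the
#' returned bundle; no training data is retained.
#'
#' @param records A filtered transcript tibble with `label` set on every
#'   row (`"lncRNA"`/`"mRNA"`) and `cds_start`/`cds_end` (0-based
#'   half-open) on every mRNA row. Structures are required unless
#'   `with_structure = FALSE`.
#' @param with_structure Use secondary-structure features?
#' @param subset Feature subset to train on (default `"top28"`, or
#'   `"no_ssf22"` when `with_structure = FALSE`); ignored when
#'   `rfecv = TRUE`.
#' @param rfecv Select the feature subset by recursive feature elimination
#'   with cross-validation instead of a named subset.
#' @param tune Tune `nrounds`/`max_depth`/`eta` by cross-validation over
#'   the default grid of [tune_classifier()] before the final fit.
#' @param nrounds,max_depth,eta XGBoost parameters of the final fit
#'   (overridden by tuning when `tune = TRUE`).
#' @param smote_k SMOTE neighbour count.
#' @param folds Cross-validation folds for tuning/RFECV.
#' @param seed Integer seed; fixed seed and input give an identical model.
#' @param threads Worker processes for feature extraction.
#' @param structure_source Free-text note on where structures came from
#'   (e.g. `"rnafold"` or `"fallback"`), recorded in the bundle metadata.
#' @return An object of class `lnc_model`.
#' @export
train_model <- function(records, with_structure = TRUE, subset = NULL,
                        rfecv = FALSE, tune = FALSE,
                        nrounds = 200L, max_depth = 6L, eta = 0.1,
                        smote_k = 5L, folds = 10L, seed = 1L, threads = 1L,
                        structure_source = "user") {
  stopifnot(is.data.frame(records), nrow(records) > 0L)
  if (anyNA(records$label)) {
    stop("all training records need a label", call. = FALSE)
  }
  classes <- sort(unique(records$label))
  if (!identical(classes, c("lncRNA", "mRNA"))) {
    stop("training needs both classes 'lncRNA' and 'mRNA'; got: ",
         paste(classes, collapse = ", "), call. = FALSE)
  }
  mrna <- records[records$label == "mRNA", , drop = FALSE]
  lnc <- records[records$label == "lncRNA", , drop = FALSE]

  no_cds <- is.na(mrna$cds_start) | is.na(mrna$cds_end)
  if (any(no_cds)) {
    stop("mRNA training record(s) without CDS annotation: ",
         paste(head(mrna$id[no_cds], 5L), collapse = ", "),
         "; the hexamer table requires CDS", call. = FALSE)
  }
  cds_seqs <- substr(mrna$sequence, mrna$cds_start + 1L, mrna$cds_end)
  hexamer_table <- build_hexamer_table(cds_seqs, lnc$sequence)
  sass_tables <- if (with_structure) build_sass_tables(mrna, lnc) else NULL

  if (is.null(subset)) subset <- if (with_structure) "top28" else "no_ssf22"
  feats <- extract_features(records, hexamer_table, sass_tables,
                            subset = "full57", with_structure = with_structure,
                            threads = threads)
  x <- feats[, setdiff(names(feats), "id")]
  scaler <- zscore_fit(x)
  z <- zscore_apply(x, scaler)

  bal <- smote_balance(z, records$label, k_neighbors = smote_k, seed = seed)

  rfecv_trace <- NULL
  if (rfecv) {
    candidates <- if (with_structure) FULL_57 else NO_SSF_FULL()
    sel <- rfecv_select(bal$features[, candidates, drop = FALSE], bal$labels,
                        folds = folds, seed = seed)
    selected <- sel$features
    rfecv_trace <- sel$trace
    subset <- "rfecv"
  } else {
    selected <- feature_schema(subset)
  }

  if (tune) {
    tuned <- tune_classifier(bal$features[, selected, drop = FALSE], bal$labels,
                             folds = folds, seed = seed)
    nrounds <- tuned$nrounds[1]; max_depth <- tuned$max_depth[1]; eta <- tuned$eta[1]
  }

  y <- as.integer(bal$labels == "lncRNA")
  fit <- fit_xgb(as.matrix(bal$features[, selected, drop = FALSE]), y,
                 default_xgb_params(max_depth, eta), nrounds, seed)

  structure(
    list(
      subset = subset,
      features = selected,
      scaler = scaler,
      hexamer_table = hexamer_table,
      sass_tables = sass_tables,
      classifier = fit,
      params = list(nrounds = nrounds, max_depth = max_depth, eta = eta,
                    smote_k = smote_k, seed = seed),
      with_structure = with_structure,
      structure_source = if (with_structure) structure_source else "none",
      class_counts = c(lncRNA = nrow(lnc), mRNA = nrow(mrna)),
      n_synthetic = bal$n_synthetic,
      rfecv_trace = rfecv_trace
    ),
    class = "lnc_model"
  )
}

# full schema restricted to structure-free features (for RFECV without SSFs)
NO_SSF_FULL <- function() setdiff(FULL_57, SSF_FEATURES)

#' @export
print.lnc_model <- function(x, ...) {
  cat("lncRNA/mRNA boosted-tree classifier\n")
  cat(sprintf("  features: %d (%s subset)%s\n", length(x$features), x$subset,
              if (x$with_structure) "" else " [structure-free]"))
  cat(sprintf("  trained on %d lncRNA + %d mRNA (%d synthetic minority rows)\n",
              x$class_counts[["lncRNA"]], x$class_counts[["mRNA"]], x$n_synthetic))
  cat(sprintf("  xgboost: %d rounds, depth %d, eta %g\n",
              x$params$nrounds, x$params$max_depth, x$params$eta))
  invisible(x)
}

#' Predict lncRNA probabilities for new transcripts
#'
#' Applies the bundle's probability tables, feature schema, scaler and
#' classifier to new records. Structure-free bundles ignore any provided
#' structures; structure-using bundles require one per record.
#'
#' @param object An `lnc_model`.
#' @param records A transcript tibble.
#' @param threshold Probability threshold for the label (ties to lncRNA).
#' @param threads Worker processes for feature extraction.
#' @param ... Unused.
#' @return A tibble with `id`, `length`, `predicted_label`,
#'   `lncRNA_probability`, in input order.
#' @export
predict.lnc_model <- function(object, records, threshold = 0.5, threads = 1L, ...) {
  feats <- extract_features(records, object$hexamer_table, object$sass_tables,
                            subset = "full57",
                            with_structure = object$with_structure,
                            threads = threads)
  x <- feats[, setdiff(names(feats), "id")]
  z <- zscore_apply(x, object$scaler)
  m <- as.matrix(z[, object$features, drop = FALSE])
  prob <- if (nrow(m) == 0L) numeric(0) else
    predict(object$classifier, xgboost::xgb.DMatrix(m))
  tibble(
    id = records$id,
    length = nchar(records$sequence),
    predicted_label = ifelse(prob >= threshold, "lncRNA", "mRNA"),
    lncRNA_probability = as.numeric(prob)
  )
}

#' Evaluate predictions against true labels
#'
#' @param truth Character vector of true labels.
#' @param probabilities lncRNA probabilities.
#' @param threshold Label threshold.
#' @return A list with `metrics` ([compute_metrics()]) and `roc`
#'   ([roc_auc()]).
#' @export
evaluate_predictions <- function(truth, probabilities, threshold = 0.5) {
  predicted <- ifelse(probabilities >= threshold, "lncRNA", "mRNA")
  list(metrics = compute_metrics(truth, predicted),
       roc = roc_auc(truth, probabilities))
}

#' Persist a trained model bundle to a directory
#'
#' Writes a self-contained bundle: a JSON manifest (format version, feature
#' subset, scaler-free metadata), the scaler and probability tables as TSV,
#' and the classifier in XGBoost's JSON format. No training data is
#' embedded.
#'
#' @param model An `lnc_model`.
#' @param dir Target directory (created if needed).
#' @return Invisibly, `dir`.
#' @export
save_model <- function(model, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(
    format_version = 1L,
    package = "lncsieve",
    subset = model$subset,
    features = model$features,
    params = model$params,
    with_structure = model$with_structure,
    structure_source = model$structure_source,
    class_counts = as.list(model$class_counts),
    n_synthetic = model$n_synthetic
  )
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  readr::write_tsv(model$scaler, file.path(dir, "scaler.tsv"))
  readr::write_tsv(model$hexamer_table, file.path(dir, "hexamer.tsv"))
  if (model$with_structure) {
    for (k in names(model$sass_tables)) {
      readr::write_tsv(model$sass_tables[[k]], file.path(dir, paste0("sass_", k, ".tsv")))
    }
  }
  xgboost::xgb.save(model$classifier, file.path(dir, "classifier.json"))
  invisible(dir)
}

#' Load a model bundle written by [save_model()]
#'
#' @param dir Bundle directory.
#' @return An `lnc_model`.
#' @export
load_model <- function(dir) {
  manifest_path <- file.path(dir, "manifest.json")
  if (!file.exists(manifest_path)) {
    stop("not a model bundle: missing ", manifest_path, call. = FALSE)
  }
  manifest <- jsonlite::read_json(manifest_path, simplifyVector = TRUE)
  if (is.null(manifest$format_version) || manifest$format_version != 1L) {
    stop("unsupported bundle format version: ", manifest$format_version, call. = FALSE)
  }
  tsv <- function(name, types) readr::read_tsv(file.path(dir, name), col_types = types)
  sass_tables <- NULL
  if (isTRUE(manifest$with_structure)) {
    sass_tables <- lapply(paste0("k", 1:5), function(k) {
      tsv(paste0("sass_", k, ".tsv"), "cdd")
    })
    names(sass_tables) <- paste0("k", 1:5)
  }
  structure(
    list(
      subset = manifest$subset,
      features = manifest$features,
      scaler = tsv("scaler.tsv", "cdd"),
      hexamer_table = tsv("hexamer.tsv", "cdd"),
      sass_tables = sass_tables,
      classifier = xgboost::xgb.load(file.path(dir, "classifier.json")),
      params = manifest$params,
      with_structure = isTRUE(manifest$with_structure),
      structure_source = manifest$structure_source,
      class_counts = unlist(manifest$class_counts),
      n_synthetic = manifest$n_synthetic,
      rfecv_trace = NULL
    ),
    class = "lnc_model"
  )
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a fitted model: per-feature importance
#'
#' @param x An `lnc_model`.
#' @param ... Unused.
#' @return A tibble with `feature`, `gain`, `cover`, `frequency`, sorted by
#'   gain; selected features with zero importance are included.
#' @export
tidy.lnc_model <- function(x, ...) {
  imp <- xgboost::xgb.importance(model = x$classifier)
  out <- tibble(feature = x$features) |>
    dplyr::left_join(
      tibble(feature = imp$Feature, gain = imp$Gain,
             cover = imp$Cover, frequency = imp$Frequency),
      by = "feature"
    ) |>
    dplyr::mutate(dplyr::across(c("gain", "cover", "frequency"),
                                ~ ifelse(is.na(.x), 0, .x))) |>
    dplyr::arrange(dplyr::desc(.data$gain))
  out
}

#' Glance at a fitted model
#'
#' @param x An `lnc_model`.
#' @param ... Unused.
#' @return A one-row tibble of training metadata.
#' @export
glance.lnc_model <- function(x, ...) {
  tibble(
    n_lncrna = x$class_counts[["lncRNA"]],
    n_mrna = x$class_counts[["mRNA"]],
    n_synthetic = x$n_synthetic,
    n_features = length(x$features),
    subset = x$subset,
    with_structure = x$with_structure,
    nrounds = x$params$nrounds,
    max_depth = x$params$max_depth,
    eta = x$params$eta
  )
}

#' Tidy a metrics report
#'
#' @param x An `lnc_metrics`.
#' @param ... Unused.
#' @return A one-row tibble of counts and metrics.
#' @export
tidy.lnc_metrics <- function(x, ...) {
  as_tibble(x[c("tp", "fp", "tn", "fn", "sensitivity", "specificity",
                "precision", "accuracy", "f_score", "mcc")])
}
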