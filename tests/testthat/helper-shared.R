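# Small shared fixtures built once per test session (memoised in this
# environment) so several test files can reuse the same trained model.

.shared <- new.env(parent = emptyenv())

shared_training_records <- function() {
  if (is.null(.shared$train)) {
    .shared$train <- generate_transcripts(n_mrna = 100L, n_lncrna = 100L, seed = 101L)
  }
  .shared$train
}

shared_test_records <- function() {
  if (is.null(.shared$test)) {
    .shared$test <- generate_transcripts(n_mrna = 60L, n_lncrna = 60L, seed = 202L)
  }
  .shared$test
}

shared_model <- function() {
  if (is.null(.shared$model)) {
    .shared$model <- train_model(shared_training_records(), seed = 5L)
  }
  .shared$model
}

shared_tables <- function() {
  if (is.null(.shared$tables)) {
    rec <- shared_training_records()
    mrna <- rec[rec$label == "mRNA", ]
    lnc <- rec[rec$label == "lncRNA", ]
    cds <- substr(mrna$sequence, mrna$cds_start + 1, mrna$cds_end)
    .shared$tables <- list(
      hexamer = build_hexamer_table(cds, lnc$sequence),
      sass = build_sass_tables(mrna, lnc)
    )
  }
  .shared$tables
}
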