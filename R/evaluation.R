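#' Tally a confusion table
#'
#' Rows are true classes, columns predicted classes. The predicted-class list
#' may contain classes absent from the truth (e.g. a training class missing
#' from the test set), yielding columns with no matching row.
#'
#' @param true_labels,predicted_labels Equal-length character vectors.
#' @param classes_true,classes_pred Class orders; default to the sorted
#'   distinct labels of each vector.
#' @return An object of class `confusion_table`: list with `counts`
#'   (|true| x |pred| integer matrix, dimnames set), `classes_true`,
#'   `classes_pred`.
#' @export
confusion_table <- function(true_labels, predicted_labels,
                            classes_true = NULL, classes_pred = NULL) {
  if (length(true_labels) != length(predicted_labels)) {
    stop("confusion_table: label vectors differ in length")
  }
  if (is.null(classes_true)) classes_true <- sort(unique(true_labels))
  if (is.null(classes_pred)) classes_pred <- sort(unique(c(classes_true, predicted_labels)))
  if (!all(true_labels %in% classes_true)) {
    stop("confusion_table: true label outside the class order")
  }
  if (!all(predicted_labels %in% classes_pred)) {
    stop("confusion_table: predicted label outside the class order")
  }
  counts <- table(
    factor(true_labels, levels = classes_true),
    factor(predicted_labels, levels = classes_pred)
  )
  counts <- matrix(as.integer(counts),
    nrow = length(classes_true),
    dimnames = list(classes_true, classes_pred)
  )
  structure(
    list(counts = counts, classes_true = classes_true, classes_pred = classes_pred),
    class = "confusion_table"
  )
}

#' Build a confusion table directly from per-class totals and correct counts
#'
#' Convenience constructor for worked examples where only class sizes N_i and
#' correct counts C_i are known: off-diagonal errors are pooled into an
#' `"other"` column (they do not affect micro/macro accuracy).
#'
#' @param classes Class names.
#' @param n_per_class Class sizes N_i.
#' @param correct Correct counts C_i.
#' @return A `confusion_table`.
#' @export
confusion_from_counts <- function(classes, n_per_class, correct) {
  stopifnot(
    length(classes) == length(n_per_class),
    length(classes) == length(correct), all(correct <= n_per_class)
  )
  counts <- matrix(0L,
    nrow = length(classes), ncol = length(classes) + 1,
    dimnames = list(classes, c(classes, "other"))
  )
  for (i in seq_along(classes)) {
    counts[i, i] <- as.integer(correct[i])
    counts[i, length(classes) + 1] <- as.integer(n_per_class[i] - correct[i])
  }
  structure(
    list(
      counts = counts, classes_true = classes,
      classes_pred = c(classes, "other")
    ),
    class = "confusion_table"
  )
}

#' @export
print.confusion_table <- function(x, ...) {
  cat("<confusion_table>\n")
  print(x$counts)
  cat(sprintf(
    "micro = %.2f%%, macro = %.2f%%\n",
    micro_accuracy(x), macro_accuracy(x)
  ))
  invisible(x)
}

# diagonal correct counts C_i (0 for true classes missing from predictions)
correct_counts <- function(ct) {
  vapply(seq_along(ct$classes_true), function(i) {
    j <- match(ct$classes_true[i], ct$classes_pred)
    if (is.na(j)) 0L else ct$counts[i, j]
  }, 0L)
}

#' Micro-accuracy (percent)
#'
#' The pooled fraction correct, `100 * sum(C_i) / sum(N_i)`; weights classes
#' by their size.
#'
#' @param ct A [confusion_table()].
#' @return Percentage in `[0, 100]`.
#' @export
micro_accuracy <- function(ct) {
  total <- sum(ct$counts)
  if (total == 0) stop("micro_accuracy: empty confusion table")
  100 * sum(correct_counts(ct)) / total
}

#' Macro-accuracy (percent)
#'
#' The unweighted mean of per-class accuracies, `100 * mean(C_i / N_i)`;
#' gives every class equal weight. Equals micro-accuracy when class sizes are
#' balanced.
#'
#' @param ct A [confusion_table()].
#' @return Percentage in `[0, 100]`.
#' @export
macro_accuracy <- function(ct) {
  n_i <- rowSums(ct$counts)
  if (any(n_i == 0)) stop("macro_accuracy: a true class has no samples")
  100 * mean(correct_counts(ct) / n_i)
}

#' Per-class accuracies (percent)
#'
#' @param ct A [confusion_table()].
#' @return Named numeric vector, one entry per true class.
#' @export
per_class_accuracy <- function(ct) {
  n_i <- rowSums(ct$counts)
  setNames(100 * correct_counts(ct) / n_i, ct$classes_true)
}

new_experiment_result <- function(ct, metadata = list()) {
  structure(
    list(
      confusion = ct,
      per_class_accuracy = per_class_accuracy(ct),
      micro = micro_accuracy(ct),
      macro = macro_accuracy(ct),
      metadata = metadata
    ),
    class = "experiment_result"
  )
}

#' @export
print.experiment_result <- function(x, ...) {
  cat("<experiment_result>\n")
  print(x$confusion$counts)
  cat("per-class accuracy (%):\n")
  print(round(x$per_class_accuracy, 2))
  cat(sprintf("micro = %.2f%%, macro = %.2f%%\n", x$micro, x$macro))
  invisible(x)
}

#' K-fold cross-validation of a full pipeline
#'
#' Splits the labelled dataset into folds (stratified by class by default; an
#' unstratified plain random split is available), and for each fold rebuilds
#' the entire pipeline on the remaining folds: feature space from the training
#' part only, binary encoding, PCA with the dimension re-selected on the
#' training part, classifier with hyperparameters re-tuned on the training
#' part (per the `spec`). Held-out predictions are pooled into a single
#' confusion table.
#'
#' @param dataset A labelled [profile_dataset()]; every class needs at least
#'   `folds` samples.
#' @param spec A [pipeline_spec()].
#' @param folds Number of folds (default 5).
#' @param seed Integer seed for the fold split and inner selections.
#' @param stratified Stratify folds by class (default TRUE).
#' @return An `experiment_result`.
#' @export
cross_validate <- function(dataset, spec, folds = 5, seed = 1, stratified = TRUE) {
  labels <- dataset_labels(dataset)
  if (any(is.na(labels))) stop("cross_validate: dataset contains unlabelled samples")
  tab <- table(labels)
  if (any(tab < folds)) {
    stop(sprintf(
      "cross_validate: class '%s' has fewer samples than folds",
      names(tab)[tab < folds][1]
    ))
  }
  fold_id <- make_folds(labels, folds, seed, stratified = stratified)
  truth <- character(0)
  preds <- character(0)
  for (f in seq_len(folds)) {
    train <- dataset_subset(dataset, fold_id != f)
    test <- dataset_subset(dataset, fold_id == f)
    space <- suppressWarnings(build_feature_space(train))
    X_train <- suppressMessages(encode_binary(train, space))
    X_test <- suppressMessages(encode_binary(test, space))
    model <- fit_pipeline(X_train, dataset_labels(train), spec, seed = seed + f)
    preds <- c(preds, predict_pipeline(model, X_test))
    truth <- c(truth, dataset_labels(test))
  }
  ct <- confusion_table(truth, preds,
    classes_true = dataset$label_universe,
    classes_pred = dataset$label_universe
  )
  new_experiment_result(ct, metadata = list(
    folds = folds, seed = seed, stratified = stratified, spec = spec
  ))
}

#' Independent-test evaluation under a missing-data strategy
#'
#' Fits on `train` and evaluates on `test` under one of four encodings:
#' `plain` and `rcrs` (binary encoding; untyped positions read as reference),
#' `probability` (binary indicators plus 1122 per-position variables holding
#' the training polymorphism rate where untyped), and `common_region` (the
#' training features are restricted to each test sample's typed region and a
#' fresh PCA + classifier is fitted per distinct region signature, cached).
#' The confusion table uses the training label universe as predicted classes
#' and the test label universe as true classes, so a training class absent
#' from the test set appears as a column without a row.
#'
#' @param train,test Labelled [profile_dataset()]s.
#' @param strategy One of `"plain"`, `"rcrs"`, `"probability"`,
#'   `"common_region"`.
#' @param spec A [pipeline_spec()].
#' @param seed Integer seed for inner selections.
#' @param min_overlap Passed to [restrict_to_common_region()].
#' @return An `experiment_result`; for `common_region`, unclassifiable test
#'   samples (no feature overlap) are excluded from the counts and listed in
#'   `metadata$unclassifiable`.
#' @export
holdout_evaluate <- function(train, test,
                             strategy = c("plain", "rcrs", "probability", "common_region"),
                             spec = pipeline_spec("svm"), seed = 1,
                             min_overlap = 0) {
  strategy <- match.arg(strategy)
  if (length(train$label_universe) < 2) {
    stop("holdout_evaluate: training set needs at least two classes")
  }
  y_train <- dataset_labels(train)
  truth <- dataset_labels(test)
  meta <- list(strategy = strategy, seed = seed, spec = spec)

  if (strategy %in% c("plain", "rcrs")) {
    space <- build_feature_space(train)
    model <- fit_pipeline(encode_binary(train, space), y_train, spec, seed = seed)
    preds <- predict_pipeline(model, suppressMessages(encode_binary(test, space)))
    meta$settings <- model$settings
  } else if (strategy == "probability") {
    space <- build_feature_space(train)
    rates <- position_rates(train)
    model <- fit_pipeline(
      encode_probability(train, space, rates), y_train, spec,
      seed = seed
    )
    preds <- predict_pipeline(
      model, suppressMessages(encode_probability(test, space, rates))
    )
    meta$settings <- model$settings
  } else {
    sigs <- vapply(test$samples, function(s) region_signature(s$typed), "")
    preds <- rep(NA_character_, length(test$samples))
    for (sig in unique(sigs)) {
      idx <- which(sigs == sig)
      rep_sample <- test$samples[[idx[1]]]
      restricted <- tryCatch(
        restrict_to_common_region(rep_sample, train, min_overlap = min_overlap),
        error = function(e) NULL
      )
      if (is.null(restricted)) next # whole signature group unclassifiable
      model <- fit_pipeline(restricted$train, y_train, spec, seed = seed)
      test_mat <- suppressMessages(
        encode_binary(dataset_subset(test, idx), restricted$space)
      )
      preds[idx] <- predict_pipeline(model, test_mat)
    }
    bad <- is.na(preds)
    if (any(bad)) {
      meta$unclassifiable <- dataset_ids(test)[bad]
      message(sprintf(
        "holdout_evaluate: %d test samples unclassifiable under common_region",
        sum(bad)
      ))
      truth <- truth[!bad]
      preds <- preds[!bad]
    }
  }
  ct <- confusion_table(truth, preds,
    classes_true = test$label_universe,
    classes_pred = sort(unique(c(train$label_universe, test$label_universe)))
  )
  new_experiment_result(ct, metadata = meta)
}
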