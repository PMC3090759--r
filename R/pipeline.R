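#' Describe a classification pipeline
#'
#' A pipeline couples one of the four classifiers with its preprocessing and
#' hyperparameter policy. PCA precedes the SVM and the Gaussian classifiers
#' but never 1NN (Hamming distance lives on the binary encoding). The retained
#' PCA dimension k and, for the SVM, (C, gamma) are selected by
#' cross-validation on the training part when `tune = TRUE`; with
#' `tune = FALSE` the fixed values are used as given.
#'
#' @param classifier One of `"svm"`, `"lda"`, `"qda"`, `"nn1"`, or
#'   `"majority"` (a trivial largest-class baseline used for sanity anchors).
#' @param use_pca Apply PCA? Defaults to TRUE for svm/lda/qda, forced FALSE
#'   for nn1 and majority.
#' @param k Fixed PCA dimension when `tune = FALSE` (NULL: all axes).
#' @param k_candidates Candidate dimensions for [select_k()]; NULL uses its
#'   default grid.
#' @param C,gamma Fixed SVM hyperparameters when `tune = FALSE`
#'   (gamma NULL: 1/n).
#' @param C_grid,gamma_grid Tuning grids for [tune_svm()].
#' @param tune Re-select k (and C, gamma for the SVM) on each training part?
#' @param tune_folds Folds for the inner selection loops.
#' @param regularization Ridge for the Gaussian classifiers (NULL: automatic).
#' @param priors Prior policy for the Gaussian classifiers.
#' @return An object of class `pipeline_spec`.
#' @export
pipeline_spec <- function(classifier = c("svm", "lda", "qda", "nn1", "majority"),
                          use_pca = NULL, k = NULL, k_candidates = NULL,
                          C = 1, gamma = NULL,
                          C_grid = 2^seq(-5, 15, by = 2),
                          gamma_grid = 2^seq(-15, 3, by = 2),
                          tune = FALSE, tune_folds = 5,
                          regularization = NULL,
                          priors = c("empirical", "uniform")) {
  classifier <- match.arg(classifier)
  priors <- match.arg(priors)
  if (classifier %in% c("nn1", "majority")) {
    use_pca <- FALSE
  } else if (is.null(use_pca)) {
    use_pca <- TRUE
  }
  structure(
    list(
      classifier = classifier, use_pca = use_pca, k = k,
      k_candidates = k_candidates, C = C, gamma = gamma,
      C_grid = C_grid, gamma_grid = gamma_grid, tune = tune,
      tune_folds = tune_folds, regularization = regularization,
      priors = priors
    ),
    class = "pipeline_spec"
  )
}

#' @export
print.pipeline_spec <- function(x, ...) {
  cat(sprintf(
    "<pipeline_spec> %s%s, tune = %s\n",
    if (x$use_pca) "PCA-" else "", toupper(x$classifier), x$tune
  ))
  invisible(x)
}

# fit the bare classifier on an already-projected matrix
fit_classifier <- function(X, y, spec) {
  switch(spec$classifier,
    svm = train_svm(X, y, C = spec$C, gamma = spec$gamma),
    lda = train_gaussian(X, y,
      shared_covariance = TRUE,
      regularization = spec$regularization, priors = spec$priors
    ),
    qda = train_gaussian(X, y,
      shared_covariance = FALSE,
      regularization = spec$regularization, priors = spec$priors
    ),
    nn1 = nn_reference(X, y),
    majority = {
      tab <- table(y)
      structure(
        list(label = names(tab)[which.max(tab)]),
        class = "majority_model"
      )
    }
  )
}

predict_classifier <- function(model, X) {
  if (inherits(model, "svm_model")) {
    return(predict_svm(model, X))
  }
  if (inherits(model, "gaussian_model")) {
    return(predict_gaussian(model, X)$labels)
  }
  if (inherits(model, "nn_reference")) {
    return(predict_1nn(model, X))
  }
  if (inherits(model, "majority_model")) {
    return(rep(model$label, nrow(as_matrix_values(X))))
  }
  stop("unknown classifier model")
}

#' Fit a full pipeline on encoded training data
#'
#' Optionally selects the PCA dimension and SVM hyperparameters by
#' cross-validation on the training data, then fits PCA (if used) and the
#' classifier. Degenerate inputs with zero feature columns fall back to the
#' majority-class baseline.
#'
#' @param x Training `feature_matrix` or numeric matrix.
#' @param y Training labels.
#' @param spec A [pipeline_spec()].
#' @param seed Seed for the inner selection splits.
#' @return An object of class `pipeline_model` (serializable with
#'   [save_model()]).
#' @export
fit_pipeline <- function(x, y, spec, seed = 1) {
  X <- as_matrix_values(x)
  y <- as.character(y)
  if (ncol(X) == 0 || length(unique(y)) < 2) {
    tab <- table(y)
    return(structure(
      list(
        spec = spec, pca = NULL, k = 0L, n = ncol(X),
        model = structure(list(label = names(tab)[which.max(tab)]),
          class = "majority_model"
        ),
        settings = list(degenerate = TRUE)
      ),
      class = "pipeline_model"
    ))
  }
  settings <- list()
  pca <- NULL
  k <- NULL
  Xp <- X
  if (spec$use_pca) {
    work <- spec
    if (spec$classifier == "svm" && spec$tune) {
      # joint re-tuning is quadratic in grid size; select k at the fixed
      # (C, gamma), then tune (C, gamma) at the selected k
      work$tune <- FALSE
    }
    if (spec$tune || is.null(spec$k)) {
      k <- select_k(X, y, work,
        folds = spec$tune_folds,
        candidates = spec$k_candidates, seed = seed
      )
    } else {
      k <- min(spec$k, ncol(X), nrow(X) - 1)
    }
    pca <- fit_pca(X)
    k <- min(k, ncol(pca$axes))
    Xp <- pca_transform(pca, X, k)
    settings$k <- k
  }
  if (spec$classifier == "svm" && spec$tune) {
    tuned <- tune_svm(Xp, y,
      C_grid = spec$C_grid, gamma_grid = spec$gamma_grid,
      folds = spec$tune_folds, seed = seed
    )
    spec$C <- tuned$C
    spec$gamma <- tuned$gamma
    settings$C <- tuned$C
    settings$gamma <- tuned$gamma
  }
  model <- fit_classifier(Xp, y, spec)
  structure(
    list(spec = spec, pca = pca, k = k, n = ncol(X), model = model, settings = settings),
    class = "pipeline_model"
  )
}

#' Predict with a fitted pipeline
#'
#' @param model A [fit_pipeline()] result.
#' @param x Matrix or `feature_matrix` with the training width.
#' @return Character vector of predicted labels.
#' @export
predict_pipeline <- function(model, x) {
  X <- as_matrix_values(x)
  if (!is.null(model$pca)) {
    X <- pca_transform(model$pca, X, model$k)
  }
  predict_classifier(model$model, X)
}

#' Serialize / restore fitted models
#'
#' Models (PCA, classifiers, pipelines) are plain R lists and are stored with
#' `saveRDS`; these helpers exist so CLI commands can pass models between
#' invocations.
#'
#' @param model Any fitted model object from this package.
#' @param path Destination file.
#' @return `path` invisibly; `load_model` returns the restored object.
#' @export
save_model <- function(model, path) {
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) readRDS(path)

#' Stratified fold assignment
#'
#' Assigns samples to `folds` cross-validation folds. With `stratified = TRUE`
#' (default) samples are dealt class by class into the currently smallest
#' folds, so per-class counts differ by at most 1 between folds and total fold
#' sizes also differ by at most 1. Unstratified assignment is a plain random
#' split with sizes differing by at most 1.
#'
#' @param labels Class labels (used only when stratified).
#' @param folds Number of folds.
#' @param seed Integer seed.
#' @param stratified Stratify by class?
#' @return Integer vector of fold ids in `1:folds`.
#' @export
make_folds <- function(labels, folds, seed = 1, stratified = TRUE) {
  m <- length(labels)
  if (folds < 2) stop("make_folds: folds must be >= 2")
  if (m < folds) stop("make_folds: fewer samples than folds")
  with_seed(seed, {
    fold_id <- integer(m)
    if (!stratified) {
      sizes <- rep(m %/% folds, folds) + (seq_len(folds) <= m %% folds)
      fold_id[sample.int(m)] <- rep(seq_len(folds), times = sizes)
    } else {
      fill <- integer(folds)
      for (g in unique(labels)) {
        idx <- which(labels == g)
        if (length(idx) > 1) idx <- sample(idx)
        for (i in idx) {
          f <- order(fill, sample.int(folds))[1] # random tie-break among smallest
          fold_id[i] <- f
          fill[f] <- fill[f] + 1L
        }
      }
    }
    fold_id
  })
}

# evaluate code under a fixed RNG seed, restoring the caller's RNG state
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, globalenv())
    } else if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  code
}
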