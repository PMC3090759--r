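#' Fit principal component analysis
#'
#' Centres columns by their training means and eigendecomposes the 1/(m-1)
#' sample covariance. Axes (columns of the orthogonal matrix P) are ordered by
#' decreasing eigenvalue and sign-fixed so each axis's largest-magnitude
#' component is positive, making the decomposition deterministic. Zero-variance
#' columns are retained and yield zero eigenvalues. When n > m the
#' decomposition is computed through the m x m Gram matrix; in that case only
#' the min(m, n) data-supported axes are returned (the remainder of the
#' nullspace carries eigenvalue 0 and is never selected).
#'
#' @param x A `feature_matrix` or plain numeric matrix with m >= 2 rows.
#' @return An object of class `pca_model`: list with `means`, `axes`
#'   (n x r, orthonormal columns), `eigenvalues` (length r, non-increasing)
#'   and `n` (original width).
#' @export
fit_pca <- function(x) {
  X <- as_matrix_values(x)
  m <- nrow(X)
  n <- ncol(X)
  if (m < 2) stop("fit_pca: at least 2 samples required")
  means <- colMeans(X)
  Xc <- sweep(X, 2, means, "-")
  if (n <= m) {
    S <- crossprod(Xc) / (m - 1)
    e <- eigen(S, symmetric = TRUE)
    axes <- e$vectors
    eigenvalues <- pmax(e$values, 0)
  } else {
    G <- tcrossprod(Xc) / (m - 1)
    e <- eigen(G, symmetric = TRUE)
    lam <- pmax(e$values, 0)
    keep <- lam > max(lam[1], 1) * 1e-12
    # always keep at least one axis even for constant data
    if (!any(keep)) keep[1] <- TRUE
    U <- e$vectors[, keep, drop = FALSE]
    lam_k <- lam[keep]
    axes <- crossprod(Xc, U)
    scale <- sqrt(pmax(lam_k * (m - 1), .Machine$double.eps))
    axes <- sweep(axes, 2, scale, "/")
    eigenvalues <- lam_k
  }
  axes <- fix_axis_signs(axes)
  structure(
    list(means = means, axes = axes, eigenvalues = eigenvalues, n = n),
    class = "pca_model"
  )
}

#' @export
print.pca_model <- function(x, ...) {
  cat(sprintf(
    "<pca_model> n = %d variables, %d axes; leading eigenvalue %.4g\n",
    x$n, ncol(x$axes), x$eigenvalues[1]
  ))
  invisible(x)
}

# orient each column so its largest-magnitude entry is positive
fix_axis_signs <- function(axes) {
  for (j in seq_len(ncol(axes))) {
    i <- which.max(abs(axes[, j]))
    if (axes[i, j] < 0) axes[, j] <- -axes[, j]
  }
  axes
}

as_matrix_values <- function(x) {
  if (inherits(x, "feature_matrix")) {
    return(x$values)
  }
  as.matrix(x)
}

#' Project data onto the leading principal axes
#'
#' Computes Y = (X - means) P truncated to the k leading columns (the axes of
#' largest training variance).
#'
#' @param model A [fit_pca()] result.
#' @param x Matrix or `feature_matrix` with the model's original width.
#' @param k Number of leading axes to keep (defaults to all available).
#' @return An m x k numeric matrix.
#' @export
pca_transform <- function(model, x, k = ncol(model$axes)) {
  X <- as_matrix_values(x)
  if (ncol(X) != model$n) {
    stop(sprintf(
      "pca_transform: input width %d does not match model width %d",
      ncol(X), model$n
    ))
  }
  if (k < 1 || k > ncol(model$axes)) {
    stop(sprintf("pca_transform: k must lie in [1, %d]", ncol(model$axes)))
  }
  sweep(X, 2, model$means, "-") %*% model$axes[, seq_len(k), drop = FALSE]
}

#' Select the retained PCA dimension by cross-validation
#'
#' For each candidate k, fits the supplied classifier on the k-dimensional
#' projection within each training fold and scores the held-out fold;
#' returns the candidate with the highest mean micro-accuracy, ties broken
#' toward smaller k.
#'
#' @param x Matrix or `feature_matrix` of training samples.
#' @param labels Character vector of training labels.
#' @param classifier_spec A [pipeline_spec()] naming the classifier and its
#'   (fixed) hyperparameters; PCA settings inside it are ignored here.
#' @param folds Number of cross-validation folds (default 5).
#' @param candidates Candidate dimensions; defaults to
#'   {1, 2, 5, 10, 20, 50, 100, 150, 200} intersected with the feasible range.
#' @param seed Integer seed for the fold split.
#' @param stratified Stratify folds by class (default TRUE).
#' @return The selected k (integer).
#' @export
select_k <- function(x, labels, classifier_spec, folds = 5,
                     candidates = NULL, seed = 1, stratified = TRUE) {
  X <- as_matrix_values(x)
  m <- nrow(X)
  if (m < folds) stop("select_k: fewer samples than folds")
  max_k <- min(m - 1, ncol(X))
  if (is.null(candidates)) {
    candidates <- default_k_candidates(max_k)
  }
  candidates <- sort(unique(as.integer(candidates)))
  if (length(candidates) == 0 || any(candidates < 1)) {
    stop("select_k: candidates must be positive integers")
  }
  if (any(candidates > ncol(X))) stop("select_k: candidate exceeds variable count")
  if (length(candidates) == 1) {
    return(candidates)
  }
  fold_id <- make_folds(labels, folds, seed, stratified = stratified)
  acc <- matrix(NA_real_, nrow = folds, ncol = length(candidates))
  for (f in seq_len(folds)) {
    tr <- fold_id != f
    te <- !tr
    pca <- fit_pca(X[tr, , drop = FALSE])
    usable <- candidates[candidates <= ncol(pca$axes)]
    proj_tr <- pca_transform(pca, X[tr, , drop = FALSE], max(usable))
    proj_te <- pca_transform(pca, X[te, , drop = FALSE], max(usable))
    for (ci in seq_along(candidates)) {
      kk <- candidates[ci]
      if (!(kk %in% usable)) next
      model <- fit_classifier(
        proj_tr[, seq_len(kk), drop = FALSE], labels[tr], classifier_spec
      )
      pred <- predict_classifier(model, proj_te[, seq_len(kk), drop = FALSE])
      acc[f, ci] <- mean(pred == labels[te])
    }
  }
  mean_acc <- colMeans(acc, na.rm = TRUE)
  mean_acc[is.nan(mean_acc)] <- -Inf
  candidates[which.max(mean_acc)] # ties go to the smallest k (sorted order)
}

default_k_candidates <- function(max_k) {
  cand <- c(1L, 2L, 5L, 10L, 20L, 50L, 100L, 150L, 200L)
  cand <- cand[cand <= max_k]
  if (length(cand) == 0) cand <- max(1L, max_k)
  cand
}
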