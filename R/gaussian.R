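#' Train a Gaussian (linear/quadratic discriminant) classifier
#'
#' Models each class as a multivariate normal with mean mu_g and covariance
#' Sigma_g (QDA) or a covariance pooled across classes (LDA,
#' `shared_covariance = TRUE`). Priors pi_g are the empirical class
#' frequencies by default. A ridge `regularization` is added to covariance
#' diagonals so near-singular scatter (common with sparse binary features)
#' stays invertible; the default scales with the mean diagonal.
#'
#' @param x Numeric matrix or `feature_matrix`.
#' @param y Class labels; every class needs at least 2 samples.
#' @param shared_covariance Pool the covariance across classes (LDA)?
#' @param regularization Ridge added to covariance diagonals; `NULL` (default)
#'   uses `1e-6 * mean(diag(Sigma))` with an absolute floor of `1e-8`.
#' @param priors `"empirical"` (class frequencies) or `"uniform"`.
#' @return An object of class `gaussian_model`.
#' @export
train_gaussian <- function(x, y, shared_covariance = FALSE,
                           regularization = NULL,
                           priors = c("empirical", "uniform")) {
  priors <- match.arg(priors)
  X <- as_matrix_values(x)
  y <- as.character(y)
  stopifnot(nrow(X) == length(y))
  classes <- sort(unique(y))
  if (length(classes) < 2) stop("train_gaussian: at least two classes required")
  counts <- table(factor(y, levels = classes))
  if (any(counts < 2)) {
    stop(sprintf(
      "train_gaussian: class '%s' has fewer than 2 samples",
      names(counts)[counts < 2][1]
    ))
  }
  n <- ncol(X)
  means <- lapply(classes, function(g) colMeans(X[y == g, , drop = FALSE]))
  covs <- lapply(classes, function(g) stats::cov(X[y == g, , drop = FALSE]))
  if (shared_covariance) {
    pooled <- matrix(0, n, n)
    for (i in seq_along(classes)) {
      pooled <- pooled + (counts[i] - 1) * covs[[i]]
    }
    pooled <- pooled / (nrow(X) - length(classes))
    covs <- rep(list(pooled), length(classes))
  }
  covs <- lapply(covs, function(S) {
    eps <- if (is.null(regularization)) {
      max(1e-6 * mean(diag(S)), 1e-8)
    } else {
      regularization
    }
    S + diag(eps, n)
  })
  pi_g <- if (priors == "empirical") {
    as.numeric(counts) / nrow(X)
  } else {
    rep(1 / length(classes), length(classes))
  }
  structure(
    list(
      classes = classes, means = means, covariances = covs,
      priors = pi_g, shared = shared_covariance, n = n
    ),
    class = "gaussian_model"
  )
}

#' @export
print.gaussian_model <- function(x, ...) {
  cat(sprintf(
    "<gaussian_model> %s, %d classes (%s)\n",
    if (x$shared) "shared covariance (LDA)" else "per-class covariance (QDA)",
    length(x$classes), paste(x$classes, collapse = ", ")
  ))
  invisible(x)
}

#' Predict with a Gaussian classifier
#'
#' Computes log posterior log pi_g + log N(t; mu_g, Sigma_g) per class in log
#' space (via Cholesky factors), normalises, and assigns the argmax class.
#'
#' @param model A [train_gaussian()] result.
#' @param x Matrix (or `feature_matrix`) of test rows.
#' @return List with `labels` (character) and `posteriors` (m x K matrix,
#'   rows summing to 1, columns named by class).
#' @export
predict_gaussian <- function(model, x) {
  T <- as_matrix_values(x)
  if (ncol(T) != model$n) {
    stop(sprintf(
      "predict_gaussian: input width %d does not match model width %d",
      ncol(T), model$n
    ))
  }
  K <- length(model$classes)
  loglik <- matrix(0, nrow = nrow(T), ncol = K)
  for (g in seq_len(K)) {
    S <- model$covariances[[g]]
    R <- tryCatch(chol(S), error = function(e) {
      stop(paste(
        "predict_gaussian: singular class covariance;",
        "increase the ridge regularization in train_gaussian"
      ))
    })
    logdet <- 2 * sum(log(diag(R)))
    centred <- sweep(T, 2, model$means[[g]], "-")
    # Mahalanobis via triangular solve: |R^-T d|^2
    z <- backsolve(R, t(centred), transpose = TRUE)
    maha <- colSums(z^2)
    loglik[, g] <- -0.5 * (model$n * log(2 * pi) + logdet + maha) +
      log(model$priors[g])
  }
  shift <- apply(loglik, 1, max)
  post <- exp(loglik - shift)
  post <- post / rowSums(post)
  colnames(post) <- model$classes
  list(
    labels = model$classes[apply(loglik, 1, which.max)],
    posteriors = post
  )
}
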