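rbf_kernel <- function(A, B, gamma) {
  exp(-gamma * row_sq_dist(A, B))
}

#' Train a soft-margin RBF-kernel SVM (one-against-one multiclass)
#'
#' For every unordered class pair, solves the soft-margin maximum-margin dual
#' (box constraints 0 <= alpha_i <= C, equality constraint sum alpha_i y_i = 0)
#' by sequential minimal optimization on the radial-basis kernel
#' K(x1, x2) = exp(-gamma |x1 - x2|^2). Multiclass prediction is by
#' one-against-one voting; vote ties are broken toward the class earliest in
#' the (sorted) class list.
#'
#' @param x Numeric matrix or `feature_matrix` of training samples.
#' @param y Character vector of class labels (at least 2 classes, each with
#'   at least 1 sample).
#' @param C Positive penalty constant.
#' @param gamma Positive kernel width parameter; default `1/ncol(x)`.
#' @param tol KKT gap tolerance for the dual solver.
#' @param max_iter Iteration cap per pairwise subproblem.
#' @return An object of class `svm_model`.
#' @export
train_svm <- function(x, y, C = 1, gamma = NULL, tol = 1e-3, max_iter = 200000L) {
  X <- as_matrix_values(x)
  y <- as.character(y)
  stopifnot(nrow(X) == length(y), C > 0)
  if (is.null(gamma)) gamma <- 1 / max(1, ncol(X))
  stopifnot(gamma > 0)
  classes <- sort(unique(y))
  if (length(classes) < 2) stop("train_svm: at least two classes required")
  pairs <- utils::combn(classes, 2, simplify = FALSE)
  machines <- lapply(pairs, function(pr) {
    sel <- y %in% pr
    Xp <- X[sel, , drop = FALSE]
    # first class of the pair is coded +1
    yp <- ifelse(y[sel] == pr[1], 1, -1)
    K <- rbf_kernel(Xp, Xp, gamma)
    sol <- smo_solve(K, yp, C, tol, max_iter)
    sv <- which(sol$alpha > 1e-10)
    list(
      classes = pr,
      sv = Xp[sv, , drop = FALSE],
      coef = sol$alpha[sv] * yp[sv],
      b = sol$b,
      converged = sol$converged
    )
  })
  structure(
    list(machines = machines, classes = classes, C = C, gamma = gamma, n = ncol(X)),
    class = "svm_model"
  )
}

#' @export
print.svm_model <- function(x, ...) {
  cat(sprintf(
    "<svm_model> %d classes (%s), C = %g, gamma = %g\n",
    length(x$classes), paste(x$classes, collapse = ", "), x$C, x$gamma
  ))
  invisible(x)
}

# pairwise decision values f(t) = sum coef_i K(sv_i, t) + b for one machine
svm_decision <- function(machine, gamma, T) {
  if (nrow(machine$sv) == 0) {
    return(rep(machine$b, nrow(T)))
  }
  as.numeric(crossprod(rbf_kernel(machine$sv, T, gamma), machine$coef)) + machine$b
}

#' Predict with a trained SVM
#'
#' Each pairwise machine votes by the sign of its decision function; the
#' majority class wins, ties broken by class order.
#'
#' @param model An [train_svm()] result.
#' @param x Matrix (or `feature_matrix`) with the training width.
#' @return Character vector of predicted labels.
#' @export
predict_svm <- function(model, x) {
  T <- as_matrix_values(x)
  if (ncol(T) != model$n) {
    stop(sprintf(
      "predict_svm: input width %d does not match model width %d",
      ncol(T), model$n
    ))
  }
  votes <- matrix(0L,
    nrow = nrow(T), ncol = length(model$classes),
    dimnames = list(NULL, model$classes)
  )
  for (mach in model$machines) {
    f <- svm_decision(mach, model$gamma, T)
    win <- ifelse(f >= 0, mach$classes[1], mach$classes[2])
    for (cl in mach$classes) {
      votes[, cl] <- votes[, cl] + (win == cl)
    }
  }
  model$classes[apply(votes, 1, which.max)]
}

#' Tune SVM hyperparameters by cross-validation
#'
#' Evaluates every (C, gamma) grid pair by k-fold cross-validated
#' micro-accuracy and returns the best pair; ties are broken toward smaller C,
#' then smaller gamma. Default grids are the standard coarse log2 grids
#' C in 2^{-5, -3, ..., 15}, gamma in 2^{-15, -13, ..., 3}.
#'
#' @param x Training matrix (or `feature_matrix`).
#' @param y Class labels.
#' @param C_grid,gamma_grid Numeric candidate vectors.
#' @param folds Number of folds (default 5).
#' @param seed Seed for the fold split.
#' @param stratified Stratify folds by class (default TRUE).
#' @return List with elements `C`, `gamma` and `accuracy` (mean CV
#'   micro-accuracy of the winner, percent).
#' @export
tune_svm <- function(x, y, C_grid = 2^seq(-5, 15, by = 2),
                     gamma_grid = 2^seq(-15, 3, by = 2),
                     folds = 5, seed = 1, stratified = TRUE) {
  X <- as_matrix_values(x)
  y <- as.character(y)
  if (length(C_grid) == 0 || length(gamma_grid) == 0) {
    stop("tune_svm: empty hyperparameter grid")
  }
  if (nrow(X) < folds) stop("tune_svm: fewer samples than folds")
  grid <- expand.grid(C = sort(C_grid), gamma = sort(gamma_grid))
  if (nrow(grid) == 1) {
    return(list(C = grid$C[1], gamma = grid$gamma[1], accuracy = NA_real_))
  }
  fold_id <- make_folds(y, folds, seed, stratified = stratified)
  acc <- matrix(0, nrow = folds, ncol = nrow(grid))
  for (f in seq_len(folds)) {
    tr <- fold_id != f
    for (g in seq_len(nrow(grid))) {
      model <- train_svm(X[tr, , drop = FALSE], y[tr],
        C = grid$C[g], gamma = grid$gamma[g]
      )
      pred <- predict_svm(model, X[!tr, , drop = FALSE])
      acc[f, g] <- mean(pred == y[!tr])
    }
  }
  mean_acc <- colMeans(acc)
  # grid is sorted by gamma slowest, C fastest; pick smallest C then gamma on ties
  ord <- order(-mean_acc, grid$C, grid$gamma)
  best <- ord[1]
  list(
    C = grid$C[best], gamma = grid$gamma[best],
    accuracy = 100 * mean_acc[best]
  )
}
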