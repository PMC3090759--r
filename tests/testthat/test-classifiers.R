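test_that("two-point SVM yields the midpoint separator", {
  X <- matrix(c(-1, 1), ncol = 1)
  y <- c("A", "B")
  # small gamma approximates the linear kernel locally; the max-margin
  # boundary between -1 and +1 is at 0
  model <- train_svm(X, y, C = 1e6, gamma = 0.01)
  expect_identical(predict_svm(model, matrix(c(0.5, -0.5, 2, -2), ncol = 1)),
    c("B", "A", "B", "A"))
  # decision value at the midpoint is (numerically) zero
  f <- mthvr:::svm_decision(model$machines[[1]], model$gamma, matrix(0, 1, 1))
  expect_lt(abs(f), 1e-6)
})

test_that("SVM respects box constraints and mirror symmetry", {
  set.seed(5)
  X <- matrix(c(rnorm(20, -2), rnorm(20, 2)), ncol = 1)
  y <- rep(c("A", "B"), each = 20)
  C <- 3
  model <- train_svm(X, y, C = C, gamma = 0.5)
  coef <- model$machines[[1]]$coef
  expect_true(all(abs(coef) <= C + 1e-9)) # 0 <= alpha_i <= C
  # mirror-symmetric inputs flip the decision
  pred_pos <- predict_svm(model, matrix(c(1.5, 2.5), ncol = 1))
  model_neg <- train_svm(-X, y, C = C, gamma = 0.5)
  pred_neg <- predict_svm(model_neg, -matrix(c(1.5, 2.5), ncol = 1))
  expect_identical(pred_pos, pred_neg)
})

test_that("large-C SVM separates separable data exactly (property)", {
  for (seed in 1:5) {
    set.seed(seed)
    n_per <- 15
    X <- rbind(
      matrix(rnorm(n_per * 2, -3), ncol = 2),
      matrix(rnorm(n_per * 2, 3), ncol = 2)
    )
    y <- rep(c("A", "B"), each = n_per)
    model <- train_svm(X, y, C = 1e6, gamma = 0.5)
    expect_identical(predict_svm(model, X), y)
    # support-vector duplicate is classified to its own class
    sv1 <- model$machines[[1]]$sv[1, , drop = FALSE]
    expect_identical(
      predict_svm(model, sv1),
      y[which(apply(X, 1, function(r) all(r == sv1)))[1]]
    )
    # dual feasibility: sum alpha_i y_i = 0 within tolerance
    expect_lt(abs(sum(model$machines[[1]]$coef)), 1e-6)
  }
})

test_that("one-against-one voting handles three classes and ties deterministically", {
  set.seed(8)
  X <- rbind(
    matrix(rnorm(20, -5), ncol = 1),
    matrix(rnorm(20, 0), ncol = 1),
    matrix(rnorm(20, 5), ncol = 1)
  )
  y <- rep(c("A", "B", "C"), each = 20)
  model <- train_svm(X, y, C = 100, gamma = 0.5)
  expect_identical(predict_svm(model, matrix(c(-5, 0, 5), ncol = 1)), c("A", "B", "C"))
  expect_error(train_svm(X, rep("A", 60)), "two classes")
})

test_that("tune_svm is an argmax over the grid", {
  set.seed(9)
  X <- matrix(c(rnorm(25, -2), rnorm(25, 2)), ncol = 1)
  y <- rep(c("A", "B"), each = 25)
  # 1x1 grid returns that pair
  t1 <- tune_svm(X, y, C_grid = 4, gamma_grid = 0.25)
  expect_equal(t1$C, 4)
  expect_equal(t1$gamma, 0.25)

  C_grid <- c(0.01, 1, 100)
  g_grid <- c(0.01, 1)
  best <- tune_svm(X, y, C_grid = C_grid, gamma_grid = g_grid, folds = 3, seed = 2)
  # exhaustive replay: no grid pair beats the winner's CV accuracy
  fold_id <- make_folds(y, 3, seed = 2)
  replay <- function(C, gamma) {
    fold_acc <- vapply(1:3, function(f) {
      m <- train_svm(X[fold_id != f, , drop = FALSE], y[fold_id != f], C = C, gamma = gamma)
      mean(predict_svm(m, X[fold_id == f, , drop = FALSE]) == y[fold_id == f])
    }, 0)
    100 * mean(fold_acc) # mean of per-fold accuracies, as in tune_svm
  }
  accs <- outer(C_grid, g_grid, Vectorize(replay))
  expect_equal(best$accuracy, max(accs), tolerance = 1e-9)
  # order independence absent ties
  best2 <- tune_svm(X, y, C_grid = rev(C_grid), gamma_grid = rev(g_grid), folds = 3, seed = 2)
  expect_equal(best2$C, best$C)
  expect_equal(best2$gamma, best$gamma)
})

test_that("Gaussian training recovers closed-form moments", {
  # symmetric 1-D classes about 0 and 2
  X <- matrix(c(-1, 0, 1, 1, 2, 3), ncol = 1)
  y <- rep(c("a", "b"), each = 3)
  m <- train_gaussian(X, y, shared_covariance = TRUE, regularization = 0)
  expect_equal(m$means[[1]][1], 0)
  expect_equal(m$means[[2]][1], 2)
  expect_equal(m$covariances[[1]][1, 1], 1) # pooled: ((2)*1 + (2)*1)/4
  expect_equal(m$priors, c(0.5, 0.5)) # equal class sizes -> 1/K
  # identical per-class scatter: pooled covariance equals each class's own
  mq <- train_gaussian(X, y, shared_covariance = FALSE, regularization = 0)
  expect_equal(mq$covariances[[1]], m$covariances[[1]])
  expect_error(train_gaussian(matrix(1:3, ncol = 1), c("a", "a", "b")), "fewer than 2")
})

test_that("LDA boundary matches the closed form, including the prior shift", {
  # classes N(0,1), N(2,1): equal priors put the boundary at 1.0
  set.seed(10)
  X <- matrix(c(rnorm(200), rnorm(200, 2)), ncol = 1)
  y <- rep(c("a", "b"), each = 200)
  model <- train_gaussian(X, y, shared_covariance = TRUE)
  # force the exact population parameters to test the decision rule itself
  model$means <- list(0, 2)
  model$covariances <- list(matrix(1), matrix(1))
  model$priors <- c(0.5, 0.5)
  pred <- predict_gaussian(model, matrix(c(0.9, 1.1), ncol = 1))
  expect_identical(pred$labels, c("a", "b"))
  expect_equal(rowSums(pred$posteriors), c(1, 1), tolerance = 1e-10)
  # posterior is exactly 1/2 on the boundary
  expect_equal(unname(predict_gaussian(model, matrix(1))$posteriors[1, 1]), 0.5,
    tolerance = 1e-10
  )
  # priors (0.9, 0.1) shift the boundary to 1 + ln(9)/2 ~ 2.0986
  model$priors <- c(0.9, 0.1)
  shift <- 1 + log(9) / 2
  pred2 <- predict_gaussian(model, matrix(c(shift - 0.01, shift + 0.01), ncol = 1))
  expect_identical(pred2$labels, c("a", "b"))
})

test_that("QDA reproduces the two-sided quadratic boundary", {
  # N(0,1) vs N(0,4): log-density equality at x^2 (1/2 - 1/8) = ln 2,
  # i.e. |x*| = sqrt(8 ln(2) / 3) ~ 1.3596
  model <- structure(
    list(
      classes = c("narrow", "wide"),
      means = list(0, 0),
      covariances = list(matrix(1), matrix(4)),
      priors = c(0.5, 0.5), shared = FALSE, n = 1L
    ),
    class = "gaussian_model"
  )
  xstar <- sqrt(8 * log(2) / 3)
  pred <- predict_gaussian(
    model,
    matrix(c(0, xstar - 0.01, xstar + 0.01, -xstar - 0.01), ncol = 1)
  )
  expect_identical(pred$labels, c("narrow", "narrow", "wide", "wide"))
})

test_that("QDA with covariances forced equal reproduces LDA decisions", {
  set.seed(11)
  X <- rbind(
    matrix(rnorm(60, -1), ncol = 2),
    matrix(rnorm(60, 1), ncol = 2)
  )
  y <- rep(c("a", "b"), each = 30)
  lda <- train_gaussian(X, y, shared_covariance = TRUE)
  qda <- train_gaussian(X, y, shared_covariance = FALSE)
  qda$covariances <- lda$covariances
  grid <- as.matrix(expand.grid(seq(-3, 3, 0.25), seq(-3, 3, 0.25)))
  expect_identical(
    predict_gaussian(lda, grid)$labels,
    predict_gaussian(qda, grid)$labels
  )
})

test_that("gaussian posteriors normalize and singularity advises ridge", {
  set.seed(12)
  X <- matrix(rnorm(40), ncol = 2)
  X[, 2] <- X[, 1] # perfectly collinear -> singular covariance
  y <- rep(c("a", "b"), 10)
  model <- train_gaussian(X, y, regularization = 0)
  expect_error(predict_gaussian(model, X), "ridge")
  model_r <- train_gaussian(X, y) # automatic ridge
  post <- predict_gaussian(model_r, X)$posteriors
  expect_equal(rowSums(post), rep(1, 20), tolerance = 1e-10)
})

test_that("predict_1nn matches brute-force Hamming enumeration (property)", {
  brute_1nn <- function(ref, labels, t, classes) {
    d <- apply(ref, 1, function(r) sum(r != t))
    nearest <- labels[d == min(d)]
    tab <- table(factor(nearest, levels = classes))
    names(tab)[which.max(tab)]
  }
  for (seed in 1:20) {
    set.seed(seed)
    m <- sample(3:20, 1)
    n <- sample(2:15, 1)
    ref <- matrix(rbinom(m * n, 1, 0.4), nrow = m)
    labels <- sample(c("A", "B", "C"), m, replace = TRUE)
    while (length(unique(labels)) < 2) labels <- sample(c("A", "B", "C"), m, replace = TRUE)
    T <- matrix(rbinom(10 * n, 1, 0.4), nrow = 10)
    nn <- nn_reference(ref, labels)
    got <- predict_1nn(nn, T)
    want <- apply(T, 1, brute_1nn, ref = ref, labels = labels, classes = nn$classes)
    expect_identical(got, unname(want))
  }
})

test_that("1NN handles exact matches, majority votes and rejects non-binary input", {
  ref <- nn_reference(rbind(c(0, 0, 0), c(1, 1, 1)), c("A", "B"))
  expect_identical(predict_1nn(ref, rbind(c(1, 1, 0))), "B") # distances 2 vs 1
  expect_identical(predict_1nn(ref, rbind(c(0, 0, 0))), "A") # distance 0
  # nearest set {A, A, B} -> A
  ref2 <- nn_reference(
    rbind(c(0, 0), c(0, 0), c(1, 1)),
    c("A", "A", "B")
  )
  expect_identical(predict_1nn(ref2, rbind(c(1, 0))), "A")
  expect_error(nn_reference(matrix(0.5, 1, 2), "A"), "binary")
  expect_error(predict_1nn(ref, rbind(c(0.2, 0, 0))), "binary")
})
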