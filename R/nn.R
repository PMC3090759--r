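#' Build a 1-nearest-neighbour reference
#'
#' Stores the binary reference matrix and labels for Hamming-distance
#' nearest-neighbour classification. This is also the haplogroup-assignment
#' mechanism used with a labelled reference panel. PCA is never applied before
#' 1NN: Hamming distance is defined on the binary encoding itself.
#'
#' @param x Binary matrix (entries in {0, 1}) or binary `feature_matrix`.
#' @param labels Reference labels, one per row.
#' @return An object of class `nn_reference`.
#' @export
nn_reference <- function(x, labels) {
  X <- as_matrix_values(x)
  labels <- as.character(labels)
  stopifnot(nrow(X) >= 1, nrow(X) == length(labels))
  if (!all(X %in% c(0, 1))) {
    stop("nn_reference: Hamming distance requires a binary {0,1} matrix")
  }
  structure(
    list(x = X, labels = labels, classes = sort(unique(labels))),
    class = "nn_reference"
  )
}

#' @export
print.nn_reference <- function(x, ...) {
  cat(sprintf(
    "<nn_reference> %d reference samples, %d classes\n",
    nrow(x$x), length(x$classes)
  ))
  invisible(x)
}

#' Classify by 1-nearest-neighbour Hamming distance
#'
#' Each test row is assigned the label of its nearest reference row by the
#' number of mismatching positions. When several reference rows tie at the
#' minimal distance, the majority label among the nearest set wins; remaining
#' ties are broken by class order.
#'
#' @param reference A [nn_reference()].
#' @param x Binary matrix (or `feature_matrix`) of test rows.
#' @return Character vector of predicted labels.
#' @export
predict_1nn <- function(reference, x) {
  T <- as_matrix_values(x)
  if (ncol(T) != ncol(reference$x)) {
    stop(sprintf(
      "predict_1nn: input width %d does not match reference width %d",
      ncol(T), ncol(reference$x)
    ))
  }
  if (!all(T %in% c(0, 1))) {
    stop("predict_1nn: Hamming distance requires binary {0,1} inputs")
  }
  # Hamming distance between binary rows: |a| + |b| - 2 <a, b>
  ra <- rowSums(reference$x)
  rb <- rowSums(T)
  D <- outer(ra, rb, "+") - 2 * tcrossprod(reference$x, T)
  vapply(seq_len(nrow(T)), function(j) {
    d <- D[, j]
    nearest <- reference$labels[d <= min(d) + 1e-9]
    tab <- table(factor(nearest, levels = reference$classes))
    names(tab)[which.max(tab)]
  }, "")
}
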