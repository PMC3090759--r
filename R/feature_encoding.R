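#' Build a feature space from training profiles
#'
#' The feature universe is the ordered set of distinct polymorphisms observed
#' in the training samples. Test-only polymorphisms carry no signal for a
#' model trained on this space and are dropped (with a logged count) at
#' encoding time. Features are ordered along the concatenated HVR axis
#' (HVR1 16024-16569 then HVR2 1-576), with substitutions, insertions and
#' deletions at the same site kept contiguous in that order.
#'
#' @param training A non-empty [profile_dataset()].
#' @return An object of class `feature_space`: list with `tokens` (canonical
#'   token order), `positions` (rCRS position per token) and `source_region`
#'   (union of training typed ranges).
#' @export
build_feature_space <- function(training) {
  if (length(training$samples) == 0) stop("build_feature_space: empty training set")
  tokens <- unique(unlist(lapply(training$samples, function(s) s$polymorphisms)))
  tokens <- canonical_token_order(tokens)
  if (length(tokens) == 0) {
    warning("build_feature_space: training set carries no polymorphisms (n = 0)")
  }
  source_region <- Reduce(
    function(a, b) region_union(a, b),
    lapply(training$samples, function(s) s$typed)
  )
  positions <- if (length(tokens)) parse_polymorphisms(tokens)$position else integer(0)
  structure(
    list(tokens = tokens, positions = positions, source_region = source_region),
    class = "feature_space"
  )
}

#' @export
print.feature_space <- function(x, ...) {
  cat(sprintf("<feature_space> n = %d polymorphisms\n", length(x$tokens)))
  invisible(x)
}

# union of two region sets (merging overlaps/adjacency within a block)
region_union <- function(a, b) {
  df <- rbind(as.data.frame(a), as.data.frame(b))
  if (nrow(df) == 0) {
    return(region_set())
  }
  df <- df[order(df$start), , drop = FALSE]
  starts <- df$start[1]
  ends <- df$end[1]
  for (i in seq_len(nrow(df))[-1]) {
    j <- length(starts)
    if (df$start[i] <= ends[j] + 1L &&
      axis_block(df$start[i]) == axis_block(starts[j])) {
      ends[j] <- max(ends[j], df$end[i])
    } else {
      starts <- c(starts, df$start[i])
      ends <- c(ends, df$end[i])
    }
  }
  region_set(starts, ends)
}

axis_block <- function(pos) ifelse(pos >= HVR1_START, "HVR1", "HVR2")

new_feature_matrix <- function(values, row_ids, labels, space) {
  dimnames(values) <- NULL
  structure(
    list(values = values, row_ids = row_ids, labels = labels, space = space),
    class = "feature_matrix"
  )
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat(sprintf(
    "<feature_matrix> %d samples x %d features\n",
    nrow(x$values), ncol(x$values)
  ))
  invisible(x)
}

#' Plain binary encoding
#'
#' Entry (i, j) is 1 iff sample i harbours feature j. Polymorphisms of a
#' sample that are absent from the space are ignored; their total count is
#' reported via `message()` when positive.
#'
#' @param samples A [profile_dataset()].
#' @param space A [build_feature_space()] result.
#' @return A `feature_matrix` (values in {0, 1}).
#' @export
encode_binary <- function(samples, space) {
  n <- length(space$tokens)
  m <- length(samples$samples)
  values <- matrix(0, nrow = m, ncol = n)
  dropped <- 0L
  for (i in seq_len(m)) {
    toks <- samples$samples[[i]]$polymorphisms
    j <- match(toks, space$tokens)
    dropped <- dropped + sum(is.na(j))
    values[i, j[!is.na(j)]] <- 1
  }
  if (dropped > 0) {
    message(sprintf("encode_binary: %d out-of-space polymorphisms ignored", dropped))
  }
  new_feature_matrix(values, dataset_ids(samples), dataset_labels(samples), space)
}

#' Reference-imputation (rCRS) encoding
#'
#' Identical to [encode_binary()]: untyped positions are treated as identical
#' to the reference, i.e. every feature the sample was not sequenced for is
#' encoded 0. Kept as a named strategy so the missing-data comparison is
#' explicit; because the rCRS is of Caucasian origin this scheme biases
#' predictions toward reference-like classes.
#'
#' @inheritParams encode_binary
#' @return A `feature_matrix` (values in {0, 1}).
#' @export
encode_rcrs <- function(samples, space) {
  encode_binary(samples, space)
}

#' Per-position polymorphism rates from training data
#'
#' For each of the 1122 HVR positions, the fraction of training samples typed
#' at the position that harbour any polymorphism there (substitutions,
#' insertions anchored at the position, and deletions pooled). Positions
#' typed in no sample get rate 0.
#'
#' @param training A non-empty [profile_dataset()].
#' @return An object of class `position_rate_table`: data.frame with
#'   `position` (axis order) and `rate`.
#' @export
position_rates <- function(training) {
  if (length(training$samples) == 0) stop("position_rates: empty training set")
  axis <- hvr_axis()
  typed_counts <- numeric(length(axis))
  poly_counts <- numeric(length(axis))
  for (s in training$samples) {
    typed <- region_contains(s$typed, axis)
    typed_counts <- typed_counts + typed
    if (length(s$polymorphisms) > 0) {
      pos <- parse_polymorphisms(s$polymorphisms)$position
      idx <- unique(axis_index(pos))
      idx <- idx[!is.na(idx)]
      poly_counts[idx] <- poly_counts[idx] + 1
    }
  }
  rate <- ifelse(typed_counts > 0, poly_counts / typed_counts, 0)
  structure(
    data.frame(position = axis, rate = rate),
    class = c("position_rate_table", "data.frame")
  )
}

#' Probability encoding for missing data
#'
#' Concatenates the binary in-space indicators (untyped features 0) with 1122
#' per-position variables: 1 if the sample is typed and polymorphic at the
#' position, 0 if typed and reference-identical, and the training polymorphism
#' rate when untyped. Row width is therefore n + 1122.
#'
#' @inheritParams encode_binary
#' @param rates A [position_rates()] table.
#' @return A `feature_matrix` with values in `[0, 1]`.
#' @export
encode_probability <- function(samples, space, rates) {
  stopifnot(inherits(rates, "position_rate_table"))
  base <- encode_binary(samples, space)
  axis <- hvr_axis()
  m <- length(samples$samples)
  block <- matrix(0, nrow = m, ncol = length(axis))
  for (i in seq_len(m)) {
    s <- samples$samples[[i]]
    typed <- region_contains(s$typed, axis)
    row <- ifelse(typed, 0, rates$rate)
    if (length(s$polymorphisms) > 0) {
      pos <- parse_polymorphisms(s$polymorphisms)$position
      idx <- unique(axis_index(pos))
      idx <- idx[!is.na(idx)]
      row[idx[typed[idx]]] <- 1
    }
    block[i, ] <- row
  }
  new_feature_matrix(
    cbind(base$values, block), base$row_ids, base$labels, space
  )
}

#' Common-region restriction for one test profile
#'
#' Restricts the training feature universe to the polymorphisms whose
#' positions lie inside the test sample's typed ranges, so the model sees only
#' sequence shared between test and training. Training samples are retained
#' even under partial overlap (their uncovered features encode 0) unless
#' their typed overlap with the test region falls below `min_overlap`.
#'
#' @param test A [sample_profile()] with non-empty typed ranges.
#' @param training A [profile_dataset()].
#' @param min_overlap Minimum fraction of the test region a training sample
#'   must cover to be kept (default 0: keep all).
#' @return List with `space` (restricted `feature_space`), `train` (the
#'   restricted training `feature_matrix`) and `test_row` (1 x n matrix for
#'   the test sample).
#' @export
restrict_to_common_region <- function(test, training, min_overlap = 0) {
  if (region_length(test$typed) == 0) {
    stop("restrict_to_common_region: test sample has no typed region")
  }
  full <- build_feature_space(training)
  keep <- region_contains(test$typed, full$positions)
  if (!any(keep)) {
    stop(paste(
      "restrict_to_common_region: the test region overlaps no training",
      "polymorphism; consider the rcrs or probability strategy"
    ))
  }
  space <- structure(
    list(
      tokens = full$tokens[keep],
      positions = full$positions[keep],
      source_region = region_intersect(full$source_region, test$typed)
    ),
    class = "feature_space"
  )
  train_set <- training
  if (min_overlap > 0) {
    test_len <- region_length(test$typed)
    frac <- vapply(training$samples, function(s) {
      region_length(region_intersect(s$typed, test$typed)) / test_len
    }, 0)
    train_set <- dataset_subset(training, frac >= min_overlap)
  }
  train_mat <- suppressMessages(encode_binary(train_set, space))
  test_mat <- suppressMessages(
    encode_binary(profile_dataset(list(test)), space)
  )
  list(space = space, train = train_mat, test_row = test_mat$values)
}

#' Export a feature matrix as TSV
#'
#' Audit output: `sample_id`, `label`, then one column per feature headed by
#' its canonical token (positional probability columns are headed `pos_<p>`).
#'
#' @param fm A `feature_matrix`.
#' @param path File path or connection.
#' @return `path`, invisibly.
#' @export
write_feature_matrix <- function(fm, path) {
  n_space <- length(fm$space$tokens)
  extra <- ncol(fm$values) - n_space
  headers <- fm$space$tokens
  if (extra > 0) headers <- c(headers, paste0("pos_", hvr_axis()))
  df <- data.frame(
    sample_id = fm$row_ids, label = fm$labels,
    fm$values, check.names = FALSE, stringsAsFactors = FALSE
  )
  names(df)[-(1:2)] <- headers
  utils::write.table(df, path,
    sep = "\t", quote = FALSE,
    row.names = FALSE, fileEncoding = "UTF-8"
  )
  invisible(path)
}
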