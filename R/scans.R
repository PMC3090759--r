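#' Iterative feature-deletion scan
#'
#' Orders the dataset's distinct polymorphisms along the concatenated HVR axis
#' (HVR1 16024-16569 then HVR2 1-576; the two ends non-adjacent on the
#' circular genome are the axis ends) and iteratively removes groups of
#' `ceiling(fraction * n)` features from the chosen end, re-running
#' cross-validation after each round. Round 0 is the full-data baseline.
#'
#' @param dataset A labelled [profile_dataset()], fully typed over the scan
#'   universe.
#' @param from_end `"hvr1_end"` deletes from the HVR1 end (axis start, as in
#'   scanning from HVR1 towards HVR2); `"hvr2_end"` from the HVR2 end.
#' @param fraction Fraction of the original feature count removed per round
#'   (default 0.10, so ten rounds exhaust the set).
#' @param spec A [pipeline_spec()].
#' @param folds,seed,stratified Passed to [cross_validate()].
#' @return A data.frame of class `scan_result` with columns `round`,
#'   `n_features`, `micro`, `macro` (accuracies NA once no features remain).
#' @export
deletion_scan <- function(dataset, from_end = c("hvr1_end", "hvr2_end"),
                          fraction = 0.10, spec = pipeline_spec("svm"),
                          folds = 5, seed = 1, stratified = TRUE) {
  from_end <- match.arg(from_end)
  tokens <- canonical_token_order(
    unlist(lapply(dataset$samples, function(s) s$polymorphisms))
  )
  n <- length(tokens)
  if (n == 0) stop("deletion_scan: dataset carries no polymorphisms")
  chunk <- ceiling(fraction * n)
  rounds <- 0:ceiling(n / chunk)
  out <- data.frame(
    round = rounds,
    n_features = pmax(0L, n - rounds * chunk),
    micro = NA_real_, macro = NA_real_
  )
  for (r in rounds) {
    keep_n <- n - r * chunk
    if (keep_n <= 0) {
      if (r < max(rounds)) warning("deletion_scan: feature set exhausted early")
      break
    }
    keep <- if (from_end == "hvr1_end") {
      tail(tokens, keep_n) # deleting from the HVR1 end = axis start
    } else {
      head(tokens, keep_n)
    }
    res <- cross_validate(
      filter_polymorphisms(dataset, keep), spec,
      folds = folds, seed = seed, stratified = stratified
    )
    out$micro[out$round == r] <- res$micro
    out$macro[out$round == r] <- res$macro
  }
  structure(out, class = c("scan_result", "data.frame"))
}

#' Sliding-window informativeness scan
#'
#' Generates datasets each retaining only the polymorphisms inside a window of
#' `round(nucleotide_fraction * 1122)` nucleotides on the concatenated HVR
#' axis, at `n_windows` evenly spaced start offsets spanning the axis, and
#' cross-validates each. Windows containing no polymorphism are recorded with
#' NA accuracy.
#'
#' @param dataset A labelled [profile_dataset()] typed over the HVR universe.
#' @param nucleotide_fraction Window width as a fraction of the 1122-base
#'   universe (default 0.10, i.e. 112 bases).
#' @param n_windows Number of windows (default 20).
#' @param spec A [pipeline_spec()].
#' @param folds,seed,stratified Passed to [cross_validate()].
#' @return A data.frame of class `scan_result` with columns `window`,
#'   `axis_start`, `axis_end`, `start_position`, `n_features`, `micro`,
#'   `macro`.
#' @export
window_scan <- function(dataset, nucleotide_fraction = 0.10, n_windows = 20,
                        spec = pipeline_spec("svm"), folds = 5, seed = 1,
                        stratified = TRUE) {
  axis <- hvr_axis()
  L <- length(axis)
  w <- round(nucleotide_fraction * L)
  starts <- round(seq(1, L - w + 1, length.out = n_windows))
  tokens <- canonical_token_order(
    unlist(lapply(dataset$samples, function(s) s$polymorphisms))
  )
  tok_axis <- axis_index(parse_polymorphisms(tokens)$position)
  out <- data.frame(
    window = seq_len(n_windows),
    axis_start = starts, axis_end = starts + w - 1L,
    start_position = axis[starts],
    n_features = NA_integer_, micro = NA_real_, macro = NA_real_
  )
  for (i in seq_len(n_windows)) {
    keep <- tokens[tok_axis >= starts[i] & tok_axis <= starts[i] + w - 1L]
    out$n_features[i] <- length(keep)
    if (length(keep) == 0) next
    res <- cross_validate(
      filter_polymorphisms(dataset, keep), spec,
      folds = folds, seed = seed, stratified = stratified
    )
    out$micro[i] <- res$micro
    out$macro[i] <- res$macro
  }
  structure(out, class = c("scan_result", "data.frame"))
}
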