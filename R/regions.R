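#' Typed-region sets
#'
#' A region set records which parts of HVR1/HVR2 were actually sequenced for
#' a sample, as an ordered list of disjoint 1-based inclusive intervals. Each
#' interval must lie entirely within one HVR block (HVR1 = 16024-16569,
#' HVR2 = 1-576); intervals crossing the block boundary are rejected because
#' the two blocks are only circularly adjacent on the genome.
#'
#' @param start,end Integer vectors of equal length: interval endpoints,
#'   1-based inclusive.
#' @return An object of class `region_set`: a data.frame with columns
#'   `start` and `end`, sorted by `start`.
#' @examples
#' region_set(c(16024, 73), c(16365, 340))
#' @export
region_set <- function(start = integer(0), end = integer(0)) {
  start <- as.integer(start)
  end <- as.integer(end)
  if (length(start) != length(end)) {
    stop("start and end must have the same length")
  }
  if (any(is.na(start)) || any(is.na(end))) stop("NA region endpoint")
  if (any(start > end)) stop("region start exceeds end")
  in_hvr1 <- start >= HVR1_START & end <= HVR1_END
  in_hvr2 <- start >= HVR2_START & end <= HVR2_END
  if (any(!(in_hvr1 | in_hvr2))) {
    bad <- which(!(in_hvr1 | in_hvr2))[1]
    stop(sprintf(
      "region %d-%d is not contained in HVR1 (16024-16569) or HVR2 (1-576)",
      start[bad], end[bad]
    ))
  }
  o <- order(start)
  start <- start[o]
  end <- end[o]
  if (length(start) > 1 && any(start[-1] <= end[-length(end)])) {
    stop("regions overlap; typed regions must be disjoint")
  }
  structure(
    data.frame(start = start, end = end),
    class = c("region_set", "data.frame")
  )
}

#' @export
print.region_set <- function(x, ...) {
  cat("<region_set> ", format_regions(x), "\n", sep = "")
  invisible(x)
}

# "start-end;start-end" text form used in the profile TSV dialect
format_regions <- function(rs) {
  if (nrow(rs) == 0) {
    return("")
  }
  paste(sprintf("%d-%d", rs$start, rs$end), collapse = ";")
}

parse_regions <- function(text) {
  text <- trimws(text)
  if (is.na(text) || text == "") {
    return(region_set())
  }
  parts <- strsplit(text, ";", fixed = TRUE)[[1]]
  m <- regmatches(parts, regexec("^([0-9]+)-([0-9]+)$", parts))
  bad <- vapply(m, length, 0L) != 3L
  if (any(bad)) {
    stop(sprintf("malformed range string '%s'", parts[bad][1]))
  }
  region_set(
    vapply(m, function(g) as.integer(g[2]), 0L),
    vapply(m, function(g) as.integer(g[3]), 0L)
  )
}

#' Membership of positions in a region set
#'
#' @param rs A [region_set()].
#' @param positions Integer vector of rCRS positions.
#' @return Logical vector: is each position inside some interval of `rs`?
#' @export
region_contains <- function(rs, positions) {
  if (nrow(rs) == 0) {
    return(rep(FALSE, length(positions)))
  }
  out <- rep(FALSE, length(positions))
  for (i in seq_len(nrow(rs))) {
    out <- out | (positions >= rs$start[i] & positions <= rs$end[i])
  }
  out
}

#' Does one region set fully contain another?
#'
#' @param rs A [region_set()] (the candidate container).
#' @param region A [region_set()] to test for containment.
#' @return TRUE iff every interval of `region` lies inside some interval
#'   of `rs`.
#' @export
region_covers <- function(rs, region) {
  if (nrow(region) == 0) {
    return(TRUE)
  }
  for (i in seq_len(nrow(region))) {
    covered <- any(rs$start <= region$start[i] & rs$end >= region$end[i])
    if (!covered) {
      return(FALSE)
    }
  }
  TRUE
}

#' Intersection of two region sets
#'
#' @param a,b [region_set()] objects.
#' @return The region set of positions typed in both.
#' @export
region_intersect <- function(a, b) {
  starts <- integer(0)
  ends <- integer(0)
  for (i in seq_len(nrow(a))) {
    s <- pmax(a$start[i], b$start)
    e <- pmin(a$end[i], b$end)
    keep <- s <= e
    starts <- c(starts, s[keep])
    ends <- c(ends, e[keep])
  }
  region_set(starts, ends)
}

# total number of positions in the set
region_length <- function(rs) {
  if (nrow(rs) == 0) {
    return(0L)
  }
  sum(rs$end - rs$start + 1L)
}

# canonical text signature, used to cache common-region models
region_signature <- function(rs) format_regions(rs)
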