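#' Construct a single sample profile
#'
#' @param sample_id Sample identifier (unique within a dataset).
#' @param typed A [region_set()] of sequenced ranges.
#' @param polymorphisms Character vector of polymorphism tokens (canonicalised
#'   and deduplicated; set semantics).
#' @param label Optional population label (NA when unlabelled).
#' @param country Optional country of origin.
#' @return An object of class `sample_profile`.
#' @export
sample_profile <- function(sample_id, typed, polymorphisms = character(0),
                           label = NA_character_, country = NA_character_) {
  stopifnot(inherits(typed, "region_set"))
  if (length(polymorphisms) > 0) {
    df <- parse_polymorphisms(polymorphisms)
    inside <- region_contains(typed, df$position)
    if (any(!inside)) {
      stop(sprintf(
        "sample '%s': polymorphism '%s' lies outside the typed regions",
        sample_id, df$token[!inside][1]
      ))
    }
    polymorphisms <- canonical_token_order(df$token)
  } else {
    polymorphisms <- character(0)
  }
  structure(
    list(
      sample_id = as.character(sample_id),
      label = as.character(label),
      country = as.character(country),
      typed = typed,
      polymorphisms = polymorphisms
    ),
    class = "sample_profile"
  )
}

#' @export
print.sample_profile <- function(x, ...) {
  cat(sprintf(
    "<sample_profile> %s label=%s typed=%s [%d polymorphisms]\n",
    x$sample_id, x$label, format_regions(x$typed), length(x$polymorphisms)
  ))
  invisible(x)
}

#' Construct a profile dataset
#'
#' @param samples A list of [sample_profile()] objects with unique ids.
#' @return An object of class `profile_dataset`: list with `samples` and
#'   `label_universe` (the sorted distinct non-missing labels).
#' @export
profile_dataset <- function(samples) {
  ids <- vapply(samples, function(s) s$sample_id, "")
  if (anyDuplicated(ids)) {
    stop(sprintf("duplicate sample_id '%s'", ids[duplicated(ids)][1]))
  }
  labels <- vapply(samples, function(s) s$label, "")
  structure(
    list(
      samples = samples,
      label_universe = sort(unique(labels[!is.na(labels)]))
    ),
    class = "profile_dataset"
  )
}

#' @export
print.profile_dataset <- function(x, ...) {
  cat(sprintf(
    "<profile_dataset> %d samples, labels: %s\n",
    length(x$samples), paste(x$label_universe, collapse = ", ")
  ))
  invisible(x)
}

#' @export
length.profile_dataset <- function(x) length(x$samples)

dataset_labels <- function(dataset) {
  vapply(dataset$samples, function(s) s$label, "")
}

dataset_ids <- function(dataset) {
  vapply(dataset$samples, function(s) s$sample_id, "")
}

# subset keeping class invariants
dataset_subset <- function(dataset, idx) {
  profile_dataset(dataset$samples[idx])
}

PROFILE_TSV_HEADER <- c("sample_id", "label", "country", "ranges", "polymorphisms")

#' Read a profile table
#'
#' The TSV dialect has header
#' `sample_id<TAB>label<TAB>country<TAB>ranges<TAB>polymorphisms`; `ranges`
#' is `start-end` pairs joined by `;`, `polymorphisms` is canonical tokens
#' joined by single spaces. Empty fields denote a missing label/country or an
#' rCRS-identical profile. Every polymorphism must fall inside its sample's
#' typed ranges.
#'
#' @param path File path or connection.
#' @return A [profile_dataset()].
#' @export
read_profile_table <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  if (length(lines) == 0) stop("empty profile table: missing header")
  header <- strsplit(lines[1], "\t", fixed = TRUE)[[1]]
  if (!identical(header, PROFILE_TSV_HEADER)) {
    stop(sprintf(
      "unexpected header: '%s'", lines[1]
    ))
  }
  rows <- lines[-1]
  rows <- rows[nzchar(rows)]
  samples <- lapply(rows, function(line) {
    f <- strsplit(line, "\t", fixed = TRUE)[[1]]
    length(f) <- 5L # pad missing trailing fields
    f[is.na(f)] <- ""
    toks <- strsplit(trimws(f[5]), " +")[[1]]
    toks <- toks[nzchar(toks)]
    sample_profile(
      sample_id = f[1],
      label = if (nzchar(f[2])) f[2] else NA_character_,
      country = if (nzchar(f[3])) f[3] else NA_character_,
      typed = parse_regions(f[4]),
      polymorphisms = toks
    )
  })
  profile_dataset(samples)
}

#' Write a profile table
#'
#' Inverse of [read_profile_table()]: `read_profile_table(write_profile_table(d))`
#' reproduces `d`.
#'
#' @param dataset A [profile_dataset()].
#' @param path File path or connection.
#' @return `path`, invisibly.
#' @export
write_profile_table <- function(dataset, path) {
  rows <- vapply(dataset$samples, function(s) {
    paste(
      s$sample_id,
      if (is.na(s$label)) "" else s$label,
      if (is.na(s$country)) "" else s$country,
      format_regions(s$typed),
      paste(s$polymorphisms, collapse = " "),
      sep = "\t"
    )
  }, "")
  writeLines(c(paste(PROFILE_TSV_HEADER, collapse = "\t"), rows), path, useBytes = TRUE)
  invisible(path)
}

#' Trim a dataset to a target region
#'
#' Intersects every sample's typed ranges and polymorphism set with `region`.
#' With `require_full_coverage`, samples whose typed ranges do not fully
#' contain `region` are dropped first (e.g. keeping only samples typed over
#' 16024-16365).
#'
#' @param dataset A [profile_dataset()].
#' @param region A [region_set()].
#' @param require_full_coverage Drop samples not covering all of `region`?
#' @return The trimmed [profile_dataset()]; warns when empty.
#' @export
trim_dataset <- function(dataset, region, require_full_coverage = FALSE) {
  keep <- rep(TRUE, length(dataset$samples))
  if (require_full_coverage) {
    keep <- vapply(dataset$samples, function(s) region_covers(s$typed, region), TRUE)
  }
  samples <- lapply(dataset$samples[keep], function(s) {
    typed <- region_intersect(s$typed, region)
    toks <- s$polymorphisms
    if (length(toks) > 0) {
      df <- parse_polymorphisms(toks)
      toks <- df$token[region_contains(typed, df$position)]
    }
    sample_profile(s$sample_id, typed, toks, s$label, s$country)
  })
  if (length(samples) == 0) warning("trim_dataset: no samples retained")
  profile_dataset(samples)
}

#' Per-position coverage fractions
#'
#' For each of the 1122 positions of the HVR universe (HVR1 then HVR2 on the
#' concatenated axis), the fraction of samples whose typed ranges contain it.
#'
#' @param dataset A non-empty [profile_dataset()].
#' @return A data.frame with columns `position` (rCRS coordinate, axis order)
#'   and `fraction` in `[0, 1]`.
#' @export
coverage_profile <- function(dataset) {
  if (length(dataset$samples) == 0) stop("coverage_profile: empty dataset")
  axis <- hvr_axis()
  counts <- numeric(length(axis))
  for (s in dataset$samples) {
    counts <- counts + region_contains(s$typed, axis)
  }
  data.frame(position = axis, fraction = counts / length(dataset$samples))
}

# drop the listed polymorphism tokens from every sample (used by scans)
filter_polymorphisms <- function(dataset, keep_tokens) {
  samples <- lapply(dataset$samples, function(s) {
    s$polymorphisms <- intersect(s$polymorphisms, keep_tokens)
    s
  })
  profile_dataset(samples)
}
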