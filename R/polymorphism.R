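#' Parse an rCRS-relative polymorphism token
#'
#' Tokens name a sample's differences from the revised Cambridge Reference
#' Sequence: `16298C` is a substitution to C at position 16298, `16124.1C`
#' is the insertion of a C after position 16124 (first inserted base), and a
#' deletion is written `16189-` (also accepted on input as `16189DEL`, then
#' canonicalised to the `-` form). IUPAC ambiguity codes and point
#' heteroplasmies are rejected: silently coercing them would corrupt the
#' feature space.
#'
#' @param token A single polymorphism token.
#' @return An object of class `polymorphism`: a list with `position`,
#'   `kind` (one of `"substitution"`, `"insertion"`, `"deletion"`), `base`
#'   (NA for deletions) and `insert_index` (NA unless an insertion).
#' @examples
#' parse_polymorphism("16298C")
#' parse_polymorphism("16124.1C")
#' parse_polymorphism("16189-")
#' @export
parse_polymorphism <- function(token) {
  df <- parse_polymorphisms(token)
  structure(
    list(
      position = df$position, kind = df$kind,
      base = df$base, insert_index = df$insert_index
    ),
    class = "polymorphism"
  )
}

#' @export
print.polymorphism <- function(x, ...) {
  cat("<polymorphism> ", render_polymorphism(x), "\n", sep = "")
  invisible(x)
}

#' Vectorised polymorphism parser
#'
#' @param tokens Character vector of tokens.
#' @return A data.frame with one row per token: `position`, `kind`, `base`,
#'   `insert_index` and `token` (the canonical rendering).
#' @export
parse_polymorphisms <- function(tokens) {
  if (length(tokens) == 0) {
    return(data.frame(
      position = integer(0), kind = character(0), base = character(0),
      insert_index = integer(0), token = character(0),
      stringsAsFactors = FALSE
    ))
  }
  tokens <- as.character(tokens)
  if (any(is.na(tokens) | tokens == "")) stop("empty polymorphism token")
  position <- rep(NA_integer_, length(tokens))
  kind <- rep(NA_character_, length(tokens))
  base <- rep(NA_character_, length(tokens))
  insert_index <- rep(NA_integer_, length(tokens))

  sub_m <- regexec("^([0-9]+)([ACGT])$", tokens)
  ins_m <- regexec("^([0-9]+)\\.([0-9]+)([ACGT])$", tokens)
  del_m <- regexec("^([0-9]+)(-|DEL)$", tokens)
  for (i in seq_along(tokens)) {
    g <- regmatches(tokens[i], sub_m[i])[[1]]
    if (length(g) == 3) {
      position[i] <- as.integer(g[2])
      kind[i] <- "substitution"
      base[i] <- g[3]
      next
    }
    g <- regmatches(tokens[i], ins_m[i])[[1]]
    if (length(g) == 4) {
      idx <- as.integer(g[3])
      if (idx < 1) stop(sprintf("malformed polymorphism token '%s': insertion index must be positive", tokens[i]))
      position[i] <- as.integer(g[2])
      kind[i] <- "insertion"
      base[i] <- g[4]
      insert_index[i] <- idx
      next
    }
    g <- regmatches(tokens[i], del_m[i])[[1]]
    if (length(g) == 3) {
      position[i] <- as.integer(g[2])
      kind[i] <- "deletion"
      next
    }
    stop(sprintf("malformed polymorphism token '%s'", tokens[i]))
  }
  out_of_range <- position < 1L | position > RCRS_LENGTH
  if (any(out_of_range)) {
    stop(sprintf(
      "polymorphism token '%s': position outside [1, %d]",
      tokens[out_of_range][1], RCRS_LENGTH
    ))
  }
  df <- data.frame(
    position = position, kind = kind, base = base,
    insert_index = insert_index, stringsAsFactors = FALSE
  )
  df$token <- render_tokens(df)
  df
}

render_tokens <- function(df) {
  ifelse(df$kind == "substitution", paste0(df$position, df$base),
    ifelse(df$kind == "insertion",
      paste0(df$position, ".", df$insert_index, df$base),
      paste0(df$position, "-")
    )
  )
}

#' Canonical text rendering of a polymorphism
#'
#' `render_polymorphism(parse_polymorphism(tok))` returns `tok` for every
#' canonical token.
#'
#' @param p A `polymorphism` object or a data.frame as returned by
#'   [parse_polymorphisms()].
#' @return Character vector of canonical tokens.
#' @export
render_polymorphism <- function(p) {
  if (inherits(p, "polymorphism")) {
    p <- data.frame(
      position = p$position, kind = p$kind, base = p$base,
      insert_index = p$insert_index, stringsAsFactors = FALSE
    )
  }
  render_tokens(p)
}

# Deterministic feature order: concatenated HVR axis position first (HVR1
# then HVR2, so scan order and feature order agree), then kind
# (substitution < insertion < deletion, keeping each site's features
# contiguous with the substitution leading), then insertion index, then base.
# Positions outside the HVR universe (legal rCRS but outside the analysis
# blocks) sort after all HVR positions, by raw coordinate.
order_tokens <- function(df) {
  ax <- axis_index(df$position)
  ax[is.na(ax)] <- 2000L + df$position[is.na(ax)]
  kind_rank <- match(df$kind, c("substitution", "insertion", "deletion"))
  idx <- ifelse(is.na(df$insert_index), 0L, df$insert_index)
  b <- ifelse(is.na(df$base), "", df$base)
  order(ax, kind_rank, idx, b)
}

# sort + dedupe a token character vector into canonical feature order
canonical_token_order <- function(tokens) {
  tokens <- unique(tokens)
  if (length(tokens) == 0) {
    return(character(0))
  }
  df <- parse_polymorphisms(tokens)
  df$token[order_tokens(df)]
}
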