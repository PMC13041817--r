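# Internal normalisation helpers.
#
# Identity and attribute strings are compared after lower-casing and
# whitespace trimming; no synonym resolution is attempted (entity grounding
# is the job of the upstream extraction pipeline).

#' Normalize an identity or attribute string
#'
#' Lower-cases, trims leading/trailing whitespace, and collapses internal
#' whitespace runs. `NA` becomes the empty string. The operation is
#' idempotent, which the comparison logic relies on.
#'
#' @param x Character vector.
#' @return Character vector of the same length.
#' @export
#' @examples
#' normalize_identity(c("  LKB1 ", "AMPK\t alpha", NA))
normalize_identity <- function(x) {
  x <- as.character(x)
  x[is.na(x)] <- ""
  stringr::str_squish(stringr::str_to_lower(x))
}

# TRUE where the (already normalized) value counts as absent.
is_blank <- function(x) {
  is.na(x) | x == "" | x == "nan" | x == "na" | x == "none" | x == "null"
}

#' Build the identity key of an element
#'
#' Node identity in the baseline graph is the pair (normalized identifier,
#' element type): two elements match only when both components agree.
#'
#' @param identifier Element identifier (database ID, gene symbol, or name).
#' @param type Element type (e.g. `"protein"`, `"gene"`, `"chemical"`).
#' @return Character key, `"<identifier>||<type>"`.
#' @export
element_key <- function(identifier, type) {
  paste0(normalize_identity(identifier), "||", normalize_element_type(type))
}

# Element types are free-form in the wild; blanks map to "other".
normalize_element_type <- function(x) {
  x <- normalize_identity(x)
  x[is_blank(x)] <- "other"
  x
}

#' Default sign vocabulary
#'
#' Editable lookup table mapping dialect variants of the regulation sign to
#' the canonical values `"positive"` / `"negative"`. Values not present in
#' the table are rejected at read time rather than guessed.
#'
#' @return A tibble with columns `value` and `sign`.
#' @export
default_sign_map <- function() {
  tibble::tibble(
    value = c(
      "positive", "activation", "activate", "activates", "increase",
      "increases", "+", "pos", "1", "up", "upregulation", "up-regulation",
      "stimulation",
      "negative", "inhibition", "inhibit", "inhibits", "decrease",
      "decreases", "-", "−", "neg", "-1", "down", "downregulation",
      "down-regulation", "repression"
    ),
    sign = rep(c("positive", "negative"), c(13L, 14L))
  )
}

# Connection type: direct vs indirect; blank defaults to indirect so that
# unannotated rows never trigger direct-specific flagging.
normalize_connection <- function(x) {
  x <- normalize_identity(x)
  out <- rep("indirect", length(x))
  out[x %in% c("direct", "true", "yes", "t", "1")] <- "direct"
  out
}

# Serialise / parse the free-form context map ("key:value;key:value").
parse_context_map <- function(x) {
  x <- normalize_identity(x)
  if (is_blank(x)) {
    return(character())
  }
  parts <- stringr::str_split_1(x, ";")
  parts <- parts[!is_blank(stringr::str_squish(parts))]
  kv <- stringr::str_split_fixed(parts, ":", 2L)
  vals <- stringr::str_squish(kv[, 2L])
  names(vals) <- stringr::str_squish(kv[, 1L])
  vals[!is_blank(names(vals)) & !is_blank(vals)]
}
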