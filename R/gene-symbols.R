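#' Normalize gene symbols
#'
#' Canonicalizes gene-symbol tokens so that symbol equality is string equality:
#' surrounding whitespace is stripped and the token is uppercased. Symbols are
#' the universal node key throughout the package; no alias or identifier
#' mapping is attempted (mapping to a single symbol space is the caller's
#' responsibility).
#'
#' Normalization is idempotent: `normalize_symbols(normalize_symbols(x))` is
#' identical to `normalize_symbols(x)`.
#'
#' @param x character vector of gene symbols.
#' @return character vector of the same length, normalized.
#' @examples
#' normalize_symbols(c(" ift88 ", "C14orf177"))
#' @export
normalize_symbols <- function(x) {
  if (!is.character(x)) {
    x <- as.character(x)
  }
  out <- toupper(trimws(x))
  bad <- !nzchar(out) | is.na(out)
  if (any(bad)) {
    stop("empty gene symbol at position(s) ",
         paste(utils::head(which(bad), 5L), collapse = ", "))
  }
  ws <- grepl("[[:space:]]", out)
  if (any(ws)) {
    stop("gene symbol with internal whitespace: ",
         paste(utils::head(out[ws], 5L), collapse = ", "))
  }
  out
}

# TRUE for tokens that look like numbers rather than gene symbols
# (e.g. Excel date corruption such as "42435").
looks_numeric_symbol <- function(x) {
  grepl("^[0-9]+$", x)
}
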