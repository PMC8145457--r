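# Token-set name similarity used for fuzzy-match candidate ranking and the
# duplicate review report. Word order is irrelevant ("fresh beans" vs
# "beans, fresh"); small spelling differences are absorbed by an edit-distance
# ratio over the sorted-token strings.

#' Token-set similarity between two food names
#'
#' Both names are canonicalized (lowercase, punctuation stripped), split into
#' word tokens, the tokens sorted and re-joined, and the similarity returned
#' as `1 - levenshtein / max(nchar)` over the two sorted-token strings. The
#' score is 1 for names that differ only in word order and degrades smoothly
#' with spelling differences.
#'
#' @param a,b Character scalars.
#' @return Similarity in `[0, 1]`.
#' @export
#' @examples
#' token_similarity("bean, fresh", "fresh beans")  # > 0.9
token_similarity <- function(a, b) {
  sa <- sorted_tokens(a)
  sb <- sorted_tokens(b)
  if (!nzchar(sa) && !nzchar(sb)) return(1)
  d <- as.integer(utils::adist(sa, sb))
  1 - d / max(nchar(sa), nchar(sb))
}

sorted_tokens <- function(x) {
  x <- tolower(x)
  x <- gsub("[^a-z0-9 ]+", " ", x)
  toks <- strsplit(trimws(gsub("\\s+", " ", x)), " ", fixed = TRUE)[[1]]
  paste(sort(toks[nzchar(toks)]), collapse = " ")
}
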