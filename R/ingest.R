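# Ingestion and deduplication: read method-specific food-mention lists,
# drop non-edible items, canonicalize names and merge to a unique food list.
# Mentions come from three collection methods: focus group discussions (FGD),
# individual dietary surveys (SURVEY) and market/shop audits (MARKET).

FOOD_METHODS <- c("FGD", "SURVEY", "MARKET")

#' Build a table of raw food mentions
#'
#' @param raw_name Character vector of food names as collected.
#' @param method Collection method, one of `"FGD"`, `"SURVEY"`, `"MARKET"`
#'   (recycled).
#' @param locality,note Optional free-text columns (recycled).
#' @return A tibble with columns `raw_name`, `method`, `locality`, `note`.
#' @export
food_mentions <- function(raw_name, method, locality = "", note = "") {
  if (any(!nzchar(trimws(raw_name)))) {
    stop_fct("raw_name must be non-empty", class = "fct_mention_error")
  }
  if (!all(method %in% FOOD_METHODS)) {
    stop_fct("method must be one of ", paste(FOOD_METHODS, collapse = ", "),
             class = "fct_mention_error")
  }
  tibble::tibble(raw_name = as.character(raw_name),
                 method = rep_len(method, length(raw_name)),
                 locality = rep_len(as.character(locality), length(raw_name)),
                 note = rep_len(as.character(note), length(raw_name)))
}

#' Read one method's mention list from CSV
#'
#' Expects columns `raw_name`, `locality`, `note` (missing optional columns
#' are filled with empty strings).
#'
#' @param path CSV file path.
#' @param method Collection method tag to stamp on every row.
#' @return A mentions tibble (see [food_mentions()]).
#' @export
read_method_csv <- function(path, method) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  blank_na <- function(x) {
    if (is.null(x)) return("")
    ifelse(is.na(x), "", as.character(x))
  }
  food_mentions(df$raw_name, method,
                locality = blank_na(df$locality), note = blank_na(df$note))
}

#' Canonicalize a raw food name
#'
#' Lowercases, collapses whitespace, strips punctuation (commas and hyphens
#' inside names are kept, since canonical names like "beans, fresh" use them),
#' extracts any parenthetical descriptor as a synonym rather than part of the
#' key, and finally applies the synonym map (e.g. a local-language name to its
#' canonical English entry). Deterministic.
#'
#' @param raw_name Character scalar.
#' @param synonym_map Named character vector mapping alternative names to
#'   canonical names. Matching is on the normalized form.
#' @return A list with `canonical` (character) and `synonyms` (character
#'   vector of extracted parenthetical descriptors).
#' @export
#' @examples
#' canonicalize_name("  Matoke ")$canonical                 # "matoke"
#' canonicalize_name("Obushera (millet drink)")             # synonym kept
#' canonicalize_name("ebihimba", c(ebihimba = "beans, fresh"))
canonicalize_name <- function(raw_name, synonym_map = character()) {
  if (!is.character(raw_name) || length(raw_name) != 1 || !nzchar(trimws(raw_name))) {
    stop_fct("raw_name must be a non-empty string", class = "fct_name_error")
  }
  x <- tolower(raw_name)
  synonyms <- character()
  paren <- regmatches(x, gregexpr("\\(([^)]*)\\)", x))[[1]]
  if (length(paren)) {
    synonyms <- trimws(gsub("[()]", "", paren))
    synonyms <- synonyms[nzchar(synonyms)]
    x <- gsub("\\([^)]*\\)", " ", x)
  }
  x <- gsub("[^a-z0-9, -]+", " ", x)
  x <- gsub("\\s*,\\s*", ", ", x)        # normalize comma spacing
  x <- trimws(gsub("\\s+", " ", x))
  x <- sub(",$", "", x)
  if (!nzchar(x)) {
    stop_fct("name '", raw_name, "' is empty after normalization",
             class = "fct_name_error")
  }
  if (length(synonym_map) && x %in% names(synonym_map)) {
    x <- unname(synonym_map[[x]])
  }
  list(canonical = x, synonyms = synonyms)
}

#' Partition mentions into edible and excluded items
#'
#' A mention is excluded when its canonical name matches one of the
#' (lowercase) exclusion terms — the step that removes non-edible items such
#' as cigarettes from collected food lists.
#'
#' @param mentions Mentions tibble.
#' @param exclusion_terms Character vector of lowercase canonical names to
#'   drop.
#' @param synonym_map Passed to [canonicalize_name()].
#' @return List with `kept` and `excluded` mention tibbles; together they
#'   partition the input.
#' @export
filter_edible <- function(mentions, exclusion_terms = character(),
                          synonym_map = character()) {
  if (nrow(mentions) == 0) {
    return(list(kept = mentions, excluded = mentions))
  }
  canon <- vapply(mentions$raw_name,
                  function(n) canonicalize_name(n, synonym_map)$canonical,
                  character(1), USE.NAMES = FALSE)
  drop <- canon %in% exclusion_terms
  list(kept = mentions[!drop, , drop = FALSE],
       excluded = mentions[drop, , drop = FALSE])
}

#' Merge method lists into a unique canonical food list
#'
#' Deduplication is exact match on the canonical name after synonym mapping
#' (the study-level judgement call of merging near-identical spellings is
#' delegated to the synonym map plus the fuzzy review report; nothing is
#' auto-merged on similarity alone). The result records, per canonical name,
#' which collection methods mentioned it and all contributing raw mentions.
#'
#' @param lists Named list of mention tibbles, names drawn from
#'   `FGD`/`SURVEY`/`MARKET` (a method column inside each tibble is also
#'   honoured); or a single mentions tibble.
#' @param synonym_map Passed to [canonicalize_name()].
#' @param review_threshold Similarity above which two distinct canonical
#'   names are flagged as possible duplicates in the review report
#'   (default 0.9).
#' @return An object of class `canonical_food_list`: a list with `entries`
#'   (tibble: `canonical_name`, `methods_seen`, `n_mentions`, `synonyms`,
#'   `mentions` list-column) and `review` (tibble of fuzzy duplicate
#'   candidates: `name_a`, `name_b`, `similarity`).
#' @export
merge_deduplicate <- function(lists, synonym_map = character(),
                              review_threshold = 0.9) {
  if (is.data.frame(lists)) lists <- list(lists)
  mentions <- do.call(rbind, unname(lists))
  if (is.null(mentions) || nrow(mentions) == 0) {
    entries <- tibble::tibble(canonical_name = character(),
                              methods_seen = list(), n_mentions = integer(),
                              synonyms = list(), mentions = list())
    return(structure(list(entries = entries,
                          review = tibble::tibble(name_a = character(),
                                                  name_b = character(),
                                                  similarity = numeric())),
                     class = "canonical_food_list"))
  }
  canon <- lapply(mentions$raw_name, canonicalize_name, synonym_map = synonym_map)
  mentions$canonical_name <- vapply(canon, `[[`, character(1), "canonical")
  syns <- lapply(canon, `[[`, "synonyms")

  keys <- sort(unique(mentions$canonical_name))
  idx <- split(seq_len(nrow(mentions)), mentions$canonical_name)[keys]
  entries <- tibble::tibble(
    canonical_name = keys,
    methods_seen = unname(lapply(idx, function(i)
      intersect(FOOD_METHODS, unique(mentions$method[i])))),
    n_mentions = unname(vapply(idx, length, integer(1))),
    synonyms = unname(lapply(idx, function(i)
      unique(unlist(syns[i])) %||% character())),
    mentions = unname(lapply(idx, function(i)
      mentions[i, c("raw_name", "method", "locality", "note"), drop = FALSE]))
  )

  review <- fuzzy_review(keys, review_threshold)
  structure(list(entries = entries, review = review),
            class = "canonical_food_list")
}

# Pairs of distinct canonical names similar enough to deserve a human look.
fuzzy_review <- function(names, threshold) {
  out <- list()
  if (length(names) >= 2) {
    sorted <- vapply(names, sorted_tokens, character(1))
    n <- length(names)
    for (i in seq_len(n - 1)) {
      d <- as.integer(utils::adist(sorted[i], sorted[(i + 1):n]))
      sim <- 1 - d / pmax(nchar(sorted[i]), nchar(sorted[(i + 1):n]))
      hit <- which(sim >= threshold)
      if (length(hit)) {
        out[[length(out) + 1]] <- tibble::tibble(
          name_a = names[i], name_b = names[i + hit], similarity = sim[hit])
      }
    }
  }
  if (length(out)) do.call(rbind, out)
  else tibble::tibble(name_a = character(), name_b = character(),
                      similarity = numeric())
}

#' @export
print.canonical_food_list <- function(x, ...) {
  cat("<canonical_food_list> ", nrow(x$entries), " unique foods from ",
      sum(x$entries$n_mentions), " mentions; ",
      nrow(x$review), " fuzzy duplicate candidate pair(s)\n", sep = "")
  invisible(x)
}
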