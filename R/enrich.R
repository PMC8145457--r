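# Enrichment: portions, accompanying-food prompts and local-language
# synonyms. All three operations are idempotent and commute, so enrichment
# order never matters.

#' Attach household-measure portions to a record
#'
#' Assigned portion descriptions are looked up in the registry of gram
#' weights; a generic "100 g" portion is always present so every record is
#' usable even without local measures.
#'
#' @param record A [food_record()].
#' @param registry Named numeric vector: portion description -> grams per
#'   unit.
#' @param assignments Named list: canonical food name -> character vector of
#'   portion descriptions.
#' @return The record with `portions` populated.
#' @export
attach_portions <- function(record, registry = numeric(), assignments = list()) {
  wanted <- assignments[[record$canonical_name]] %||% character()
  unknown <- setdiff(wanted, names(registry))
  if (length(unknown)) {
    stop_fct("portion description(s) not in registry: ",
             paste(unknown, collapse = ", "), class = "fct_portion_error")
  }
  p <- tibble::tibble(description = c(wanted, "100 g"),
                      grams_per_unit = c(unname(registry[wanted]), 100))
  p <- p[!duplicated(p$description), , drop = FALSE]
  record$portions <- p
  record
}

#' Attach accompanying-food prompts to a record
#'
#' Prompts name foods commonly consumed with the record's food (milk and
#' sugar with porridge, say); a dietary-assessment front-end surfaces them
#' automatically. Every prompted food must exist in the database.
#'
#' @param record A [food_record()].
#' @param prompt_map Named list: canonical food name -> character vector of
#'   accompanying canonical food names.
#' @param db_index Named character vector: canonical name -> record id for
#'   the whole database (referential-integrity check).
#' @return The record with `accompaniments` set to the prompted record ids.
#' @export
attach_accompaniments <- function(record, prompt_map = list(), db_index = character()) {
  prompted <- prompt_map[[record$canonical_name]] %||% character()
  dangling <- setdiff(prompted, names(db_index))
  if (length(dangling)) {
    stop_fct("prompt target(s) absent from database: ",
             paste(dangling, collapse = ", "), class = "fct_prompt_error")
  }
  record$accompaniments <- unname(db_index[prompted])
  record
}

#' Attach local-language synonyms to a record
#'
#' @param record A [food_record()].
#' @param translations Tibble with columns `food`, `language`, `text`.
#' @return The record with `synonyms` appended, deduplicated
#'   case-insensitively within language.
#' @export
attach_synonyms <- function(record, translations) {
  mine <- translations[translations$food == record$canonical_name, , drop = FALSE]
  s <- rbind(record$synonyms,
             tibble::tibble(language = mine$language, text = mine$text))
  s <- s[!duplicated(paste(s$language, tolower(s$text))), , drop = FALSE]
  record$synonyms <- s
  record
}
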