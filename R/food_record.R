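# A food record is one canonical database entry: provenance, complete
# nutrient vector, household-measure portions, accompaniment prompts and
# local-language synonyms.

#' Construct a food record
#'
#' @param id Stable identifier.
#' @param canonical_name Normalized English name.
#' @param food_group One of the database's food groups (see
#'   [food_groups()]).
#' @param source One of `HOST_GENERIC`, `AFRICAN_FCT`, `LABEL`,
#'   `GENERATED_RECIPE`.
#' @param nutrients A `nutrient_vector`.
#' @param provenance Reference-table code (`"TABLE:CODE"`), label + donor
#'   reference, or recipe id, depending on `source`.
#' @param synonyms Tibble with columns `language`, `text` (may be empty).
#' @param portions Tibble with columns `description`, `grams_per_unit`.
#' @param accompaniments Character vector of accompanying food ids.
#' @return A `food_record` list.
#' @export
food_record <- function(id, canonical_name, food_group, source, nutrients,
                        provenance,
                        synonyms = tibble::tibble(language = character(),
                                                  text = character()),
                        portions = tibble::tibble(description = character(),
                                                  grams_per_unit = numeric()),
                        accompaniments = character()) {
  if (!source %in% SOURCE_TAGS) {
    stop_fct("unknown source tag '", source, "'", class = "fct_record_error")
  }
  if (!food_group %in% food_groups()) {
    stop_fct("unknown food group '", food_group, "'", class = "fct_record_error")
  }
  if (is.na(provenance) || !nzchar(provenance)) {
    stop_fct("record '", canonical_name, "': provenance required for source ",
             source, class = "fct_record_error")
  }
  if (source == "LABEL" && !grepl("donor=", provenance, fixed = TRUE)) {
    stop_fct("LABEL record '", canonical_name,
             "' must reference its generic donor in provenance (donor=TABLE:CODE)",
             class = "fct_record_error")
  }
  if (any(portions$grams_per_unit <= 0)) {
    stop_fct("portion gram weights must be positive", class = "fct_record_error")
  }
  structure(list(id = id, canonical_name = canonical_name,
                 food_group = food_group, source = source,
                 nutrients = nutrients, provenance = provenance,
                 synonyms = synonyms, portions = portions,
                 accompaniments = accompaniments),
            class = "food_record")
}

#' Food groups used by the database
#' @return Character vector of group keys.
#' @export
food_groups <- function() {
  c("fruit_vegetable", "cereal", "meat_fish", "eggs_dairy", "sugary",
    "oils_fats_condiments", "soft_drink", "alcoholic", "other")
}

#' @export
print.food_record <- function(x, ...) {
  cat("<food_record> ", x$id, " '", x$canonical_name, "' [", x$food_group,
      ", ", x$source, "]\n", sep = "")
  invisible(x)
}

#' Construct a daily requirement profile
#'
#' @param group_label Demographic group, e.g. `"male, 1 year"`.
#' @param requirements Named numeric vector: nutrient key -> daily amount in
#'   that nutrient's panel unit; all positive.
#' @return A `requirement_profile` list.
#' @export
requirement_profile <- function(group_label, requirements) {
  if (any(requirements <= 0)) {
    stop_fct("requirement amounts must be positive", class = "fct_profile_error")
  }
  structure(list(group_label = group_label,
                 requirements = requirements),
            class = "requirement_profile")
}
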