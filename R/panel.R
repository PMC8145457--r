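# Nutrient panel and unit registry: the shared vocabulary of the package.
# Every nutrient value anywhere is "per 100 g edible portion" in the unit the
# panel declares for that nutrient.

#' Unit registry
#'
#' Registered units with their dimension and scale factor to the dimension's
#' base unit. Mass units scale to grams; energy units to kilocalories using
#' the standard thermochemical factor 1 kcal = 4.184 kJ. Retinol equivalents
#' (`ug_RE`) are their own dimension: they are micrograms numerically but must
#' not be silently converted into plain mass.
#'
#' @return A tibble with columns `unit`, `dimension`, `to_base`.
#' @export
unit_registry <- function() {
  tibble::tibble(
    unit      = c("g", "mg", "ug", "kcal", "kJ", "ug_RE"),
    dimension = c("mass", "mass", "mass", "energy", "energy", "retinol_equivalent"),
    to_base   = c(1, 1e-3, 1e-6, 1, 1 / 4.184, 1)
  )
}

KCAL_PER_KJ <- 1 / 4.184

#' Convert a quantity between registered units
#'
#' @param value Numeric quantity (vectorised).
#' @param from,to Unit keys present in [unit_registry()].
#' @param registry Unit registry table; defaults to the built-in one.
#' @return `value` expressed in `to` units.
#' @export
#' @examples
#' convert_unit(0.5, "g", "mg")     # 500
#' convert_unit(100, "kcal", "kJ")  # 418.4
convert_unit <- function(value, from, to, registry = unit_registry()) {
  i <- match(from, registry$unit)
  j <- match(to, registry$unit)
  if (is.na(i) || is.na(j)) {
    stop_fct("unknown unit(s): ", paste(setdiff(c(from, to), registry$unit), collapse = ", "),
             class = "fct_unit_error")
  }
  if (registry$dimension[i] != registry$dimension[j]) {
    stop_fct("cannot convert '", from, "' (", registry$dimension[i], ") to '",
             to, "' (", registry$dimension[j], ")", class = "fct_unit_error")
  }
  value * registry$to_base[i] / registry$to_base[j]
}

#' Default compact nutrient panel
#'
#' A panel is a table of nutrient definitions: key, display name, unit,
#' nutrient class (energy / macro / micro) and, for energy-contributing
#' nutrients, the Atwater factor in kcal per gram (protein 4, carbohydrate 4,
#' fat 9, fibre 2, alcohol 7). A production deployment can extend the panel up
#' to the ~120 nutrients a host dietary-assessment platform carries; all
#' package logic is panel-driven, so the compact default is only a default.
#'
#' @return A tibble with columns `key`, `display_name`, `unit`,
#'   `nutrient_class`, `atwater`.
#' @export
default_panel <- function() {
  p <- tibble::tibble(
    key = c("energy_kcal", "energy_kJ", "protein", "fat", "carbohydrate",
            "fibre", "calcium", "iron", "zinc", "vitamin_a", "vitamin_c"),
    display_name = c("Energy", "Energy", "Protein", "Fat", "Carbohydrate",
                     "Fibre", "Calcium", "Iron", "Zinc",
                     "Vitamin A (retinol equivalents)", "Vitamin C"),
    unit = c("kcal", "kJ", "g", "g", "g", "g", "mg", "mg", "mg", "ug_RE", "mg"),
    nutrient_class = c("energy", "energy", "macro", "macro", "macro",
                       "macro", "micro", "micro", "micro", "micro", "micro"),
    atwater = c(NA, NA, 4, 9, 4, 2, NA, NA, NA, NA, NA)
  )
  validate_panel(p)
  p
}

#' Validate a nutrient panel definition
#'
#' Checks key uniqueness, registered units, and that Atwater factors are only
#' set on energy-contributing nutrients (protein, carbohydrate, fat, alcohol,
#' fibre).
#'
#' @param panel Panel tibble.
#' @return The panel, invisibly; errors describe the first violation found.
#' @export
validate_panel <- function(panel) {
  stopifnot(all(c("key", "display_name", "unit", "nutrient_class", "atwater")
                %in% names(panel)))
  if (anyDuplicated(panel$key)) {
    stop_fct("duplicate nutrient keys in panel", class = "fct_panel_error")
  }
  bad_unit <- setdiff(panel$unit, unit_registry()$unit)
  if (length(bad_unit)) {
    stop_fct("panel uses unregistered unit(s): ", paste(bad_unit, collapse = ", "),
             class = "fct_panel_error")
  }
  allowed_atwater <- c("protein", "carbohydrate", "fat", "alcohol", "fibre")
  bearer <- panel$key[!is.na(panel$atwater)]
  if (!all(bearer %in% allowed_atwater)) {
    stop_fct("atwater factor set on non energy-contributing nutrient: ",
             paste(setdiff(bearer, allowed_atwater), collapse = ", "),
             class = "fct_panel_error")
  }
  invisible(panel)
}

#' Read a nutrient panel from a YAML config file
#'
#' The file holds a list of `{key, name, unit, class, atwater}` entries;
#' `atwater: ~` (null) marks non energy-contributing nutrients.
#'
#' @param path Path to the YAML file.
#' @return A validated panel tibble.
#' @export
read_panel <- function(path) {
  raw <- yaml::read_yaml(path)
  p <- tibble::tibble(
    key = vapply(raw, function(x) x$key, character(1)),
    display_name = vapply(raw, function(x) x$name, character(1)),
    unit = vapply(raw, function(x) x$unit, character(1)),
    nutrient_class = vapply(raw, function(x) x$class, character(1)),
    atwater = vapply(raw, function(x) as.numeric(x$atwater %||% NA_real_), numeric(1))
  )
  validate_panel(p)
  p
}

#' Write a nutrient panel to YAML
#'
#' @param panel Panel tibble.
#' @param path Destination file.
#' @return `path`, invisibly.
#' @export
write_panel <- function(panel, path) {
  entries <- lapply(seq_len(nrow(panel)), function(i) {
    list(key = panel$key[i], name = panel$display_name[i], unit = panel$unit[i],
         class = panel$nutrient_class[i],
         atwater = if (is.na(panel$atwater[i])) NULL else panel$atwater[i])
  })
  yaml::write_yaml(entries, path)
  invisible(path)
}
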