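# Nutrient vectors: per-100 g edible-portion values over a panel, with
# explicit missingness (NA). The class is a named numeric covering exactly the
# panel's keys, so values and missing partition the panel by construction.

#' Construct a nutrient vector over a panel
#'
#' @param values Named numeric vector; names must be panel keys. Keys not
#'   supplied are recorded as missing. `NA` entries are also treated as
#'   missing.
#' @param panel Nutrient panel tibble (see [default_panel()]).
#' @param check_energy If `TRUE` (default), require that when both
#'   `energy_kcal` and `energy_kJ` are present they agree under
#'   kJ = kcal x 4.184 to within 0.5 %.
#' @return A `nutrient_vector`: named numeric over the full panel with `NA`
#'   marking missing nutrients.
#' @export
#' @examples
#' nutrient_vector(c(protein = 2, carbohydrate = 20, fat = 1,
#'                   fibre = 0, energy_kcal = 97, energy_kJ = 97 * 4.184,
#'                   calcium = 10, iron = 1, zinc = 0.5,
#'                   vitamin_a = 5, vitamin_c = 2))
nutrient_vector <- function(values = numeric(), panel = default_panel(),
                            check_energy = TRUE) {
  if (length(values) && is.null(names(values))) {
    stop_fct("values must be named by nutrient key", class = "fct_nv_error")
  }
  unknown <- setdiff(names(values), panel$key)
  if (length(unknown)) {
    stop_fct("unknown nutrient key(s): ", paste(unknown, collapse = ", "),
             class = "fct_nv_error")
  }
  if (any(values < 0, na.rm = TRUE)) {
    stop_fct("negative nutrient values are not allowed",
             class = "fct_nv_error")
  }
  out <- stats::setNames(rep(NA_real_, nrow(panel)), panel$key)
  out[names(values)] <- as.numeric(values)
  if (check_energy &&
      all(c("energy_kcal", "energy_kJ") %in% panel$key) &&
      !is.na(out["energy_kcal"]) && !is.na(out["energy_kJ"]) &&
      out["energy_kcal"] > 0) {
    rel <- abs(out["energy_kJ"] - out["energy_kcal"] * 4.184) /
      (out["energy_kcal"] * 4.184)
    if (rel > 0.005) {
      stop_fct(sprintf("energy_kJ (%.1f) disagrees with energy_kcal x 4.184 (%.1f) by %.1f%%",
                       out["energy_kJ"], out["energy_kcal"] * 4.184, 100 * rel),
               class = "fct_nv_error")
    }
  }
  structure(out, class = c("nutrient_vector", "numeric"))
}

#' @export
print.nutrient_vector <- function(x, ...) {
  cat("<nutrient_vector> per 100 g edible portion\n")
  print(unclass(x), ...)
  invisible(x)
}

#' Keys with no value in a nutrient vector
#' @param nv A `nutrient_vector`.
#' @return Character vector of missing nutrient keys.
#' @export
nv_missing <- function(nv) names(nv)[is.na(nv)]

#' Is a nutrient vector complete on its panel?
#' @param nv A `nutrient_vector`.
#' @return `TRUE` when no nutrient is missing.
#' @export
nv_complete <- function(nv) !anyNA(nv)

as_nutrient_vector <- function(x, panel, check_energy = TRUE) {
  if (inherits(x, "nutrient_vector")) return(x)
  x <- x[!is.na(x)]
  nutrient_vector(x, panel = panel, check_energy = check_energy)
}

#' Energy implied by the Atwater components of a vector
#'
#' Cross-check quantity for quality control: the kcal per 100 g implied by the
#' energy-contributing nutrients, sum of value_k x atwater_k over the panel's
#' Atwater-bearing nutrients (protein and carbohydrate 4 kcal/g, fat 9,
#' fibre 2, alcohol 7 under the default panel).
#'
#' @param nv A `nutrient_vector`.
#' @param panel The panel `nv` was built over.
#' @return Energy in kcal per 100 g.
#' @export
#' @examples
#' panel <- default_panel()
#' nv <- nutrient_vector(c(protein = 2, carbohydrate = 20, fat = 1, fibre = 0),
#'                       panel, check_energy = FALSE)
#' energy_from_atwater(nv, panel)  # 4*2 + 4*20 + 9*1 = 97
energy_from_atwater <- function(nv, panel = default_panel()) {
  bearer <- panel$key[!is.na(panel$atwater)]
  gaps <- intersect(bearer, nv_missing(nv))
  if (length(gaps)) {
    stop_fct("cannot compute Atwater energy; missing: ",
             paste(gaps, collapse = ", "), class = "fct_incomplete_error")
  }
  sum(unclass(nv)[bearer] * panel$atwater[match(bearer, panel$key)])
}
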