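# Dietary-adequacy arithmetic: how much of a dish meets a daily requirement,
# and how far a given intake goes towards a requirement profile. Units are
# the panel's; requirement profiles must use the same units.

#' Dish mass required to meet a daily requirement
#'
#' For a nutrient density `d` (amount per 100 g) and daily requirement `r`,
#' the required mass is `100 * r / d` grams. A zero density means the
#' requirement can never be met from this food; `Inf` is returned explicitly.
#'
#' @param density Nutrient amount per 100 g of the dish (> 0 for a finite
#'   answer).
#' @param requirement Daily requirement in the same unit.
#' @return Mass in grams (possibly `Inf`).
#' @export
#' @examples
#' required_mass(77, 770)   # 1000 g of a 77 kcal/100 g dish for 770 kcal/d
required_mass <- function(density, requirement) {
  if (density < 0 || requirement <= 0) {
    stop_fct("density must be >= 0 and requirement > 0",
             class = "fct_adequacy_error")
  }
  if (density == 0) return(Inf)
  100 * requirement / density
}

#' Nutrient amounts delivered by a given mass of a food
#'
#' @param record A [food_record()] with a complete nutrient vector.
#' @param mass_g Mass eaten, grams.
#' @return Named numeric vector of nutrient amounts (panel units).
#' @export
#' @examples
#' # 1000 g of a dish with iron 0.8 mg/100 g delivers 8 mg iron
nutrient_per_mass <- function(record, mass_g) {
  if (!nv_complete(record$nutrients)) {
    stop_fct("record '", record$canonical_name, "' has an incomplete vector",
             class = "fct_incomplete_error")
  }
  unclass(record$nutrients) * mass_g / 100
}

#' Adequacy ratios of an intake against a requirement profile
#'
#' @param intake Named numeric vector of nutrient amounts (as from
#'   [nutrient_per_mass()]).
#' @param profile A [requirement_profile()]. Only nutrients present in the
#'   profile are reported.
#' @return Named numeric vector: intake / requirement per nutrient (may
#'   exceed 1).
#' @export
#' @examples
#' prof <- requirement_profile("male, 1 year",
#'                             c(energy_kcal = 770, vitamin_a = 400))
#' adequacy_ratio(c(energy_kcal = 770, vitamin_a = 14), prof)
adequacy_ratio <- function(intake, profile) {
  keys <- names(profile$requirements)
  gaps <- setdiff(keys, names(intake))
  if (length(gaps)) {
    stop_fct("intake lacks nutrient(s) named in the profile: ",
             paste(gaps, collapse = ", "), class = "fct_adequacy_error")
  }
  intake[keys] / profile$requirements
}

#' Per-dish adequacy table
#'
#' Convenience wrapper: mass of the dish needed to satisfy each profiled
#' nutrient on its own, and the adequacy ratio of every profiled nutrient at
#' the mass that exactly satisfies `anchor` (default energy).
#'
#' @param record A [food_record()].
#' @param profile A [requirement_profile()].
#' @param anchor Nutrient key whose requirement fixes the evaluated mass.
#' @return Tibble: `nutrient`, `density_per_100g`, `requirement`,
#'   `required_mass_g`, `intake_at_anchor_mass`, `adequacy_at_anchor_mass`.
#' @export
adequacy_table <- function(record, profile, anchor = "energy_kcal") {
  keys <- names(profile$requirements)
  dens <- unclass(record$nutrients)[keys]
  req <- profile$requirements
  req_mass <- mapply(required_mass, dens, req)
  anchor_mass <- required_mass(dens[[anchor]], req[[anchor]])
  intake <- nutrient_per_mass(record, anchor_mass)[keys]
  tibble::tibble(nutrient = keys,
                 density_per_100g = unname(dens),
                 requirement = unname(req),
                 required_mass_g = unname(req_mass),
                 intake_at_anchor_mass = unname(intake),
                 adequacy_at_anchor_mass = unname(adequacy_ratio(intake, profile)))
}

#' Read requirement profiles from YAML
#'
#' File layout: named map of group label -> map nutrient key -> daily amount.
#'
#' @param path YAML path.
#' @return Named list of [requirement_profile()]s.
#' @export
read_profiles <- function(path) {
  raw <- yaml::read_yaml(path)
  out <- lapply(names(raw), function(lbl) {
    requirement_profile(lbl, unlist(raw[[lbl]]))
  })
  stats::setNames(out, names(raw))
}

#' Demo requirement profile: 1-year-old boy
#'
#' FAO-cited daily energy requirement of 770 kcal and vitamin A requirement
#' of 400 ug RE for a male child aged one year — the group used in the
#' package's worked complementary-feeding example.
#'
#' @return A [requirement_profile()].
#' @export
profile_boy_1y <- function() {
  requirement_profile("male, 1 year", c(energy_kcal = 770, vitamin_a = 400))
}
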