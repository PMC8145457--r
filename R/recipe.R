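# Recipe nutrient calculation: per-100 g vectors for composite dishes from
# participant-reported ingredient amounts. Two modes coexist per ingredient:
#
#   COOKED — amounts refer to the ready-to-eat ingredient and its reference
#     vector is cooked-basis, so no water or cooking factor is applied (the
#     common case: cooking change is already embodied in the cooked entry);
#   RAW — amounts are raw masses, the reference vector is raw-basis, and a
#     cooking-yield factor (cooked mass / raw mass) plus optional per-nutrient
#     retention fractions convert to the cooked dish.
#
# Nutrient mass comes from the reported (state-basis) mass; dish mass from
# cooked-equivalent masses plus added water; added water contributes mass but
# no nutrients.

#' Construct a recipe ingredient
#'
#' @param food Canonical name of a food resolvable to a complete
#'   `nutrient_vector` on the same basis as `state`.
#' @param state `"COOKED"` (default) or `"RAW"`.
#' @param amounts Numeric vector of participant-reported masses in grams
#'   (one per report); all positive.
#' @param yield Cooking-yield factor, cooked mass / raw mass; required for
#'   RAW ingredients, ignored for COOKED.
#' @param retention Named numeric vector of nutrient retention fractions in
#'   (0, 1], applied to RAW ingredients only; nutrients not named retain 1.
#' @return An `ingredient` list.
#' @export
ingredient <- function(food, state = c("COOKED", "RAW"), amounts,
                       yield = NULL, retention = numeric()) {
  state <- match.arg(state)
  if (length(amounts) == 0 || any(amounts <= 0)) {
    stop_fct("ingredient '", food, "': amounts must be a non-empty vector of positive masses",
             class = "fct_recipe_error")
  }
  if (state == "RAW") {
    if (is.null(yield) || yield <= 0) {
      stop_fct("ingredient '", food, "': RAW state requires yield > 0",
               class = "fct_recipe_error")
    }
    if (length(retention) && (any(retention <= 0) || any(retention > 1))) {
      stop_fct("ingredient '", food, "': retention fractions must lie in (0, 1]",
               class = "fct_recipe_error")
    }
  } else {
    yield <- 1
    retention <- numeric()
  }
  structure(list(food = food, state = state, amounts = as.numeric(amounts),
                 yield = yield, retention = retention),
            class = "ingredient")
}

#' Construct a composite recipe
#'
#' @param recipe_id Stable identifier.
#' @param name Dish name.
#' @param ingredients List of [ingredient()] objects (at least one).
#' @param variant Variant tag distinguishing versions of the same dish
#'   (e.g. `"fresh_beans"` vs `"dried_beans"`), or `"none"`.
#' @param cooking_method One of `"boiled"`, `"fried"`, `"raw_assembled"`.
#' @param water_added_g Water added during cooking, grams (>= 0).
#' @param measured_cooked_mass_g Measured mass of the finished dish, or
#'   `NULL` to compute it from cooked-equivalent ingredient masses + water.
#' @param food_group Food group for the resulting database record.
#' @return A `recipe` list.
#' @export
recipe <- function(recipe_id, name, ingredients, variant = "none",
                   cooking_method = c("boiled", "fried", "raw_assembled"),
                   water_added_g = 0, measured_cooked_mass_g = NULL,
                   food_group = "other") {
  cooking_method <- match.arg(cooking_method)
  if (length(ingredients) < 1) {
    stop_fct("recipe '", name, "' needs at least one ingredient",
             class = "fct_recipe_error")
  }
  if (water_added_g < 0) {
    stop_fct("water_added_g must be >= 0", class = "fct_recipe_error")
  }
  if (!is.null(measured_cooked_mass_g) && measured_cooked_mass_g <= 0) {
    stop_fct("measured_cooked_mass_g must be positive when given",
             class = "fct_recipe_error")
  }
  structure(list(recipe_id = recipe_id, name = name, variant = variant,
                 cooking_method = cooking_method,
                 water_added_g = water_added_g,
                 measured_cooked_mass_g = measured_cooked_mass_g,
                 ingredients = ingredients, food_group = food_group),
            class = "recipe")
}

#' Average participant-reported amounts for one ingredient
#'
#' Participants report the ingredient quantity independently; the recipe uses
#' their arithmetic mean.
#'
#' @param amounts Non-empty numeric vector of positive masses (g).
#' @return Mean mass in grams.
#' @export
average_ingredient_amount <- function(amounts) {
  if (length(amounts) == 0) {
    stop_fct("no reported amounts to average", class = "fct_recipe_error")
  }
  if (any(amounts <= 0)) {
    stop_fct("reported amounts must be positive", class = "fct_recipe_error")
  }
  mean(amounts)
}

# Cooked-equivalent mass of each ingredient: the mass it contributes to the
# finished dish (mean raw mass x yield for RAW; mean reported mass for COOKED).
cooked_equivalent_masses <- function(rec) {
  vapply(rec$ingredients, function(ing) {
    average_ingredient_amount(ing$amounts) * ing$yield
  }, numeric(1))
}

state_basis_masses <- function(rec) {
  vapply(rec$ingredients, function(ing) average_ingredient_amount(ing$amounts),
         numeric(1))
}

#' Ingredient percentages of a recipe
#'
#' Each ingredient's cooked-equivalent mass as a fraction of the total
#' cooked-equivalent ingredient mass (added water excluded). Fractions sum
#' to 1.
#'
#' @param rec A [recipe()].
#' @return Named numeric vector of fractions, one per ingredient food.
#' @export
ingredient_percentages <- function(rec) {
  m <- cooked_equivalent_masses(rec)
  total <- sum(m)
  if (total <= 0) {
    stop_fct("recipe '", rec$name, "': total ingredient mass is zero",
             class = "fct_recipe_error")
  }
  stats::setNames(m / total, vapply(rec$ingredients, `[[`, character(1), "food"))
}

#' Mass of the finished dish, with water bookkeeping
#'
#' Uses the measured cooked mass when recorded; otherwise the sum of
#' cooked-equivalent ingredient masses plus added water. The water balance
#' (raw-side masses + added water - cooked mass) is reported as evaporation
#' when positive; a negative balance (net absorption beyond the accounted
#' water) can only arise with a measured mass and is flagged.
#'
#' @param rec A [recipe()].
#' @return List with `mass_g`, `evaporation_g`, `flag` (`NA` or a note).
#' @export
cooked_dish_mass <- function(rec) {
  ce_total <- sum(cooked_equivalent_masses(rec)) + rec$water_added_g
  raw_side <- sum(state_basis_masses(rec)) + rec$water_added_g
  if (!is.null(rec$measured_cooked_mass_g)) {
    mass <- rec$measured_cooked_mass_g
  } else {
    mass <- ce_total
  }
  delta <- raw_side - mass
  flag <- NA_character_
  if (delta < 0 && !is.null(rec$measured_cooked_mass_g)) {
    flag <- "measured dish mass exceeds raw-side inputs: unaccounted water absorption"
  }
  list(mass_g = mass, evaporation_g = delta, flag = flag)
}

#' Per-100 g nutrient vector of a composite dish
#'
#' Total nutrient mass is `sum_i mass_i x n_i(k) / 100 x retention_i(k)` where
#' `mass_i` is the averaged state-basis mass and `n_i` the ingredient's
#' per-100 g vector on the same basis (retention applies to RAW ingredients
#' only). Division by the cooked dish mass then yields the per-100 g density;
#' added water dilutes but carries no nutrients.
#'
#' @param rec A [recipe()].
#' @param resolver Function `food name -> nutrient_vector` (complete, on the
#'   ingredient's state basis).
#' @param panel Nutrient panel.
#' @return A complete `nutrient_vector` for 100 g of the cooked dish.
#' @export
compute_recipe_per100g <- function(rec, resolver, panel = default_panel()) {
  total <- stats::setNames(rep(0, nrow(panel)), panel$key)
  for (ing in rec$ingredients) {
    nv <- resolver(ing$food)
    if (is.null(nv)) {
      stop_fct("recipe '", rec$name, "': ingredient '", ing$food,
               "' does not resolve to a nutrient vector",
               class = "fct_recipe_error")
    }
    if (!nv_complete(nv)) {
      stop_fct("recipe '", rec$name, "': ingredient '", ing$food,
               "' vector incomplete; missing: ",
               paste(nv_missing(nv), collapse = ", "),
               class = "fct_incomplete_error")
    }
    mass <- average_ingredient_amount(ing$amounts)
    ret <- stats::setNames(rep(1, nrow(panel)), panel$key)
    if (ing$state == "RAW" && length(ing$retention)) {
      ret[names(ing$retention)] <- ing$retention
    }
    total <- total + mass * unclass(nv) / 100 * ret
  }
  dish <- cooked_dish_mass(rec)
  per100 <- total * 100 / dish$mass_g
  # the energy pair is recomputed jointly so mixing keeps kcal/kJ coherent
  nutrient_vector(per100, panel, check_energy = TRUE)
}
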