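# Shared test helpers: a complete nutrient vector builder and a lazily built,
# memoised default fixture + database so expensive end-to-end objects are
# constructed once per test run.

.cache <- new.env(parent = emptyenv())

default_fixture <- function(seed = 1) {
  key <- paste0("fixture_", seed)
  if (is.null(.cache[[key]])) .cache[[key]] <- generate_fixture(seed)
  .cache[[key]]
}

default_db <- function(seed = 1) {
  key <- paste0("db_", seed)
  if (is.null(.cache[[key]])) .cache[[key]] <- build_database(default_fixture(seed))
  .cache[[key]]
}

# complete vector on the default panel with overridable entries; energy pair
# kept coherent unless explicitly supplied
make_nv <- function(..., panel = default_panel()) {
  over <- c(...)
  base <- c(protein = 2, fat = 1, carbohydrate = 20, fibre = 1,
            calcium = 10, iron = 1, zinc = 0.5, vitamin_a = 5, vitamin_c = 2)
  base[names(over)[names(over) %in% names(base)]] <-
    over[names(over) %in% names(base)]
  e <- if ("energy_kcal" %in% names(over)) over[["energy_kcal"]] else
    4 * base[["protein"]] + 9 * base[["fat"]] + 4 * base[["carbohydrate"]] +
    2 * base[["fibre"]]
  kj <- if ("energy_kJ" %in% names(over)) over[["energy_kJ"]] else e * 4.184
  nutrient_vector(c(energy_kcal = e, energy_kJ = kj, base), panel,
                  check_energy = FALSE)
}

# minimal record wrapper for QC / adequacy tests
make_record <- function(nv, id = "t001", name = "test food",
                        group = "fruit_vegetable", source = "HOST_GENERIC",
                        provenance = "HOST:H001") {
  food_record(id, name, group, source, nv, provenance)
}

# independent brute-force oracle for recipe nutrient mass: per ingredient,
# total nutrient k is mass * density / 100 * retention, straight off the
# definition, summed with a plain loop
oracle_recipe_totals <- function(rec, vectors, panel) {
  totals <- setNames(rep(0, nrow(panel)), panel$key)
  for (ing in rec$ingredients) {
    m <- mean(ing$amounts)
    for (k in panel$key) {
      r <- 1
      if (ing$state == "RAW" && k %in% names(ing$retention)) r <- ing$retention[[k]]
      totals[k] <- totals[k] + m * unclass(vectors[[ing$food]])[[k]] / 100 * r
    }
  }
  totals
}
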