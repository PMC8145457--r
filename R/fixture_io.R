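# Fixture serialization: every generated input is written in the plain-text
# format the corresponding pipeline reader consumes, so generated fixtures
# and real study inputs travel through identical code paths.

#' Write a fixture to a directory
#'
#' Emits: `panel.yaml`, `fgd.csv` / `survey.csv` / `market.csv`,
#' `reference_tables.csv`, `labels.csv`, `recipes.yaml`, `food_groups.csv`,
#' `portion_registry.yaml`, `portion_assignments.yaml`, `prompts.yaml`,
#' `translations.csv`, `exclusions.csv`, `synonym_map.csv`, `manifest.json`.
#' Identical fixtures produce byte-identical files.
#'
#' @param fixture A [generate_fixture()] result.
#' @param dir Output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_fixture <- function(fixture, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(dir, f)
  wcsv <- function(df, f) utils::write.csv(df, p(f), row.names = FALSE)

  write_panel(fixture$panel, p("panel.yaml"))
  wcsv(fixture$mentions$FGD, "fgd.csv")
  wcsv(fixture$mentions$SURVEY, "survey.csv")
  wcsv(fixture$mentions$MARKET, "market.csv")
  wcsv(fixture$reference, "reference_tables.csv")
  wcsv(fixture$labels, "labels.csv")
  wcsv(fixture$food_groups, "food_groups.csv")
  wcsv(fixture$translations, "translations.csv")
  wcsv(tibble::tibble(term = fixture$exclusion_terms), "exclusions.csv")
  wcsv(tibble::tibble(alias = names(fixture$synonym_map),
                      canonical = unname(fixture$synonym_map)),
       "synonym_map.csv")

  rec_yaml <- lapply(names(fixture$recipes), function(fn) {
    r <- fixture$recipes[[fn]]
    list(recipe_id = r$recipe_id, name = r$name, food_name = fn,
         variant = r$variant, method = r$cooking_method,
         water_added_g = r$water_added_g,
         measured_cooked_mass_g = r$measured_cooked_mass_g,
         food_group = r$food_group,
         ingredients = lapply(r$ingredients, function(ing) {
           out <- list(food = ing$food, state = ing$state,
                       amounts = as.list(ing$amounts))
           if (ing$state == "RAW") {
             out$yield <- ing$yield
             if (length(ing$retention)) out$retention <- as.list(ing$retention)
           }
           out
         }))
  })
  yaml::write_yaml(rec_yaml, p("recipes.yaml"))
  yaml::write_yaml(as.list(fixture$portion_registry), p("portion_registry.yaml"))
  yaml::write_yaml(fixture$portion_assignments, p("portion_assignments.yaml"))
  yaml::write_yaml(fixture$prompts, p("prompts.yaml"))
  jsonlite::write_json(fixture$manifest, p("manifest.json"), auto_unbox = TRUE)
  invisible(dir)
}

#' Read recipes from YAML
#'
#' @param path `recipes.yaml` path.
#' @return Named list of [recipe()]s keyed by canonical food name.
#' @export
read_recipes_yaml <- function(path) {
  raw <- yaml::read_yaml(path)
  out <- lapply(raw, function(r) {
    ings <- lapply(r$ingredients, function(ing) {
      ingredient(ing$food, state = ing$state,
                 amounts = unlist(ing$amounts),
                 yield = ing$yield,
                 retention = if (is.null(ing$retention)) numeric()
                             else unlist(ing$retention))
    })
    recipe(r$recipe_id, r$name, ings, variant = r$variant,
           cooking_method = r$method, water_added_g = r$water_added_g,
           measured_cooked_mass_g = r$measured_cooked_mass_g,
           food_group = r$food_group)
  })
  stats::setNames(out, vapply(raw, `[[`, character(1), "food_name"))
}

#' Read a fixture back from a directory
#'
#' Inverse of [write_fixture()]; the result is usable anywhere a freshly
#' generated fixture is.
#'
#' @param dir Fixture directory.
#' @return A `fixture` list.
#' @export
read_fixture <- function(dir) {
  p <- function(f) file.path(dir, f)
  rcsv <- function(f) tibble::as_tibble(
    utils::read.csv(p(f), stringsAsFactors = FALSE, check.names = FALSE))
  panel <- read_panel(p("panel.yaml"))
  syn <- rcsv("synonym_map.csv")
  reg <- unlist(yaml::read_yaml(p("portion_registry.yaml")))
  assignments <- lapply(yaml::read_yaml(p("portion_assignments.yaml")), unlist)
  prompts <- lapply(yaml::read_yaml(p("prompts.yaml")), unlist)
  labels <- rcsv("labels.csv")
  for (k in panel$key) labels[[k]] <- as.numeric(labels[[k]])
  structure(list(
    panel = panel,
    mentions = list(FGD = read_method_csv(p("fgd.csv"), "FGD"),
                    SURVEY = read_method_csv(p("survey.csv"), "SURVEY"),
                    MARKET = read_method_csv(p("market.csv"), "MARKET")),
    reference = read_reference_csv(p("reference_tables.csv"), panel),
    labels = labels,
    recipes = read_recipes_yaml(p("recipes.yaml")),
    food_groups = rcsv("food_groups.csv"),
    portion_registry = reg,
    portion_assignments = assignments,
    prompts = prompts,
    translations = rcsv("translations.csv"),
    exclusion_terms = rcsv("exclusions.csv")$term,
    synonym_map = stats::setNames(syn$canonical, syn$alias),
    manifest = jsonlite::read_json(p("manifest.json"), simplifyVector = TRUE)
  ), class = "fixture")
}
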