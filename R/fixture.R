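# Seeded synthetic study-input generator. Produces the complete input set the
# pipeline consumes — method-specific mention lists, reference composition
# tables, back-of-pack label records, recipes, portion / prompt / translation
# configs — with the structure of the compiled-study conditions: mention
# lists of 139/69/95 whose canonical union is 148 foods, of which 82 resolve
# to the host table, 37 to regional African tables, 27 to generated recipes
# and 2 to partially labelled branded products.

#' Fixture configuration
#'
#' Defaults encode the study conditions the generator emulates. Counts are
#' validated for mutual consistency before any generation.
#'
#' @param n_fgd,n_survey,n_market Mention-list sizes per collection method.
#' @param n_unique Number of unique canonical foods across the three lists.
#' @param n_african Foods found only in regional (African) reference tables.
#' @param n_labels Branded foods with partial back-of-pack labels.
#' @param n_recipes Composite dishes sourced from generated recipes.
#' @param group_counts Named integer vector of foods per food group (must sum
#'   to `n_unique`).
#' @param recipe_group_counts Recipe templates instantiated per food group
#'   (must sum to `n_recipes`).
#' @param host_overlap Number of host-table foods that also appear in the
#'   Ugandan table with closely similar macronutrients (exercises the
#'   keep-host-when-similar rule).
#' @param african_weights Sampling weights for assigning regional-only foods
#'   to the Uganda / Tanzania / Kenya tables.
#' @return A validated `fixture_config` list.
#' @export
fixture_config <- function(n_fgd = 139, n_survey = 69, n_market = 95,
                           n_unique = 148, n_african = 37, n_labels = 2,
                           n_recipes = 27,
                           group_counts = c(fruit_vegetable = 64, cereal = 38,
                                            meat_fish = 20, eggs_dairy = 7,
                                            sugary = 5, oils_fats_condiments = 5,
                                            soft_drink = 6, alcoholic = 2,
                                            other = 1),
                           recipe_group_counts = c(fruit_vegetable = 13,
                                                   cereal = 13, meat_fish = 1),
                           host_overlap = 18,
                           african_weights = c(UGANDA = 0.6, TANZANIA = 0.25,
                                               KENYA = 0.15)) {
  cfg <- list(n_fgd = n_fgd, n_survey = n_survey, n_market = n_market,
              n_unique = n_unique, n_african = n_african, n_labels = n_labels,
              n_recipes = n_recipes, group_counts = group_counts,
              recipe_group_counts = recipe_group_counts,
              host_overlap = host_overlap, african_weights = african_weights)
  cfg$n_host <- n_unique - n_african - n_labels - n_recipes
  if (cfg$n_host < 0) {
    stop_fct("source counts exceed n_unique", class = "fct_fixture_error")
  }
  if (sum(group_counts) != n_unique) {
    stop_fct("group_counts must sum to n_unique (", n_unique, "), got ",
             sum(group_counts), class = "fct_fixture_error")
  }
  if (n_unique > n_fgd + n_survey + n_market) {
    stop_fct("n_unique exceeds the total number of mentions",
             class = "fct_fixture_error")
  }
  if (any(c(n_fgd, n_survey, n_market) > n_unique)) {
    stop_fct("a method list cannot mention more foods than exist",
             class = "fct_fixture_error")
  }
  if (sum(recipe_group_counts) != n_recipes) {
    stop_fct("recipe_group_counts must sum to n_recipes",
             class = "fct_fixture_error")
  }
  tpl_groups <- table(vapply(recipe_templates(), `[[`, character(1), "group"))
  for (grp in names(recipe_group_counts)) {
    have <- if (grp %in% names(tpl_groups)) tpl_groups[[grp]] else 0L
    if (recipe_group_counts[[grp]] > have) {
      stop_fct("not enough recipe templates for group '", grp, "'",
               class = "fct_fixture_error")
    }
  }
  if (is.null(solve_overlap(n_fgd, n_survey, n_market, n_unique))) {
    stop_fct("no feasible method-overlap structure for the configured sizes",
             class = "fct_fixture_error")
  }
  structure(cfg, class = "fixture_config")
}

# Solve the method-membership class sizes: partition the unique foods into
# the seven FGD/SURVEY/MARKET membership classes so the per-method totals
# match. Deterministic: prefers the largest all-methods class for which every
# class can stay non-empty, falling back to any feasible solution.
solve_overlap <- function(nF, nS, nM, U) {
  D <- nF + nS + nM - U  # duplicated memberships
  if (D < 0) return(NULL)
  fallback <- NULL
  for (g in seq(min(nF, nS, nM), 0)) {
    s <- D - 2 * g
    if (s < 0) next
    for (d in 0:s) {
      for (e in 0:(s - d)) {
        f <- s - d - e
        a <- nF - d - e - g
        b <- nS - d - f - g
        c_ <- nM - e - f - g
        if (a < 0 || b < 0 || c_ < 0) next
        sol <- c(F = a, S = b, M = c_, FS = d, FM = e, SM = f, FSM = g)
        if (is.null(fallback)) fallback <- sol
        if (all(sol >= 1)) return(sol)
      }
    }
  }
  fallback
}

#' Draw a complete synthetic nutrient vector
#'
#' Energy is drawn uniformly from the archetype's (or the food group's
#' default) kcal range; macronutrient grams follow the archetype's energy
#' shares under Atwater factors, with a joint +-5 % jitter so declared energy
#' and Atwater-implied energy agree within 15 %; energy_kJ is kcal x 4.184;
#' micronutrients are drawn from the archetype ranges. Uses the current RNG
#' state.
#'
#' @param food_group One of [food_groups()].
#' @param archetype Optional archetype key from the generator's calibration
#'   table; defaults to the group's generic archetype.
#' @param panel Nutrient panel (compact default).
#' @return A complete `nutrient_vector`.
#' @export
generate_nutrient_vector <- function(food_group, archetype = NULL,
                                     panel = default_panel()) {
  arch <- food_archetypes()
  key <- archetype %||% paste0("generic_", food_group)
  if (!key %in% names(arch)) {
    stop_fct("unknown archetype '", key, "'", class = "fct_fixture_error")
  }
  a <- arch[[key]]
  e <- stats::runif(1, a$e[1], a$e[2])
  jitter <- stats::runif(1, 0.95, 1.05)
  sh <- a$shares
  carb_share <- max(0, 1 - sum(sh))
  grams <- c(protein = e * jitter * sh[["protein"]] / 4,
             fat = e * jitter * sh[["fat"]] / 9,
             fibre = e * jitter * sh[["fibre"]] / 2,
             carbohydrate = e * jitter * carb_share / 4)
  nutrient_vector(c(energy_kcal = e, energy_kJ = e * 4.184, grams,
                    calcium = stats::runif(1, a$ca[1], a$ca[2]),
                    iron = stats::runif(1, a$fe[1], a$fe[2]),
                    zinc = stats::runif(1, a$zn[1], a$zn[2]),
                    vitamin_a = stats::runif(1, a$va[1], a$va[2]),
                    vitamin_c = stats::runif(1, a$vc[1], a$vc[2])),
                  panel)
}

#' Generate the 27 composite-dish recipes
#'
#' Instantiates the recipe templates with participant-report jitter: each
#' ingredient receives 1–5 reported amounts drawn within +-10 % of its base
#' amount. The set contains a fresh/dried bean variant pair sharing a recipe
#' name, exactly two recipes with RAW-state ingredients (cooking yield,
#' retention and added water) and exactly one dish with animal protein.
#' Uses the current RNG state.
#'
#' @param recipe_group_counts Named integer vector: how many recipe templates
#'   to instantiate per food group (defaults to the full template set).
#' @return Named list of [recipe()] objects keyed by canonical food name.
#' @export
generate_recipes <- function(recipe_group_counts = c(fruit_vegetable = 13,
                                                     cereal = 13,
                                                     meat_fish = 1)) {
  tpls <- select_recipe_templates(recipe_group_counts)
  out <- lapply(seq_along(tpls), function(i) {
    t <- tpls[[i]]
    ings <- lapply(t$ingredients, function(g) {
      n <- sample(1:5, 1)
      amounts <- round(g$base * stats::runif(n, 0.9, 1.1), 1)
      ingredient(g$food, state = g$state, amounts = amounts,
                 yield = g$yield, retention = g$retention %||% numeric())
    })
    recipe(sprintf("R%03d", i), t$name, ings, variant = t$variant,
           cooking_method = t$method, water_added_g = t$water,
           food_group = t$group)
  })
  stats::setNames(out, vapply(tpls, `[[`, character(1), "food_name"))
}

# Take the first k templates of each group, in template order.
select_recipe_templates <- function(recipe_group_counts) {
  tpls <- recipe_templates()
  groups <- vapply(tpls, `[[`, character(1), "group")
  keep <- unlist(lapply(names(recipe_group_counts), function(grp) {
    utils::head(which(groups == grp), recipe_group_counts[[grp]])
  }))
  tpls[sort(keep)]
}

# Raw-name styling for mention lists: deterministic given the RNG state.
style_mention <- function(name, rukiga = NA_character_) {
  u <- stats::runif(1)
  if (!is.na(rukiga) && u < 0.3) return(rukiga)
  if (u < 0.45) return(toupper(name))
  if (u < 0.65) {
    # capitalize first letter
    return(paste0(toupper(substr(name, 1, 1)), substr(name, 2, nchar(name))))
  }
  if (u < 0.75) return(paste0("  ", name, " "))
  name
}

#' Generate a full synthetic study-input fixture
#'
#' @param seed Integer seed; identical seed and config give an identical
#'   fixture (and byte-identical files via [write_fixture()]).
#' @param config A [fixture_config()].
#' @return A `fixture` list: `panel`, `mentions` (named list of tibbles per
#'   method), `reference` (combined reference-table tibble), `labels`
#'   (label-record tibble with a `donor_code` column), `recipes` (named list
#'   of [recipe()]s), `food_groups` (tibble `canonical_name`, `food_group`),
#'   `portion_registry`, `portion_assignments`, `prompts`, `translations`,
#'   `exclusion_terms`, `synonym_map`, `manifest`.
#' @export
generate_fixture <- function(seed = 1, config = fixture_config()) {
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, envir = globalenv()), add = TRUE)
  set.seed(seed)

  panel <- default_panel()
  pool <- base_food_pool()
  tpls <- select_recipe_templates(config$recipe_group_counts)
  recipe_foods <- tibble::tibble(
    name = vapply(tpls, `[[`, character(1), "food_name"),
    food_group = vapply(tpls, `[[`, character(1), "group"),
    archetype = NA_character_, is_label = FALSE)

  # --- select base foods per group to meet the configured counts -----------
  needed <- config$group_counts
  rec_per_group <- table(recipe_foods$food_group)
  base_sel <- list()
  for (grp in names(needed)) {
    want <- needed[[grp]] - (if (grp %in% names(rec_per_group))
      rec_per_group[[grp]] else 0L)
    avail <- pool[pool$food_group == grp, , drop = FALSE]
    if (nrow(avail) < want) {
      stop_fct("food pool too small for group '", grp, "' (need ", want,
               ", have ", nrow(avail), ")", class = "fct_fixture_error")
    }
    # labels are mandatory picks; the rest fill in pool order
    lab <- avail[avail$is_label, , drop = FALSE]
    rest <- avail[!avail$is_label, , drop = FALSE]
    base_sel[[grp]] <- rbind(lab, rest)[seq_len(want), , drop = FALSE]
  }
  base <- do.call(rbind, base_sel)
  if (sum(base$is_label) != config$n_labels) {
    stop_fct("configured group counts exclude the label foods",
             class = "fct_fixture_error")
  }

  all_foods <- rbind(base, recipe_foods)
  stopifnot(nrow(all_foods) == config$n_unique)

  # --- source assignment: labels fixed, n_african sampled from the rest ----
  candidates <- which(!base$is_label)
  african_idx <- sort(sample(candidates, config$n_african))
  base$planned_source <- ifelse(base$is_label, "LABEL", "HOST_GENERIC")
  base$planned_source[african_idx] <- "AFRICAN_FCT"

  # --- nutrient vectors for base foods and donors --------------------------
  base_nv <- lapply(seq_len(nrow(base)), function(i)
    generate_nutrient_vector(base$food_group[i], base$archetype[i], panel))
  names(base_nv) <- base$name
  donors <- label_donor_pool()
  donor_nv <- lapply(seq_len(nrow(donors)), function(i)
    generate_nutrient_vector("oils_fats_condiments", donors$archetype[i], panel))

  nv_row <- function(nv) {
    v <- unclass(nv)
    stats::setNames(as.list(v), names(v))
  }
  ref_rows <- list()
  add_row <- function(table_id, food_code, name, nv) {
    ref_rows[[length(ref_rows) + 1]] <<- tibble::as_tibble(
      c(list(table_id = table_id, food_code = food_code, name = name),
        nv_row(nv)))
  }

  host_i <- which(base$planned_source == "HOST_GENERIC")
  for (k in seq_along(host_i)) {
    add_row("HOST", sprintf("H%03d", k), base$name[host_i[k]],
            base_nv[[host_i[k]]])
  }
  for (k in seq_len(nrow(donors))) {
    add_row("HOST", donors$food_code[k], donors$name[k], donor_nv[[k]])
  }
  # a subset of host foods also sits in the Ugandan table with macros within
  # +-8 %, so the keep-host-when-similar comparison is exercised
  overlap_i <- sample(host_i, min(config$host_overlap, length(host_i)))
  u_code <- 0L
  for (i in overlap_i) {
    v <- unclass(base_nv[[i]])
    jit <- stats::runif(length(v), 0.92, 1.08)
    v2 <- v * jit
    v2["energy_kJ"] <- v2["energy_kcal"] * 4.184
    u_code <- u_code + 1L
    add_row("UGANDA", sprintf("U9%02d", u_code), base$name[i],
            nutrient_vector(v2, panel, check_energy = FALSE))
  }
  african_i <- which(base$planned_source == "AFRICAN_FCT")
  tabs <- sample(names(config$african_weights), length(african_i),
                 replace = TRUE, prob = config$african_weights)
  counters <- c(UGANDA = 0L, TANZANIA = 0L, KENYA = 0L)
  for (k in seq_along(african_i)) {
    tb <- tabs[k]
    counters[tb] <- counters[tb] + 1L
    add_row(tb, sprintf("%s%03d", substr(tb, 1, 1), counters[tb]),
            base$name[african_i[k]], base_nv[[african_i[k]]])
  }
  reference <- do.call(rbind, ref_rows)

  # --- back-of-pack label records: partial panels --------------------------
  declared <- c("energy_kcal", "energy_kJ", "protein", "fat", "carbohydrate")
  label_i <- which(base$is_label)
  label_rows <- lapply(seq_along(label_i), function(k) {
    i <- label_i[k]
    v <- unclass(base_nv[[i]])
    v[setdiff(names(v), declared)] <- NA_real_
    donor <- donors$food_code[match(base$name[i], donors$label_food)]
    tibble::as_tibble(c(list(table_id = "LABEL",
                             food_code = sprintf("L%03d", k),
                             name = base$name[i],
                             donor_code = paste0("HOST:", donor)),
                        stats::setNames(as.list(v), names(v))))
  })
  labels <- do.call(rbind, label_rows)

  # --- method lists: membership classes, then styled raw mentions ----------
  sizes <- solve_overlap(config$n_fgd, config$n_survey, config$n_market,
                         config$n_unique)
  class_of <- rep(names(sizes), sizes)
  class_of <- sample(class_of)  # which food lands in which class is seeded
  names(class_of) <- sample(all_foods$name)
  membership <- list(
    FGD = names(class_of)[class_of %in% c("F", "FS", "FM", "FSM")],
    SURVEY = names(class_of)[class_of %in% c("S", "FS", "SM", "FSM")],
    MARKET = names(class_of)[class_of %in% c("M", "FM", "SM", "FSM")])
  translations <- translation_pool()
  rukiga_of <- stats::setNames(translations$text, translations$food)
  localities <- c("Buhoma", "Byumba", "Mukono", "Kihembe")
  mentions <- lapply(names(membership), function(m) {
    foods <- sample(membership[[m]])
    raw <- vapply(foods, function(f)
      style_mention(f, rukiga_of[f] %||% NA_character_), character(1))
    food_mentions(unname(raw), m,
                  locality = sample(localities, length(foods), replace = TRUE))
  })
  names(mentions) <- names(membership)

  # --- recipes, enrichment configs ----------------------------------------
  recipes <- generate_recipes(config$recipe_group_counts)

  portion_registry <- c("soup spoon" = 30, "cup" = 240, "ladle" = 120,
                        "handful" = 40, "small plate" = 250, "piece" = 50,
                        "glass" = 200, "slice" = 35)
  fixed_assign <- list(
    "beans, dried, boiled" = "soup spoon",
    "beans, fresh" = c("soup spoon", "ladle"),
    "matoke with fresh beans" = "small plate",
    "matoke with dried beans" = "small plate",
    "porridge, maize" = "cup", "porridge, millet" = "cup",
    "milk, fresh, whole" = c("glass", "cup"), "bread, white" = "slice")
  extra <- setdiff(sample(all_foods$name, min(30, nrow(all_foods))),
                   names(fixed_assign))
  portion_assignments <- c(fixed_assign, stats::setNames(
    lapply(extra, function(f) sample(names(portion_registry),
                                     sample(1:2, 1))), extra))

  prompts <- list(
    "porridge, maize" = c("milk, fresh, whole", "sugar"),
    "porridge, millet" = c("milk, fresh, whole", "sugar"),
    "tea, black" = c("milk, fresh, whole", "sugar"),
    "chapati" = "beans, fresh")

  synonym_map <- stats::setNames(translations$food, translations$text)

  manifest <- list(seed = seed,
                   config_hash = fnv1a32(jsonlite::toJSON(unclass(config),
                                                          auto_unbox = TRUE)),
                   n_unique = config$n_unique,
                   provenance = "SYNTHETIC fixture: all nutrient values are generated, not reference data")

  structure(list(panel = panel, mentions = mentions, reference = reference,
                 labels = labels, recipes = recipes,
                 food_groups = tibble::tibble(canonical_name = all_foods$name,
                                              food_group = all_foods$food_group),
                 portion_registry = portion_registry,
                 portion_assignments = portion_assignments,
                 prompts = prompts, translations = translations,
                 exclusion_terms = c("cigarettes", "soap", "paraffin", "charcoal"),
                 synonym_map = synonym_map, manifest = manifest),
            class = "fixture")
}

#' @export
print.fixture <- function(x, ...) {
  cat("<fixture> ", sum(vapply(x$mentions, nrow, integer(1))),
      " mentions over ", length(x$mentions), " methods; ",
      nrow(x$food_groups), " planned foods; ", length(x$recipes),
      " recipes (seed ", x$manifest$seed, ")\n", sep = "")
  invisible(x)
}
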