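test_that("default fixture reproduces the collection structure", {
  fx <- default_fixture()
  sizes <- vapply(fx$mentions, nrow, integer(1))
  expect_equal(unname(sizes), c(139, 69, 95))
  expect_equal(sum(sizes), 303)

  merged <- merge_deduplicate(fx$mentions, fx$synonym_map)
  expect_equal(nrow(merged$entries), 148)
  expect_setequal(merged$entries$canonical_name, fx$food_groups$canonical_name)

  # planned source structure: 27 recipe-only foods, 2 labels, the rest split
  # host / regional
  ref_names <- unique(fx$reference$name)
  recipe_only <- setdiff(fx$food_groups$canonical_name,
                         c(ref_names, fx$labels$name))
  expect_equal(length(recipe_only), 27)
  expect_setequal(recipe_only, names(fx$recipes))
  expect_equal(nrow(fx$labels), 2)
  host_names <- fx$reference$name[fx$reference$table_id == "HOST"]
  african_only <- setdiff(ref_names, host_names)
  expect_equal(length(intersect(host_names, fx$food_groups$canonical_name)), 82)
  expect_equal(length(african_only), 37)

  # food-group counts follow the configured composition
  counts <- table(fx$food_groups$food_group)
  expect_equal(counts[["fruit_vegetable"]], 64)
  expect_equal(counts[["cereal"]], 38)
  expect_equal(counts[["meat_fish"]], 20)
  expect_equal(counts[["eggs_dairy"]], 7)
  expect_equal(counts[["soft_drink"]], 6)
  expect_equal(counts[["alcoholic"]], 2)
  expect_equal(counts[["other"]], 1)
})

test_that("identical seeds give byte-identical fixture files", {
  d1 <- tempfile(); d2 <- tempfile(); d3 <- tempfile()
  on.exit(unlink(c(d1, d2, d3), recursive = TRUE))
  write_fixture(generate_fixture(42), d1)
  write_fixture(generate_fixture(42), d2)
  write_fixture(generate_fixture(43), d3)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     label = paste("file", f))
  }
  # a different seed must actually change the data
  expect_false(identical(readLines(file.path(d1, "fgd.csv")),
                         readLines(file.path(d3, "fgd.csv"))))
})

test_that("fixtures round-trip through their own readers", {
  fx <- default_fixture()
  dir <- tempfile()
  on.exit(unlink(dir, recursive = TRUE))
  write_fixture(fx, dir)
  back <- read_fixture(dir)
  expect_equal(back$mentions, fx$mentions)
  expect_equal(back$reference, fx$reference, tolerance = 1e-12)
  expect_equal(back$labels, fx$labels, tolerance = 1e-12)
  expect_equal(back$recipes, fx$recipes)
  expect_equal(back$food_groups, fx$food_groups)
  expect_equal(back$portion_registry, fx$portion_registry)
  expect_equal(back$synonym_map, fx$synonym_map)
  expect_equal(back$panel, fx$panel)

  # a round-tripped fixture builds the same database
  db_mem <- default_db()
  db_disk <- build_database(back)
  expect_equal(db_disk$shares$by_source, db_mem$shares$by_source)
})

test_that("inconsistent fixture configs are rejected before generation", {
  expect_error(fixture_config(n_unique = 400), class = "fct_fixture_error")
  expect_error(fixture_config(group_counts = c(fruit_vegetable = 10)),
               class = "fct_fixture_error")
  expect_error(fixture_config(n_african = 300), class = "fct_fixture_error")
})

test_that("small configured overlaps deduplicate as designed", {
  cfg <- fixture_config(n_fgd = 6, n_survey = 5, n_market = 4, n_unique = 10,
                        n_african = 2, n_labels = 2, n_recipes = 3,
                        group_counts = c(fruit_vegetable = 4, cereal = 3,
                                         meat_fish = 1, eggs_dairy = 0,
                                         sugary = 1, oils_fats_condiments = 1,
                                         soft_drink = 0, alcoholic = 0,
                                         other = 0),
                        recipe_group_counts = c(fruit_vegetable = 2,
                                                cereal = 1, meat_fish = 0),
                        host_overlap = 2)
  fx <- generate_fixture(11, cfg)
  sizes <- vapply(fx$mentions, nrow, integer(1))
  expect_equal(unname(sizes), c(6, 5, 4))
  merged <- merge_deduplicate(fx$mentions, fx$synonym_map)
  expect_equal(nrow(merged$entries), 10)
  expect_equal(sum(sizes) - nrow(merged$entries), 5)  # duplicated mentions
})

test_that("generated nutrient vectors respect group calibration", {
  set.seed(77)
  for (i in 1:200) {
    nv <- generate_nutrient_vector("fruit_vegetable")
    e <- unclass(nv)[["energy_kcal"]]
    expect_gte(e, 15); expect_lte(e, 120)
    expect_true(nv_complete(nv))
    # kJ identity and Atwater coherence within 15 %
    expect_equal(unclass(nv)[["energy_kJ"]], e * 4.184, tolerance = 1e-12)
    expect_lte(abs(energy_from_atwater(nv) - e) / e, 0.15)
  }
  for (i in 1:50) {
    nv <- generate_nutrient_vector("meat_fish", archetype = "fish_fried")
    expect_gt(unclass(nv)[["energy_kcal"]], 200)
  }
  expect_error(generate_nutrient_vector("fruit_vegetable", "no_such"),
               class = "fct_fixture_error")
})

test_that("generated recipes have the designed composition", {
  fx <- default_fixture()
  recs <- fx$recipes
  expect_length(recs, 27)

  animal_foods <- c("tilapia, fried", "tilapia, boiled", "nile perch, fried",
                    "beef, boiled", "goat meat, boiled", "chicken, boiled",
                    "milk, fresh, whole", "egg, boiled", "silverfish, dried")
  has_animal <- vapply(recs, function(r)
    any(vapply(r$ingredients, `[[`, character(1), "food") %in% animal_foods),
    logical(1))
  expect_equal(sum(has_animal), 1)

  raw_mode <- vapply(recs, function(r)
    any(vapply(r$ingredients, `[[`, character(1), "state") == "RAW"),
    logical(1))
  expect_equal(sum(raw_mode), 2)

  n_ing <- vapply(recs, function(r) length(r$ingredients), integer(1))
  expect_true(all(n_ing >= 2 & n_ing <= 5))
  n_amounts <- unlist(lapply(recs, function(r)
    vapply(r$ingredients, function(i) length(i$amounts), integer(1))))
  expect_true(all(n_amounts >= 1 & n_amounts <= 5))

  # fresh/dried variant pair shares a recipe name, differs in variant tag
  names_tab <- vapply(recs, `[[`, character(1), "name")
  variants <- vapply(recs, `[[`, character(1), "variant")
  pair <- names_tab[variants == "fresh_beans"]
  expect_true(length(pair) >= 1)
  expect_true(all(pair %in% names_tab[variants == "dried_beans"]))
})
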