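panel <- default_panel()

# per-100 g vectors with a given kcal density, macros scaled to match
dish_nv <- function(kcal) {
  # all energy from carbohydrate keeps the Atwater identity exact
  make_nv(energy_kcal = kcal, energy_kJ = kcal * 4.184,
          protein = 0, fat = 0, fibre = 0, carbohydrate = kcal / 4)
}

test_that("participant amounts are averaged arithmetically", {
  expect_equal(average_ingredient_amount(c(200, 300, 400)), 300)
  expect_equal(average_ingredient_amount(250), 250)
  expect_equal(average_ingredient_amount(c(100, 150)), 125)
  expect_error(average_ingredient_amount(numeric()), class = "fct_recipe_error")
  expect_error(average_ingredient_amount(c(100, -5)), class = "fct_recipe_error")
})

test_that("ingredient percentages use cooked-equivalent masses and sum to 1", {
  rec <- recipe("r1", "beans and matoke",
                list(ingredient("beans", amounts = 300),
                     ingredient("matoke", amounts = 200)))
  pct <- ingredient_percentages(rec)
  expect_equal(unname(pct), c(0.6, 0.4))

  single <- recipe("r2", "solo", list(ingredient("x", amounts = 123)))
  expect_equal(unname(ingredient_percentages(single)), 1)

  # RAW rice 100 g with yield 2.5 contributes 250 g cooked-equivalent
  mixed <- recipe("r3", "rice and sauce",
                  list(ingredient("rice", "RAW", 100, yield = 2.5),
                       ingredient("sauce", amounts = 250)))
  expect_equal(unname(ingredient_percentages(mixed)), c(0.5, 0.5))
  expect_equal(sum(ingredient_percentages(mixed)), 1, tolerance = 1e-9)
})

test_that("dish mass uses measurement when present, else bookkeeping", {
  rec <- recipe("r1", "stew",
                list(ingredient("a", amounts = 600),
                     ingredient("b", amounts = 400)),
                measured_cooked_mass_g = 800)
  dm <- cooked_dish_mass(rec)
  expect_equal(dm$mass_g, 800)
  expect_equal(dm$evaporation_g, 200)

  rec2 <- recipe("r2", "mix",
                 list(ingredient("a", amounts = 300),
                      ingredient("b", amounts = 200)))
  expect_equal(cooked_dish_mass(rec2)$mass_g, 500)

  rec3 <- recipe("r3", "boiled rice",
                 list(ingredient("rice", "RAW", 100, yield = 2.5)),
                 water_added_g = 150)
  expect_equal(cooked_dish_mass(rec3)$mass_g, 400)

  expect_error(recipe("r4", "bad", list(ingredient("a", amounts = 1)),
                      measured_cooked_mass_g = -1), class = "fct_recipe_error")
})

test_that("per-100 g computation matches hand arithmetic", {
  vectors <- list(beans = dish_nv(120), matoke = dish_nv(110))
  resolver <- function(f) vectors[[f]]

  rec <- recipe("r1", "beans with matoke",
                list(ingredient("beans", amounts = 300),
                     ingredient("matoke", amounts = 200)))
  out <- compute_recipe_per100g(rec, resolver, panel)
  expect_equal(unclass(out)[["energy_kcal"]], 116)  # (360 + 220) / 500 * 100

  # single cooked ingredient: identity
  solo <- recipe("r2", "solo", list(ingredient("beans", amounts = 250)))
  expect_equal(unclass(compute_recipe_per100g(solo, resolver, panel)),
               unclass(vectors$beans), tolerance = 1e-12)

  # raw 100 g at 350 kcal raw-basis, yield 2.5: water uptake dilutes to 140
  raw_vec <- list(rice = dish_nv(350))
  raw_rec <- recipe("r3", "boiled rice",
                    list(ingredient("rice", "RAW", 100, yield = 2.5)))
  out_raw <- compute_recipe_per100g(raw_rec, function(f) raw_vec[[f]], panel)
  expect_equal(unclass(out_raw)[["energy_kcal"]], 140)

  expect_error(compute_recipe_per100g(rec, function(f) NULL, panel),
               class = "fct_recipe_error")
  gappy <- nutrient_vector(c(protein = 1), panel, check_energy = FALSE)
  expect_error(compute_recipe_per100g(solo, function(f) gappy, panel),
               class = "fct_incomplete_error")
})

test_that("retention factors act on RAW ingredients only", {
  v <- list(x = make_nv(vitamin_c = 10, iron = 2))
  raw_rec <- recipe("r", "x boiled",
                    list(ingredient("x", "RAW", 100, yield = 1,
                                    retention = c(vitamin_c = 0.5))))
  out <- compute_recipe_per100g(raw_rec, function(f) v[[f]], panel)
  expect_equal(unclass(out)[["vitamin_c"]], 5)
  expect_equal(unclass(out)[["iron"]], 2)  # untouched
})

test_that("recipe engine agrees with the brute-force nutrient-mass oracle", {
  set.seed(99)
  foods <- paste0("food", 1:8)
  for (trial in 1:200) {
    vectors <- stats::setNames(lapply(foods, function(f) {
      kcal <- runif(1, 30, 400)
      make_nv(energy_kcal = kcal, energy_kJ = kcal * 4.184,
              protein = 0, fat = 0, fibre = 0, carbohydrate = kcal / 4,
              calcium = runif(1, 1, 300), iron = runif(1, 0.1, 6),
              zinc = runif(1, 0.1, 3), vitamin_a = runif(1, 0, 600),
              vitamin_c = runif(1, 0, 50))
    }), foods)
    n_ing <- sample(2:5, 1)
    picks <- sample(foods, n_ing)
    ings <- lapply(picks, function(f) {
      if (runif(1) < 0.3) {
        ingredient(f, "RAW", amounts = runif(sample(1:5, 1), 20, 400),
                   yield = runif(1, 1.2, 3),
                   retention = c(vitamin_c = runif(1, 0.5, 1)))
      } else {
        ingredient(f, amounts = runif(sample(1:5, 1), 20, 400))
      }
    })
    rec <- recipe(paste0("t", trial), "random dish", ings,
                  water_added_g = sample(c(0, 0, 150), 1))
    out <- compute_recipe_per100g(rec, function(f) vectors[[f]], panel)
    dish_mass <- cooked_dish_mass(rec)$mass_g
    # nutrient mass conservation: per-100 g x mass / 100 == brute-force totals
    expect_equal(unclass(out) * dish_mass / 100,
                 oracle_recipe_totals(rec, vectors, panel),
                 tolerance = 1e-9)
  }
})

test_that("all-cooked dishes stay within ingredient density bounds (convexity)", {
  set.seed(7)
  for (trial in 1:50) {
    kcals <- runif(3, 20, 300)
    vectors <- list(a = dish_nv(kcals[1]), b = dish_nv(kcals[2]),
                    c = dish_nv(kcals[3]))
    rec <- recipe("t", "dish",
                  lapply(names(vectors), function(f)
                    ingredient(f, amounts = runif(1, 50, 500))))
    out <- unclass(compute_recipe_per100g(rec, function(f) vectors[[f]], panel))
    for (k in panel$key) {
      dens <- vapply(vectors, function(v) unclass(v)[[k]], numeric(1))
      expect_gte(out[[k]], min(dens) - 1e-9)
      expect_lte(out[[k]], max(dens) + 1e-9)
    }
  }
})

test_that("scaling all masses leaves the per-100 g vector unchanged", {
  vectors <- list(a = dish_nv(150), b = dish_nv(90))
  base <- recipe("r", "dish", list(ingredient("a", amounts = c(200, 300)),
                                   ingredient("b", amounts = 100)),
                 measured_cooked_mass_g = 320)
  for (c_ in c(0.5, 2, 10)) {
    scaled <- recipe("r", "dish",
                     list(ingredient("a", amounts = c(200, 300) * c_),
                          ingredient("b", amounts = 100 * c_)),
                     measured_cooked_mass_g = 320 * c_)
    expect_equal(
      unclass(compute_recipe_per100g(scaled, function(f) vectors[[f]], panel)),
      unclass(compute_recipe_per100g(base, function(f) vectors[[f]], panel)),
      tolerance = 1e-12)
  }
})

test_that("adding pure water strictly dilutes every nonzero nutrient", {
  vectors <- list(a = dish_nv(150), b = make_nv())
  dry <- recipe("r", "dish", list(ingredient("a", amounts = 300),
                                  ingredient("b", amounts = 200)))
  wet <- recipe("r", "dish", dry$ingredients, water_added_g = 250)
  out_dry <- unclass(compute_recipe_per100g(dry, function(f) vectors[[f]], panel))
  out_wet <- unclass(compute_recipe_per100g(wet, function(f) vectors[[f]], panel))
  nz <- out_dry > 0
  expect_true(all(out_wet[nz] < out_dry[nz]))
  expect_true(all(out_wet[!nz] == 0))
})

test_that("recipe YAML round-trips through writer and reader", {
  fx <- default_fixture()
  path <- tempfile(fileext = ".yaml")
  on.exit(unlink(path))
  dir <- tempfile()
  write_fixture(fx, dir)
  on.exit(unlink(dir, recursive = TRUE), add = TRUE)
  back <- read_recipes_yaml(file.path(dir, "recipes.yaml"))
  expect_equal(back, fx$recipes)
})
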