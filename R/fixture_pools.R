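# Calibration data for the synthetic study-input generator. Everything here
# is SYNTHETIC: the names are realistic south-western Ugandan foods, but every
# nutrient number is drawn from the archetype ranges below, which are
# order-of-magnitude plausible per-100 g densities, not reference values.

# Archetype parameters: energy range (kcal/100 g), energy shares of protein /
# fat / fibre (carbohydrate takes the remainder, Atwater 4/9/2/4 kcal per g),
# and micronutrient ranges (calcium, iron, zinc mg; vitamin A ug RE;
# vitamin C mg).
food_archetypes <- function() {
  a <- function(e, p, f, fib, ca = c(5, 120), fe = c(0.3, 2.5),
                zn = c(0.2, 2), va = c(0, 80), vc = c(0, 10)) {
    list(e = e, shares = c(protein = p, fat = f, fibre = fib),
         ca = ca, fe = fe, zn = zn, va = va, vc = vc)
  }
  list(
    leafy_veg     = a(c(35, 70), .25, .10, .10, ca = c(50, 250), fe = c(1, 3.5),
                      va = c(200, 800), vc = c(15, 45)),
    raw_veg       = a(c(25, 50), .15, .05, .10, va = c(20, 400), vc = c(10, 30)),
    fruit         = a(c(30, 90), .05, .05, .05, va = c(10, 300), vc = c(15, 60)),
    oily_fruit    = a(c(120, 180), .05, .75, .05, vc = c(5, 20)),
    starchy       = a(c(90, 130), .07, .03, .05, vc = c(3, 20)),
    legume_cooked = a(c(80, 130), .25, .08, .12, fe = c(1.5, 3.5), zn = c(0.8, 2)),
    legume_raw    = a(c(300, 370), .24, .06, .15, fe = c(3, 7), zn = c(2, 4)),
    nut_paste     = a(c(500, 600), .17, .60, .05, fe = c(1.5, 4)),
    flour         = a(c(330, 370), .10, .04, .06, fe = c(1, 4)),
    cooked_cereal = a(c(100, 180), .08, .05, .03),
    porridge      = a(c(50, 90), .10, .08, .04),
    bread         = a(c(230, 280), .12, .12, .04),
    bread_fried   = a(c(250, 340), .09, .35, .03),
    trad_bread    = a(c(180, 260), .12, .08, .08, fe = c(1.5, 4)),
    biscuit       = a(c(400, 480), .06, .30, .02),
    meat          = a(c(120, 260), .55, .44, 0, fe = c(1, 3.5), zn = c(2, 6), va = c(0, 40)),
    organ         = a(c(130, 220), .60, .38, 0, fe = c(4, 10), va = c(2000, 8000)),
    fish_fried    = a(c(350, 420), .45, .45, 0, ca = c(50, 400), fe = c(1, 3)),
    fish_boiled   = a(c(90, 150), .70, .25, 0, ca = c(50, 400)),
    fish_dried    = a(c(250, 330), .65, .33, 0, ca = c(300, 1200), fe = c(2, 6)),
    insect        = a(c(350, 450), .40, .50, 0, fe = c(2, 8)),
    egg           = a(c(140, 200), .35, .62, 0, fe = c(1.5, 3), va = c(100, 250)),
    milk          = a(c(50, 100), .22, .48, 0, ca = c(100, 300), va = c(20, 80)),
    dairy_conc    = a(c(300, 520), .25, .50, 0, ca = c(400, 1200), va = c(100, 500)),
    sugar_conc    = a(c(300, 385), .01, .01, 0),
    confection    = a(c(450, 560), .05, .50, .02),
    fat_oil       = a(c(700, 860), .005, .99, 0),
    beverage      = a(c(1, 60), .05, .02, 0, vc = c(0, 25)),
    alcohol       = a(c(30, 80), .05, .02, 0),
    condiment     = a(c(250, 350), .12, .25, .15, fe = c(2, 10)),
    # group-level defaults for draws without a named archetype
    generic_fruit_vegetable      = a(c(15, 120), .15, .10, .08, vc = c(5, 40)),
    generic_cereal               = a(c(80, 360), .10, .10, .05),
    generic_meat_fish            = a(c(100, 420), .50, .40, 0),
    generic_eggs_dairy           = a(c(40, 520), .25, .50, 0, ca = c(100, 800)),
    generic_sugary               = a(c(300, 380), .02, .05, 0),
    generic_oils_fats_condiments = a(c(300, 900), .02, .80, .02),
    generic_soft_drink           = a(c(1, 80), .05, .02, 0),
    generic_alcoholic            = a(c(30, 80), .05, .02, 0),
    generic_other                = a(c(1, 350), .12, .25, .10)
  )
}

# Non-recipe food pool: 121 foods with group, archetype and role flags.
# Labels are the two branded items with partial back-of-pack nutrients.
base_food_pool <- function() {
  f <- function(name, group, archetype, label = FALSE) {
    tibble::tibble(name = name, food_group = group, archetype = archetype,
                   is_label = label)
  }
  fv <- function(n, a) f(n, "fruit_vegetable", a)
  ce <- function(n, a) f(n, "cereal", a)
  mf <- function(n, a) f(n, "meat_fish", a)
  pool <- rbind(
    # fruit & vegetable (51)
    fv("matoke, boiled", "starchy"), fv("sweet potato, boiled", "starchy"),
    fv("irish potato, boiled", "starchy"), fv("cassava, boiled", "starchy"),
    fv("yam, boiled", "starchy"), fv("pumpkin, boiled", "raw_veg"),
    fv("beans, fresh", "legume_cooked"), fv("beans, dried, boiled", "legume_cooked"),
    fv("beans, dried, raw", "legume_raw"), fv("peas, fresh, boiled", "legume_cooked"),
    fv("cowpeas, boiled", "legume_cooked"), fv("green beans, boiled", "raw_veg"),
    fv("groundnuts, roasted", "nut_paste"),
    fv("amaranth leaves, boiled", "leafy_veg"), fv("dodo leaves, boiled", "leafy_veg"),
    fv("pumpkin leaves, boiled", "leafy_veg"), fv("cassava leaves, boiled", "leafy_veg"),
    fv("spinach, boiled", "leafy_veg"), fv("cabbage, boiled", "leafy_veg"),
    fv("okra, boiled", "leafy_veg"), fv("mushrooms, boiled", "leafy_veg"),
    fv("tomato, raw", "raw_veg"), fv("onion, raw", "raw_veg"),
    fv("carrot, raw", "raw_veg"), fv("green pepper, raw", "raw_veg"),
    fv("cucumber, raw", "raw_veg"),
    fv("avocado", "oily_fruit"), fv("mango", "fruit"), fv("papaya", "fruit"),
    fv("pineapple", "fruit"), fv("jackfruit", "fruit"), fv("passion fruit", "fruit"),
    fv("sweet banana", "fruit"), fv("orange", "fruit"), fv("lemon", "fruit"),
    fv("guava", "fruit"), fv("watermelon", "fruit"), fv("sugarcane", "fruit"),
    fv("gooseberry", "fruit"), fv("tree tomato", "fruit"),
    do.call(rbind, lapply(1:11, function(i)
      fv(paste0("wild leafy vegetable, type ", i), "leafy_veg"))),
    # cereal (25)
    ce("maize flour", "flour"), ce("millet flour", "flour"),
    ce("sorghum flour", "flour"), ce("cassava flour", "flour"),
    ce("wheat flour", "flour"), ce("rice, raw", "flour"),
    ce("finger millet, whole", "flour"),
    ce("posho, maize, cooked", "cooked_cereal"), ce("rice, boiled", "cooked_cereal"),
    ce("spaghetti, boiled", "cooked_cereal"), ce("maize, boiled", "cooked_cereal"),
    ce("sorghum, boiled", "cooked_cereal"),
    ce("porridge, maize", "porridge"), ce("porridge, millet", "porridge"),
    ce("oats porridge", "porridge"),
    ce("bread, white", "bread"), ce("chapati", "bread_fried"),
    ce("mandazi", "bread_fried"), ce("samosa", "bread_fried"),
    ce("doughnut", "bread_fried"), ce("pancake", "bread_fried"),
    ce("millet bread", "trad_bread"),
    ce("maize, roasted", "flour"), ce("popcorn", "flour"),
    ce("biscuits, plain", "biscuit"),
    # meat & fish (19)
    mf("beef, boiled", "meat"), mf("beef, fried", "meat"),
    mf("goat meat, boiled", "meat"), mf("goat meat, roasted", "meat"),
    mf("chicken, boiled", "meat"), mf("chicken, roasted", "meat"),
    mf("pork, fried", "meat"), mf("mutton, boiled", "meat"),
    mf("rabbit, boiled", "meat"), mf("liver, fried", "organ"),
    mf("offal, boiled", "organ"),
    mf("tilapia, fried", "fish_fried"), mf("nile perch, fried", "fish_fried"),
    mf("tilapia, boiled", "fish_boiled"), mf("fish, dried, boiled", "fish_boiled"),
    mf("silverfish, dried", "fish_dried"), mf("smoked fish", "fish_dried"),
    mf("grasshoppers, fried", "insect"), mf("white ants, fried", "insect"),
    # eggs & dairy (7)
    f("egg, boiled", "eggs_dairy", "egg"), f("egg, fried", "eggs_dairy", "egg"),
    f("milk, fresh, whole", "eggs_dairy", "milk"),
    f("milk, fermented", "eggs_dairy", "milk"),
    f("yoghurt", "eggs_dairy", "milk"),
    f("milk powder", "eggs_dairy", "dairy_conc"),
    f("cheese", "eggs_dairy", "dairy_conc"),
    # sugary (5, one branded label)
    f("sugar", "sugary", "sugar_conc"), f("honey", "sugary", "sugar_conc"),
    f("sweets, boiled", "sugary", "sugar_conc"),
    f("chocolate", "sugary", "confection"),
    f("tip top glucose biscuits, branded", "sugary", "biscuit", label = TRUE),
    # oils, fats & condiments (5, one branded label)
    f("oil, palm", "oils_fats_condiments", "fat_oil"),
    f("ghee", "oils_fats_condiments", "fat_oil"),
    f("margarine", "oils_fats_condiments", "fat_oil"),
    f("groundnut paste", "oils_fats_condiments", "nut_paste"),
    f("kijani vegetable cooking oil, branded", "oils_fats_condiments", "fat_oil",
      label = TRUE),
    # soft drinks (6)
    f("obushera", "soft_drink", "beverage"), f("tea, black", "soft_drink", "beverage"),
    f("coffee, black", "soft_drink", "beverage"),
    f("soda, cola", "soft_drink", "beverage"),
    f("soda, orange", "soft_drink", "beverage"),
    f("passion fruit juice", "soft_drink", "beverage"),
    # alcoholic (2)
    f("banana beer", "alcoholic", "alcohol"), f("millet beer", "alcoholic", "alcohol"),
    # other (1): remainder food outside the named groups
    f("curry powder", "other", "condiment")
  )
  stopifnot(!anyDuplicated(pool$name))
  pool
}

# Donor rows present only in the host table: complete generic products the
# two label records borrow their missing nutrients from.
label_donor_pool <- function() {
  tibble::tibble(
    name = c("oil, vegetable, refined", "biscuits, glucose"),
    archetype = c("fat_oil", "biscuit"),
    food_code = c("D001", "D002"),
    label_food = c("kijani vegetable cooking oil, branded",
                   "tip top glucose biscuits, branded")
  )
}

# Local-language (Rukiga) translations for a set of staples. The words are
# synthetic stand-ins for fieldwork output, not a linguistic resource.
translation_pool <- function() {
  tibble::tibble(
    food = c("matoke, boiled", "beans, fresh", "beans, dried, boiled",
             "sweet potato, boiled", "millet bread", "amaranth leaves, boiled",
             "groundnuts, roasted", "milk, fresh, whole", "obushera",
             "silverfish, dried"),
    language = "rukiga",
    text = c("ebitookye", "ebihimba", "ebihimba bikaze", "ebitakuri",
             "akaro", "doodo", "ebinyobwa", "amate", "obushera bwa kashera",
             "mukene")
  )
}

# Recipe templates for the 27 generated composite dishes. Base amounts are
# grams; participant reports are jittered around them. food_name is the
# canonical database entry; variant pairs share `name`. Exactly two recipes
# use RAW-state ingredients (yield + retention + water), and exactly one
# contains animal protein (the fried-fish dish).
recipe_templates <- function() {
  ing <- function(food, base, state = "COOKED", yield = NULL, retention = NULL) {
    list(food = food, base = base, state = state, yield = yield,
         retention = retention)
  }
  tpl <- function(name, food_name, group, variant = "none", method = "boiled",
                  water = 0, ingredients = list()) {
    list(name = name, food_name = food_name, group = group, variant = variant,
         method = method, water = water, ingredients = ingredients)
  }
  list(
    tpl("matoke with beans", "matoke with fresh beans", "fruit_vegetable",
        variant = "fresh_beans",
        ingredients = list(ing("matoke, boiled", 600), ing("beans, fresh", 400))),
    tpl("matoke with beans", "matoke with dried beans", "fruit_vegetable",
        variant = "dried_beans", water = 200,
        ingredients = list(ing("matoke, boiled", 600),
                           ing("beans, dried, raw", 150, state = "RAW", yield = 2.4,
                               retention = c(vitamin_c = 0.7, vitamin_a = 0.9)))),
    tpl("sweet potato with fresh beans", "sweet potato with fresh beans",
        "fruit_vegetable",
        ingredients = list(ing("sweet potato, boiled", 500), ing("beans, fresh", 350))),
    tpl("cassava with beans", "cassava with beans", "fruit_vegetable",
        ingredients = list(ing("cassava, boiled", 500),
                           ing("beans, dried, boiled", 300))),
    tpl("amaranth leaves with groundnut sauce", "amaranth leaves with groundnut sauce",
        "fruit_vegetable",
        ingredients = list(ing("amaranth leaves, boiled", 500),
                           ing("groundnut paste", 60), ing("tomato, raw", 80),
                           ing("onion, raw", 40))),
    tpl("dodo leaves with groundnut sauce", "dodo leaves with groundnut sauce",
        "fruit_vegetable",
        ingredients = list(ing("dodo leaves, boiled", 450),
                           ing("groundnut paste", 50), ing("onion, raw", 30))),
    tpl("pumpkin leaves with tomato and onion", "pumpkin leaves with tomato and onion",
        "fruit_vegetable",
        ingredients = list(ing("pumpkin leaves, boiled", 500),
                           ing("tomato, raw", 100), ing("onion, raw", 50))),
    tpl("cabbage with tomato and onion", "cabbage with tomato and onion",
        "fruit_vegetable",
        ingredients = list(ing("cabbage, boiled", 500), ing("tomato, raw", 100),
                           ing("onion, raw", 50))),
    tpl("irish potato with fresh beans", "irish potato with fresh beans",
        "fruit_vegetable",
        ingredients = list(ing("irish potato, boiled", 500), ing("beans, fresh", 300))),
    tpl("yam with fresh beans", "yam with fresh beans", "fruit_vegetable",
        ingredients = list(ing("yam, boiled", 450), ing("beans, fresh", 300))),
    tpl("mixed vegetable stew", "mixed vegetable stew", "fruit_vegetable",
        ingredients = list(ing("cabbage, boiled", 300), ing("carrot, raw", 150),
                           ing("tomato, raw", 100), ing("onion, raw", 50))),
    tpl("pumpkin with groundnut sauce", "pumpkin with groundnut sauce",
        "fruit_vegetable",
        ingredients = list(ing("pumpkin, boiled", 500), ing("groundnut paste", 60))),
    tpl("green beans with tomato", "green beans with tomato", "fruit_vegetable",
        ingredients = list(ing("green beans, boiled", 400), ing("tomato, raw", 100))),
    tpl("posho with beans", "posho with fresh beans", "cereal",
        variant = "fresh_beans",
        ingredients = list(ing("posho, maize, cooked", 500), ing("beans, fresh", 350))),
    tpl("posho with beans", "posho with dried beans", "cereal",
        variant = "dried_beans",
        ingredients = list(ing("posho, maize, cooked", 500),
                           ing("beans, dried, boiled", 300))),
    tpl("rice with groundnut sauce", "rice with groundnut sauce", "cereal",
        water = 100,
        ingredients = list(ing("rice, raw", 200, state = "RAW", yield = 2.5,
                               retention = c(vitamin_c = 0.75)),
                           ing("groundnut paste", 80), ing("onion, raw", 40))),
    tpl("rice with fresh beans", "rice with fresh beans", "cereal",
        ingredients = list(ing("rice, boiled", 400), ing("beans, fresh", 300))),
    tpl("millet bread with greens", "millet bread with greens", "cereal",
        ingredients = list(ing("millet bread", 300),
                           ing("amaranth leaves, boiled", 200))),
    tpl("millet bread with beans", "millet bread with beans", "cereal",
        ingredients = list(ing("millet bread", 300), ing("beans, fresh", 200))),
    tpl("maize with beans", "maize with beans", "cereal",
        ingredients = list(ing("maize, boiled", 400), ing("beans, fresh", 300))),
    tpl("spaghetti with tomato sauce", "spaghetti with tomato sauce", "cereal",
        method = "fried",
        ingredients = list(ing("spaghetti, boiled", 400), ing("tomato, raw", 90),
                           ing("onion, raw", 30), ing("oil, palm", 15))),
    tpl("chapati with beans", "chapati with beans", "cereal",
        ingredients = list(ing("chapati", 180), ing("beans, fresh", 320))),
    tpl("millet porridge with sugar", "millet porridge with sugar", "cereal",
        ingredients = list(ing("porridge, millet", 500), ing("sugar", 30))),
    tpl("sorghum with beans", "sorghum with beans", "cereal",
        ingredients = list(ing("sorghum, boiled", 400), ing("beans, fresh", 300))),
    tpl("rice with vegetables", "rice with vegetables", "cereal",
        ingredients = list(ing("rice, boiled", 400), ing("carrot, raw", 100),
                           ing("peas, fresh, boiled", 100))),
    tpl("posho with greens", "posho with greens", "cereal",
        ingredients = list(ing("posho, maize, cooked", 500),
                           ing("dodo leaves, boiled", 250))),
    tpl("fried tilapia with tomato and onion", "fried tilapia with tomato and onion",
        "meat_fish", method = "fried",
        ingredients = list(ing("tilapia, fried", 320), ing("oil, palm", 60),
                           ing("tomato, raw", 40), ing("onion, raw", 20)))
  )
}
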