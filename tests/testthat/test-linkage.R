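# helpers: tiny in-code reference tables
ref_row <- function(table_id, code, name, nv) {
  v <- unclass(nv)
  tibble::as_tibble(c(list(table_id = table_id, food_code = code, name = name),
                      stats::setNames(as.list(v), names(v))))
}

test_that("candidate ranking puts exact matches first, fuzzy after", {
  tabs <- rbind(ref_row("HOST", "H001", "matoke", make_nv()),
                ref_row("UGANDA", "U001", "fresh beans", make_nv()),
                ref_row("KENYA", "K001", "posho", make_nv()))

  cand <- find_candidates("matoke", tabs)
  expect_equal(cand$food_code[1], "H001")
  expect_true(cand$exact[1])

  # token-set match above 0.9 despite word order and singular/plural
  cand2 <- find_candidates("bean, fresh", tabs, threshold = 0.85)
  expect_equal(cand2$name[1], "fresh beans")
  expect_gt(cand2$similarity[1], 0.9)
  expect_false(cand2$exact[1])

  expect_equal(nrow(find_candidates("obushera", tabs)), 0)
})

test_that("macronutrient similarity reports per-key relative differences", {
  a <- make_nv(protein = 7.0)
  b <- make_nv(protein = 7.5)
  res <- macro_similarity(a, b, tolerance = 0.20)
  expect_equal(res$report$rel_diff[res$report$key == "protein"], 0.5 / 7.5,
               tolerance = 1e-12)
  expect_true(res$similar)

  same <- macro_similarity(make_nv(), make_nv())
  expect_true(same$similar)
  expect_true(all(same$report$rel_diff == 0))

  far <- macro_similarity(make_nv(fat = 1), make_nv(fat = 10))
  expect_equal(far$report$rel_diff[far$report$key == "fat"], 0.9)
  expect_false(far$similar)

  incomplete <- nutrient_vector(c(protein = 1), check_energy = FALSE)
  expect_error(macro_similarity(incomplete, make_nv()),
               class = "fct_incomplete_error")
})

test_that("source precedence: host-if-similar, then regional, label, recipe", {
  host_nv <- make_nv(protein = 7.0)
  similar_nv <- make_nv(protein = 7.5)
  different_nv <- make_nv(protein = 20, fat = 9, carbohydrate = 50,
                          energy_kcal = 4 * 20 + 9 * 9 + 4 * 50 + 2,
                          energy_kJ = (4 * 20 + 9 * 9 + 4 * 50 + 2) * 4.184)

  tabs <- rbind(ref_row("HOST", "H001", "matoke", host_nv),
                ref_row("UGANDA", "U001", "matoke", similar_nv))
  dec <- resolve_source("matoke", find_candidates("matoke", tabs))
  expect_equal(dec$source_tag, "HOST_GENERIC")
  expect_false(is.null(dec$similarity_report))  # comparison must be on record

  tabs2 <- rbind(ref_row("HOST", "H001", "matoke", host_nv),
                 ref_row("UGANDA", "U001", "matoke", different_nv))
  dec2 <- resolve_source("matoke", find_candidates("matoke", tabs2))
  expect_equal(dec2$source_tag, "AFRICAN_FCT")
  expect_equal(dec2$table_id, "UGANDA")

  # no host: regional consultation order Uganda > Tanzania > Kenya
  tabs3 <- rbind(ref_row("TANZANIA", "T001", "obushera", make_nv()),
                 ref_row("UGANDA", "U002", "obushera", make_nv()),
                 ref_row("KENYA", "K001", "obushera", make_nv()))
  dec3 <- resolve_source("obushera", find_candidates("obushera", tabs3))
  expect_equal(dec3$source_tag, "AFRICAN_FCT")
  expect_equal(dec3$table_id, "UGANDA")

  # nothing anywhere: label, then generated-recipe fallback
  empty <- find_candidates("novel dish", tabs3)
  lab <- ref_row("LABEL", "L001", "novel dish", make_nv())
  expect_equal(resolve_source("novel dish", empty, lab)$source_tag, "LABEL")
  dec5 <- resolve_source("novel dish", empty, NULL)
  expect_equal(dec5$source_tag, "GENERATED_RECIPE")
  expect_true(is.na(dec5$food_code))
})

test_that("an exact regional match outranks a merely fuzzy host match", {
  tabs <- rbind(ref_row("HOST", "H001", "wild greens, type 1", make_nv()),
                ref_row("UGANDA", "U001", "wild greens, type 2", make_nv()))
  dec <- resolve_source("wild greens, type 2",
                        find_candidates("wild greens, type 2", tabs))
  expect_equal(dec$source_tag, "AFRICAN_FCT")
  expect_equal(dec$food_code, "U001")
})

test_that("resolution is deterministic for fixed inputs", {
  tabs <- rbind(ref_row("HOST", "H001", "matoke", make_nv()),
                ref_row("UGANDA", "U001", "matoke", make_nv(protein = 2.2)))
  d1 <- resolve_source("matoke", find_candidates("matoke", tabs))
  d2 <- resolve_source("matoke", find_candidates("matoke", tabs))
  expect_equal(d1[c("source_tag", "table_id", "food_code")],
               d2[c("source_tag", "table_id", "food_code")])
})

test_that("label borrowing fills gaps and never overwrites declared values", {
  panel <- default_panel()
  label <- nutrient_vector(c(energy_kcal = 450, energy_kJ = 450 * 4.184,
                             fat = 20), panel, check_energy = FALSE)
  donor <- make_nv(fat = 33, iron = 2.1)

  out <- borrow_missing_nutrients(label, donor, panel)
  expect_true(nv_complete(out))
  expect_equal(unclass(out)[["energy_kcal"]], 450)   # declared retained
  expect_equal(unclass(out)[["fat"]], 20)            # declared retained
  expect_equal(unclass(out)[["iron"]], 2.1)          # borrowed
  expect_equal(unclass(out)[["protein"]],
               unclass(donor)[["protein"]])

  # nothing to borrow: label returned as-is
  full <- make_nv()
  expect_equal(unclass(borrow_missing_nutrients(full, donor, panel)),
               unclass(full))

  # donor must be complete
  expect_error(borrow_missing_nutrients(label, label, panel),
               class = "fct_borrow_error")

  # property: declared values always survive, over random gap patterns
  set.seed(21)
  for (i in 1:25) {
    keys <- panel$key
    declared <- sample(keys, sample(1:(length(keys) - 1), 1))
    v <- stats::setNames(runif(length(declared), 0.1, 50), declared)
    lab_i <- nutrient_vector(v, panel, check_energy = FALSE)
    out_i <- borrow_missing_nutrients(lab_i, donor, panel)
    expect_true(nv_complete(out_i))
    expect_equal(unclass(out_i)[declared], v[declared])
  }
})
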