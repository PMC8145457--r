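test_that("canonicalization trims, lowercases and extracts parentheticals", {
  expect_equal(canonicalize_name("  Matoke ")$canonical, "matoke")

  res <- canonicalize_name("Obushera (millet drink)")
  expect_equal(res$canonical, "obushera")
  expect_equal(res$synonyms, "millet drink")

  expect_equal(canonicalize_name("ebihimba",
                                 c(ebihimba = "beans, fresh"))$canonical,
               "beans, fresh")

  # comma spacing and internal whitespace normalize deterministically
  expect_equal(canonicalize_name("Beans ,   FRESH")$canonical, "beans, fresh")
  expect_error(canonicalize_name("   "), class = "fct_name_error")
  expect_error(canonicalize_name("(?)"), class = "fct_name_error")
})

test_that("edibility filter partitions mentions by exclusion terms", {
  m <- food_mentions(c("cigarettes", "matoke"), "FGD")
  res <- filter_edible(m, exclusion_terms = "cigarettes")
  expect_equal(res$kept$raw_name, "matoke")
  expect_equal(res$excluded$raw_name, "cigarettes")
  expect_equal(nrow(res$kept) + nrow(res$excluded), nrow(m))

  empty <- food_mentions(character(), "FGD")
  res0 <- filter_edible(empty, "cigarettes")
  expect_equal(nrow(res0$kept), 0)
  expect_equal(nrow(res0$excluded), 0)

  res2 <- filter_edible(food_mentions(c("soap", "salt"), "MARKET"), "soap")
  expect_equal(res2$kept$raw_name, "salt")
})

test_that("merging collapses spelling variants of the same food", {
  lists <- list(FGD = food_mentions("matoke", "FGD"),
                SURVEY = food_mentions("Matoke", "SURVEY"),
                MARKET = food_mentions("matoke ", "MARKET"))
  out <- merge_deduplicate(lists)
  expect_equal(nrow(out$entries), 1)
  expect_setequal(out$entries$methods_seen[[1]], c("FGD", "SURVEY", "MARKET"))
  expect_equal(out$entries$n_mentions, 3L)

  disjoint <- list(FGD = food_mentions("a", "FGD"),
                   SURVEY = food_mentions("b", "SURVEY"),
                   MARKET = food_mentions("c", "MARKET"))
  expect_equal(nrow(merge_deduplicate(disjoint)$entries), 3)
})

test_that("merging is idempotent and order-independent", {
  set.seed(5)
  pool <- c("matoke", "beans, fresh", "posho", "obushera (millet drink)",
            "Sweet Potato", "tilapia, fried", "MILK", "sugar")
  lists <- list(
    FGD = food_mentions(sample(pool, 6), "FGD"),
    SURVEY = food_mentions(sample(pool, 4), "SURVEY"),
    MARKET = food_mentions(sample(pool, 5), "MARKET"))

  merged <- merge_deduplicate(lists)

  # permuting the input lists yields the identical canonical list
  for (perm in list(c(2, 1, 3), c(3, 2, 1), c(2, 3, 1))) {
    expect_equal(merge_deduplicate(lists[perm])$entries$canonical_name,
                 merged$entries$canonical_name)
  }

  # re-merging the merged mentions changes nothing
  flat <- do.call(rbind, lapply(merged$entries$mentions, identity))
  again <- merge_deduplicate(flat)
  expect_equal(again$entries$canonical_name, merged$entries$canonical_name)
  expect_equal(again$entries$n_mentions, merged$entries$n_mentions)

  # every entry traces back to at least one real mention, none invented
  expect_true(all(merged$entries$n_mentions >= 1))
  expect_lte(nrow(merged$entries), sum(vapply(lists, nrow, integer(1))))
})

test_that("fuzzy near-duplicates land in the review report, unmerged", {
  lists <- list(FGD = food_mentions(c("fresh beans", "matoke"), "FGD"),
                SURVEY = food_mentions("fresh bean", "SURVEY"))
  out <- merge_deduplicate(lists, review_threshold = 0.9)
  expect_equal(nrow(out$entries), 3)  # not auto-merged
  expect_true(any(out$review$name_a == "fresh bean" &
                  out$review$name_b == "fresh beans"))
  expect_true(all(out$review$similarity >= 0.9))
})

test_that("token-set similarity ignores word order and scores typos high", {
  expect_gt(token_similarity("bean, fresh", "fresh beans"), 0.9)
  expect_equal(token_similarity("fresh beans", "beans fresh"), 1)
  expect_lt(token_similarity("obushera", "matoke"), 0.5)
})

test_that("method lists read back from CSV identically", {
  m <- food_mentions(c("matoke", "  Beans "), "FGD", locality = c("A", "B"))
  path <- tempfile(fileext = ".csv")
  on.exit(unlink(path))
  write.csv(m, path, row.names = FALSE)
  back <- read_method_csv(path, "FGD")
  expect_equal(back, m)
})
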