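Package: fctforge
Title: Compile Locally Relevant Food Composition Databases
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for compiling a food composition database for a local study
    population from multi-method food lists: ingestion and deduplication of
    food mentions collected by focus groups, individual surveys and market
    audits; precedence-based linkage of each unique food to host and regional
    reference nutrient tables, with nutrient borrowing for partially labelled
    branded products; per-100 g nutrient calculation for composite recipes
    with cooking-yield and retention factors; enrichment with household-measure
    portions, accompanying-food prompts and local-language synonyms; automated
    quality checks; nutrient-adequacy assessment against daily requirement
    profiles; and a seeded synthetic-fixture generator so the whole pipeline is
    exercisable without access to proprietary reference tables.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    tibble,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
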