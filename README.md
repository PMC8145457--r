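# fctforge

Tools for compiling a locally relevant **food composition table (FCT)** — the
reference dataset behind any dietary assessment — from the kind of multi-method
fieldwork used in low-income settings where no national FCT exists.

Dietary assessment (24-h recalls, food diaries, FFQs) needs, for every food a
community actually eats, a complete per-100 g edible-portion nutrient vector.
Compiling one for an understudied population is a pipeline problem:

1. **Ingestion** — food mentions collected by three methods (focus group
   discussions, individual dietary surveys, market/shop audits) are cleaned,
   non-edible items dropped, names canonicalized, and duplicates across
   methods merged into a unique food list.
2. **Linkage** — each unique food is matched to a nutrient source under a
   precedence policy: keep the host platform's generic entry when its
   macronutrients are similar to the best regional (African-table) candidate
   (|a − b| / max(b, ε) ≤ 0.20 per macro by default), otherwise the regional
   entry (Uganda before Tanzania before Kenya), otherwise a back-of-pack
   label record whose missing nutrients are borrowed from a complete generic
   donor, otherwise a generated recipe.
3. **Recipe calculation** — composite dishes get per-100 g vectors from
   participant-reported ingredient amounts. For cooked-basis ingredients the
   dish nutrient *k* is Σᵢ mᵢ·nᵢ(k)/100 scaled by 100/M (M = cooked dish
   mass); raw-basis ingredients additionally apply a cooking-yield factor
   (cooked/raw mass), per-nutrient retention fractions, and added-water
   bookkeeping. Declared energy is cross-checked against Atwater factors
   (4/4/9/2 kcal/g for protein/carbohydrate/fat/fibre) and kJ = kcal × 4.184.
4. **Enrichment** — household-measure portions (e.g. soup spoon = 30 g),
   accompanying-food prompts (milk and sugar with porridge), and
   local-language synonyms.
5. **Quality control** — completeness over the nutrient panel (export is
   blocked on failures), energy consistency, plausibility ranges, and
   source/food-group share reports with half-up integer rounding.
6. **Adequacy** — mass of a dish needed to satisfy a daily requirement
   (100·r/d grams for density d and requirement r) and per-nutrient adequacy
   ratios against an age/sex requirement profile.

A seeded synthetic generator emulates a full study input set — mention lists
of 139/69/95 deduplicating to 148 unique foods, 27 composite recipes
(including fresh/dried bean variant pairs and one fish dish), 2 branded items
with partial labels, 37 regional-only and 82 host-table foods — so the whole
pipeline is exercisable without any proprietary reference table. All
generated nutrient values are explicitly synthetic.

## Worked example

```r
library(fctforge)
fx <- generate_fixture(seed = 1)   # synthetic study inputs
db <- build_database(fx)           # full compilation
db
#> <fct_database> 148 records | HOST_GENERIC:82 AFRICAN_FCT:37 LABEL:2 GENERATED_RECIPE:27
#> QC: INFO=0, WARN=0, FAIL=0
```

148 foods compiled: 82 kept from the host table, 37 from regional tables, 27
computed from recipes, 2 from labels; no quality-control findings, so export
is allowed. One generated dish:

```r
dish <- Filter(function(r) r$canonical_name == "matoke with fresh beans", db$records)[[1]]
round(unclass(dish$nutrients), 2)
#>  energy_kcal    energy_kJ      protein          fat carbohydrate        fibre
#>        91.45       382.63         3.12         0.49        16.57         3.45
#>      calcium         iron         zinc    vitamin_a    vitamin_c
#>        67.39         1.74         1.26        69.36         9.42
```

A 91 kcal/100 g cooked matoke-and-bean dish. How much of it would a 1-year-old
boy (FAO energy requirement 770 kcal/d) have to eat?

```r
adequacy_table(dish, profile_boy_1y())
```

prints the required mass per nutrient and the adequacy of each nutrient at
the energy-satisfying mass — about 842 g here; a dish at 77 kcal/100 g needs
exactly 1000 g (`required_mass(77, 770)`), which is the arithmetic behind
assessing whether low-energy complementary foods can meet infant needs at
all.

The same flow is scriptable from a shell:

```sh
Rscript inst/cli/fctforge.R fixture --seed 1 --out fixtures/
Rscript inst/cli/fctforge.R build --fixture fixtures/ --out out/
Rscript inst/cli/fctforge.R report --db out/database.csv
Rscript inst/cli/fctforge.R adequacy --seed 1 --dish "matoke with fresh beans"
```

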