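---
title: "Compiling a locally relevant food composition database"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Compiling a locally relevant food composition database}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fctforge)
```

fctforge builds a food composition table (FCT) for a study population from
multi-method food lists. This vignette is the methods account: what the
pipeline computes, the assumptions behind each stage, the parameters that
matter and why they default as they do, what the synthetic fixture does and
does not emulate, and the limitations a user should keep in mind.

## The compilation model

The unit of output is a **food record**: a canonical English name, a food
group, a complete nutrient vector per 100 g edible portion over a configured
panel, a provenance trail, household-measure portions, accompaniment prompts
and local-language synonyms. The pipeline is a deterministic function of its
inputs: mention lists, reference tables, label records, recipes and the
enrichment configs.

### Nutrient panel and units

The panel is config-driven (`default_panel()`, `read_panel()`). The compact
default carries energy (kcal and kJ), protein, fat, carbohydrate, fibre,
calcium, iron, zinc, vitamin A (µg retinol equivalents) and vitamin C. A
production panel can be much wider — host dietary-assessment platforms carry
on the order of 120 nutrients — and every operation is written against the
panel, not a fixed list. Units come from a registry with three dimensions
(mass, energy, retinol equivalents); retinol equivalents are deliberately not
convertible to plain mass, so a µg_RE value can never silently become µg of
something else. Energy uses the standard thermochemical factor
kJ = kcal × 4.184; the Atwater factors are the conventional 4 (protein),
4 (carbohydrate), 9 (fat), 2 (fibre), 7 (alcohol) kcal/g. Both constants are
stated in the registry/panel rather than scattered through code.

The `nutrient_vector` type enforces the panel contract at construction:
values and missingness partition the panel, values are non-negative, and when
both energy fields are present they must agree under the 4.184 factor to
within 0.5 %. This makes "complete" a checkable property (`nv_complete()`),
which is what the export gate keys on.

### Ingestion and deduplication

Names are canonicalized by lowercasing, whitespace collapse and punctuation
stripping (commas and hyphens inside names survive, since canonical entries
like "beans, fresh" use them). Parenthetical descriptors — "obushera (millet
drink)" — become synonyms rather than part of the key. A synonym map applies
last, folding local-language or variant spellings onto canonical entries.

Deduplication is **exact match on the canonical name after synonym mapping**.
The design question here was whether to auto-merge fuzzy near-duplicates; the
original compilation workflow this mirrors used human judgement for that
call, so the package refuses to guess: pairs of distinct canonical names
whose token-set similarity reaches the review threshold (default 0.9) are
written to a review report for a person to adjudicate, and the synonym map is
the mechanism for encoding the verdict. Nothing is merged silently.

Token-set similarity is sorted-token Levenshtein: both names are normalized,
tokenized, sorted and re-joined, and similarity is 1 − distance/max(length).
Word order is free ("bean, fresh" ≈ "fresh beans" scores ≈ 0.91) and small
spelling variants degrade smoothly.

### Linkage precedence

Each unique food is resolved against the reference tables in a fixed
precedence: (1) the host platform's generic entry, provided its
macronutrients are similar to the best regional candidate or no regional
candidate exists; (2) the best regional entry, consulting Uganda before
Tanzania before Kenya; (3) a back-of-pack label record; (4) a generated
recipe as the always-available fallback. Two parameters matter:

* **match threshold** (default 0.85): minimum token-set similarity for a
  fuzzy name match to count as a candidate at all. Exact name/synonym
  matches always qualify and rank first.
* **macro tolerance** (default 0.20): per-key relative difference
  |a − b| / max(b, ε) on energy, protein, fat and carbohydrate under which
  a host entry is "similar enough" to stand in for a regional one. The
  source workflow states the similarity judgement qualitatively; 0.20 is a
  declared configuration choice, logged in every decision, not a claim
  about the original process.

One rule was added after the precedence policy met real candidate sets: an
exact name match in any table outranks merely fuzzy matches elsewhere. A
compiler holding the food under its exact name in the Ugandan table would not
trade it for a host entry that only resembles the name; without this rule,
families of similar names ("wild leafy vegetable, type 1/2/…") cross-match
and corrupt source attribution.

Label records keep every declared value verbatim; only nutrients in the
label's missing set are borrowed from the donor (`borrow_missing_nutrients`),
and the donor must be complete. The donor reference is part of the record's
provenance.

### Recipe calculation

Two modes coexist, selected per ingredient by its `state`:

* **COOKED** (default): reported amounts refer to the ready-to-eat
  ingredient and its reference vector is cooked-basis, so neither water nor
  a cooking factor applies — the cooking transformation is already embodied
  in the reference entry. This is the common case.
* **RAW**: amounts are raw masses against a raw-basis vector; a yield
  factor (cooked/raw mass) converts the dish-mass contribution, retention
  fractions (defaulting to 1) discount heat-labile nutrients, and added
  water contributes mass but no nutrients.

Participant amounts are averaged arithmetically (the field data warrant
nothing fancier). Nutrient mass comes from the state-basis mass; dish mass
from cooked-equivalent masses plus water, unless a measured cooked mass is
recorded, in which case the measurement wins and the raw-side/cooked-side
difference is reported as evaporation (or flagged as unaccounted absorption
when negative). The per-100 g vector is total nutrient mass × 100 / dish
mass. Useful consequences, all property-tested: all-cooked zero-water dishes
are convex combinations of ingredient densities; scaling every mass leaves
the density vector unchanged; adding pure water strictly dilutes.

Fresh- and dried-bean versions of a dish are distinct food records sharing a
recipe name and distinguished by a variant tag, reflecting that both versions
are cooked and eaten in similar amounts.

### Quality control and shares

QC is read-only and severity-tiered: completeness failures **block export**
(a record missing panel nutrients is not a usable FCT entry); energy
inconsistency (declared kcal vs Atwater, tolerance 0.15; kJ vs kcal × 4.184,
0.5 %) and range violations (physically motivated per-100 g ceilings, e.g.
900 kcal — pure fat — as the energy maximum) **warn**, since the original
checks at this stage were judgement calls.

Share reports recompute percentages from counts at print time, never store
them, and round half-up to integer percent (base R's `round()` would give
banker's rounding, which is not how compiled-database shares are reported).

### Adequacy

`required_mass(d, r) = 100·r/d` grams; `nutrient_per_mass` scales the
per-100 g vector; `adequacy_ratio` divides intake by a requirement profile.
The shipped demo profile is a 1-year-old boy with the FAO-cited 770 kcal/d
energy requirement and 400 µg RE vitamin A. An iron requirement is
deliberately not shipped in the demo profile: the figure quoted in the
motivating context (50–100 mg/d for a 1-year-old) is implausible against
standard references, so iron adequacy is left to user-supplied profiles.
Zero density yields an explicit `Inf` ("this food can never meet that
requirement"), not an error.

## The synthetic fixture

`generate_fixture(seed)` emits a full input set with the structure of the
study conditions the package was built around: mention lists of 139, 69 and
95 foods whose canonical union is exactly 148; 82 foods resolving to the
host table, 37 to regional tables (sampled 60/25/15 across
Uganda/Tanzania/Kenya), 27 to generated recipes and 2 to partial labels;
food-group counts of 64 fruit/vegetable, 38 cereal, 20 meat/fish, 7
eggs/dairy, 5 sugary, 5 oils/fats/condiments, 6 soft drinks, 2 alcoholic —
these sum to 147, and the remaining food is assigned to "other" (the group
arithmetic in the motivating compilation is itself off by one, and "other"
is the least distorting home for the remainder).

The method-overlap structure is solved, not sampled: the seven
membership-class sizes (FGD-only, SURVEY-only, …, all-three) are derived
from the configured list sizes, preferring the largest all-methods class
that keeps every class non-empty; which *food* lands in which class is
seeded-random. Raw mentions are styled (case, padding, occasional
local-language names resolved by the synonym map) so deduplication has real
work to do.

Nutrient vectors are drawn per archetype (leafy vegetable, starchy staple,
cooked legume, fried fish, oil, …): energy uniform in the archetype's
kcal range, macronutrient grams from archetype energy shares under Atwater
factors with a joint ±5 % jitter (so declared and Atwater-implied energy
agree within 15 % by construction), kJ locked to kcal × 4.184, micros from
archetype ranges. The calibration targets the observed energy landscape of
the study's dishes: every non-fish composite dish lands in 25–236 kcal/100 g
and the one fried-fish dish exceeds 350 kcal/100 g. Twenty-seven recipe
templates (13 bean/vegetable, 13 bean/cereal, 1 fish; one fresh/dried bean
variant pair; exactly two recipes in RAW mode with yield factors, mirroring
a compilation in which only two dishes required raw-ingredient treatment)
are instantiated with 1–5 participant reports per ingredient within ±10 % of
template amounts.

What the fixture does **not** emulate: real nutrient correlations (values
are independent draws within archetypes), measurement error structure,
seasonal or varietal variation, genuinely ambiguous duplicate names
(deduplication on the fixture is exact-match clean by design), and any
nutritional truth — every number is fictional and flagged SYNTHETIC in the
manifest. Passing tests on the fixture therefore demonstrate pipeline
correctness (counts, conservation, precedence, round-trips), not nutritional
validity on field data.

## Numerical and design choices

* Half-up integer rounding for printed shares; full-precision (`%.17g`)
  serialization in exports so export → import is exact.
* Recipe nutrient-mass conservation is tested against a brute-force oracle
  at 1e-9 relative on 200 randomized small recipes per run.
* The kcal/kJ direction is fixed as kJ = kcal × 4.184; field descriptions of
  this conversion are sometimes phrased in the inverse direction, which is
  dimensionally the kJ → kcal derivation.
* Deduplication never auto-merges on similarity; the review report plus
  synonym map replace human adjudication with an auditable equivalent.
* Problem sizes in the shipped tests (148-food fixture, 200-recipe property
  trials, compact 11-nutrient panel) are chosen to keep a full run in tens
  of seconds while covering every code path; the panel is the axis a
  production user would widen first.

## Limitations

* Linkage quality is bounded by name matching; foods consumed under names
  absent from every table resolve to recipes or fail visibly, never
  silently to a wrong entry — but the match threshold is a blunt
  instrument, and the review CSV is the intended safety net.
* Retention and yield factors are config inputs with provenance fields, not
  a shipped database; defaults (retention 1.0) understate cooking losses if
  left untouched in RAW mode.
* No bioavailability modelling: adequacy ratios compare intake to
  requirements, ignoring absorption (iron absorption from vegetable-based
  diets can be a small fraction of intake, so adequacy ratios overstate
  what reaches the body).
* The exporter targets a generic CSV/JSON schema, not any platform's native
  import format.
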