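# Linkage of canonical foods to reference nutrient sources under a precedence
# policy: keep the host platform's generic entry when its macronutrients agree
# with the best regional (African-table) candidate, otherwise take the
# regional entry (Uganda before Tanzania before Kenya), otherwise a
# back-of-pack label record, otherwise fall back to a generated recipe.

REFERENCE_TABLES <- c("HOST", "UGANDA", "TANZANIA", "KENYA")
AFRICAN_TABLES <- c("UGANDA", "TANZANIA", "KENYA")
SOURCE_TAGS <- c("HOST_GENERIC", "AFRICAN_FCT", "LABEL", "GENERATED_RECIPE")

#' Default linkage configuration
#'
#' @param match_threshold Token-set similarity below which a fuzzy name match
#'   is not considered a candidate (default 0.85; exact matches always
#'   qualify).
#' @param macro_keys Nutrient keys compared when deciding whether a host
#'   entry is nutritionally similar to a regional one.
#' @param macro_tolerance Maximum per-key relative difference still counted
#'   as similar (default 0.20).
#' @return A named list of settings.
#' @export
linkage_config <- function(match_threshold = 0.85,
                           macro_keys = c("energy_kcal", "protein", "fat", "carbohydrate"),
                           macro_tolerance = 0.20) {
  list(match_threshold = match_threshold, macro_keys = macro_keys,
       macro_tolerance = macro_tolerance)
}

#' Read reference composition tables from CSV
#'
#' Layout: columns `table_id`, `food_code`, `name`, then one column per panel
#' nutrient keyed by nutrient key (units are fixed by the panel config).
#' Empty cells are missing nutrients (legitimate only for label records).
#'
#' @param path CSV path.
#' @param panel Nutrient panel.
#' @return A tibble; nutrient columns are numeric with `NA` for missing.
#' @export
read_reference_csv <- function(path, panel = default_panel()) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("table_id", "food_code", "name")
  if (!all(need %in% names(df))) {
    stop_fct("reference CSV must have columns ", paste(need, collapse = ", "),
             class = "fct_reference_error")
  }
  gaps <- setdiff(panel$key, names(df))
  if (length(gaps)) {
    stop_fct("reference CSV lacks panel nutrient column(s): ",
             paste(gaps, collapse = ", "), class = "fct_reference_error")
  }
  for (k in panel$key) df[[k]] <- as.numeric(df[[k]])
  dup <- duplicated(df[c("table_id", "food_code")])
  if (any(dup)) {
    stop_fct("duplicate food_code within a table: ",
             paste(unique(df$food_code[dup]), collapse = ", "),
             class = "fct_reference_error")
  }
  tibble::as_tibble(df[c(need, panel$key)])
}

# Nutrient vector carried by one reference-table row.
entry_nutrients <- function(row, panel, check_energy = TRUE) {
  v <- as.numeric(row[1, panel$key])
  names(v) <- panel$key
  nutrient_vector(v[!is.na(v)], panel, check_energy = check_energy)
}

#' Rank reference-table candidates for one food
#'
#' Exact matches on the canonical name (or any of its synonyms) rank first;
#' fuzzy token-set matches at or above the threshold follow in descending
#' similarity; ties break deterministically by table precedence
#' (HOST, UGANDA, TANZANIA, KENYA) then `food_code`.
#'
#' @param food Canonical food name.
#' @param tables Reference tibble (see [read_reference_csv()]).
#' @param threshold Minimum fuzzy similarity.
#' @param synonyms Optional character vector of alternative names for `food`.
#' @return Candidate rows with extra columns `similarity` and `exact`, best
#'   first; zero rows when nothing qualifies.
#' @export
find_candidates <- function(food, tables, threshold = 0.85,
                            synonyms = character()) {
  if (nrow(tables) == 0) return(tables)
  targets <- unique(c(food, synonyms))
  targets_tok <- vapply(targets, sorted_tokens, character(1))
  name_tok <- vapply(tables$name, sorted_tokens, character(1), USE.NAMES = FALSE)
  sim <- vapply(name_tok, function(nt) {
    max(1 - as.integer(utils::adist(targets_tok, nt)) /
          pmax(nchar(targets_tok), nchar(nt)))
  }, numeric(1))
  exact <- name_tok %in% targets_tok
  keep <- exact | sim >= threshold
  out <- tables[keep, , drop = FALSE]
  out$similarity <- ifelse(exact[keep], 1, sim[keep])
  out$exact <- exact[keep]
  prec <- match(out$table_id, REFERENCE_TABLES)
  out[order(-out$exact, -out$similarity, prec, out$food_code), , drop = FALSE]
}

#' Compare macronutrients of two candidate entries
#'
#' Per-key relative difference `|a - b| / max(b, eps)` with verdict SIMILAR
#' when every key is within tolerance. Used to decide whether the host
#' platform's generic entry can stand in for a regional one.
#'
#' @param a,b `nutrient_vector`s (a: host candidate, b: regional candidate).
#' @param macro_keys Keys to compare.
#' @param tolerance Per-key relative-difference ceiling (default 0.20).
#' @param eps Denominator floor guarding division by zero.
#' @return List with `report` (tibble `key`, `a`, `b`, `rel_diff`) and
#'   `similar` (logical).
#' @export
#' @examples
#' # protein 7.0 vs 7.5 g: |7.0 - 7.5| / 7.5 ~ 0.067, well within 0.20
macro_similarity <- function(a, b,
                             macro_keys = c("energy_kcal", "protein", "fat", "carbohydrate"),
                             tolerance = 0.20, eps = 1e-9) {
  gaps <- c(intersect(macro_keys, nv_missing(a)),
            intersect(macro_keys, nv_missing(b)))
  if (length(gaps)) {
    stop_fct("macro similarity needs values for: ",
             paste(unique(gaps), collapse = ", "),
             class = "fct_incomplete_error")
  }
  va <- unclass(a)[macro_keys]
  vb <- unclass(b)[macro_keys]
  rel <- abs(va - vb) / pmax(vb, eps)
  list(report = tibble::tibble(key = macro_keys, a = unname(va), b = unname(vb),
                               rel_diff = unname(rel)),
       similar = all(rel <= tolerance))
}

#' Resolve the nutrient source for one food
#'
#' Applies the precedence policy over ranked candidates: (1) a host generic
#' entry, provided it is macro-similar to the best regional candidate or no
#' regional candidate exists; (2) the best regional entry (Uganda before
#' Tanzania before Kenya); (3) a back-of-pack label record; (4) generated
#' recipe as the always-available fallback.
#'
#' @param food Canonical food name.
#' @param candidates Ranked candidate tibble from [find_candidates()] (may
#'   have zero rows).
#' @param label_record One-row reference tibble holding the food's label
#'   nutrients, or `NULL`.
#' @param panel Nutrient panel.
#' @param config See [linkage_config()].
#' @return A `match_decision` list: `food`, `source_tag`, `table_id`,
#'   `food_code`, `rationale`, `similarity_report` (tibble or `NULL`).
#' @export
resolve_source <- function(food, candidates, label_record = NULL,
                           panel = default_panel(), config = linkage_config()) {
  # exact name matches outrank fuzzy ones across tables: when any table
  # holds the food under its exact name, merely similar names elsewhere do
  # not compete
  if (nrow(candidates) && any(candidates$exact)) {
    candidates <- candidates[candidates$exact, , drop = FALSE]
  }
  host <- candidates[candidates$table_id == "HOST", , drop = FALSE]
  african <- candidates[candidates$table_id %in% AFRICAN_TABLES, , drop = FALSE]
  if (nrow(african)) {
    prec <- match(african$table_id, AFRICAN_TABLES)
    african <- african[order(-african$exact, -african$similarity, prec,
                             african$food_code), , drop = FALSE]
  }

  decision <- function(tag, row = NULL, rationale = "", report = NULL) {
    structure(list(food = food, source_tag = tag,
                   table_id = if (is.null(row)) NA_character_ else row$table_id,
                   food_code = if (is.null(row)) NA_character_ else row$food_code,
                   rationale = rationale, similarity_report = report),
              class = "match_decision")
  }

  if (nrow(host)) {
    if (nrow(african) == 0) {
      return(decision("HOST_GENERIC", host[1, ],
                      "host entry; no regional candidate to compare"))
    }
    cmp <- macro_similarity(entry_nutrients(host[1, ], panel),
                            entry_nutrients(african[1, ], panel),
                            macro_keys = config$macro_keys,
                            tolerance = config$macro_tolerance)
    if (cmp$similar) {
      return(decision("HOST_GENERIC", host[1, ],
                      sprintf("host entry kept: macros within %.0f%% of %s:%s",
                              100 * config$macro_tolerance,
                              african$table_id[1], african$food_code[1]),
                      cmp$report))
    }
    return(decision("AFRICAN_FCT", african[1, ],
                    sprintf("regional entry preferred: host macros differ from %s:%s beyond %.0f%%",
                            african$table_id[1], african$food_code[1],
                            100 * config$macro_tolerance),
                    cmp$report))
  }
  if (nrow(african)) {
    return(decision("AFRICAN_FCT", african[1, ],
                    paste0("no host match; best regional entry ",
                           african$table_id[1], ":", african$food_code[1])))
  }
  if (!is.null(label_record)) {
    return(decision("LABEL", label_record,
                    "no reference-table match; back-of-pack label record"))
  }
  decision("GENERATED_RECIPE", NULL,
           "no reference-table match and no label; nutrient vector to be generated from a recipe")
}

#' Fill a label record's missing nutrients from a complete generic donor
#'
#' Back-of-pack labels declare only a handful of nutrients; the remainder is
#' borrowed from a similar generic product with a complete panel. Declared
#' label values are always retained verbatim.
#'
#' @param label `nutrient_vector` with gaps (the label's declared values).
#' @param donor Complete `nutrient_vector` of the matched generic product.
#' @param panel Nutrient panel.
#' @return A complete `nutrient_vector`.
#' @export
borrow_missing_nutrients <- function(label, donor, panel = default_panel()) {
  if (!nv_complete(donor)) {
    stop_fct("donor vector incomplete; missing: ",
             paste(nv_missing(donor), collapse = ", "),
             class = "fct_borrow_error")
  }
  out <- unclass(label)
  fill <- nv_missing(label)
  out[fill] <- unclass(donor)[fill]
  nutrient_vector(out, panel, check_energy = FALSE)
}
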