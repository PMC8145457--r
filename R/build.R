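# Pipeline driver: ingestion -> linkage -> recipe calculation -> enrichment
# -> quality checks, plus database export / import.

#' Pipeline configuration
#'
#' @param match_threshold,macro_keys,macro_tolerance See [linkage_config()].
#' @param energy_tolerance Atwater discrepancy triggering a QC warning.
#' @param bounds Plausibility bounds for [check_range()].
#' @return Named list of settings.
#' @export
build_config <- function(match_threshold = 0.85,
                         macro_keys = c("energy_kcal", "protein", "fat", "carbohydrate"),
                         macro_tolerance = 0.20,
                         energy_tolerance = 0.15,
                         bounds = default_bounds()) {
  c(linkage_config(match_threshold, macro_keys, macro_tolerance),
    list(energy_tolerance = energy_tolerance, bounds = bounds))
}

#' Build the food composition database from a fixture (or equivalent inputs)
#'
#' Runs the full compilation: drop non-edible mentions, canonicalize and
#' deduplicate the three method lists, link every unique food to its nutrient
#' source under the precedence policy, fill label gaps from generic donors,
#' compute recipe nutrient vectors, enrich with portions / prompts /
#' synonyms, and run quality checks.
#'
#' @param fixture A `fixture` (from [generate_fixture()] or [read_fixture()]).
#' @param config A [build_config()].
#' @return An `fct_database`: list with `records` (list of [food_record()]s,
#'   id-sorted), `decisions` (linkage decision log tibble), `food_list`
#'   (the deduplicated [merge_deduplicate()] result), `qc` (a `qc_report`),
#'   `shares` ([source_share_report()] output), `panel`.
#' @export
build_database <- function(fixture, config = build_config()) {
  panel <- fixture$panel

  # 1-2: exclusion + dedup
  kept <- lapply(fixture$mentions, function(m)
    filter_edible(m, fixture$exclusion_terms, fixture$synonym_map)$kept)
  food_list <- merge_deduplicate(kept, fixture$synonym_map)
  entries <- food_list$entries

  group_of <- stats::setNames(fixture$food_groups$food_group,
                              fixture$food_groups$canonical_name)
  missing_groups <- setdiff(entries$canonical_name, names(group_of))
  if (length(missing_groups)) {
    stop_fct("no food-group assignment for: ",
             paste(utils::head(missing_groups, 5), collapse = "; "),
             class = "fct_build_error")
  }

  # 3: linkage decisions
  label_by_name <- split(fixture$labels, fixture$labels$name)
  decisions <- vector("list", nrow(entries))
  for (i in seq_len(nrow(entries))) {
    nm <- entries$canonical_name[i]
    cand <- find_candidates(nm, fixture$reference,
                            threshold = config$match_threshold,
                            synonyms = entries$synonyms[[i]])
    dec <- resolve_source(nm, cand, label_record = label_by_name[[nm]],
                          panel = panel, config = config)
    decisions[[i]] <- dec
  }

  decision_log <- tibble::tibble(
    food = vapply(decisions, `[[`, character(1), "food"),
    source_tag = vapply(decisions, `[[`, character(1), "source_tag"),
    table_id = vapply(decisions, `[[`, character(1), "table_id"),
    food_code = vapply(decisions, `[[`, character(1), "food_code"),
    rationale = vapply(decisions, `[[`, character(1), "rationale"))

  # 4: nutrient vectors (tables and labels first, then recipes over them)
  order_ids <- order(entries$canonical_name)
  ids <- stats::setNames(sprintf("swu%03d", seq_len(nrow(entries))),
                         entries$canonical_name[order_ids])
  records <- list()
  resolver_env <- new.env(parent = emptyenv())
  ref_key <- paste(fixture$reference$table_id, fixture$reference$food_code)

  make_record <- function(nm, dec) {
    grp <- group_of[[nm]]
    if (dec$source_tag %in% c("HOST_GENERIC", "AFRICAN_FCT")) {
      row <- fixture$reference[ref_key == paste(dec$table_id, dec$food_code), ]
      nv <- entry_nutrients(row, panel)
      prov <- paste0(dec$table_id, ":", dec$food_code)
    } else if (dec$source_tag == "LABEL") {
      lab <- label_by_name[[nm]]
      nv_label <- entry_nutrients(lab[, c("table_id", "food_code", "name", panel$key)],
                                  panel, check_energy = FALSE)
      donor_row <- fixture$reference[ref_key == sub(":", " ", lab$donor_code), ]
      if (nrow(donor_row) != 1) {
        stop_fct("label donor ", lab$donor_code, " not found in reference tables",
                 class = "fct_build_error")
      }
      nv <- borrow_missing_nutrients(nv_label, entry_nutrients(donor_row, panel),
                                     panel)
      prov <- paste0("LABEL:", lab$food_code, ";donor=", lab$donor_code)
    } else {
      rec <- fixture$recipes[[nm]]
      if (is.null(rec)) {
        stop_fct("food '", nm, "' matched no source and has no recipe",
                 class = "fct_build_error")
      }
      nv <- compute_recipe_per100g(rec, function(f) resolver_env[[f]], panel)
      prov <- rec$recipe_id
      grp <- rec$food_group
    }
    food_record(ids[[nm]], nm, grp, dec$source_tag, nv, prov)
  }

  recipe_pending <- list()
  for (i in seq_len(nrow(entries))) {
    nm <- entries$canonical_name[i]
    dec <- decisions[[i]]
    if (dec$source_tag == "GENERATED_RECIPE") {
      recipe_pending[[nm]] <- dec
    } else {
      rec <- make_record(nm, dec)
      records[[nm]] <- rec
      resolver_env[[nm]] <- rec$nutrients
    }
  }
  for (nm in names(recipe_pending)) {
    records[[nm]] <- make_record(nm, recipe_pending[[nm]])
  }

  # 5 & 7: enrichment
  db_index <- stats::setNames(
    vapply(records, `[[`, character(1), "id"),
    vapply(records, `[[`, character(1), "canonical_name"))
  translations <- fixture$translations
  records <- lapply(records, function(rec) {
    rec <- attach_portions(rec, fixture$portion_registry,
                           fixture$portion_assignments)
    rec <- attach_accompaniments(rec, fixture$prompts, db_index)
    attach_synonyms(rec, translations)
  })
  records <- records[order(vapply(records, `[[`, character(1), "id"))]

  # 6: quality checks
  qc <- run_qc(records, panel, bounds = config$bounds,
               energy_tolerance = config$energy_tolerance)

  structure(list(records = unname(records), decisions = decision_log,
                 food_list = food_list, qc = qc,
                 shares = source_share_report(records), panel = panel),
            class = "fct_database")
}

#' @export
print.fct_database <- function(x, ...) {
  s <- x$shares$by_source
  cat("<fct_database> ", length(x$records), " records | ",
      paste(s$key, s$count, sep = ":", collapse = " "), "\n", sep = "")
  cat("QC: ", paste(names(x$qc$summary), x$qc$summary, sep = "=",
                    collapse = ", "), "\n", sep = "")
  invisible(x)
}

# full-precision numeric -> text (round-trips doubles exactly)
num_chr <- function(x) {
  ifelse(is.na(x), "", vapply(x, function(v) sprintf("%.17g", v), character(1)))
}

serialize_portions <- function(p) {
  paste(paste0(p$description, "=", num_chr(p$grams_per_unit)), collapse = ";")
}
serialize_synonyms <- function(s) {
  if (nrow(s) == 0) return("")
  paste(paste0(s$language, ":", s$text), collapse = ";")
}

#' Export a compiled database
#'
#' CSV: one row per food with columns id, canonical_name, food_group, source,
#' provenance, one column per panel nutrient (`key (unit)` header), portions
#' serialized as `description=grams;...`, accompaniments as an id list,
#' synonyms as `language:text;...`. JSON mirrors the same schema. Export is
#' refused while quality-control FAIL findings remain.
#'
#' @param db An `fct_database`.
#' @param path Output file path.
#' @param format `"csv"` or `"json"`.
#' @return `path`, invisibly.
#' @export
export_database <- function(db, path, format = c("csv", "json")) {
  format <- match.arg(format)
  if (!qc_passed(db$qc)) {
    stop_fct("export blocked: ", db$qc$summary[["FAIL"]],
             " unresolved QC FAIL finding(s)", class = "fct_export_error")
  }
  panel <- db$panel
  nut_headers <- paste0(panel$key, " (", panel$unit, ")")
  rows <- lapply(db$records, function(r) {
    base <- list(id = r$id, canonical_name = r$canonical_name,
                 food_group = r$food_group, source = r$source,
                 provenance = r$provenance)
    nuts <- as.list(unclass(r$nutrients))
    names(nuts) <- nut_headers
    c(base, nuts,
      list(portions = serialize_portions(r$portions),
           accompaniments = paste(r$accompaniments, collapse = ";"),
           synonyms = serialize_synonyms(r$synonyms)))
  })
  if (format == "json") {
    jsonlite::write_json(rows, path, auto_unbox = TRUE, digits = I(17),
                         pretty = TRUE, null = "null")
    return(invisible(path))
  }
  header <- c("id", "canonical_name", "food_group", "source", "provenance",
              nut_headers, "portions", "accompaniments", "synonyms")
  df <- do.call(rbind, lapply(rows, function(r) {
    vals <- vapply(header, function(h) {
      v <- r[[h]]
      if (is.numeric(v)) num_chr(v) else as.character(v)
    }, character(1))
    as.data.frame(as.list(stats::setNames(vals, header)),
                  check.names = FALSE, optional = TRUE)
  }))
  if (is.null(df)) {
    df <- as.data.frame(stats::setNames(rep(list(character()), length(header)),
                                        header), check.names = FALSE)
  }
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

parse_portions <- function(txt) {
  if (!nzchar(txt)) {
    return(tibble::tibble(description = character(), grams_per_unit = numeric()))
  }
  parts <- strsplit(strsplit(txt, ";", fixed = TRUE)[[1]], "=", fixed = TRUE)
  tibble::tibble(description = vapply(parts, `[[`, character(1), 1),
                 grams_per_unit = as.numeric(vapply(parts, `[[`, character(1), 2)))
}
parse_synonyms <- function(txt) {
  if (!nzchar(txt)) {
    return(tibble::tibble(language = character(), text = character()))
  }
  parts <- strsplit(strsplit(txt, ";", fixed = TRUE)[[1]], ":", fixed = TRUE)
  tibble::tibble(language = vapply(parts, `[[`, character(1), 1),
                 text = vapply(parts, `[[`, character(1), 2))
}

#' Import a previously exported database
#'
#' Reconstructs the list of [food_record()]s exactly as exported.
#'
#' @param path File written by [export_database()].
#' @param panel Nutrient panel the export used.
#' @param format `"csv"` or `"json"` (guessed from the extension by default).
#' @return List of [food_record()]s.
#' @export
import_database <- function(path, panel = default_panel(), format = NULL) {
  format <- format %||% (if (grepl("\\.json$", path)) "json" else "csv")
  nut_headers <- paste0(panel$key, " (", panel$unit, ")")
  if (format == "json") {
    rows <- jsonlite::read_json(path)
    get_chr <- function(r, k) as.character(r[[k]] %||% "")
    get_nv <- function(r) {
      v <- vapply(nut_headers, function(h) {
        x <- r[[h]]
        if (is.null(x)) NA_real_ else as.numeric(x)
      }, numeric(1))
      names(v) <- panel$key
      v
    }
  } else {
    df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE,
                          colClasses = "character")
    rows <- lapply(seq_len(nrow(df)), function(i) as.list(df[i, , drop = FALSE]))
    get_chr <- function(r, k) r[[k]]
    get_nv <- function(r) {
      v <- vapply(nut_headers, function(h) {
        x <- r[[h]]
        if (!nzchar(x)) NA_real_ else as.numeric(x)
      }, numeric(1))
      names(v) <- panel$key
      v
    }
  }
  lapply(rows, function(r) {
    acc <- get_chr(r, "accompaniments")
    food_record(get_chr(r, "id"), get_chr(r, "canonical_name"),
                get_chr(r, "food_group"), get_chr(r, "source"),
                nutrient_vector(get_nv(r), panel, check_energy = FALSE),
                get_chr(r, "provenance"),
                synonyms = parse_synonyms(get_chr(r, "synonyms")),
                portions = parse_portions(get_chr(r, "portions")),
                accompaniments = if (nzchar(acc))
                  strsplit(acc, ";", fixed = TRUE)[[1]] else character())
  })
}
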