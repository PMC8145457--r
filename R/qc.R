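# Quality checks: automated plausibility and completeness screening that
# stands in for the compiling nutritionists' review. QC is read-only; export
# is gated on the absence of FAIL findings.

finding <- function(id, check, severity, message) {
  tibble::tibble(record_id = id, check = check, severity = severity,
                 message = message)
}

no_findings <- function() {
  tibble::tibble(record_id = character(), check = character(),
                 severity = character(), message = character())
}

#' Completeness check
#'
#' Every exported record must carry a value for every panel nutrient. A
#' missing nutrient is a FAIL (export-blocking).
#'
#' @param record A [food_record()].
#' @param panel Nutrient panel.
#' @return Findings tibble (zero rows when complete).
#' @export
check_completeness <- function(record, panel = default_panel()) {
  gaps <- nv_missing(record$nutrients)
  if (!length(gaps)) return(no_findings())
  finding(record$id, "completeness", "FAIL",
          paste0("missing nutrient(s): ", paste(gaps, collapse = ", ")))
}

#' Energy-consistency check
#'
#' Declared kcal is compared with the energy implied by Atwater components
#' (WARN beyond `tolerance`, default 15 %), and the declared kJ with
#' kcal x 4.184 (WARN beyond 0.5 %).
#'
#' @param record A [food_record()].
#' @param panel Nutrient panel.
#' @param tolerance Relative discrepancy triggering the Atwater warning.
#' @param eps Denominator floor.
#' @return Findings tibble.
#' @export
check_energy_consistency <- function(record, panel = default_panel(),
                                     tolerance = 0.15, eps = 1e-9) {
  nv <- record$nutrients
  out <- no_findings()
  declared <- unclass(nv)["energy_kcal"]
  if (!is.na(declared)) {
    implied <- energy_from_atwater(nv, panel)
    rel <- abs(declared - implied) / max(declared, eps)
    if (rel > tolerance) {
      out <- rbind(out, finding(record$id, "energy_atwater", "WARN",
                                sprintf("declared %.0f kcal vs Atwater %.0f kcal (%.0f%% apart)",
                                        declared, implied, 100 * rel)))
    }
  }
  kj <- unclass(nv)["energy_kJ"]
  if (!is.na(declared) && !is.na(kj) && declared > 0) {
    rel_kj <- abs(kj - declared * 4.184) / (declared * 4.184)
    if (rel_kj > 0.005) {
      out <- rbind(out, finding(record$id, "energy_kj_kcal", "WARN",
                                sprintf("energy_kJ %.1f vs kcal x 4.184 = %.1f",
                                        kj, declared * 4.184)))
    }
  }
  out
}

#' Default plausibility bounds per nutrient
#'
#' Physically motivated per-100 g ceilings (no food exceeds ~900 kcal/100 g,
#' the density of pure fat) used by [check_range()] when no per-group bounds
#' config is supplied.
#'
#' @return Named list: nutrient key -> `c(lo, hi)`.
#' @export
default_bounds <- function() {
  list(energy_kcal = c(0, 900), energy_kJ = c(0, 900 * 4.184),
       protein = c(0, 100), fat = c(0, 100), carbohydrate = c(0, 100),
       fibre = c(0, 50), calcium = c(0, 2000), iron = c(0, 60),
       zinc = c(0, 60), vitamin_a = c(0, 20000), vitamin_c = c(0, 2000))
}

#' Range (plausibility) check
#'
#' @param record A [food_record()].
#' @param bounds Named list nutrient key -> `c(lo, hi)`; keys absent from the
#'   list are not checked.
#' @return Findings tibble (WARN per out-of-bounds nutrient).
#' @export
check_range <- function(record, bounds = default_bounds()) {
  nv <- unclass(record$nutrients)
  out <- no_findings()
  for (k in intersect(names(bounds), names(nv))) {
    v <- nv[[k]]
    if (is.na(v)) next
    b <- bounds[[k]]
    if (v < b[1] || v > b[2]) {
      out <- rbind(out, finding(record$id, "range", "WARN",
                                sprintf("%s = %g outside [%g, %g]", k, v, b[1], b[2])))
    }
  }
  out
}

#' Run all checks over a database
#'
#' @param db List of [food_record()]s.
#' @param panel Nutrient panel.
#' @param bounds See [check_range()].
#' @param energy_tolerance See [check_energy_consistency()].
#' @return A `qc_report`: list with `findings` tibble and `summary` (named
#'   counts per severity, including zero counts).
#' @export
run_qc <- function(db, panel = default_panel(), bounds = default_bounds(),
                   energy_tolerance = 0.15) {
  findings <- no_findings()
  for (rec in db) {
    findings <- rbind(findings,
                      check_completeness(rec, panel),
                      if (!is.na(unclass(rec$nutrients)["energy_kcal"]))
                        check_energy_consistency(rec, panel, energy_tolerance),
                      check_range(rec, bounds))
  }
  sev <- c(INFO = 0L, WARN = 0L, FAIL = 0L)
  tab <- table(findings$severity)
  sev[names(tab)] <- as.integer(tab)
  structure(list(findings = findings, summary = sev), class = "qc_report")
}

#' @export
print.qc_report <- function(x, ...) {
  cat("<qc_report> ", sum(x$summary), " finding(s): ",
      paste(names(x$summary), x$summary, sep = "=", collapse = ", "), "\n",
      sep = "")
  if (nrow(x$findings)) print(x$findings, n = 20)
  invisible(x)
}

#' Does a QC report allow export?
#' @param report A `qc_report`.
#' @return `TRUE` when no FAIL finding remains.
#' @export
qc_passed <- function(report) report$summary[["FAIL"]] == 0L

#' Source and food-group share report
#'
#' Counts of records per nutrient source and per food group, with
#' integer-rounded (half-up) percentage shares recomputed from the counts.
#'
#' @param db List of [food_record()]s.
#' @return List of two tibbles, `by_source` and `by_group`, each with
#'   `count` and `percent`; counts sum to the database size.
#' @export
source_share_report <- function(db) {
  n <- length(db)
  share_tab <- function(values, levels) {
    counts <- vapply(levels, function(l) sum(values == l), integer(1))
    tibble::tibble(key = levels, count = unname(counts),
                   percent = round_half_up(100 * unname(counts) / n))
  }
  list(
    by_source = share_tab(vapply(db, `[[`, character(1), "source"), SOURCE_TAGS),
    by_group = share_tab(vapply(db, `[[`, character(1), "food_group"), food_groups()),
    n = n
  )
}
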