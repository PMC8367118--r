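#' Focal-practice adjustments and the audit ledger
#'
#' The focal practice's totals pass through a fixed, auditable chain of
#' adjustments before comparison: removal of an out-of-area site cohort
#' (population only -- the spending extract holds no costs for that area),
#' removal of a legacy cohort still receiving traditional care (at the
#' reference area's average cost and weighting), an expected-cost
#' correction for lower-than-expected prior utilisation, and GDP-deflator
#' inflation when comparing across financial years. Every step appends a
#' row to an adjustment ledger from which the final totals can be replayed
#' exactly.
#'
#' @name adjustments
NULL

# --- ledger -----------------------------------------------------------

ledger_init <- function(practice_id, scheme, registered, spend) {
  tibble::tibble(
    practice_id = practice_id, scheme = scheme, step = "initial",
    persons_removed = 0, spend_removed = 0, weighted_removed = 0,
    factor_applied = 1,
    registered = registered, spend = spend,
    weighted = NA_real_, cost_pwp = NA_real_
  )
}

ledger_append <- function(ledger, step, persons_removed = 0,
                          spend_removed = 0, weighted_removed = 0,
                          factor_applied = 1,
                          registered = NULL, spend = NULL,
                          weighted = NULL, cost_pwp = NULL) {
  last <- ledger[nrow(ledger), ]
  if (persons_removed < 0 || spend_removed < 0 || weighted_removed < 0) {
    ws_abort("Ledger removals must be non-negative", "ws_bad_ledger")
  }
  dplyr::bind_rows(ledger, tibble::tibble(
    practice_id = last$practice_id, scheme = last$scheme, step = step,
    persons_removed = persons_removed, spend_removed = spend_removed,
    weighted_removed = weighted_removed, factor_applied = factor_applied,
    registered = registered %||% (last$registered - persons_removed),
    spend = spend %||% (last$spend - spend_removed),
    weighted = weighted %||%
      (if (is.na(last$weighted)) NA_real_
       else last$weighted - weighted_removed),
    cost_pwp = cost_pwp %||%
      (if (is.na(last$cost_pwp)) NA_real_
       else last$cost_pwp * factor_applied)
  ))
}

#' Replay an adjustment ledger
#'
#' Recomputes every running total from the initial row and the recorded
#' removals and factors, and checks the stored totals match exactly. Steps
#' that *set* a total rather than decrement it (the weighting step sets
#' `weighted`; the cost step sets `cost_pwp`) are re-derived from the
#' state they were computed from.
#'
#' @param ledger A ledger tibble as produced by [run_pipeline()] (one
#'   scheme at a time or with a `scheme` column).
#' @return `TRUE` invisibly; errors describing the first divergent step
#'   otherwise.
#' @export
ledger_replay <- function(ledger) {
  for (sch in unique(ledger$scheme)) {
    l <- ledger[ledger$scheme == sch, ]
    if (l$step[1] != "initial") {
      ws_abort("Ledger does not start at an 'initial' row", "ws_bad_ledger")
    }
    state <- l[1, c("registered", "spend", "weighted", "cost_pwp")]
    for (k in seq_len(nrow(l))[-1]) {
      row <- l[k, ]
      state$registered <- state$registered - row$persons_removed
      state$spend <- state$spend - row$spend_removed
      if (row$step == "weighting") {
        state$weighted <- row$weighted
      } else if (!is.na(state$weighted)) {
        state$weighted <- state$weighted - row$weighted_removed
      }
      if (row$step == "cost_per_weighted_patient") {
        state$cost_pwp <- state$spend / state$weighted
      } else if (!is.na(state$cost_pwp)) {
        state$cost_pwp <- state$cost_pwp * row$factor_applied
      }
      same <- function(a, b) (is.na(a) && is.na(b)) ||
        (!is.na(a) && !is.na(b) && identical(as.numeric(a), as.numeric(b)))
      if (!same(state$registered, row$registered) ||
          !same(state$spend, row$spend) ||
          !same(state$weighted, row$weighted) ||
          !same(state$cost_pwp, row$cost_pwp)) {
        ws_abort(paste0("Ledger replay diverges at step '", row$step,
                        "' (scheme ", sch, ")"),
                 "ws_ledger_replay")
      }
    }
  }
  invisible(TRUE)
}

#' @rdname adjustments
#' @param ledger Ledger tibble.
#' @param path Output CSV path.
#' @export
write_ledger <- function(ledger, path) {
  utils::write.csv(ledger, path, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

# --- the three focal adjustments + inflation --------------------------

#' Remove a satellite-site cohort from a population profile
#'
#' Patients registered at a site outside the spending extract's coverage
#' are removed from the population band by band. Spending is deliberately
#' left unchanged: the extract holds no costs for them, so no reciprocal
#' spend adjustment exists.
#'
#' @param profile Averaged profile tibble (`sex`, `age_band`, `count`).
#' @param site_profile Profile of the site cohort; must not exceed the
#'   practice population in any band.
#' @return The reduced profile.
#' @export
remove_site_cohort <- function(profile, site_profile) {
  validate_profile(profile)
  validate_profile(site_profile, "site_profile")
  joined <- dplyr::left_join(
    profile,
    dplyr::rename(site_profile, site_count = "count"),
    by = c("sex", "age_band")
  )
  joined$site_count[is.na(joined$site_count)] <- 0
  extra_bands <- setdiff(paste(site_profile$sex, site_profile$age_band),
                         paste(profile$sex, profile$age_band))
  over <- joined$site_count > joined$count
  if (any(over) || length(extra_bands) > 0) {
    offender <- c(paste(joined$sex[over], joined$age_band[over]), extra_bands)
    ws_abort(paste0("Site cohort exceeds the practice population in band(s): ",
                    paste(offender, collapse = ", ")),
             "ws_site_exceeds")
  }
  joined |>
    dplyr::mutate(count = .data$count - .data$site_count) |>
    dplyr::select("sex", "age_band", "count")
}

#' Remove a cohort at reference average cost and weighting
#'
#' A legacy cohort whose spending cannot be separated out is removed by
#' assigning it the reference area's average cost per patient and average
#' need weighting: spend falls by `cohort_size x reference_cost_per_patient`,
#' the registered count by `cohort_size`, and the weighted count by
#' `cohort_size x reference_need_index`.
#'
#' @param spend,registered,weighted The practice totals before removal.
#' @param cohort_size Persons in the cohort (must be below `registered`).
#' @param reference_cost_per_patient Average cost (GBP) per patient in the
#'   reference area.
#' @param reference_need_index Average need index in the reference area.
#' @return A list with the adjusted `spend`, `registered`, `weighted` and
#'   the amounts removed.
#' @export
remove_reference_cohort <- function(spend, registered, weighted,
                                    cohort_size,
                                    reference_cost_per_patient,
                                    reference_need_index) {
  if (cohort_size < 0 || cohort_size >= registered) {
    ws_abort("Cohort size must be non-negative and below the registered count",
             "ws_bad_cohort")
  }
  if (reference_cost_per_patient <= 0 || reference_need_index <= 0) {
    ws_abort("Reference cost and need index must be positive", "ws_bad_cohort")
  }
  spend_removed <- cohort_size * reference_cost_per_patient
  weighted_removed <- cohort_size * reference_need_index
  if (spend - spend_removed < 0 || weighted - weighted_removed < 0) {
    ws_abort(paste0("Reference values inconsistent with practice totals: ",
                    "removal would drive spend or weighted count below zero"),
             "ws_bad_cohort")
  }
  list(
    spend = spend - spend_removed,
    registered = registered - cohort_size,
    weighted = weighted - weighted_removed,
    spend_removed = spend_removed,
    weighted_removed = weighted_removed
  )
}

#' Expected-cost correction factor for prior-utilisation differences
#'
#' Computes how much lower the focal population's actual hospital cost is
#' expected to be than its demographics alone imply, using per-band
#' attendance rates, unit costs and relative prior-use modifiers (for
#' example from a matched-cohort review). The expected cost is evaluated
#' once with unmodified rates and once with each rate multiplied by its
#' modifier; the factor is the relative shortfall
#' `(base - modified) / base`. Downstream, the focal cost per weighted
#' patient is multiplied by `1 + factor` -- a conservative correction that
#' raises the focal cost when the modifiers are below 1.
#'
#' @param profile Averaged profile tibble for the focal population.
#' @param modifiers Rate-modifier table: tibble with `sex`, `age_band`,
#'   `category`, `attendance_rate` (attendances per person-year),
#'   `unit_cost` (GBP per attendance) and `modifier` (relative prior use,
#'   dimensionless > 0). See [read_rate_modifiers()].
#' @return The correction factor (dimensionless; 0 when all modifiers are
#'   1, 0.12 when modified expected cost is 12% below baseline).
#' @export
expected_cost_correction <- function(profile, modifiers) {
  validate_profile(profile)
  required <- c("sex", "age_band", "category", "attendance_rate",
                "unit_cost", "modifier")
  missing <- setdiff(required, names(modifiers))
  if (length(missing) > 0) {
    ws_abort(paste0("Modifier table lacks column(s): ",
                    paste(missing, collapse = ", ")),
             "ws_bad_modifiers")
  }
  if (any(modifiers$modifier <= 0 | !is.finite(modifiers$modifier)) ||
      any(modifiers$attendance_rate < 0) || any(modifiers$unit_cost < 0)) {
    ws_abort("Modifiers must be positive; rates and unit costs non-negative",
             "ws_bad_modifiers")
  }
  joined <- dplyr::inner_join(profile, modifiers, by = c("sex", "age_band"),
                              relationship = "many-to-many")
  expected_base <- sum(joined$count * joined$attendance_rate * joined$unit_cost)
  if (expected_base <= 0) {
    ws_abort("Expected baseline cost is non-positive; check rates and profile",
             "ws_bad_modifiers")
  }
  expected_modified <- sum(joined$count * joined$attendance_rate *
                             joined$modifier * joined$unit_cost)
  (expected_base - expected_modified) / expected_base
}

#' Restate a cost in another financial year's prices
#'
#' Whole-economy GDP-deflator inflation: `cost x deflator_target /
#' deflator_source`. Chaining through an intermediate year equals the
#' direct conversion.
#'
#' @param cost Cost in GBP (source-year terms).
#' @param deflator Deflator series: tibble with `financial_year` and
#'   `deflator` (index values, any base year).
#' @param from_year,to_year Financial year labels present in the series.
#' @return The cost in target-year terms.
#' @export
#' @examples
#' defl <- tibble::tibble(financial_year = c("2018/19", "2019/20"),
#'                        deflator = c(100, 102))
#' apply_inflation(500, defl, "2018/19", "2019/20") # 510
apply_inflation <- function(cost, deflator, from_year, to_year) {
  lookup <- function(fy) {
    v <- deflator$deflator[deflator$financial_year == fy]
    if (length(v) != 1) {
      ws_abort(paste0("Financial year '", fy, "' missing from deflator table"),
               "ws_missing_deflator")
    }
    if (!is.finite(v) || v <= 0) {
      ws_abort(paste0("Deflator for '", fy, "' must be positive"),
               "ws_missing_deflator")
    }
    v
  }
  cost * lookup(to_year) / lookup(from_year)
}

# --- table readers ----------------------------------------------------

#' Read supporting tables
#'
#' `read_rate_modifiers()` reads the attendance-rate / unit-cost /
#' modifier table (columns `sex`, `age_band`, `category`,
#' `attendance_rate`, `unit_cost`, `modifier`); `read_deflator()` reads a
#' two-column `financial_year`, `deflator` series. Comma-delimited, UTF-8,
#' header row mandatory.
#'
#' @param path File path.
#' @return A tibble.
#' @export
read_rate_modifiers <- function(path) {
  df <- tibble::as_tibble(utils::read.csv(path, stringsAsFactors = FALSE))
  required <- c("sex", "age_band", "category", "attendance_rate",
                "unit_cost", "modifier")
  missing <- setdiff(required, names(df))
  if (length(missing) > 0) {
    ws_abort(paste0("Modifier file ", path, " lacks column(s): ",
                    paste(missing, collapse = ", ")),
             "ws_bad_file")
  }
  df
}

#' @rdname read_rate_modifiers
#' @export
read_deflator <- function(path) {
  df <- tibble::as_tibble(utils::read.csv(path, stringsAsFactors = FALSE))
  if (!all(c("financial_year", "deflator") %in% names(df))) {
    ws_abort(paste0("Deflator file ", path,
                    " must have columns financial_year, deflator"),
             "ws_bad_file")
  }
  df
}
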