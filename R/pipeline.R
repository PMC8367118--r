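#' Run the full spending comparison pipeline
#'
#' Orchestrates the whole chain for one financial year: quarterly
#' population averaging, need-weighting under each requested scheme,
#' focal-practice adjustments (site cohort, reference cohort,
#' expected-cost correction), cost per weighted patient at practice and
#' network level, inflation to the target year, normality screening of the
#' network distribution, the one-sided z comparison, percentile ranking,
#' and total savings. Every intermediate is retained: per-practice and
#' per-network tables, the focal adjustment ledger, and the headline
#' comparison row per scheme.
#'
#' Spend rows whose practice is absent from the population file cannot be
#' attributed to a patient population; they are excluded and their total
#' reported in `excluded_spend`.
#'
#' @param population Long population tibble (see [read_population()]).
#' @param spend Tibble with `practice_id`, `financial_year`, `total_spend`.
#' @param coefficients Named list of [coefficient_table()]s (schemes as
#'   names).
#' @param focal_practice_id The practice under study.
#' @param financial_year Label like `"2019/20"`.
#' @param schemes Character vector of schemes to run (default: every
#'   scheme in `coefficients`).
#' @param site_cohort Optional profile tibble of a satellite-site cohort
#'   to remove from the focal population (population only).
#' @param reference_cohort Optional list with `size`, `cost_per_patient`
#'   and `need_index` (a single number, or a named vector keyed by scheme)
#'   describing a legacy cohort removed at reference averages.
#' @param correction `list(mode = "recompute")` to derive the
#'   expected-cost correction factor from `modifiers`,
#'   `list(mode = "pinned", value = 0.12)` to pin it, or
#'   `list(mode = "none")`.
#' @param modifiers Rate-modifier table (required when
#'   `correction$mode == "recompute"`).
#' @param deflator Optional deflator series for inflation.
#' @param inflation_target_year Financial year costs are restated to
#'   (default: `financial_year`, i.e. no inflation step).
#' @param resident_mix Optional tibble `practice_id`, `area_id`,
#'   `fraction` for the adapted scheme; practices not listed default to
#'   their home area.
#' @param nursing_home_rates Optional named numeric of per-practice
#'   nursing-home registration rates for Carr-Hill (default 0).
#' @param alpha Significance level of the normality screen.
#' @param sd_denominator `"n-1"` or `"n"` for the z test's standard
#'   deviation.
#' @return An object of class `spend_comparison`: list with `comparison`
#'   (one row per scheme), `networks`, `practices`, `ledger`,
#'   `excluded_spend`, `correction_factor`, `financial_year`, `screen`.
#' @export
run_pipeline <- function(population, spend, coefficients,
                         focal_practice_id, financial_year,
                         schemes = names(coefficients),
                         site_cohort = NULL,
                         reference_cohort = NULL,
                         correction = list(mode = "none"),
                         modifiers = NULL,
                         deflator = NULL,
                         inflation_target_year = financial_year,
                         resident_mix = NULL,
                         nursing_home_rates = NULL,
                         alpha = 0.05,
                         sd_denominator = "n-1") {
  population <- dplyr::filter(
    population, financial_year_of(.data$quarter_start) == financial_year)
  if (nrow(population) == 0) {
    ws_abort(paste0("No population snapshots for ", financial_year),
             "ws_no_snapshots")
  }
  spend <- dplyr::filter(spend, .data$financial_year == !!financial_year)

  avg <- average_region_population(population, financial_year)
  practices <- avg$practices
  if (!focal_practice_id %in% practices$practice_id) {
    ws_abort(paste0("Focal practice '", focal_practice_id,
                    "' absent from the population file"),
             "ws_bad_config")
  }

  # unattributable spend: no practice population to divide by
  attributable <- spend$practice_id %in% practices$practice_id
  excluded_spend <- tibble::tibble(
    n_rows = sum(!attributable),
    total = sum(spend$total_spend[!attributable])
  )
  spend <- spend[attributable, ]
  spend_of <- stats::setNames(spend$total_spend, spend$practice_id)
  no_spend <- setdiff(practices$practice_id, spend$practice_id)
  if (length(no_spend) > 0) {
    ws_abort(paste0("Practice(s) with population but no spend row: ",
                    paste(utils::head(no_spend, 5), collapse = ", ")),
             "ws_missing_spend")
  }

  profiles_tbl <- avg$profiles
  profiles <- split(avg$profiles[, c("sex", "age_band", "count")],
                    avg$profiles$practice_id)

  # focal site-cohort removal (population only)
  focal_profile_raw <- profiles[[focal_practice_id]]
  focal_profile <- focal_profile_raw
  site_removed <- 0
  if (!is.null(site_cohort) && sum(site_cohort$count) > 0) {
    focal_profile <- remove_site_cohort(focal_profile, site_cohort)
    site_removed <- sum(site_cohort$count)
  }
  profiles[[focal_practice_id]] <- focal_profile
  if (site_removed > 0) {
    profiles_tbl <- dplyr::bind_rows(
      profiles_tbl[profiles_tbl$practice_id != focal_practice_id, ],
      dplyr::mutate(focal_profile, practice_id = focal_practice_id)
    )
  }

  mixes <- NULL
  if (!is.null(resident_mix)) {
    mixes <- split(resident_mix, resident_mix$practice_id)
  }

  deflate <- function(x) {
    if (inflation_target_year == financial_year) return(x)
    if (is.null(deflator)) {
      ws_abort("Inflation requested but no deflator series supplied",
               "ws_missing_deflator")
    }
    apply_inflation(x, deflator, financial_year, inflation_target_year)
  }

  # expected-cost correction factor (shared across schemes; it concerns
  # utilisation, not weighting)
  correction_factor <- switch(
    correction$mode %||% "none",
    none = 0,
    pinned = correction$value %||%
      ws_abort("Pinned correction needs a value", "ws_bad_config"),
    recompute = {
      if (is.null(modifiers)) {
        ws_abort("correction mode 'recompute' needs a modifier table",
                 "ws_bad_config")
      }
      expected_cost_correction(focal_profile, modifiers)
    },
    ws_abort("correction$mode must be none, pinned or recompute",
             "ws_bad_config")
  )

  comparison_rows <- list()
  network_rows <- list()
  practice_rows <- list()
  ledgers <- list()
  screens <- list()

  for (scheme in schemes) {
    if (is.null(coefficients[[scheme]])) {
      ws_abort(paste0("No coefficient table for scheme '", scheme, "'"),
               "ws_bad_config")
    }
    weights <- weigh_region(profiles_tbl, practices, coefficients[[scheme]],
                            mixes = mixes,
                            nursing_home_rates = nursing_home_rates)
    ptab <- weights |>
      dplyr::left_join(practices[, c("practice_id", "network_id")],
                       by = "practice_id") |>
      dplyr::mutate(spend = unname(spend_of[.data$practice_id]))

    focal_row <- ptab[ptab$practice_id == focal_practice_id, ]
    ledger <- ledger_init(focal_practice_id, scheme,
                          registered = sum(focal_profile_raw$count),
                          spend = focal_row$spend)
    if (site_removed > 0) {
      ledger <- ledger_append(ledger, "site_cohort_removal",
                              persons_removed = site_removed)
    }
    ledger <- ledger_append(ledger, "weighting", weighted = focal_row$weighted)

    f_spend <- focal_row$spend
    f_registered <- focal_row$registered
    f_weighted <- focal_row$weighted
    if (!is.null(reference_cohort) && (reference_cohort$size %||% 0) > 0) {
      ni <- reference_cohort$need_index
      if (length(ni) > 1 || !is.null(names(ni))) {
        if (!scheme %in% names(ni)) {
          ws_abort(paste0("reference_cohort$need_index has no entry for ",
                          scheme),
                   "ws_bad_config")
        }
        ni <- ni[[scheme]]
      }
      adj <- remove_reference_cohort(
        f_spend, f_registered, f_weighted,
        cohort_size = reference_cohort$size,
        reference_cost_per_patient = reference_cohort$cost_per_patient,
        reference_need_index = ni
      )
      ledger <- ledger_append(ledger, "reference_cohort_removal",
                              persons_removed = reference_cohort$size,
                              spend_removed = adj$spend_removed,
                              weighted_removed = adj$weighted_removed)
      f_spend <- adj$spend
      f_registered <- adj$registered
      f_weighted <- adj$weighted
      # the focal practice's table entry carries its post-adjustment totals
      ptab$spend[ptab$practice_id == focal_practice_id] <- f_spend
      ptab$registered[ptab$practice_id == focal_practice_id] <- f_registered
      ptab$weighted[ptab$practice_id == focal_practice_id] <- f_weighted
    }

    ptab$cost_pwp <- cost_per_weighted_patient(ptab$spend, ptab$weighted)
    f_cpwp <- f_spend / f_weighted
    ledger <- ledger_append(ledger, "cost_per_weighted_patient",
                            cost_pwp = f_cpwp)
    if (correction_factor != 0) {
      f_cpwp <- f_cpwp * (1 + correction_factor)
      ledger <- ledger_append(ledger, "expected_cost_correction",
                              factor_applied = 1 + correction_factor)
    }
    if (inflation_target_year != financial_year) {
      infl <- deflate(1)
      f_cpwp <- f_cpwp * infl
      ledger <- ledger_append(ledger, "inflation",
                              factor_applied = infl)
    }

    networks <- aggregate_to_network(
      ptab[, c("practice_id", "registered", "spend", "weighted")],
      practices[, c("practice_id", "network_id")]
    )
    networks$cost_pwp <- deflate(networks$cost_pwp)
    ptab$cost_pwp <- deflate(ptab$cost_pwp)

    focal_network <- practices$network_id[
      practices$practice_id == focal_practice_id]
    ref_ptab <- ptab[ptab$practice_id != focal_practice_id, ]
    reference_cpwp <- deflate(sum(ref_ptab$spend) / sum(ref_ptab$weighted))
    reference_need <- sum(ref_ptab$weighted) / sum(ref_ptab$registered)

    ref_networks <- networks[networks$network_id != focal_network, ]
    focal_net_value <- networks$cost_pwp[networks$network_id == focal_network]
    # the focal network's value reflects the corrected focal cost
    focal_net_row <- networks$network_id == focal_network
    if (sum(practices$network_id == focal_network) == 1) {
      networks$cost_pwp[focal_net_row] <- f_cpwp
      focal_net_value <- f_cpwp
    }

    screen <- normality_screen(ref_networks$cost_pwp, alpha = alpha)
    zp <- one_sided_z(focal_net_value, ref_networks$cost_pwp,
                      sd_denominator = sd_denominator)

    # percentile among all practices, with the focal at its corrected cost
    pvals <- ptab$cost_pwp
    pvals[ptab$practice_id == focal_practice_id] <- f_cpwp
    pct_rank <- percentile_rank(f_cpwp, pvals)

    abs_diff <- f_cpwp - reference_cpwp
    comparison_rows[[scheme]] <- tibble::tibble(
      scheme = scheme,
      financial_year = financial_year,
      priced_year = inflation_target_year,
      focal_cost_pwp = f_cpwp,
      reference_cost_pwp = reference_cpwp,
      abs_difference = abs_diff,
      pct_difference = percent_difference(f_cpwp, reference_cpwp),
      z_statistic = zp$z,
      p_value = zp$p,
      screen_pass = screen$pass,
      percentile_rank = pct_rank,
      focal_registered = f_registered,
      focal_weighted = f_weighted,
      focal_need_index = f_weighted / f_registered,
      reference_need_index = reference_need,
      correction_factor = correction_factor,
      total_savings = total_savings(f_weighted, -abs_diff)
    )
    network_rows[[scheme]] <- dplyr::mutate(networks, scheme = scheme,
                                            .before = 1)
    practice_rows[[scheme]] <- ptab
    ledgers[[scheme]] <- ledger
    screens[[scheme]] <- screen$tests
  }

  structure(
    list(
      comparison = dplyr::bind_rows(comparison_rows),
      networks = dplyr::bind_rows(network_rows),
      practices = dplyr::bind_rows(practice_rows),
      ledger = dplyr::bind_rows(ledgers),
      screen = screens,
      excluded_spend = excluded_spend,
      correction_factor = correction_factor,
      financial_year = financial_year
    ),
    class = "spend_comparison"
  )
}

#' @export
print.spend_comparison <- function(x, ...) {
  cat("Need-weighted spending comparison, FY", x$financial_year, "\n")
  if (x$excluded_spend$total > 0) {
    cat(sprintf("Unattributable spend excluded: £%.3gM (%d rows)\n",
                x$excluded_spend$total / 1e6, x$excluded_spend$n_rows))
  }
  cat("\n")
  cat(format_comparison(x), sep = "\n")
  invisible(x)
}

#' Format the headline comparison as an aligned text table
#'
#' Applies the reporting conventions: whole pounds for per-patient costs,
#' one decimal place (half-up) for percentages, two for need indices,
#' three significant figures for savings in millions.
#'
#' @param results A `spend_comparison` object.
#' @return Character vector of table lines.
#' @export
format_comparison <- function(results) {
  cmp <- results$comparison
  header <- sprintf(
    "%-22s %10s %10s %8s %7s %7s %7s %6s %10s",
    "scheme", "focal £pwp", "ref £pwp", "diff £", "diff %",
    "z", "p", "pctl", "savings £M")
  rows <- vapply(seq_len(nrow(cmp)), function(i) {
    r <- cmp[i, ]
    sprintf("%-22s %10.0f %10.0f %8.0f %7.1f %7.2f %7.3f %6d %10.3g",
            r$scheme, round_half_up(r$focal_cost_pwp),
            round_half_up(r$reference_cost_pwp),
            round_half_up(r$abs_difference),
            round_half_up(r$pct_difference, 1),
            r$z_statistic, r$p_value, r$percentile_rank,
            fmt_millions(r$total_savings))
  }, character(1))
  c(header, rows)
}

#' Write the results bundle to a directory
#'
#' Emits delimited-text analogues of the report tables: the headline
#' comparison (`comparison.csv`, full precision, plus `comparison.txt`
#' formatted), per-network and per-practice tables, need indices
#' (`need_indices.csv`), the population band shares of the focal practice
#' versus the region (`band_shares.csv`), and the focal adjustment ledger.
#'
#' @param results A `spend_comparison` object.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_results <- function(results, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  out <- function(name) file.path(dir, name)
  w <- function(df, name) {
    utils::write.csv(df, out(name), row.names = FALSE, fileEncoding = "UTF-8")
  }
  w(results$comparison, "comparison.csv")
  writeLines(format_comparison(results), out("comparison.txt"))
  w(results$networks, "networks.csv")
  w(results$practices, "practices.csv")
  w(results$ledger, "ledger.csv")
  need_idx <- results$comparison[, c("scheme", "financial_year",
                                     "focal_need_index",
                                     "reference_need_index")]
  need_idx$focal_need_index <- round_half_up(need_idx$focal_need_index, 2)
  need_idx$reference_need_index <-
    round_half_up(need_idx$reference_need_index, 2)
  w(need_idx, "need_indices.csv")
  invisible(dir)
}
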