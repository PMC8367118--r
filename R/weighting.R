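#' Need-weighting engines
#'
#' Each engine converts an averaged population profile into a *weighted*
#' population: registered persons multiplied by relative-need coefficients
#' so that populations with different age-sex structures, deprivation and
#' local conditions become comparable. All schemes compose as
#' (band-level product-sum) x (product of local factors) -- the standard
#' multiplicative capitation convention -- and are homogeneous of degree 1
#' in the population.
#'
#' @param profile Averaged profile tibble (`sex`, `age_band`, `count`).
#' @param coefficients A [coefficient_table()] of the matching scheme.
#' @param area_id The practice's home area, used to look up local factors.
#' @param practice_id Optional identifier carried into the result.
#' @return A one-row tibble with `practice_id`, `scheme`, `registered`,
#'   `weighted` and `need_index` (= weighted / registered).
#' @name weighting
NULL

check_scheme <- function(coefficients, scheme) {
  if (!inherits(coefficients, "coef_table")) {
    ws_abort("coefficients must be a coef_table", "ws_bad_coefficients")
  }
  if (coefficients$scheme != scheme) {
    ws_abort(paste0("Coefficient table is for scheme '", coefficients$scheme,
                    "', not '", scheme, "'"),
             "ws_scheme_mismatch")
  }
}

# Band-level product-sum: sum over bands of count x combined need.
# Errors (rather than defaulting) when the profile holds a band the table
# does not price.
band_product_sum <- function(profile, coefficients) {
  validate_profile(profile)
  need <- combined_band_need(coefficients)
  joined <- dplyr::left_join(profile, need, by = c("sex", "age_band"))
  orphan <- is.na(joined$need) & joined$count > 0
  if (any(orphan)) {
    ws_abort(
      paste0("Band(s) present in profile but absent from the ",
             coefficients$scheme, " table: ",
             paste(unique(paste(joined$sex[orphan], joined$age_band[orphan])),
                   collapse = ", ")),
      "ws_unknown_band"
    )
  }
  sum(joined$count * joined$need, na.rm = TRUE)
}

weighted_result <- function(practice_id, scheme, registered, weighted) {
  tibble::tibble(
    practice_id = practice_id,
    scheme = scheme,
    registered = registered,
    weighted = weighted,
    need_index = if (registered > 0) weighted / registered else NA_real_
  )
}

#' @describeIn weighting Commissioner core-services allocation: per-band
#'   need is the component-weight-summed multiplier over the general &
#'   acute, mental health, maternity, community and prescribing
#'   components; the result is scaled by the product of the home area's
#'   local factors (utilisation, supply, price, unmet need, deprivation,
#'   smallness).
#' @export
core_services_weight <- function(profile, coefficients, area_id,
                                 practice_id = NA_character_) {
  check_scheme(coefficients, "core_services")
  ps <- band_product_sum(profile, coefficients)
  weighted <- ps * local_factor_product(coefficients, area_id)
  weighted_result(practice_id, "core_services", sum(profile$count), weighted)
}

#' @describeIn weighting Adapted core-services scheme: only the general &
#'   acute and maternity components are priced (the spending extract being
#'   compared holds no mental health, community or prescribing costs), the
#'   practice's actual averaged profile is always used, and local factors
#'   are averaged over the areas its patients actually live in, weighted
#'   by `resident_area_mix` (named fractions summing to 1).
#' @param resident_area_mix Named numeric: fraction of the practice's
#'   patients resident in each area; must sum to 1 within 1e-6.
#' @export
core_services_adapted_weight <- function(profile, coefficients,
                                         resident_area_mix,
                                         practice_id = NA_character_) {
  check_scheme(coefficients, "core_services_adapted")
  if (is.null(names(resident_area_mix)) ||
      any(!nzchar(names(resident_area_mix)))) {
    ws_abort("resident_area_mix must be a named vector of area fractions",
             "ws_bad_residence_mix")
  }
  if (abs(sum(resident_area_mix) - 1) > 1e-6) {
    ws_abort(sprintf(
      "resident_area_mix sums to %.8f, not 1", sum(resident_area_mix)),
      "ws_bad_residence_mix")
  }
  per_area <- vapply(names(resident_area_mix),
                     function(a) local_factor_product(coefficients, a),
                     numeric(1))
  effective_local <- sum(resident_area_mix * per_area)
  ps <- band_product_sum(profile, coefficients)
  weighted_result(practice_id, "core_services_adapted",
                  sum(profile$count), ps * effective_local)
}

#' @describeIn weighting Carr-Hill global-sum weighting: the age-sex
#'   workload curve scaled by local premature mortality, market forces and
#'   rurality, with a premium per registered nursing-home patient:
#'   `weighted = product-sum x mortality x market_forces x rurality x
#'   (1 + premium x nursing_home_rate)`.
#' @param nursing_home_rate Fraction of the registered population resident
#'   in nursing homes (>= 0).
#' @export
carr_hill_weight <- function(profile, coefficients, area_id,
                             nursing_home_rate = 0,
                             practice_id = NA_character_) {
  check_scheme(coefficients, "carr_hill")
  if (!is.finite(nursing_home_rate) || nursing_home_rate < 0) {
    ws_abort("nursing_home_rate must be non-negative", "ws_bad_rate")
  }
  f <- coefficients$local_factors[[as.character(area_id)]]
  if (is.null(f)) {
    ws_abort(paste0("Area '", area_id, "' not present in carr_hill ",
                    "local factors"),
             "ws_unknown_area")
  }
  ps <- band_product_sum(profile, coefficients)
  weighted <- ps * f[["mortality"]] * f[["market_forces"]] * f[["rurality"]] *
    (1 + coefficients$nursing_home_premium * nursing_home_rate)
  weighted_result(practice_id, "carr_hill", sum(profile$count), weighted)
}

# Vectorised engine used by run_pipeline() and the generator: one join
# over all practices instead of a per-practice call. Semantically
# identical to mapping the per-practice functions (asserted in tests).
weigh_region <- function(profiles, practices, coefficients,
                         mixes = NULL, nursing_home_rates = NULL) {
  scheme <- coefficients$scheme
  need <- combined_band_need(coefficients)
  joined <- dplyr::left_join(profiles, need, by = c("sex", "age_band"))
  orphan <- is.na(joined$need) & joined$count > 0
  if (any(orphan)) {
    ws_abort(
      paste0("Band(s) present in profile but absent from the ", scheme,
             " table: ",
             paste(unique(paste(joined$sex[orphan], joined$age_band[orphan])),
                   collapse = ", ")),
      "ws_unknown_band"
    )
  }
  ps <- joined |>
    dplyr::group_by(.data$practice_id) |>
    dplyr::summarise(registered = sum(.data$count),
                     product_sum = sum(.data$count * .data$need),
                     .groups = "drop") |>
    dplyr::left_join(practices[, c("practice_id", "area_id")],
                     by = "practice_id")
  areas <- unique(ps$area_id)
  lf_prod <- vapply(areas, function(a) local_factor_product(coefficients, a),
                    numeric(1))
  names(lf_prod) <- areas
  factor <- unname(lf_prod[ps$area_id])
  if (scheme == "core_services_adapted" && !is.null(mixes)) {
    for (pid in names(mixes)) {
      m <- mixes[[pid]]
      mix <- stats::setNames(m$fraction, m$area_id)
      if (abs(sum(mix) - 1) > 1e-6) {
        ws_abort(sprintf("resident_area_mix for %s sums to %.8f, not 1",
                         pid, sum(mix)),
                 "ws_bad_residence_mix")
      }
      per_area <- vapply(names(mix),
                         function(a) local_factor_product(coefficients, a),
                         numeric(1))
      factor[ps$practice_id == pid] <- sum(mix * per_area)
    }
  }
  if (scheme == "carr_hill") {
    rate <- rep(0, nrow(ps))
    if (!is.null(nursing_home_rates)) {
      hit <- ps$practice_id %in% names(nursing_home_rates)
      rate[hit] <- unname(nursing_home_rates[ps$practice_id[hit]])
    }
    if (any(rate < 0)) {
      ws_abort("nursing_home_rate must be non-negative", "ws_bad_rate")
    }
    factor <- factor * (1 + coefficients$nursing_home_premium * rate)
  }
  tibble::tibble(
    practice_id = ps$practice_id,
    scheme = scheme,
    registered = ps$registered,
    weighted = ps$product_sum * factor,
    need_index = ifelse(ps$registered > 0,
                        ps$product_sum * factor / ps$registered, NA_real_)
  )
}

#' Need index
#'
#' The weighted population relative to the registered population: an index
#' above 1 marks a population with higher-than-baseline expected cost.
#'
#' @param weighted Weighted persons (> 0 whenever registered > 0).
#' @param registered Registered (averaged) persons; must be positive.
#' @return `weighted / registered`.
#' @export
#' @examples
#' need_index(66, 100) # 0.66
need_index <- function(weighted, registered) {
  if (any(!is.finite(registered)) || any(registered <= 0)) {
    ws_abort("need index undefined for non-positive registered population",
             "ws_zero_population")
  }
  weighted / registered
}
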