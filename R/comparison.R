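#' Cost per weighted patient
#'
#' Total spending divided by the weighted population: the standardised
#' metric under which practices and networks of different size and need
#' become comparable. Aggregates must be formed by summing spend and
#' weighted counts *before* dividing; the mean of member ratios is a
#' different (and wrong) quantity.
#'
#' @param total_spend Total spend in GBP (>= 0).
#' @param weighted Weighted persons (> 0).
#' @return GBP per weighted patient. Vectorised.
#' @export
#' @examples
#' cost_per_weighted_patient(1e6, 2000) # 500
cost_per_weighted_patient <- function(total_spend, weighted) {
  if (any(!is.finite(weighted)) || any(weighted <= 0)) {
    ws_abort("Weighted population must be positive", "ws_zero_population")
  }
  total_spend / weighted
}

#' Aggregate practice spend and weighted counts to networks
#'
#' @param practice_results Tibble with `practice_id`, `spend`, `weighted`
#'   (and optionally `registered`).
#' @param network_map Tibble with `practice_id`, `network_id`; every
#'   practice must map to exactly one network.
#' @return Per-network tibble: `network_id`, `n_practices`, `spend`,
#'   `weighted` (and `registered` if supplied), `cost_pwp`.
#' @export
aggregate_to_network <- function(practice_results, network_map) {
  network_map <- dplyr::distinct(network_map, .data$practice_id,
                                 .data$network_id)
  if (anyDuplicated(network_map$practice_id)) {
    dup <- unique(network_map$practice_id[duplicated(network_map$practice_id)])
    ws_abort(paste0("Practice(s) mapped to more than one network: ",
                    paste(dup, collapse = ", ")),
             "ws_bad_network_map")
  }
  joined <- dplyr::left_join(practice_results, network_map, by = "practice_id")
  orphans <- unique(joined$practice_id[is.na(joined$network_id)])
  if (length(orphans) > 0) {
    ws_abort(paste0("Practice(s) with no network: ",
                    paste(orphans, collapse = ", ")),
             "ws_bad_network_map")
  }
  out <- joined |>
    dplyr::group_by(.data$network_id) |>
    dplyr::summarise(
      n_practices = dplyr::n(),
      dplyr::across(dplyr::any_of(c("registered", "spend", "weighted")), sum),
      .groups = "drop"
    )
  dplyr::mutate(out, cost_pwp = cost_per_weighted_patient(.data$spend,
                                                          .data$weighted))
}

#' Percent difference of a focal value from a reference value
#'
#' @param focal,reference GBP per weighted patient; `reference` > 0.
#' @return `100 * (focal - reference) / reference`; negative when the
#'   focal value is lower.
#' @export
percent_difference <- function(focal, reference) {
  if (any(!is.finite(reference)) || any(reference <= 0)) {
    ws_abort("Reference cost must be positive", "ws_bad_reference")
  }
  100 * (focal - reference) / reference
}

#' One-sided simple z comparison of a focal value against a sample
#'
#' The focal value enters as a single observation against the empirical
#' distribution of reference aggregates: `z = (focal - mean) / sd`, with
#' the lower-tail standard normal probability as the one-sided p value
#' (alternative: the focal value is lower).
#'
#' @param focal_value The focal cost per weighted patient.
#' @param reference_sample Numeric vector of reference network values
#'   (length >= 3, non-zero spread).
#' @param sd_denominator `"n-1"` (sample standard deviation, default) or
#'   `"n"` (population form).
#' @return A list with `z` and `p`.
#' @export
#' @examples
#' one_sided_z(480, c(700, 710, 720, 730, 695))
one_sided_z <- function(focal_value, reference_sample,
                        sd_denominator = c("n-1", "n")) {
  sd_denominator <- match.arg(sd_denominator)
  n <- length(reference_sample)
  if (n < 3) {
    ws_abort("Reference sample must hold at least 3 values", "ws_small_sample")
  }
  s <- stats::sd(reference_sample)
  if (sd_denominator == "n") s <- s * sqrt((n - 1) / n)
  if (!is.finite(s) || s <= 0) {
    ws_abort("Reference sample has zero variance; z undefined",
             "ws_zero_variance")
  }
  z <- (focal_value - mean(reference_sample)) / s
  list(z = z, p = stats::pnorm(z))
}

#' Normality screen for a sample of aggregate values
#'
#' Shapiro-Wilk and Kolmogorov-Smirnov (against a normal with the sample's
#' own mean and standard deviation) are both evaluated; the screen passes
#' only if neither rejects at `alpha`. The z comparison is only *reported*
#' at aggregation levels passing this screen -- practice-level data with
#' heavy outliers fail it, network aggregates typically pass.
#'
#' @param sample Numeric vector (length >= 3, non-constant).
#' @param alpha Significance level for each test (default 0.05).
#' @return A list with `tests` (tibble: `test`, `statistic`, `p`) and
#'   `pass` (logical).
#' @export
normality_screen <- function(sample, alpha = 0.05) {
  if (length(sample) < 3) {
    ws_abort("Normality screen needs at least 3 values", "ws_small_sample")
  }
  if (stats::sd(sample) == 0) {
    ws_abort("Constant sample: normality tests undefined", "ws_zero_variance")
  }
  sw <- stats::shapiro.test(sample)
  ks <- suppressWarnings(
    stats::ks.test(sample, "pnorm", mean(sample), stats::sd(sample))
  )
  tests <- tibble::tibble(
    test = c("shapiro_wilk", "kolmogorov_smirnov"),
    statistic = c(unname(sw$statistic), unname(ks$statistic)),
    p = c(sw$p.value, ks$p.value)
  )
  list(tests = tests, pass = all(tests$p > alpha))
}

#' Percentile rank of a focal value among practice values
#'
#' `ceiling(100 * #{values <= focal} / (n + 1))`, clamped to 1--100, with
#' the 1st percentile the lowest value. Ties count as below-or-equal, so
#' near-minimal values report low single-digit percentiles.
#'
#' @param focal_value The focal practice's cost per weighted patient.
#' @param all_practice_values Values to rank against (focal included if it
#'   should count as one of the ranked set).
#' @return Integer percentile in 1--100.
#' @export
percentile_rank <- function(focal_value, all_practice_values) {
  n <- length(all_practice_values)
  if (n < 1) {
    ws_abort("Cannot rank against an empty comparison set", "ws_small_sample")
  }
  pct <- ceiling(100 * sum(all_practice_values <= focal_value) / (n + 1))
  as.integer(min(100, max(1, pct)))
}

#' Total savings implied by a cost difference
#'
#' @param focal_weighted Weighted persons in the focal population (> 0).
#' @param abs_difference GBP per weighted patient; pass `reference -
#'   focal` so a lower focal cost yields positive savings.
#' @return GBP: `focal_weighted * abs_difference`.
#' @export
total_savings <- function(focal_weighted, abs_difference) {
  if (any(focal_weighted <= 0)) {
    ws_abort("Weighted population must be positive", "ws_zero_population")
  }
  focal_weighted * abs_difference
}

#' Net savings after extra primary-care provision costs
#'
#' A more accessible practice delivers more appointments per weighted
#' patient; if primary-care cost grew linearly with appointments, the
#' extra cost per weighted patient is `extra_appointment_fraction x
#' funding_per_patient` (rounded to whole pounds), which is netted off the
#' gross acute-cost difference.
#'
#' @param abs_difference Gross acute saving in GBP per weighted patient.
#' @param extra_appointment_fraction Extra appointments delivered relative
#'   to average (e.g. 0.23 for 23% more).
#' @param funding_per_patient Average primary-care funding per patient
#'   (GBP per year).
#' @return Net saving in GBP per weighted patient.
#' @export
#' @examples
#' net_savings_after_primary_care(362, 0.23, 155) # 362 - 36 = 326
net_savings_after_primary_care <- function(abs_difference,
                                           extra_appointment_fraction,
                                           funding_per_patient) {
  if (extra_appointment_fraction < 0 || funding_per_patient < 0) {
    ws_abort("Inputs must be non-negative", "ws_bad_input")
  }
  abs_difference -
    round_half_up(extra_appointment_fraction * funding_per_patient)
}
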