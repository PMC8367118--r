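#' Capitation coefficient tables
#'
#' All three weighting engines are strictly table-driven: relative need
#' multipliers by age-sex band (per service component for the commissioner
#' allocation schemes, a single workload curve for the Carr-Hill scheme)
#' plus named local adjustment factors per area. No official NHS
#' coefficients are bundled; [generate_coefficients()] produces documented
#' synthetic tables, and users can supply their own via
#' [read_coefficients()].
#'
#' @param scheme One of `"core_services"`, `"core_services_adapted"`,
#'   `"carr_hill"`.
#' @param needs For the core schemes, a tibble with columns `component`,
#'   `sex`, `age_band`, `need`; ignored for Carr-Hill.
#' @param weights Named numeric of component weights summing to 1 over the
#'   included components (core schemes only). For the adapted scheme only
#'   `general_acute` and `maternity` may carry non-zero weight.
#' @param band_need Carr-Hill only: tibble `sex`, `age_band`, `need`.
#' @param local_factors Named list: `area_id` -> named numeric multipliers.
#'   Core schemes expect `utilization`, `supply`, `price`, `unmet_need`,
#'   `deprivation`, `smallness`; Carr-Hill expects `mortality`,
#'   `market_forces`, `rurality`.
#' @param reference_mean The need index a uniform population (equal persons
#'   in every band, neutral local factors) evaluates to; checked at
#'   construction.
#' @param nursing_home_premium Carr-Hill only: extra weight per registered
#'   nursing-home patient (e.g. 0.43 adds 43%).
#' @return An object of class `coef_table`.
#' @export
coefficient_table <- function(scheme, needs = NULL, weights = NULL,
                              band_need = NULL, local_factors,
                              reference_mean,
                              nursing_home_premium = NULL) {
  scheme <- match.arg(scheme,
                      c("core_services", "core_services_adapted", "carr_hill"))
  tab <- structure(
    list(
      scheme = scheme, needs = needs, weights = weights,
      band_need = band_need, local_factors = local_factors,
      reference_mean = reference_mean,
      nursing_home_premium = nursing_home_premium
    ),
    class = "coef_table"
  )
  validate_coefficient_table(tab)
  tab
}

CORE_FACTOR_NAMES <- c("utilization", "supply", "price", "unmet_need",
                       "deprivation", "smallness")
CARR_HILL_FACTOR_NAMES <- c("mortality", "market_forces", "rurality")
ADAPTED_COMPONENTS <- c("general_acute", "maternity")
CORE_COMPONENTS <- c("general_acute", "mental_health", "maternity",
                     "community", "prescribing")

# Combined per-band relative need under a table (component-weight-summed
# for the core schemes, the raw workload curve for Carr-Hill).
combined_band_need <- function(tab) {
  if (tab$scheme == "carr_hill") {
    return(dplyr::select(tab$band_need, "sex", "age_band", "need"))
  }
  w <- tibble::tibble(component = names(tab$weights),
                      weight = unname(tab$weights))
  tab$needs |>
    dplyr::inner_join(w, by = "component") |>
    dplyr::group_by(.data$sex, .data$age_band) |>
    dplyr::summarise(need = sum(.data$weight * .data$need), .groups = "drop")
}

# First-violation-with-path schema check, run at construction and on load.
validate_coefficient_table <- function(tab) {
  fail <- function(path, why) {
    ws_abort(paste0("Invalid coefficient table at ", tab$scheme, "/", path,
                    ": ", why),
             "ws_bad_coefficients")
  }
  if (!is.numeric(tab$reference_mean) || length(tab$reference_mean) != 1 ||
      !is.finite(tab$reference_mean) || tab$reference_mean <= 0) {
    fail("reference_mean", "must be a single positive number")
  }
  if (tab$scheme == "carr_hill") {
    if (is.null(tab$band_need)) fail("band_need", "missing")
    bad <- !is.finite(tab$band_need$need) | tab$band_need$need <= 0
    if (any(bad)) {
      fail(paste0("band_need/", tab$band_need$sex[bad][1], "/",
                  tab$band_need$age_band[bad][1]),
           "multiplier not strictly positive and finite")
    }
    if (is.null(tab$nursing_home_premium) ||
        !is.finite(tab$nursing_home_premium) || tab$nursing_home_premium < 0) {
      fail("nursing_home_premium", "must be a non-negative number")
    }
    expected <- CARR_HILL_FACTOR_NAMES
  } else {
    if (is.null(tab$needs) || is.null(tab$weights)) {
      fail("components", "needs and weights both required")
    }
    if (abs(sum(tab$weights) - 1) > 1e-9) {
      fail("components/weights",
           sprintf("weights sum to %.12f, not 1", sum(tab$weights)))
    }
    if (any(tab$weights < 0)) {
      fail(paste0("components/", names(tab$weights)[tab$weights < 0][1],
                  "/weight"), "negative weight")
    }
    if (tab$scheme == "core_services_adapted") {
      excluded <- setdiff(names(tab$weights), ADAPTED_COMPONENTS)
      nonzero <- excluded[tab$weights[excluded] != 0]
      if (length(nonzero) > 0) {
        fail(paste0("components/", nonzero[1], "/weight"),
             "excluded component carries non-zero weight in the adapted scheme")
      }
    }
    bad <- !is.finite(tab$needs$need) | tab$needs$need <= 0
    if (any(bad)) {
      fail(paste0("components/", tab$needs$component[bad][1], "/need/",
                  tab$needs$sex[bad][1], "/", tab$needs$age_band[bad][1]),
           "multiplier not strictly positive and finite")
    }
    expected <- CORE_FACTOR_NAMES
  }
  for (area in names(tab$local_factors)) {
    f <- tab$local_factors[[area]]
    missing <- setdiff(expected, names(f))
    if (length(missing) > 0) {
      fail(paste0("local_factors/", area, "/", missing[1]), "factor missing")
    }
    bad <- !is.finite(f) | f <= 0
    if (any(bad)) {
      fail(paste0("local_factors/", area, "/", names(f)[bad][1]),
           "multiplier not strictly positive and finite")
    }
  }
  # Normalisation: a uniform population in neutral-factor conditions must
  # evaluate to the reference mean index.
  need <- combined_band_need(tab)
  uniform_index <- mean(need$need)
  if (abs(uniform_index - tab$reference_mean) > 1e-6 * tab$reference_mean) {
    fail("reference_mean",
         sprintf("uniform population evaluates to %.9f, table claims %.9f",
                 uniform_index, tab$reference_mean))
  }
  invisible(tab)
}

#' @export
print.coef_table <- function(x, ...) {
  need <- combined_band_need(x)
  cat("<coef_table> scheme:", x$scheme,
      "| bands:", nrow(need),
      "| areas:", length(x$local_factors),
      "| reference mean index:", format(x$reference_mean, digits = 4), "\n")
  invisible(x)
}

# Product of an area's local factors; errors name the offending area.
local_factor_product <- function(tab, area_id) {
  f <- tab$local_factors[[as.character(area_id)]]
  if (is.null(f)) {
    ws_abort(paste0("Area '", area_id, "' not present in ", tab$scheme,
                    " local factors"),
             "ws_unknown_area")
  }
  prod(f)
}

coef_table_to_list <- function(tab) {
  out <- list(scheme = tab$scheme,
              reference_mean = tab$reference_mean)
  if (tab$scheme == "carr_hill") {
    need <- tab$band_need
    out$band_need <- lapply(split(need, need$sex), function(d) {
      as.list(stats::setNames(d$need, d$age_band))
    })
    out$nursing_home_premium <- tab$nursing_home_premium
  } else {
    out$components <- lapply(names(tab$weights), function(cmp) {
      d <- tab$needs[tab$needs$component == cmp, ]
      list(
        weight = unname(tab$weights[[cmp]]),
        need = lapply(split(d, d$sex), function(s) {
          as.list(stats::setNames(s$need, s$age_band))
        })
      )
    })
    names(out$components) <- names(tab$weights)
  }
  out$local_factors <- lapply(tab$local_factors, as.list)
  out
}

coef_table_from_list <- function(x) {
  unpack_need <- function(need) {
    dplyr::bind_rows(lapply(names(need), function(sx) {
      tibble::tibble(sex = sx,
                     age_band = names(need[[sx]]),
                     need = as.numeric(unlist(need[[sx]])))
    }))
  }
  local_factors <- lapply(x$local_factors, function(f) unlist(f))
  if (identical(x$scheme, "carr_hill")) {
    coefficient_table(
      scheme = "carr_hill",
      band_need = unpack_need(x$band_need),
      local_factors = local_factors,
      reference_mean = x$reference_mean,
      nursing_home_premium = x$nursing_home_premium
    )
  } else {
    needs <- dplyr::bind_rows(lapply(names(x$components), function(cmp) {
      dplyr::mutate(unpack_need(x$components[[cmp]]$need), component = cmp)
    }))
    weights <- vapply(x$components, function(cmp) cmp$weight, numeric(1))
    coefficient_table(
      scheme = x$scheme,
      needs = needs[, c("component", "sex", "age_band", "need")],
      weights = weights,
      local_factors = local_factors,
      reference_mean = x$reference_mean
    )
  }
}

#' Read and write coefficient tables
#'
#' Tables are stored as one YAML document holding one section per scheme.
#' Every table is schema-checked on load; the first violation is reported
#' with its path (e.g. `core_services/local_factors/A03/deprivation`).
#'
#' @param path YAML file path.
#' @return `read_coefficients()`: a named list of [coefficient_table()]
#'   objects, keyed by scheme.
#' @export
read_coefficients <- function(path) {
  raw <- yaml::read_yaml(path)
  lapply(raw, coef_table_from_list)
}

#' @rdname read_coefficients
#' @param tables Named list of `coef_table` objects.
#' @export
write_coefficients <- function(tables, path) {
  # full double precision: coefficients must survive a round trip bit-near
  yaml::write_yaml(lapply(tables, coef_table_to_list), path, precision = 15)
  invisible(path)
}
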