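#' Configure a synthetic commissioning region
#'
#' Builds the configuration for [generate_region()]: a region of general
#' practices grouped into primary care networks, with one large,
#' fast-growing focal practice whose registered population is concentrated
#' in working-age adults and whose underlying spend rate is configurably
#' lower than the regional baseline. Defaults emulate the scale of a large
#' urban commissioning region: ~357 reference practices of mean list size
#' ~6,900 (lognormal dispersion) in 48 networks of ~50,000 patients, plus
#' the focal practice in a network of its own.
#'
#' @param n_practices Number of reference practices (focal excluded).
#' @param n_networks Number of reference networks; practices are assigned
#'   round-robin so networks are near-equal in practice count.
#' @param mean_list_size Mean registered list size of reference practices.
#' @param list_size_sdlog Lognormal sdlog of list sizes (0.5 spans a few
#'   hundred to ~20,000+ patients across a large region).
#' @param regional_mixture Named fractions over the canonical age-sex
#'   bands for the regional population (defaults to a working-age-heavy
#'   urban mixture); normalised internally.
#' @param mixture_concentration Dirichlet-style concentration controlling
#'   practice-to-practice demographic heterogeneity (larger = more alike).
#' @param base_cost_per_need_unit GBP of acute spend per weighted patient
#'   at baseline (default 715).
#' @param spend_noise Gamma shape of the practice spend noise at the mean
#'   list size. Shape scales proportionally with list size, so per-patient
#'   cost shocks average out in larger practices and network aggregates
#'   are approximately normal.
#' @param financial_year Financial year the region covers.
#' @param focal List describing the focal practice: `id`, `size_quarters`
#'   (registered list at each quarter start; the default grows ~10% a
#'   quarter to an average near 60,000), `mixture` (young-adult-heavy
#'   band fractions), `true_spend_multiplier` (underlying spend rate
#'   relative to baseline; default 0.65), `deprivation_percentile`,
#'   `n_resident_areas` (areas its patients are spread over for the
#'   adapted scheme's residence mix).
#' @param seed Integer seed; mandatory, all randomness flows through it.
#' @return A `region_config` list.
#' @export
region_config <- function(n_practices = 357,
                          n_networks = 48,
                          mean_list_size = 6900,
                          list_size_sdlog = 0.5,
                          regional_mixture = NULL,
                          mixture_concentration = 150,
                          base_cost_per_need_unit = 715,
                          spend_noise = 50,
                          financial_year = "2019/20",
                          focal = list(),
                          seed) {
  if (missing(seed) || !is.finite(seed)) {
    ws_abort("region_config() requires an explicit integer seed",
             "ws_bad_config")
  }
  if (!(n_practices >= n_networks) || n_networks < 2 ||
      mean_list_size <= 0 || base_cost_per_need_unit <= 0 ||
      spend_noise <= 0) {
    ws_abort("Invalid region configuration: sizes and costs must be positive",
             "ws_bad_config")
  }
  bands <- canonical_bands()
  key <- paste(bands$sex, bands$age_band)
  default_regional <- stats::setNames(
    c(0.1059, 0.1764, 0.1238, 0.0648, 0.0177,   # female 0-19 ... 80+
      0.1113, 0.1784, 0.1474, 0.0618, 0.0126),  # male   0-19 ... 80+
    key
  )
  default_focal_mix <- stats::setNames(
    c(0.0163, 0.3968, 0.0310, 0.0040, 0.0006,
      0.0134, 0.4581, 0.0732, 0.0060, 0.0005),
    key
  )
  regional_mixture <- regional_mixture %||% default_regional
  regional_mixture <- regional_mixture / sum(regional_mixture)
  focal_defaults <- list(
    id = "FOCAL",
    size_quarters = round(52000 * 1.1^(0:3)),
    mixture = default_focal_mix / sum(default_focal_mix),
    true_spend_multiplier = 0.65,
    deprivation_percentile = 45L,
    n_resident_areas = 5L
  )
  focal <- utils::modifyList(focal_defaults, focal)
  focal$mixture <- focal$mixture / sum(focal$mixture)
  bad_share <- c(regional_mixture, focal$mixture)
  if (any(bad_share < 0 | bad_share > 1)) {
    ws_abort("Mixture shares must lie in [0, 1]", "ws_bad_config")
  }
  if (any(focal$size_quarters <= 0) || focal$true_spend_multiplier < 0) {
    ws_abort("Focal sizes must be positive and the spend multiplier >= 0",
             "ws_bad_config")
  }
  structure(
    list(
      n_practices = as.integer(n_practices),
      n_networks = as.integer(n_networks),
      mean_list_size = mean_list_size,
      list_size_sdlog = list_size_sdlog,
      regional_mixture = regional_mixture,
      mixture_concentration = mixture_concentration,
      base_cost_per_need_unit = base_cost_per_need_unit,
      spend_noise = spend_noise,
      financial_year = financial_year,
      focal = focal,
      seed = as.integer(seed)
    ),
    class = "region_config"
  )
}

# Age-cost curves used by the synthetic coefficient generator. These are
# NOT official allocation coefficients: they are plausible shapes (U-shaped
# cost over age, maternity concentrated in women of childbearing age, a
# flatter consultation-workload curve for the global-sum scheme) intended
# only to exercise the engines.
synthetic_age_curves <- function() {
  list(
    general_acute = list(female = c(0.75, 0.55, 0.85, 1.90, 3.20),
                         male   = c(0.80, 0.50, 0.80, 2.00, 3.40)),
    mental_health = list(female = c(0.50, 1.10, 1.20, 1.00, 0.90),
                         male   = c(0.55, 1.05, 1.15, 0.95, 0.85)),
    maternity     = list(female = c(0.30, 3.50, 0.60, 0.05, 0.05),
                         male   = c(0.02, 0.02, 0.02, 0.02, 0.02)),
    community     = list(female = c(0.60, 0.50, 0.80, 1.80, 3.50),
                         male   = c(0.60, 0.45, 0.75, 1.70, 3.30)),
    prescribing   = list(female = c(0.40, 0.50, 1.00, 2.20, 3.00),
                         male   = c(0.40, 0.45, 1.00, 2.30, 3.10)),
    carr_hill     = list(female = c(1.00, 0.80, 0.95, 1.35, 1.90),
                         male   = c(0.95, 0.70, 0.90, 1.30, 1.85))
  )
}

CORE_WEIGHTS <- c(general_acute = 0.52, mental_health = 0.12,
                  maternity = 0.04, community = 0.12, prescribing = 0.20)

#' Generate synthetic coefficient tables
#'
#' Produces one schema-valid [coefficient_table()] per scheme with a
#' U-shaped age-cost curve (jittered per seed), a deprivation-increasing
#' local factor, and band needs scaled so the population-weighted regional
#' need index comes out near `target_index` (the 0.9--1.0 range typical of
#' a young urban region against a national reference). Synthetic, clearly
#' non-official: see [synthetic_age_curves()] source for the shapes.
#'
#' @param seed Integer seed.
#' @param banding Tibble of `sex`, `age_band` (canonical 10 bands by
#'   default).
#' @param areas Character vector of area identifiers to supply local
#'   factors for.
#' @param area_deprivation Named numeric of deprivation percentiles per
#'   area (1 = most deprived); defaults to 50 everywhere.
#' @param regional_mixture Named band fractions used for normalisation.
#' @param target_index Population-weighted regional need index to
#'   normalise to (default 0.95).
#' @return Named list of three `coef_table` objects.
#' @export
generate_coefficients <- function(seed,
                                  banding = canonical_bands(),
                                  areas = paste0("A", 1:8),
                                  area_deprivation = NULL,
                                  regional_mixture = NULL,
                                  target_index = 0.95) {
  validate_banding(unique(banding$age_band))
  withr::with_seed(seed, {
    n_age <- length(unique(banding$age_band))
    age_levels <- unique(banding$age_band)
    if (is.null(area_deprivation)) {
      area_deprivation <- stats::setNames(rep(50, length(areas)), areas)
    }
    if (is.null(regional_mixture)) {
      cfgmix <- region_config(seed = 1)$regional_mixture
      regional_mixture <- cfgmix
    }
    curves <- synthetic_age_curves()
    # map a raw curve onto the requested banding by position (curves are
    # defined over 5 age groups; other bandings are interpolated)
    curve_on_banding <- function(v) {
      stats::approx(seq_along(v), v, xout = seq(1, length(v),
                                                length.out = n_age))$y
    }
    make_needs <- function(components) {
      dplyr::bind_rows(lapply(names(components), function(cmp) {
        dplyr::bind_rows(lapply(c("female", "male"), function(sx) {
          base <- curve_on_banding(curves[[cmp]][[sx]])
          tibble::tibble(
            component = cmp, sex = sx, age_band = age_levels,
            need = base * exp(stats::rnorm(n_age, 0, 0.05))
          )
        }))
      }))
    }
    mix_vec <- function(need_tbl) {
      key <- paste(need_tbl$sex, need_tbl$age_band)
      m <- regional_mixture[key]
      m[is.na(m)] <- 0
      sum(m * need_tbl$need) / sum(m)
    }
    scale_needs <- function(needs, weights) {
      w <- tibble::tibble(component = names(weights),
                          weight = unname(weights))
      combined <- needs |>
        dplyr::inner_join(w, by = "component") |>
        dplyr::group_by(.data$sex, .data$age_band) |>
        dplyr::summarise(need = sum(.data$weight * .data$need),
                         .groups = "drop")
      s <- target_index / mix_vec(combined)
      list(needs = dplyr::mutate(needs, need = .data$need * s),
           reference_mean = mean(combined$need * s))
    }
    dep_factor <- function(slope) {
      1 + slope * (50 - area_deprivation[areas]) / 100
    }
    jitter_factor <- function(sdlog) exp(stats::rnorm(length(areas), 0, sdlog))

    core_factors <- list(
      utilization = jitter_factor(0.02), supply = jitter_factor(0.02),
      price = jitter_factor(0.015), unmet_need = rep(1, length(areas)),
      deprivation = dep_factor(0.12), smallness = rep(1, length(areas))
    )
    core_lf <- lapply(seq_along(areas), function(i) {
      vapply(core_factors, `[[`, numeric(1), i)
    })
    names(core_lf) <- areas

    ch_factors <- list(
      mortality = dep_factor(0.10) * jitter_factor(0.01),
      market_forces = jitter_factor(0.03),
      rurality = rep(1, length(areas))
    )
    ch_lf <- lapply(seq_along(areas), function(i) {
      vapply(ch_factors, `[[`, numeric(1), i)
    })
    names(ch_lf) <- areas

    core_needs <- make_needs(CORE_WEIGHTS)
    core_scaled <- scale_needs(core_needs, CORE_WEIGHTS)
    core <- coefficient_table(
      "core_services", needs = core_scaled$needs, weights = CORE_WEIGHTS,
      local_factors = core_lf, reference_mean = core_scaled$reference_mean
    )

    adapted_weights <- CORE_WEIGHTS[ADAPTED_COMPONENTS] /
      sum(CORE_WEIGHTS[ADAPTED_COMPONENTS])
    adapted_needs <- core_needs[core_needs$component %in% ADAPTED_COMPONENTS, ]
    adapted_scaled <- scale_needs(adapted_needs, adapted_weights)
    adapted <- coefficient_table(
      "core_services_adapted", needs = adapted_scaled$needs,
      weights = adapted_weights, local_factors = core_lf,
      reference_mean = adapted_scaled$reference_mean
    )

    ch_needs <- make_needs(list(carr_hill = NULL)["carr_hill"])
    ch_scaled <- scale_needs(ch_needs, c(carr_hill = 1))
    carr_hill <- coefficient_table(
      "carr_hill",
      band_need = dplyr::select(ch_scaled$needs, "sex", "age_band", "need"),
      local_factors = ch_lf, reference_mean = ch_scaled$reference_mean,
      nursing_home_premium = 0.43
    )

    list(core_services = core, core_services_adapted = adapted,
         carr_hill = carr_hill)
  })
}

#' Generate a synthetic region with known ground truth
#'
#' Draws quarterly age-sex band counts for every practice from the
#' regional mixture (with practice-level Dirichlet heterogeneity), builds
#' coefficient tables with [generate_coefficients()], and sets each
#' practice's true annual acute spend to
#' `weighted population x base_cost_per_need_unit x multiplier x noise`,
#' where the weighting uses the generated core-services table, the
#' multiplier is 1 except for the focal practice
#' (`focal$true_spend_multiplier`), and the noise is mean-1 gamma with
#' shape proportional to list size. The focal practice receives the
#' young-adult-heavy mixture, a growing quarterly trajectory, its own
#' network, and a residence mix spread over several areas. Fully
#' reproducible from the seed.
#'
#' @param config A [region_config()].
#' @return A list with tibbles `population`, `spend`, `practices` (the
#'   ground-truth manifest, including `true_spend_multiplier`),
#'   `resident_mix`, `modifiers`, `deflator`, the `coefficients` list and
#'   the `config`.
#' @export
generate_region <- function(config) {
  if (!inherits(config, "region_config")) {
    ws_abort("config must be built with region_config()", "ws_bad_config")
  }
  withr::with_seed(config$seed, {
    bands <- canonical_bands()
    key <- paste(bands$sex, bands$age_band)
    quarters <- fy_quarter_starts(config$financial_year)
    n <- config$n_practices

    practice_id <- sprintf("P%03d", seq_len(n))
    network_id <- sprintf("N%02d", rep_len(seq_len(config$n_networks), n))
    area_id <- network_id  # one area per network
    deprivation <- sample.int(100, n, replace = TRUE)

    base_size <- stats::rlnorm(
      n, log(config$mean_list_size) - config$list_size_sdlog^2 / 2,
      config$list_size_sdlog
    )
    # practice-specific demographic mixtures (Dirichlet via gamma)
    conc <- config$mixture_concentration
    mixtures <- vapply(seq_len(n), function(i) {
      g <- stats::rgamma(length(key), shape = conc * config$regional_mixture *
                           length(key), rate = 1)
      g / sum(g)
    }, numeric(length(key)))

    draw_practice <- function(sizes, probs) {
      counts <- vapply(sizes, function(sz) {
        as.numeric(stats::rmultinom(1, sz, probs))
      }, numeric(length(key)))
      tibble::tibble(
        quarter_start = rep(quarters, each = length(key)),
        sex = rep(bands$sex, length(quarters)),
        age_band = rep(bands$age_band, length(quarters)),
        count = as.numeric(counts)
      )
    }

    pop_list <- lapply(seq_len(n), function(i) {
      drift <- cumprod(c(1, 1 + stats::rnorm(3, 0.005, 0.01)))
      sizes <- pmax(1, round(base_size[i] * drift))
      dplyr::mutate(draw_practice(sizes, mixtures[, i]),
                    practice_id = practice_id[i],
                    network_id = network_id[i], area_id = area_id[i],
                    deprivation_percentile = deprivation[i])
    })

    focal <- config$focal
    focal_network <- "N_FOCAL"
    focal_area <- "A_FOCAL"
    focal_pop <- dplyr::mutate(
      draw_practice(focal$size_quarters, focal$mixture[key]),
      practice_id = focal$id, network_id = focal_network,
      area_id = focal_area,
      deprivation_percentile = focal$deprivation_percentile
    )
    population <- dplyr::bind_rows(c(pop_list, list(focal_pop)))[
      , c("practice_id", "network_id", "area_id", "quarter_start",
          "sex", "age_band", "count", "deprivation_percentile")
    ]

    areas <- c(unique(area_id), focal_area)
    area_dep <- vapply(split(deprivation, area_id), mean, numeric(1))
    area_dep <- c(area_dep[unique(area_id)],
                  stats::setNames(as.numeric(focal$deprivation_percentile),
                                  focal_area))
    coefficients <- generate_coefficients(
      seed = config$seed + 1L, banding = bands, areas = areas,
      area_deprivation = area_dep,
      regional_mixture = config$regional_mixture
    )

    # residence mixes: reference practices live in their home area; the
    # focal practice's members are spread over several areas
    n_res <- min(focal$n_resident_areas, length(areas))
    res_areas <- c(focal_area, utils::head(setdiff(areas, focal_area),
                                           n_res - 1))
    res_w <- stats::rgamma(n_res, shape = 4, rate = 1)
    resident_mix <- dplyr::bind_rows(
      tibble::tibble(practice_id = practice_id, area_id = area_id,
                     fraction = 1),
      tibble::tibble(practice_id = focal$id, area_id = res_areas,
                     fraction = res_w / sum(res_w))
    )

    nursing_home_rate <- c(stats::rbeta(n, 2, 250), 0)

    # true spend: weighted population under the generating (core) table
    all_ids <- c(practice_id, focal$id)
    all_areas <- c(area_id, focal_area)
    multipliers <- c(rep(1, n), focal$true_spend_multiplier)
    avg <- average_region_population(population, config$financial_year)
    area_map <- tibble::tibble(practice_id = all_ids, area_id = all_areas)
    w <- weigh_region(avg$profiles, area_map, coefficients$core_services)
    w <- w[match(all_ids, w$practice_id), ]
    if (is.finite(config$spend_noise)) {
      shape <- config$spend_noise * w$registered / config$mean_list_size
      noise <- stats::rgamma(length(all_ids), shape = shape, rate = shape)
    } else {
      noise <- rep(1, length(all_ids))  # noise-free limit
    }
    spend <- tibble::tibble(
      practice_id = all_ids,
      financial_year = config$financial_year,
      total_spend = w$weighted * config$base_cost_per_need_unit *
        multipliers * noise
    )

    practices <- tibble::tibble(
      practice_id = all_ids,
      network_id = c(network_id, focal_network),
      area_id = all_areas,
      deprivation_percentile = c(deprivation,
                                 as.integer(focal$deprivation_percentile)),
      nursing_home_rate = nursing_home_rate,
      true_spend_multiplier = multipliers
    )

    modifiers <- default_rate_modifiers(bands)
    deflator <- tibble::tibble(
      financial_year = c("2018/19", "2019/20"),
      deflator = c(98.0, 100.0)
    )

    list(population = population, spend = spend, practices = practices,
         resident_mix = resident_mix, modifiers = modifiers,
         deflator = deflator, coefficients = coefficients, config = config)
  })
}

# Plausible attendance rates (per person-year) and national-reference-style
# unit costs for the expected-cost correction; modifiers default to 1
# (no prior-use difference is simulated).
default_rate_modifiers <- function(bands = canonical_bands()) {
  age_levels <- unique(bands$age_band)
  n_age <- length(age_levels)
  on_banding <- function(v) {
    stats::approx(seq_along(v), v, xout = seq(1, length(v),
                                              length.out = n_age))$y
  }
  rates <- list(
    ed         = c(0.35, 0.25, 0.25, 0.40, 0.75),
    outpatient = c(0.80, 0.90, 1.40, 2.80, 3.50),
    inpatient  = c(0.08, 0.10, 0.12, 0.30, 0.55)
  )
  unit_costs <- c(ed = 160, outpatient = 130, inpatient = 1700)
  dplyr::bind_rows(lapply(names(rates), function(cat) {
    tidyr::expand_grid(sex = c("female", "male"), age_band = age_levels) |>
      dplyr::mutate(
        category = cat,
        attendance_rate = rep(on_banding(rates[[cat]]), 2),
        unit_cost = unit_costs[[cat]],
        modifier = 1
      )
  }))
}

#' Write a generated region to a directory of delimited-text files
#'
#' Emits exactly the dialects the loaders consume: `population.csv`,
#' `spend.csv`, `practices.csv` (ground-truth manifest),
#' `resident_mix.csv`, `modifiers.csv`, `deflator.csv` and
#' `coefficients.yaml`. Same seed, same bytes.
#'
#' @param region Result of [generate_region()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_region <- function(region, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  out <- function(name) file.path(dir, name)
  write_population(region$population, out("population.csv"))
  utils::write.csv(region$spend, out("spend.csv"), row.names = FALSE,
                   quote = FALSE, fileEncoding = "UTF-8")
  utils::write.csv(region$practices, out("practices.csv"), row.names = FALSE,
                   quote = FALSE, fileEncoding = "UTF-8")
  utils::write.csv(region$resident_mix, out("resident_mix.csv"),
                   row.names = FALSE, quote = FALSE, fileEncoding = "UTF-8")
  utils::write.csv(region$modifiers, out("modifiers.csv"), row.names = FALSE,
                   quote = FALSE, fileEncoding = "UTF-8")
  utils::write.csv(region$deflator, out("deflator.csv"), row.names = FALSE,
                   quote = FALSE, fileEncoding = "UTF-8")
  write_coefficients(region$coefficients, out("coefficients.yaml"))
  invisible(dir)
}
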