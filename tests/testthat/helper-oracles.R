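# Independent oracles and toy fixtures. The oracles are deliberately
# written as plain nested loops over the raw table fields so they share no
# code path with the engines they check.

bf_average <- function(snapshots) {
  quarters <- unique(snapshots$quarter_start)
  bands <- unique(snapshots[, c("sex", "age_band")])
  out <- bands
  out$count <- NA_real_
  for (i in seq_len(nrow(bands))) {
    acc <- 0
    for (q in quarters) {
      hit <- snapshots$quarter_start == q &
        snapshots$sex == bands$sex[i] &
        snapshots$age_band == bands$age_band[i]
      acc <- acc + if (any(hit)) sum(snapshots$count[hit]) else 0
    }
    out$count[i] <- acc / length(quarters)
  }
  out
}

bf_band_need <- function(tab, sex, age_band) {
  if (tab$scheme == "carr_hill") {
    return(tab$band_need$need[tab$band_need$sex == sex &
                                tab$band_need$age_band == age_band])
  }
  need <- 0
  for (cmp in names(tab$weights)) {
    hit <- tab$needs$component == cmp & tab$needs$sex == sex &
      tab$needs$age_band == age_band
    need <- need + tab$weights[[cmp]] * tab$needs$need[hit]
  }
  need
}

bf_product_sum <- function(profile, tab) {
  total <- 0
  for (i in seq_len(nrow(profile))) {
    total <- total + profile$count[i] *
      bf_band_need(tab, profile$sex[i], profile$age_band[i])
  }
  total
}

bf_core_weight <- function(profile, tab, area_id) {
  total <- bf_product_sum(profile, tab)
  f <- tab$local_factors[[area_id]]
  for (nm in names(f)) total <- total * f[[nm]]
  total
}

bf_adapted_weight <- function(profile, tab, mix) {
  eff <- 0
  for (a in names(mix)) {
    p <- 1
    f <- tab$local_factors[[a]]
    for (nm in names(f)) p <- p * f[[nm]]
    eff <- eff + mix[[a]] * p
  }
  bf_product_sum(profile, tab) * eff
}

bf_carr_hill_weight <- function(profile, tab, area_id, nh_rate) {
  f <- tab$local_factors[[area_id]]
  bf_product_sum(profile, tab) * f[["mortality"]] * f[["market_forces"]] *
    f[["rurality"]] * (1 + tab$nursing_home_premium * nh_rate)
}

# Lower-tail standard normal probability by trapezoidal integration of the
# density, independent of pnorm().
bf_normal_lower_tail <- function(z, lower = -40, n = 400000) {
  x <- seq(lower, z, length.out = n)
  d <- exp(-x^2 / 2) / sqrt(2 * pi)
  sum((d[-1] + d[-n]) / 2) * (x[2] - x[1])
}

# --- toy coefficient tables ------------------------------------------

neutral_core_factors <- function(x = 1) {
  c(utilization = x, supply = 1, price = 1, unmet_need = 1,
    deprivation = 1, smallness = 1)
}

identity_core_table <- function(scheme = "core_services",
                                areas = "A",
                                bands = canonical_bands()) {
  needs <- dplyr::mutate(bands, component = "general_acute", need = 1)
  coefficient_table(
    scheme, needs = needs, weights = c(general_acute = 1),
    local_factors = stats::setNames(
      rep(list(neutral_core_factors()), length(areas)), areas),
    reference_mean = 1
  )
}

identity_carr_hill_table <- function(bands = canonical_bands(),
                                     premium = 0.43) {
  coefficient_table(
    "carr_hill",
    band_need = dplyr::mutate(bands, need = 1),
    local_factors = list(A = c(mortality = 1, market_forces = 1,
                               rurality = 1)),
    reference_mean = 1, nursing_home_premium = premium
  )
}

# Random small table + profile for oracle-equivalence sweeps.
random_toy <- function(scheme, n_bands = sample(2:5, 1),
                       n_areas = sample(1:3, 1), n_components = 2) {
  bands <- tibble::tibble(
    sex = sample(c("female", "male"), n_bands, replace = TRUE),
    age_band = paste0("b", seq_len(n_bands))
  )
  areas <- paste0("Z", seq_len(n_areas))
  lf <- function(nms) {
    stats::setNames(
      rep(list(NULL), length(areas)), areas) |>
      lapply(function(x) stats::setNames(stats::runif(length(nms), 0.8, 1.25),
                                         nms))
  }
  profile <- dplyr::mutate(bands, count = stats::runif(n_bands, 10, 500))
  if (scheme == "carr_hill") {
    band_need <- dplyr::mutate(bands, need = stats::runif(n_bands, 0.3, 3))
    tab <- coefficient_table(
      "carr_hill", band_need = band_need,
      local_factors = lf(c("mortality", "market_forces", "rurality")),
      reference_mean = mean(band_need$need),
      nursing_home_premium = stats::runif(1, 0, 1)
    )
  } else {
    cmps <- if (scheme == "core_services_adapted") {
      c("general_acute", "maternity")[seq_len(n_components)]
    } else {
      c("general_acute", "mental_health", "maternity", "community",
        "prescribing")[seq_len(n_components)]
    }
    w <- stats::runif(length(cmps), 0.2, 1)
    w <- stats::setNames(w / sum(w), cmps)
    needs <- dplyr::bind_rows(lapply(cmps, function(cmp) {
      dplyr::mutate(bands, component = cmp,
                    need = stats::runif(n_bands, 0.3, 3))
    }))
    combined <- vapply(seq_len(n_bands), function(i) {
      s <- 0
      for (cmp in cmps) {
        s <- s + w[[cmp]] * needs$need[needs$component == cmp &
                                         needs$age_band == bands$age_band[i] &
                                         needs$sex == bands$sex[i]]
      }
      s
    }, numeric(1))
    tab <- coefficient_table(
      scheme, needs = needs, weights = w, local_factors = lf(
        c("utilization", "supply", "price", "unmet_need", "deprivation",
          "smallness")),
      reference_mean = mean(combined)
    )
  }
  list(profile = profile, table = tab,
       areas = names(tab$local_factors))
}

# Small fast region for pipeline tests.
desk_region <- function(seed, n_practices = 60, n_networks = 8, ...) {
  generate_region(region_config(n_practices = n_practices,
                                n_networks = n_networks, seed = seed, ...))
}

run_region <- function(region, ...) {
  run_pipeline(
    region$population, region$spend, region$coefficients,
    focal_practice_id = region$config$focal$id,
    financial_year = region$config$financial_year,
    resident_mix = region$resident_mix,
    nursing_home_rates = stats::setNames(region$practices$nursing_home_rate,
                                         region$practices$practice_id),
    ...
  )
}

# Focal-practice population of Table-2 shape (counts by band) used in the
# printed-arithmetic regression.
focal_fy1920_profile <- function() {
  tibble::tibble(
    sex = rep(c("female", "male"), each = 5),
    age_band = rep(c("0-19", "20-39", "40-59", "60-79", "80+"), 2),
    count = c(987, 24040, 1881, 244, 39, 814, 27757, 4436, 361, 29)
  )
}
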