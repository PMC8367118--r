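test_that("identity tables leave the population unweighted", {
  prof <- dplyr::mutate(canonical_bands(), count = 100)
  core <- core_services_weight(prof, identity_core_table(), "A")
  expect_equal(core$weighted, core$registered)
  expect_equal(core$need_index, 1)
  ch <- carr_hill_weight(prof, identity_carr_hill_table(), "A",
                         nursing_home_rate = 0)
  expect_equal(ch$weighted, ch$registered)
})

test_that("core-services weighting matches the hand product-sum", {
  needs <- tibble::tibble(
    component = "general_acute",
    sex = "female", age_band = c("0-39", "40+"), need = c(0.5, 1.5)
  )
  tab <- coefficient_table(
    "core_services", needs = needs, weights = c(general_acute = 1),
    local_factors = list(A = neutral_core_factors(1.1)),
    reference_mean = 1
  )
  prof <- tibble::tibble(sex = "female", age_band = c("0-39", "40+"),
                         count = c(100, 300))
  w <- core_services_weight(prof, tab, "A")
  expect_equal(w$weighted, (100 * 0.5 + 300 * 1.5) * 1.1)  # 550
  expect_equal(w$need_index, 1.375)
})

test_that("carr-hill weighting composes multiplicatively", {
  band_need <- tibble::tibble(sex = "female", age_band = "0+", need = 1.2)
  tab <- coefficient_table(
    "carr_hill", band_need = band_need,
    local_factors = list(A = c(mortality = 1.05, market_forces = 1,
                               rurality = 1)),
    reference_mean = 1.2, nursing_home_premium = 0.43
  )
  prof <- tibble::tibble(sex = "female", age_band = "0+", count = 100)
  w <- carr_hill_weight(prof, tab, "A", nursing_home_rate = 0)
  expect_equal(w$weighted, 100 * 1.2 * 1.05)  # 126
  # nursing-home premium: 2% of patients at +43% each
  w2 <- carr_hill_weight(prof, tab, "A", nursing_home_rate = 0.02)
  expect_equal(w2$weighted, 126 * (1 + 0.43 * 0.02))
  expect_error(carr_hill_weight(prof, tab, "A", nursing_home_rate = -0.1),
               class = "ws_bad_rate")
})

test_that("adapted scheme: degenerate mix equals the core engine; a
           symmetric two-area mix averages the local factors", {
  toy <- withr::with_seed(21, random_toy("core_services_adapted",
                                         n_bands = 4, n_areas = 2))
  adapted <- toy$table
  # same table relabelled as the core scheme for the degenerate-mix check
  core_equiv <- coefficient_table(
    "core_services", needs = adapted$needs, weights = adapted$weights,
    local_factors = adapted$local_factors,
    reference_mean = adapted$reference_mean
  )
  a1 <- toy$areas[1]
  got <- core_services_adapted_weight(toy$profile, adapted,
                                      stats::setNames(1, a1))
  want <- core_services_weight(toy$profile, core_equiv, a1)
  expect_equal(got$weighted, want$weighted, tolerance = 1e-12)

  # two areas with factor products 0.9 and 1.1, mixed 50/50 -> 1.0
  lf <- list(A = neutral_core_factors(0.9), B = neutral_core_factors(1.1))
  needs <- tibble::tibble(component = "general_acute", sex = "female",
                          age_band = "0+", need = 1)
  tab <- coefficient_table("core_services_adapted", needs = needs,
                           weights = c(general_acute = 1),
                           local_factors = lf, reference_mean = 1)
  prof <- tibble::tibble(sex = "female", age_band = "0+", count = 200)
  w <- core_services_adapted_weight(prof, tab, c(A = 0.5, B = 0.5))
  expect_equal(w$weighted, 200)
})

test_that("engine errors name the offender and refuse silent defaults", {
  prof <- dplyr::mutate(canonical_bands(), count = 10)
  tab <- identity_core_table()
  expect_error(core_services_weight(prof, tab, "NOWHERE"),
               regexp = "NOWHERE", class = "ws_unknown_area")
  stray <- dplyr::bind_rows(
    prof, tibble::tibble(sex = "female", age_band = "100+", count = 5))
  expect_error(core_services_weight(stray, tab, "A"),
               class = "ws_unknown_band")
  atab <- identity_core_table("core_services_adapted")
  expect_error(core_services_adapted_weight(prof, atab, c(A = 0.7)),
               class = "ws_bad_residence_mix")
  expect_error(core_services_adapted_weight(prof, atab, 1),
               class = "ws_bad_residence_mix")
  expect_error(core_services_weight(prof, atab, "A"),
               class = "ws_scheme_mismatch")
})

test_that("adapted tables refuse excluded components with weight", {
  needs <- dplyr::bind_rows(
    tibble::tibble(component = "general_acute", sex = "female",
                   age_band = "0+", need = 1),
    tibble::tibble(component = "mental_health", sex = "female",
                   age_band = "0+", need = 1)
  )
  expect_error(
    coefficient_table("core_services_adapted", needs = needs,
                      weights = c(general_acute = 0.8, mental_health = 0.2),
                      local_factors = list(A = neutral_core_factors()),
                      reference_mean = 1),
    regexp = "mental_health", class = "ws_bad_coefficients"
  )
  # zero weight on an excluded component is tolerated
  expect_s3_class(
    coefficient_table("core_services_adapted", needs = needs,
                      weights = c(general_acute = 1, mental_health = 0),
                      local_factors = list(A = neutral_core_factors()),
                      reference_mean = 1),
    "coef_table"
  )
})

test_that("all schemes are degree-1 homogeneous and need-monotone", {
  withr::with_seed(31, {
    for (scheme in c("core_services", "core_services_adapted", "carr_hill")) {
      toy <- random_toy(scheme, n_bands = 4, n_areas = 2,
                        n_components = if (scheme == "core_services") 3 else 2)
      area <- toy$areas[1]
      evaluate <- function(tab, prof) {
        switch(scheme,
          core_services = core_services_weight(prof, tab, area),
          core_services_adapted = core_services_adapted_weight(
            prof, tab, stats::setNames(1, area)),
          carr_hill = carr_hill_weight(prof, tab, area, 0.01)
        )
      }
      base <- evaluate(toy$table, toy$profile)
      k <- 3.7
      scaled <- evaluate(toy$table,
                         dplyr::mutate(toy$profile, count = count * k))
      expect_equal(scaled$weighted, base$weighted * k, tolerance = 1e-12)
      expect_equal(scaled$need_index, base$need_index, tolerance = 1e-12)
      # bump one band's need multiplier: weighted must strictly increase
      tab2 <- toy$table
      if (scheme == "carr_hill") {
        tab2$band_need$need[2] <- tab2$band_need$need[2] * 1.25
        tab2$reference_mean <- mean(tab2$band_need$need)
      } else {
        tab2$needs$need[2] <- tab2$needs$need[2] * 1.25
        comb <- merge(tab2$needs,
                      data.frame(component = names(tab2$weights),
                                 weight = unname(tab2$weights)))
        comb <- stats::aggregate(
          list(need = comb$need * comb$weight),
          by = list(sex = comb$sex, age_band = comb$age_band), FUN = sum)
        tab2$reference_mean <- mean(comb$need)
      }
      expect_gt(evaluate(tab2, toy$profile)$weighted, base$weighted)
    }
  })
})

test_that("the vectorised regional engine agrees with per-practice calls", {
  reg <- desk_region(seed = 13, n_practices = 12, n_networks = 4)
  avg <- average_region_population(reg$population,
                                   reg$config$financial_year)
  nh <- stats::setNames(reg$practices$nursing_home_rate,
                        reg$practices$practice_id)
  mixes <- split(reg$resident_mix, reg$resident_mix$practice_id)
  for (scheme in names(reg$coefficients)) {
    tab <- reg$coefficients[[scheme]]
    vec <- weightedspend:::weigh_region(
      avg$profiles, reg$practices, tab,
      mixes = if (scheme == "core_services_adapted") mixes else NULL,
      nursing_home_rates = if (scheme == "carr_hill") nh else NULL
    )
    for (pid in reg$practices$practice_id) {
      prof <- avg$profiles[avg$profiles$practice_id == pid,
                           c("sex", "age_band", "count")]
      area <- reg$practices$area_id[reg$practices$practice_id == pid]
      one <- switch(scheme,
        core_services = core_services_weight(prof, tab, area, pid),
        core_services_adapted = {
          m <- mixes[[pid]]
          core_services_adapted_weight(
            prof, tab, stats::setNames(m$fraction, m$area_id), pid)
        },
        carr_hill = carr_hill_weight(prof, tab, area, nh[[pid]], pid)
      )
      expect_equal(vec$weighted[vec$practice_id == pid], one$weighted,
                   tolerance = 1e-12)
    }
  }
})

test_that("need_index is the weighted-to-registered ratio", {
  expect_equal(need_index(66, 100), 0.66)
  expect_equal(need_index(250, 250), 1)
  expect_error(need_index(10, 0), class = "ws_zero_population")
})

test_that("coefficient tables round-trip through YAML with schema checks", {
  reg <- desk_region(seed = 17, n_practices = 6, n_networks = 3)
  path <- withr::local_tempfile(fileext = ".yaml")
  write_coefficients(reg$coefficients, path)
  back <- read_coefficients(path)
  expect_setequal(names(back), names(reg$coefficients))
  prof <- dplyr::mutate(canonical_bands(), count = 50)
  a <- reg$practices$area_id[1]
  expect_equal(
    core_services_weight(prof, back$core_services, a)$weighted,
    core_services_weight(prof, reg$coefficients$core_services, a)$weighted,
    tolerance = 1e-9
  )
  # corrupt one multiplier: loader reports the path of the violation
  raw <- yaml::read_yaml(path)
  raw$core_services$local_factors[[a]]$deprivation <- -1
  yaml::write_yaml(raw, path)
  expect_error(read_coefficients(path), regexp = "local_factors",
               class = "ws_bad_coefficients")
})

test_that("normalisation ties reference_mean to a uniform population", {
  needs <- tibble::tibble(component = "general_acute", sex = "female",
                          age_band = c("0-39", "40+"), need = c(0.5, 1.5))
  expect_error(
    coefficient_table("core_services", needs = needs,
                      weights = c(general_acute = 1),
                      local_factors = list(A = neutral_core_factors()),
                      reference_mean = 1.3),
    regexp = "uniform population", class = "ws_bad_coefficients"
  )
})
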