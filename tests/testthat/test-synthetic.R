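test_that("the generator is fully reproducible from its seed", {
  r1 <- desk_region(seed = 101, n_practices = 10, n_networks = 4)
  r2 <- desk_region(seed = 101, n_practices = 10, n_networks = 4)
  expect_equal(r1$population, r2$population)
  expect_equal(r1$spend, r2$spend)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  write_region(r1, d1); write_region(r2, d2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)),
                     label = paste("bytes of", f))
  }
  # and it must not disturb the caller's RNG stream
  withr::with_seed(5, {
    before <- stats::runif(1)
  })
  withr::with_seed(5, {
    invisible(desk_region(seed = 101, n_practices = 6, n_networks = 3))
    after <- stats::runif(1)
  })
  expect_identical(before, after)
})

test_that("two seeds give different but schema-valid coefficient tables", {
  t1 <- generate_coefficients(seed = 1)
  t2 <- generate_coefficients(seed = 2)
  expect_false(isTRUE(all.equal(t1$core_services$needs$need,
                                t2$core_services$needs$need)))
  for (tabs in list(t1, t2)) {
    for (tab in tabs) {
      expect_s3_class(tab, "coef_table")  # construction itself validates
    }
  }
})

test_that("generated tables are normalised and age-monotone at the top", {
  tabs <- generate_coefficients(seed = 33)
  uniform <- dplyr::mutate(canonical_bands(), count = 1)
  neutral_area <- function(tab) {
    # neutral factors: evaluate with all local factors forced to 1
    tab$local_factors <- list(X = stats::setNames(
      rep(1, length(tab$local_factors[[1]])),
      names(tab$local_factors[[1]])))
    tab
  }
  for (nm in names(tabs)) {
    tab <- neutral_area(tabs[[nm]])
    w <- switch(nm,
      core_services = core_services_weight(uniform, tab, "X"),
      core_services_adapted = core_services_adapted_weight(
        uniform, tab, c(X = 1)),
      carr_hill = carr_hill_weight(uniform, tab, "X", 0))
    expect_equal(w$need_index, tab$reference_mean, tolerance = 1e-9,
                 label = paste("uniform need index under", nm))
  }
  # an elderly-only population carries more need than the regional mean
  cfg <- region_config(seed = 1)
  elderly <- dplyr::mutate(
    canonical_bands(),
    count = ifelse(age_band %in% c("60-79", "80+"), 500, 0))
  regional <- dplyr::mutate(canonical_bands(),
                            count = 1e5 * cfg$regional_mixture[
                              paste(sex, age_band)])
  tab <- neutral_area(tabs$core_services)
  expect_gt(core_services_weight(elderly, tab, "X")$need_index,
            core_services_weight(regional, tab, "X")$need_index)
  # the regional population-weighted index sits near its target
  expect_equal(core_services_weight(regional, tab, "X")$need_index, 0.95,
               tolerance = 0.02)
})

test_that("regional totals land near their configured expectations", {
  cfg <- region_config(n_practices = 60, n_networks = 8, seed = 55)
  reg <- generate_region(cfg)
  ref <- reg$practices[reg$practices$practice_id != "FOCAL", ]
  pop <- reg$population |>
    dplyr::group_by(practice_id) |>
    dplyr::summarise(registered = sum(count) / 4)
  total_ref <- sum(pop$registered[pop$practice_id != "FOCAL"])
  mean_size <- cfg$mean_list_size
  sd_size <- mean_size * sqrt(exp(cfg$list_size_sdlog^2) - 1)
  expect_lt(abs(total_ref - 60 * mean_size), 3 * sqrt(60) * sd_size)
  # focal practice: configured trajectory and young-adult concentration
  focal <- pop$registered[pop$practice_id == "FOCAL"]
  expect_equal(focal, mean(cfg$focal$size_quarters), tolerance = 0.01)
  focal_prof <- reg$population[reg$population$practice_id == "FOCAL", ] |>
    dplyr::group_by(sex, age_band) |>
    dplyr::summarise(count = sum(count) / 4, .groups = "drop")
  young <- sum(focal_prof$count[focal_prof$age_band %in%
                                  c("20-39", "40-59")]) /
    sum(focal_prof$count)
  expect_gt(young, 0.9)
  # every practice maps to one network; networks partition the practices
  expect_equal(anyDuplicated(reg$practices$practice_id), 0L)
  expect_equal(dplyr::n_distinct(ref$network_id), 8L)
  # ground truth: only the focal practice carries a non-unit multiplier
  expect_equal(unique(ref$true_spend_multiplier), 1)
  expect_equal(
    reg$practices$true_spend_multiplier[reg$practices$practice_id == "FOCAL"],
    cfg$focal$true_spend_multiplier)
})

test_that("invalid region configurations are refused", {
  expect_error(region_config(n_practices = 4, n_networks = 8, seed = 1),
               class = "ws_bad_config")
  expect_error(region_config(seed = 1, focal = list(size_quarters = -5)),
               class = "ws_bad_config")
  expect_error(region_config(n_practices = 10, n_networks = 5),
               class = "ws_bad_config")
  expect_error(generate_region(list()), class = "ws_bad_config")
})
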