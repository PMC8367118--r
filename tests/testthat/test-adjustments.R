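test_that("site-cohort removal reduces bands, leaves spending alone", {
  prof <- focal_fy1920_profile()
  prof$count <- prof$count + c(300, 200, 100, 50, 16, 10, 5, 3, 1, 1)
  site <- tibble::tibble(sex = c("female", "male"),
                         age_band = c("20-39", "20-39"),
                         count = c(300, 386))
  out <- remove_site_cohort(prof, site)
  expect_equal(sum(prof$count) - sum(out$count), 686)
  # bands the site does not touch are untouched
  expect_equal(out$count[out$sex == "male" & out$age_band == "40-59"],
               prof$count[prof$sex == "male" & prof$age_band == "40-59"])
  # empty cohort is the identity
  empty <- dplyr::mutate(site, count = 0)
  expect_equal(remove_site_cohort(prof, empty), prof)
  # removing then re-adding restores the profile exactly
  back <- dplyr::left_join(out, dplyr::rename(site, add = count),
                           by = c("sex", "age_band"))
  back$count <- back$count + ifelse(is.na(back$add), 0, back$add)
  expect_equal(back$count, prof$count)
  # a cohort larger than any band is refused, naming the band
  too_big <- dplyr::mutate(site, count = c(300, 1e6))
  expect_error(remove_site_cohort(prof, too_big), regexp = "male 20-39",
               class = "ws_site_exceeds")
})

test_that("reference-cohort removal applies reference cost and weighting", {
  # zero-sized cohort changes nothing
  out0 <- remove_reference_cohort(1e6, 1000, 900, 0, 500, 0.9)
  expect_equal(out0$spend, 1e6)
  expect_equal(out0$registered, 1000)
  expect_equal(out0$weighted, 900)
  # a cohort at the practice's own averages preserves cost per weighted
  spend <- 2.4e6; registered <- 4000; weighted <- 3000
  own_cost <- spend / registered; own_need <- weighted / registered
  adj <- remove_reference_cohort(spend, registered, weighted, 500,
                                 own_cost, own_need)
  expect_equal(adj$spend / adj$weighted, spend / weighted, tolerance = 1e-12)
  # inconsistent references are refused
  expect_error(remove_reference_cohort(1e4, 1000, 900, 500, 10000, 0.9),
               class = "ws_bad_cohort")
  expect_error(remove_reference_cohort(1e6, 1000, 900, 1000, 500, 0.9),
               class = "ws_bad_cohort")
})

test_that("expected-cost correction follows its defining algebra", {
  prof <- tibble::tibble(sex = "female", age_band = c("0-39", "40+"),
                         count = c(1000, 500))
  mods <- tidyr::expand_grid(sex = "female", age_band = c("0-39", "40+"),
                             category = c("ed", "outpatient"))
  mods$attendance_rate <- c(0.3, 1.0, 0.5, 2.0)
  mods$unit_cost <- ifelse(mods$category == "ed", 160, 130)
  mods$modifier <- 1
  expect_equal(expected_cost_correction(prof, mods), 0)
  # single band and category with modifier 0.88 -> factor 0.12
  one <- tibble::tibble(sex = "female", age_band = "0-39", category = "ed",
                        attendance_rate = 0.3, unit_cost = 160,
                        modifier = 0.88)
  prof1 <- prof[1, ]
  expect_equal(expected_cost_correction(prof1, one), 0.12)
  # mixed modifiers against an independent double sum
  mods$modifier <- c(0.85, 0.9, 1.1, 0.75)
  base <- 0; modded <- 0
  for (i in seq_len(nrow(mods))) {
    n <- prof$count[prof$age_band == mods$age_band[i]]
    base <- base + n * mods$attendance_rate[i] * mods$unit_cost[i]
    modded <- modded + n * mods$attendance_rate[i] * mods$modifier[i] *
      mods$unit_cost[i]
  }
  expect_equal(expected_cost_correction(prof, mods),
               (base - modded) / base, tolerance = 1e-12)
  # invariant to uniform scaling of unit costs and of the population
  scaled_costs <- dplyr::mutate(mods, unit_cost = unit_cost * 7)
  expect_equal(expected_cost_correction(prof, scaled_costs),
               expected_cost_correction(prof, mods), tolerance = 1e-12)
  expect_equal(
    expected_cost_correction(dplyr::mutate(prof, count = count * 11), mods),
    expected_cost_correction(prof, mods), tolerance = 1e-12)
  # degenerate: no expected cost at all
  zero <- dplyr::mutate(mods, attendance_rate = 0)
  expect_error(expected_cost_correction(prof, zero),
               class = "ws_bad_modifiers")
})

test_that("GDP-deflator inflation is proportional and composes", {
  defl <- tibble::tibble(financial_year = c("2017/18", "2018/19", "2019/20"),
                         deflator = c(95.1, 100, 102))
  expect_equal(apply_inflation(500, defl, "2018/19", "2018/19"), 500)
  expect_equal(apply_inflation(500, defl, "2018/19", "2019/20"), 510)
  chained <- apply_inflation(
    apply_inflation(837.5, defl, "2017/18", "2018/19"),
    defl, "2018/19", "2019/20")
  direct <- apply_inflation(837.5, defl, "2017/18", "2019/20")
  expect_equal(chained, direct, tolerance = 1e-12)
  expect_error(apply_inflation(500, defl, "2016/17", "2019/20"),
               regexp = "2016/17", class = "ws_missing_deflator")
})

test_that("supporting tables load from delimited text", {
  mods <- weightedspend:::default_rate_modifiers()
  p1 <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(mods, p1, row.names = FALSE)
  expect_equal(as.data.frame(read_rate_modifiers(p1)), as.data.frame(mods))
  p2 <- withr::local_tempfile(lines = "financial_year,deflator\n2019/20,100",
                              fileext = ".csv")
  expect_equal(read_deflator(p2)$deflator, 100)
  p3 <- withr::local_tempfile(lines = "a,b\n1,2", fileext = ".csv")
  expect_error(read_rate_modifiers(p3), class = "ws_bad_file")
  expect_error(read_deflator(p3), class = "ws_bad_file")
})
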