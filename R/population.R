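#' Age-sex band utilities
#'
#' Practice populations are held in long form as *profiles*: one row per
#' age-sex band with columns `sex` (`"female"`/`"male"`), `age_band`
#' (`"0-19"`, `"20-39"`, ..., `"80+"`) and `count` (persons, possibly
#' fractional after quarterly averaging). The canonical banding uses five
#' 20-year bands per sex, but any disjoint banding covering ages 0 upwards
#' is accepted by every engine.
#'
#' @return `canonical_bands()` returns a 10-row tibble with columns `sex`
#'   and `age_band`.
#' @export
canonical_bands <- function() {
  tidyr::expand_grid(
    sex = c("female", "male"),
    age_band = c("0-19", "20-39", "40-59", "60-79", "80+")
  )
}

# Parse "20-39" / "80+" into lower/upper bounds (upper = Inf when open).
parse_age_band <- function(age_band) {
  open <- grepl("^\\d+\\+$", age_band)
  closed <- grepl("^\\d+-\\d+$", age_band)
  if (!all(open | closed)) {
    ws_abort(
      paste0("Unparseable age band(s): ",
             paste(unique(age_band[!(open | closed)]), collapse = ", ")),
      "ws_bad_band"
    )
  }
  lower <- as.integer(sub("[-+].*$|\\+$", "", age_band))
  upper <- rep(Inf, length(age_band))
  upper[closed] <- as.numeric(sub("^\\d+-", "", age_band[closed]))
  tibble::tibble(age_band = age_band, lower = lower, upper = upper)
}

# A banding (character vector of age_band labels) must be disjoint and
# cover ages 0 to open-ended with no gaps.
validate_banding <- function(age_bands) {
  b <- parse_age_band(unique(age_bands))
  b <- b[order(b$lower), ]
  if (b$lower[1] != 0) {
    ws_abort("Banding does not start at age 0", "ws_bad_band")
  }
  if (!is.infinite(b$upper[nrow(b)])) {
    ws_abort("Banding is not open-ended at the top", "ws_bad_band")
  }
  if (nrow(b) > 1) {
    gaps <- b$lower[-1] != b$upper[-nrow(b)] + 1
    if (any(gaps)) {
      ws_abort(
        paste0("Banding has a gap or overlap after band ",
               b$age_band[-nrow(b)][gaps][1]),
        "ws_bad_band"
      )
    }
  }
  invisible(b$age_band)
}

validate_profile <- function(profile, arg = "profile") {
  required <- c("sex", "age_band", "count")
  missing <- setdiff(required, names(profile))
  if (length(missing) > 0) {
    ws_abort(
      paste0(arg, " lacks column(s): ", paste(missing, collapse = ", ")),
      "ws_bad_profile"
    )
  }
  if (any(profile$count < 0)) {
    ws_abort(paste0(arg, " has negative band counts"), "ws_bad_profile")
  }
  if (anyDuplicated(paste(profile$sex, profile$age_band))) {
    ws_abort(paste0(arg, " has duplicated age-sex bands"), "ws_bad_profile")
  }
  invisible(profile)
}

#' Average the registered population over quarterly snapshots
#'
#' Registered populations change within a financial year, so the analysis
#' uses the arithmetic mean of the population at the start of each quarter.
#' The mean is taken band by band; a band absent from a snapshot counts as
#' zero in that snapshot. Fractional persons are retained.
#'
#' @param snapshots A long tibble with columns `quarter_start`, `sex`,
#'   `age_band`, `count`: one or more quarterly snapshots of one practice.
#' @return A profile tibble (`sex`, `age_band`, `count`) of per-band means;
#'   the profile total is the sum of per-band means.
#' @export
#' @examples
#' snaps <- tidyr::expand_grid(
#'   quarter_start = as.Date(c("2019-04-01", "2019-07-01")),
#'   sex = "female", age_band = c("0-19", "20-39")
#' )
#' snaps$count <- c(100, 200, 120, 240)
#' average_registered_population(snaps)
average_registered_population <- function(snapshots) {
  if (is.null(snapshots) || nrow(snapshots) == 0) {
    ws_abort("No quarterly snapshots: population data missing", "ws_no_snapshots")
  }
  if (any(snapshots$count < 0)) {
    ws_abort("snapshots have negative band counts", "ws_bad_profile")
  }
  if (anyDuplicated(paste(snapshots$quarter_start, snapshots$sex,
                          snapshots$age_band))) {
    ws_abort("snapshots have duplicated age-sex bands within a quarter",
             "ws_bad_profile")
  }
  n_quarters <- dplyr::n_distinct(snapshots$quarter_start)
  snapshots |>
    dplyr::group_by(.data$sex, .data$age_band) |>
    dplyr::summarise(count = sum(.data$count) / n_quarters, .groups = "drop") |>
    dplyr::arrange(.data$sex, .data$age_band)
}

#' Share of an averaged population in one band
#'
#' @param profile A profile tibble (`sex`, `age_band`, `count`).
#' @param sex,age_band The band to report.
#' @return Percentage of the profile total in that band (0 when the band is
#'   absent). Errors if the profile total is zero.
#' @seealso [band_shares()] for all bands at once.
#' @export
band_share <- function(profile, sex, age_band) {
  total <- sum(profile$count)
  if (total <= 0) {
    ws_abort("Profile total is zero; shares undefined", "ws_zero_population")
  }
  hit <- profile$sex == sex & profile$age_band == age_band
  100 * sum(profile$count[hit]) / total
}

#' @rdname band_share
#' @return `band_shares()` returns the profile with an added `share`
#'   column (percent); shares sum to 100.
#' @export
band_shares <- function(profile) {
  total <- sum(profile$count)
  if (total <= 0) {
    ws_abort("Profile total is zero; shares undefined", "ws_zero_population")
  }
  dplyr::mutate(profile, share = 100 * .data$count / total)
}

#' Average every practice's population for one financial year
#'
#' Applies [average_registered_population()] per practice to a regional
#' population table, keeping practice attributes. Practices with fewer than
#' four snapshots (opened or closed mid-year) are averaged over the
#' snapshots they have, and flagged.
#'
#' @param population Long tibble as read by [read_population()].
#' @param financial_year Label like `"2019/20"`. Snapshots dated outside
#'   this financial year are an error, not silently dropped.
#' @return A list with `profiles` (tibble: `practice_id`, `sex`,
#'   `age_band`, `count`) and `practices` (tibble: `practice_id`,
#'   `network_id`, `area_id`, `deprivation_percentile`, `registered`,
#'   `n_quarters`, `partial_year`).
#' @export
average_region_population <- function(population, financial_year) {
  population$quarter_start <- as.Date(population$quarter_start)
  fy_of_rows <- financial_year_of(population$quarter_start)
  if (any(fy_of_rows != financial_year)) {
    bad <- unique(population$quarter_start[fy_of_rows != financial_year])
    ws_abort(
      paste0("Snapshots dated outside financial year ", financial_year, ": ",
             paste(format(bad), collapse = ", ")),
      "ws_snapshot_outside_year"
    )
  }
  if (any(population$count < 0)) {
    ws_abort("snapshots have negative band counts", "ws_bad_profile")
  }
  if (anyDuplicated(paste(population$practice_id, population$quarter_start,
                          population$sex, population$age_band))) {
    ws_abort("snapshots have duplicated age-sex bands within a quarter",
             "ws_bad_profile")
  }
  nq <- population |>
    dplyr::group_by(.data$practice_id) |>
    dplyr::summarise(.n_quarters = dplyr::n_distinct(.data$quarter_start),
                     .groups = "drop")
  profiles <- population |>
    dplyr::group_by(.data$practice_id, .data$sex, .data$age_band) |>
    dplyr::summarise(count = sum(.data$count), .groups = "drop") |>
    dplyr::left_join(nq, by = "practice_id") |>
    dplyr::mutate(count = .data$count / .data$.n_quarters) |>
    dplyr::select(-".n_quarters") |>
    dplyr::arrange(.data$practice_id, .data$sex, .data$age_band)
  practices <- population |>
    dplyr::group_by(.data$practice_id) |>
    dplyr::summarise(
      network_id = .data$network_id[1],
      area_id = .data$area_id[1],
      deprivation_percentile = .data$deprivation_percentile[1],
      n_quarters = dplyr::n_distinct(.data$quarter_start),
      .groups = "drop"
    ) |>
    dplyr::mutate(partial_year = .data$n_quarters < 4L)
  totals <- profiles |>
    dplyr::group_by(.data$practice_id) |>
    dplyr::summarise(registered = sum(.data$count), .groups = "drop")
  practices <- dplyr::left_join(practices, totals, by = "practice_id")
  list(profiles = profiles, practices = practices)
}

#' Read and write regional population extracts
#'
#' One row per practice x quarter x age-sex band, comma-delimited with a
#' header, UTF-8. Columns: `practice_id`, `network_id`, `area_id`,
#' `quarter_start` (ISO 8601), `sex`, `age_band`, `count`,
#' `deprivation_percentile` (1--100, 1 most deprived; may be `NA`).
#'
#' @param path File path.
#' @return `read_population()` returns the table as a tibble.
#' @export
read_population <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("practice_id", "network_id", "area_id", "quarter_start",
                "sex", "age_band", "count", "deprivation_percentile")
  missing <- setdiff(required, names(df))
  if (length(missing) > 0) {
    ws_abort(
      paste0("Population file ", path, " lacks column(s): ",
             paste(missing, collapse = ", ")),
      "ws_bad_file"
    )
  }
  df$quarter_start <- as.Date(df$quarter_start)
  tibble::as_tibble(df)
}

#' @rdname read_population
#' @param population Tibble in the same layout.
#' @export
write_population <- function(population, path) {
  utils::write.csv(population, path, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}
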