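# Internal helpers shared across modules.

ws_abort <- function(message, class) {
  rlang::abort(message, class = c(class, "weightedspend_error"))
}

#' Round half away from zero
#'
#' Decimal rounding with ties going away from zero (half-up for positive
#' values), the convention used for all formatted percentages and currency
#' in this package. `base::round()` rounds half to even, which does not
#' reproduce conventionally formatted tables.
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places (default 0).
#' @return Numeric vector rounded to `digits` places.
#' @export
#' @examples
#' round_half_up(0.5)    # 1, where round(0.5) gives 0
#' round_half_up(2.345, 2)
round_half_up <- function(x, digits = 0) {
  scale <- 10^digits
  sign(x) * floor(abs(x) * scale + 0.5) / scale
}

#' @keywords internal
fmt_millions <- function(x, sigfig = 3) {
  signif(x / 1e6, sigfig)
}

# Financial year labels: "2019/20" means 1 April 2019 -- 31 March 2020.
fy_label <- function(start_year) {
  sprintf("%d/%02d", start_year, (start_year + 1) %% 100)
}

fy_start_year <- function(fy) {
  if (!all(grepl("^\\d{4}/\\d{2}$", fy))) {
    ws_abort(
      paste0("Malformed financial year label(s): ",
             paste(fy[!grepl("^\\d{4}/\\d{2}$", fy)], collapse = ", "),
             " (expected e.g. \"2019/20\")"),
      "ws_bad_fy"
    )
  }
  as.integer(substr(fy, 1, 4))
}

#' Financial year of a date
#'
#' NHS financial years run 1 April to 31 March; a date in January 2020
#' belongs to financial year `"2019/20"`.
#'
#' @param date A `Date` vector (or something coercible by `as.Date()`).
#' @return Character vector of labels like `"2019/20"`.
#' @export
financial_year_of <- function(date) {
  date <- as.Date(date)
  y <- as.integer(format(date, "%Y"))
  m <- as.integer(format(date, "%m"))
  fy_label(ifelse(m >= 4, y, y - 1L))
}

# Canonical quarter-start dates (April, July, October, January) for one FY.
fy_quarter_starts <- function(fy) {
  y <- fy_start_year(fy)
  as.Date(c(
    sprintf("%d-04-01", y), sprintf("%d-07-01", y),
    sprintf("%d-10-01", y), sprintf("%d-01-01", y + 1)
  ))
}
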