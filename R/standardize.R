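# Cost standardization: published costs arrive in many currency / price-year
# combinations; all downstream arithmetic is in the reference currency-year
# (2023 US dollars).  Conversion factors (purchasing-power-parity based) are
# user-supplied inputs, never fetched.

#' Build a currency conversion table
#'
#' Maps `(currency, price_year)` pairs to a positive multiplier taking an
#' amount in that currency and price year to 2023 US dollars.  Factors are
#' inputs (typically PPP-based); the package never retrieves them.
#'
#' @param currency Character vector of currency codes (e.g. `"GBP"`).
#' @param price_year Integer vector of price years, in `[1990, 2030]`.
#' @param multiplier Positive numeric vector of factors to 2023 USD.
#' @return A data frame of class `"fh_conversion_table"`.
#' @export
conversion_table <- function(currency, price_year, multiplier) {
  n <- length(currency)
  if (length(price_year) != n || length(multiplier) != n)
    stop("currency, price_year and multiplier must have equal length")
  price_year <- as.integer(price_year)
  if (any(price_year < 1990L | price_year > 2030L))
    stop("price_year must lie within [1990, 2030]")
  if (any(!is.finite(multiplier) | multiplier <= 0))
    stop("all multipliers must be positive")
  key <- paste(currency, price_year)
  if (anyDuplicated(key))
    stop("duplicate (currency, price_year) entry: ", key[duplicated(key)][1])
  out <- data.frame(currency = as.character(currency),
                    price_year = price_year,
                    multiplier = as.numeric(multiplier),
                    stringsAsFactors = FALSE)
  class(out) <- c("fh_conversion_table", "data.frame")
  out
}

#' Read a conversion table from CSV
#'
#' Expects columns `currency, price_year, multiplier_to_usd2023`.
#'
#' @param path Path to the CSV file.
#' @return An `"fh_conversion_table"`; see [conversion_table()].
#' @export
load_conversion_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("currency", "price_year", "multiplier_to_usd2023")
  missing <- setdiff(need, names(raw))
  if (length(missing))
    stop("missing mandatory column(s): ", paste(missing, collapse = ", "))
  conversion_table(raw$currency, raw$price_year, raw$multiplier_to_usd2023)
}

#' Convert a monetary amount to the reference currency-year
#'
#' Multiplies `value` by the table factor for its `(currency, price_year)`.
#' Conversion is linear and sign-preserving, so cost savings (negative
#' incremental costs) stay negative.
#'
#' @param value Amount(s) in the source currency and price year.
#' @param currency Currency code.
#' @param price_year Price year of `value`.
#' @param table An `"fh_conversion_table"`.
#' @return `value` expressed in 2023 US dollars.
#' @export
convert_to_reference <- function(value, currency, price_year, table) {
  stopifnot(inherits(table, "fh_conversion_table"))
  idx <- which(table$currency == currency &
                 table$price_year == as.integer(price_year))
  if (length(idx) == 0L)
    stop("no conversion entry for (", currency, ", ", price_year, ")")
  value * table$multiplier[idx]
}

#' Default uncertainty interval for a point value
#'
#' Published summary costs and effects rarely come with uncertainty
#' bounds; when a source study reports none, the synthesis assigns an
#' interval of +/- 50% of the reported value.  For negative values the
#' endpoints are swapped so the interval is always ordered, and it always
#' contains the input.
#'
#' @param value Point value (any sign).
#' @return An [interval()]: `(0.5 * value, 1.5 * value)`, ordered.
#' @export
default_interval <- function(value) {
  stopifnot(is.numeric(value), length(value) == 1L, is.finite(value))
  interval(min(0.5 * value, 1.5 * value), max(0.5 * value, 1.5 * value))
}
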