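# Unit-cost normalization: heterogeneous published cost expressions
# (rupees per feeding day, dollars per counselling visit, per household,
# per treated case, per pregnancy) are reduced to a single comparable
# basis, US$ per beneficiary per year.

#' Currency and inflation context
#'
#' Conversion conventions applied when normalizing unit costs. The INR/USD
#' rate defaults to 62.0, calibrated so that the ICDS ration norm of
#' Rs 6/day over 300 feeding days annualizes to $29.03 exactly, matching
#' the published programme-norm rate. No inflation index is applied by
#' default (`inflation_factor = 1`).
#'
#' @param inr_per_usd positive exchange rate, Indian rupees per US dollar.
#' @param inflation_factor positive multiplicative inflation adjustment.
#' @return An object of class `currency_context`.
#' @export
#' @examples
#' ctx <- currency_context()
#' to_usd(6, "INR", ctx)   # ~0.097
currency_context <- function(inr_per_usd = 62.0, inflation_factor = 1.0) {
  nc_check(is_scalar_number(inr_per_usd) && inr_per_usd > 0,
           "inr_per_usd must be a positive number")
  nc_check(is_scalar_number(inflation_factor) && inflation_factor > 0,
           "inflation_factor must be a positive number")
  structure(list(inr_per_usd = inr_per_usd, inflation_factor = inflation_factor),
            class = "currency_context")
}

#' Convert an amount to US dollars
#'
#' @param amount non-negative monetary amount.
#' @param currency `"USD"` or `"INR"`.
#' @param ctx a [currency_context()].
#' @return The amount in USD (full precision, unrounded).
#' @export
to_usd <- function(amount, currency, ctx = currency_context()) {
  nc_check(is.numeric(amount) && all(amount >= 0), "amount must be non-negative")
  stopifnot(inherits(ctx, "currency_context"))
  switch(as.character(currency),
    USD = amount,
    INR = amount / ctx$inr_per_usd,
    nc_stop(sprintf("unknown currency '%s' (expected USD or INR)", currency),
            "nutricost_config_error")
  )
}

#' Multiplicative inflation adjustment
#'
#' @param amount non-negative monetary amount.
#' @param ctx a [currency_context()].
#' @return `amount * ctx$inflation_factor`.
#' @export
inflation_adjust <- function(amount, ctx = currency_context()) {
  nc_check(is.numeric(amount) && all(amount >= 0), "amount must be non-negative")
  amount * ctx$inflation_factor
}

uc_bases <- c("per_beneficiary_year", "per_day", "per_visit",
              "per_household_year", "per_case", "per_pregnancy")

#' Construct a unit cost
#'
#' A unit cost is an amount, a currency and a basis, plus the convention
#' field the basis needs: `days_per_year` for `per_day` (e.g. 300 feeding
#' days for a full-year ration, 150 for a six-month entitlement, 90 for a
#' three-month therapeutic ration), `visits_per_year` for `per_visit`,
#' `children_per_household` for `per_household_year`. Bases
#' `per_beneficiary_year`, `per_case` and `per_pregnancy` are already
#' annual per-beneficiary quantities.
#'
#' @param amount non-negative monetary amount in `currency`.
#' @param currency `"USD"` or `"INR"`.
#' @param basis one of `per_beneficiary_year`, `per_day`, `per_visit`,
#'   `per_household_year`, `per_case`, `per_pregnancy`.
#' @param days_per_year feeding/supplementation days per year (basis `per_day`).
#' @param visits_per_year contact visits per beneficiary-year (basis `per_visit`).
#' @param children_per_household average under-five children per targeted
#'   household (basis `per_household_year`).
#' @param source free-text provenance note.
#' @return An object of class `unit_cost`.
#' @export
#' @examples
#' # Rs 6 per feeding day, 300 days/year -> $29.03 per child-year
#' uc <- unit_cost(6, "INR", "per_day", days_per_year = 300)
#' annualize(uc)
unit_cost <- function(amount, currency = c("USD", "INR"), basis = uc_bases,
                      days_per_year = NULL, visits_per_year = NULL,
                      children_per_household = NULL, source = "") {
  currency <- match.arg(currency)
  basis <- match.arg(basis)
  nc_check(is_scalar_number(amount) && amount >= 0,
           "unit cost amount must be a single non-negative number")
  need <- switch(basis,
    per_day = "days_per_year",
    per_visit = "visits_per_year",
    per_household_year = "children_per_household",
    NULL)
  conv <- list(days_per_year = days_per_year, visits_per_year = visits_per_year,
               children_per_household = children_per_household)
  given <- names(conv)[!vapply(conv, is.null, logical(1))]
  if (!is.null(need)) {
    nc_check(identical(given, need),
             sprintf("basis '%s' requires exactly the convention field '%s'", basis, need),
             "nutricost_config_error")
    nc_check(is_scalar_number(conv[[need]]) && conv[[need]] > 0,
             sprintf("%s must be a positive number", need),
             "nutricost_config_error")
  } else {
    nc_check(length(given) == 0L,
             sprintf("basis '%s' takes no convention fields (got: %s)",
                     basis, paste(given, collapse = ", ")),
             "nutricost_config_error")
  }
  structure(list(amount = amount, currency = currency, basis = basis,
                 days_per_year = days_per_year, visits_per_year = visits_per_year,
                 children_per_household = children_per_household, source = source),
            class = "unit_cost")
}

#' Annualize a unit cost to US$ per beneficiary-year
#'
#' Applies the basis convention (days x rate, visits x rate, household rate
#' divided among resident under-fives), converts to USD and applies the
#' inflation factor, all at full precision, then rounds the final annual
#' rate to the cent (half-up). The cent-rounded rate is the published form
#' of a per-beneficiary-year unit cost and is the rate used in cost
#' products, so that printed unit costs and printed cost lines remain
#' mutually consistent; set `reported = FALSE` to obtain the unrounded
#' value.
#'
#' @param uc a [unit_cost()].
#' @param ctx a [currency_context()].
#' @param reported if `TRUE` (default) round the final rate to the cent.
#' @return US$ per beneficiary per year.
#' @export
#' @examples
#' annualize(unit_cost(0.43, "USD", "per_visit", visits_per_year = 4.1)) # 1.76
#' annualize(unit_cost(15, "USD", "per_household_year",
#'                     children_per_household = 2))                      # 7.50
annualize <- function(uc, ctx = currency_context(), reported = TRUE) {
  stopifnot(inherits(uc, "unit_cost"))
  annual <- switch(uc$basis,
    per_day = uc$amount * uc$days_per_year,
    per_visit = uc$amount * uc$visits_per_year,
    per_household_year = uc$amount / uc$children_per_household,
    uc$amount  # per_beneficiary_year, per_case, per_pregnancy
  )
  annual <- inflation_adjust(to_usd(annual, uc$currency, ctx), ctx)
  if (reported) round_half_up(annual, 2) else annual
}

#' @export
print.unit_cost <- function(x, ...) {
  conv <- switch(x$basis,
    per_day = sprintf(" x %g days/yr", x$days_per_year),
    per_visit = sprintf(" x %g visits/yr", x$visits_per_year),
    per_household_year = sprintf(" / %g children per household", x$children_per_household),
    "")
  cat(sprintf("<unit_cost> %s %.4g %s%s  (annual: US$%.2f per beneficiary-year)\n",
              x$currency, x$amount, gsub("_", " ", x$basis), conv, annualize(x)))
  invisible(x)
}

#' @export
print.currency_context <- function(x, ...) {
  cat(sprintf("<currency_context> %.4g INR/USD, inflation factor %.4g\n",
              x$inr_per_usd, x$inflation_factor))
  invisible(x)
}
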