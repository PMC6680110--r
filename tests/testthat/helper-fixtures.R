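# Small in-code fixtures shared across test files.

toy_bands <- function(total = 1000, n_bands = 4) {
  lo <- seq(0, 100 - 100 / n_bands, length.out = n_bands)
  hi <- lo + 100 / n_bands
  per <- total / n_bands
  data.frame(lo = lo, hi = hi, m = rep(per / 2, n_bands), f = rep(per / 2, n_bands))
}

toy_region <- function(region_id = "toy", total = 1e6, cbr = 20, growth = 0.01,
                       whz3 = 0.05, whz2 = 0.15, waz3 = 0.08, govt = 0.02,
                       endemic = FALSE, base_year = 2011) {
  region_demographics(region_id, base_year, toy_bands(total),
                      crude_birth_rate = cbr, growth_rate = growth,
                      prev_whz_lt_m3 = whz3, prev_whz_lt_m2 = whz2,
                      prev_waz_lt_m3 = waz3, frac_women_govt = govt,
                      malaria_endemic = endemic)
}

toy_scenario <- function() {
  scenario("toy package", list(
    intervention("vita", "Vitamin A", "micronutrient_deworming",
                 target_rule("children_6_59m"),
                 unit_cost(0.07, "USD", "per_beneficiary_year")),
    intervention("cf", "Complementary food", "supplementation",
                 target_rule("children_6_23m",
                             prevalence_filter = list(indicator = "whz_lt_m2",
                                                      multiplier = 2)),
                 unit_cost(51.10, "USD", "per_beneficiary_year")),
    intervention("mnp", "Micronutrient powders", "micronutrient_deworming",
                 target_rule("children_6_23m", subtract_rule = "cf"),
                 unit_cost(3.60, "USD", "per_beneficiary_year")),
    intervention("itn", "Bed nets", "health",
                 target_rule("pregnant_women", endemic_only = TRUE),
                 unit_cost(4.84, "USD", "per_beneficiary_year"))
  ))
}

# Loaded once per test run; every target back-derived from published costs.
india_fix <- local({
  fix <- NULL
  function() {
    if (is.null(fix)) fix <<- india_2014_fixture()
    fix
  }
})

fixture_report <- function(scn = c("india_plus", "sun")) {
  scn <- match.arg(scn)
  fix <- india_fix()
  cost_scenario(fix$scenarios[[scn]], target_overrides = fix$targets[[scn]],
                region_id = "India")
}
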