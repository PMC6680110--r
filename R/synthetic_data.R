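# Synthetic census-style inputs and the packaged India 2014 fixture.
#
# The generator emulates the statistical structure of the model's inputs
# (aggregated age/sex strata, vital rates, anthropometric prevalences,
# employment share, endemicity flags) so every pipeline stage is testable
# without any external download. The India 2014 fixture back-derives the
# national target populations from published intervention costs and unit
# costs, and carries the published state-level category cost anchors.

#' Parameters for the synthetic region generator
#'
#' Defaults emulate Indian state-level inputs: state populations from a
#' few hundred thousand to two hundred million, crude birth rates 15-30
#' per 1000, growth 0.5-2.5%/yr, wasting prevalence 10-25% with severe
#' wasting 2-8%, severe underweight 5-20%, 0.1-5% of women in government
#' employment, and roughly a third of states malaria-endemic (12 of 35).
#'
#' @param seed integer RNG seed.
#' @param n_regions number of regions to generate.
#' @param population_range length-2 range of total persons per region.
#' @param cbr_range crude-birth-rate range (births/1000/yr).
#' @param growth_range annual growth-fraction range.
#' @param prevalence_ranges named list of length-2 ranges for
#'   `whz_lt_m2`, `whz_lt_m3`, `waz_lt_m3`.
#' @param frac_govt_range range for the female government-employment share.
#' @param endemic_probability probability a region is malaria-endemic.
#' @return An object of class `generator_params`.
#' @export
generator_params <- function(seed = 1L, n_regions = 10L,
                             population_range = c(5e5, 2e8),
                             cbr_range = c(15, 30),
                             growth_range = c(0.005, 0.025),
                             prevalence_ranges = list(whz_lt_m2 = c(0.10, 0.25),
                                                      whz_lt_m3 = c(0.02, 0.08),
                                                      waz_lt_m3 = c(0.05, 0.20)),
                             frac_govt_range = c(0.001, 0.05),
                             endemic_probability = 12 / 35) {
  nc_check(is_scalar_number(seed), "seed must be a number")
  nc_check(is_scalar_number(n_regions) && n_regions >= 0 && n_regions == floor(n_regions),
           "n_regions must be a non-negative integer")
  ranges <- c(list(population = population_range, cbr = cbr_range,
                   growth = growth_range, frac_govt = frac_govt_range),
              prevalence_ranges)
  for (nm in names(ranges)) {
    r <- ranges[[nm]]
    nc_check(is.numeric(r) && length(r) == 2L && r[1] <= r[2],
             sprintf("%s range must be a well-ordered length-2 numeric", nm),
             "nutricost_validation_error")
  }
  nc_check(all(c("whz_lt_m2", "whz_lt_m3", "waz_lt_m3") %in% names(prevalence_ranges)),
           "prevalence_ranges must name whz_lt_m2, whz_lt_m3, waz_lt_m3",
           "nutricost_validation_error")
  for (nm in names(prevalence_ranges)) {
    r <- prevalence_ranges[[nm]]
    nc_check(r[1] >= 0 && r[2] <= 1, sprintf("%s range must lie in [0,1]", nm),
             "nutricost_validation_error")
  }
  nc_check(is_fraction(endemic_probability), "endemic_probability must be in [0,1]",
           "nutricost_validation_error")
  nc_check(population_range[1] >= 0 && cbr_range[1] >= 0 && growth_range[1] > -1 &&
             frac_govt_range[1] >= 0 && frac_govt_range[2] <= 1,
           "degenerate parameter ranges", "nutricost_validation_error")
  structure(list(seed = as.integer(seed), n_regions = as.integer(n_regions),
                 population_range = population_range, cbr_range = cbr_range,
                 growth_range = growth_range, prevalence_ranges = prevalence_ranges,
                 frac_govt_range = frac_govt_range,
                 endemic_probability = endemic_probability),
            class = "generator_params")
}

# Census-shaped age pyramid: geometrically thinning 5-year bands over
# [0, 100), male share 51.2% (young-population sex ratio).
synthetic_band_table <- function(total_pop, decay = 0.9, male_share = 0.512) {
  k <- 0:19
  w <- decay^k / sum(decay^k)
  band_pop <- total_pop * w
  data.frame(lo = 5 * k, hi = 5 * (k + 1),
             m = band_pop * male_share, f = band_pop * (1 - male_share))
}

#' Generate synthetic region demographics
#'
#' Deterministic under the seed carried in `params`. Rates and prevalences
#' are drawn uniformly within their ranges; severe wasting is redrawn
#' (rejection) until it does not exceed wasting; the age-band table is a
#' census-shaped pyramid summing to the drawn total population.
#'
#' @param params a [generator_params()].
#' @param base_year base calendar year stamped on each record (default 2011).
#' @return A named list of `params$n_regions` [region_demographics()].
#' @export
#' @examples
#' regs <- generate_regions(generator_params(seed = 1, n_regions = 3))
#' names(regs)
generate_regions <- function(params, base_year = 2011) {
  stopifnot(inherits(params, "generator_params"))
  if (params$n_regions == 0L) return(list())
  set.seed(params$seed)
  runif_in <- function(r) stats::runif(1, r[1], r[2])
  regions <- lapply(seq_len(params$n_regions), function(i) {
    total <- runif_in(params$population_range)
    m2 <- runif_in(params$prevalence_ranges$whz_lt_m2)
    repeat {
      m3 <- runif_in(params$prevalence_ranges$whz_lt_m3)
      if (m3 <= m2) break
    }
    region_demographics(
      region_id = sprintf("region_%02d", i), base_year = base_year,
      population_by_band = synthetic_band_table(total),
      crude_birth_rate = runif_in(params$cbr_range),
      growth_rate = runif_in(params$growth_range),
      prev_whz_lt_m3 = m3, prev_whz_lt_m2 = m2,
      prev_waz_lt_m3 = runif_in(params$prevalence_ranges$waz_lt_m3),
      frac_women_govt = runif_in(params$frac_govt_range),
      malaria_endemic = stats::runif(1) < params$endemic_probability
    )
  })
  names(regions) <- vapply(regions, `[[`, "", "region_id")
  regions
}

#' Back-derive target populations from published costs
#'
#' Inverts the costing product: `TP = cost x 1e6 / annual unit cost`.
#' Re-running the forward engine on the result reproduces the published
#' costs exactly (up to floating point), which is the round-trip identity
#' the packaged fixture rests on.
#'
#' @param printed_costs named numeric vector, intervention -> US$ million/yr.
#' @param unit_costs named numeric vector, intervention -> US$ per
#'   beneficiary-year (must cover the names in `printed_costs` and be
#'   positive).
#' @return Named numeric vector, intervention -> persons.
#' @export
#' @examples
#' back_derive_target_populations(c(ifa = 56.37), c(ifa = 2.00))  # 28.185e6
back_derive_target_populations <- function(printed_costs, unit_costs) {
  nc_check(is.numeric(printed_costs) && !is.null(names(printed_costs)) &&
             all(printed_costs >= 0), "printed_costs must be named and non-negative")
  missing <- setdiff(names(printed_costs), names(unit_costs))
  nc_check(length(missing) == 0L,
           sprintf("no unit cost for: %s", paste(missing, collapse = ", ")),
           "nutricost_config_error")
  uc <- unit_costs[names(printed_costs)]
  nc_check(all(uc > 0), "unit costs must be positive to back-derive targets")
  printed_costs * 1e6 / uc
}

fixture_path <- function(file) {
  p <- system.file("extdata", file, package = "nutricost")
  nc_check(nzchar(p), sprintf("packaged fixture file missing: %s", file),
           "nutricost_validation_error")
  p
}

#' The packaged India 2014 fixture
#'
#' Loads the packaged national demographic record (2011 census base
#' projected to 2014), both scenario configurations, the published
#' per-intervention cost anchors, and the 35 state/union-territory records
#' with their five category cost anchors, then back-derives each
#' scenario's national target populations from cost / annual unit cost.
#' Every anchor carries a provenance note naming its published table
#' coordinate. A reconciliation table contrasts the back-derived targets
#' with the stationary-formula targets from the national demographics; the
#' two are never mixed.
#'
#' @return An object of class `india2014_fixture`: a list with elements
#'   `national` ([region_demographics()]), `scenarios` (list of two
#'   [scenario()]), `printed_costs` (data frame with provenance),
#'   `targets` (list of two named vectors, persons), `states` (data frame
#'   of 35 state records), `group_subtotals` (data frame of zone
#'   subtotals) and `reconciliation` (data frame).
#' @export
#' @examples
#' \dontrun{
#' fix <- india_2014_fixture()
#' rep <- cost_scenario(fix$scenarios$india_plus,
#'                      target_overrides = fix$targets$india_plus)
#' sum(as.data.frame(rep)$cost_usd_million)  # ~5930.9
#' }
india_2014_fixture <- function() {
  national <- read_demographics(fixture_path("india2014_demographics.csv"))[["India"]]
  scenarios <- list(sun = load_scenario("sun"), india_plus = load_scenario("india_plus"))
  printed <- utils::read.csv(fixture_path("india2014_printed_costs.csv"),
                             stringsAsFactors = FALSE)
  targets <- lapply(stats::setNames(nm = names(scenarios)), function(s) {
    rows <- printed[printed$scenario == s, ]
    scn <- scenarios[[s]]
    nc_check(setequal(rows$intervention_id, names(scn$interventions)),
             sprintf("printed cost anchors do not match '%s' interventions", s),
             "nutricost_validation_error")
    auc <- vapply(scn$interventions, function(iv) annualize(iv$unit_cost, scn$currency_ctx),
                  numeric(1))
    back_derive_target_populations(
      stats::setNames(rows$cost_usd_million, rows$intervention_id), auc)
  })
  states_raw <- utils::read.csv(fixture_path("india2014_states.csv"),
                                stringsAsFactors = FALSE)
  states <- states_raw[!states_raw$is_subtotal, names(states_raw) != "is_subtotal"]
  subtotals <- states_raw[as.logical(states_raw$is_subtotal),
                          names(states_raw) != "is_subtotal"]
  rownames(states) <- rownames(subtotals) <- NULL

  cohorts <- derive_cohorts(national, 2014)
  recon <- do.call(rbind, lapply(names(scenarios), function(s) {
    scn <- scenarios[[s]]
    resolved <- numeric()
    formula_tp <- vapply(topological_rule_order(lapply(scn$interventions, `[[`, "target_rule")),
                         function(id) {
                           resolved[[id]] <<- resolve_target(
                             scn$interventions[[id]]$target_rule, cohorts, national, resolved)
                           resolved[[id]]
                         }, numeric(1))
    ids <- names(scn$interventions)
    data.frame(scenario = s, intervention_id = ids,
               fixture_target = as.numeric(targets[[s]][ids]),
               formula_target = as.numeric(formula_tp[ids]),
               stringsAsFactors = FALSE)
  }))
  recon$ratio <- with(recon, ifelse(formula_target > 0, fixture_target / formula_target, NA))
  rownames(recon) <- NULL

  structure(list(national = national, scenarios = scenarios,
                 printed_costs = printed, targets = targets,
                 states = states, group_subtotals = subtotals,
                 reconciliation = recon),
            class = "india2014_fixture")
}

#' @export
print.india2014_fixture <- function(x, ...) {
  cat("<india2014_fixture>\n")
  print(x$national)
  cat(sprintf("  scenarios: %s\n",
              paste(sprintf("%s (%d interventions)",
                            names(x$scenarios),
                            vapply(x$scenarios, function(s) length(s$interventions), 1L)),
                    collapse = ", ")))
  cat(sprintf("  %d state records, %d zone subtotals, %d published cost anchors\n",
              nrow(x$states), nrow(x$group_subtotals), nrow(x$printed_costs)))
  cat("  fixture-vs-formula target reconciliation in $reconciliation\n")
  invisible(x)
}

#' State-level cost totals and shares from fixture anchors
#'
#' Sums each state's five category cost anchors and expresses the result
#' as a percentage of the national scenario total.
#'
#' @param fixture an [india_2014_fixture()].
#' @param national_total national grand total in US$ million used as the
#'   share denominator; by default the sum of the fixture's published
#'   India Plus cost anchors.
#' @return Data frame with columns `state`, `zone`, `total_population_million`,
#'   `cost_usd_million`, `share_pct`, sorted by descending cost.
#' @export
state_cost_summary <- function(fixture, national_total = NULL) {
  stopifnot(inherits(fixture, "india2014_fixture"))
  anchor_cols <- c("counselling", "supplementation", "micronutrient_deworming",
                   "health", "cash_transfers")
  st <- fixture$states
  total <- rowSums(st[, anchor_cols])
  denom <- national_total %||%
    sum(fixture$printed_costs$cost_usd_million[
      fixture$printed_costs$scenario == "india_plus"])
  out <- data.frame(state = st$state, zone = st$zone,
                    total_population_million = st$total_population_million,
                    cost_usd_million = total,
                    share_pct = round_half_up(100 * total / denom, 2),
                    stringsAsFactors = FALSE)
  out[order(-out$cost_usd_million), , drop = FALSE]
}
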