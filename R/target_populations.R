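# Target-population resolution: each intervention's eligible-beneficiary
# count is derived from a cohort plus declarative eligibility modifiers
# (prevalence filters, incidence multipliers, inpatient fractions,
# programme exclusions, endemic-area restriction, subtraction of another
# intervention's beneficiaries).

prevalence_indicators <- c("waz_lt_m3", "whz_lt_m3", "whz_lt_m2")

#' Declarative target-population rule
#'
#' @param cohort canonical cohort name (see [cohort_table()]).
#' @param prevalence_filter optional `list(indicator =, multiplier =)`
#'   restricting the cohort to a prevalence-defined subgroup; `indicator`
#'   is one of `waz_lt_m3`, `whz_lt_m3`, `whz_lt_m2`; `multiplier` scales
#'   the prevalence (e.g. 2 to convert a severe-wasting prevalence into an
#'   annual incident caseload).
#' @param incidence_multiplier extra multiplicative factor (default 1).
#' @param inpatient_fraction fraction of cases receiving facility-based
#'   care (default 1).
#' @param exclusion_fraction fraction of otherwise-eligible beneficiaries
#'   excluded (default 0); an 80% delivery cap folded into a target
#'   definition is expressed as `exclusion_fraction = 0.2`.
#' @param endemic_only restrict to malaria-endemic regions (default FALSE).
#' @param exclude_govt_workers subtract each region's fraction of women in
#'   government employment (maternity-benefit exclusion; default FALSE).
#' @param subtract_rule optional id of another intervention whose resolved
#'   target is subtracted (floored at zero), e.g. micronutrient powders
#'   excluding children already receiving complementary food.
#' @param expected_reduction anticipated fractional reduction of the
#'   target before delivery (default 0).
#' @return An object of class `target_rule`.
#' @export
#' @examples
#' target_rule("children_6_59m",
#'             prevalence_filter = list(indicator = "whz_lt_m3", multiplier = 2),
#'             inpatient_fraction = 0.15)
target_rule <- function(cohort, prevalence_filter = NULL, incidence_multiplier = 1,
                        inpatient_fraction = 1, exclusion_fraction = 0,
                        endemic_only = FALSE, exclude_govt_workers = FALSE,
                        subtract_rule = NULL, expected_reduction = 0) {
  nc_check(is.character(cohort) && length(cohort) == 1L && cohort %in% cohort_names,
           sprintf("cohort must be one of: %s", paste(cohort_names, collapse = ", ")),
           "nutricost_config_error")
  if (!is.null(prevalence_filter)) {
    nc_check(is.list(prevalence_filter) &&
               all(c("indicator", "multiplier") %in% names(prevalence_filter)) &&
               prevalence_filter$indicator %in% prevalence_indicators &&
               is_scalar_number(prevalence_filter$multiplier) &&
               prevalence_filter$multiplier >= 0,
             "prevalence_filter must be list(indicator, multiplier) with a known indicator and multiplier >= 0",
             "nutricost_config_error")
  }
  nc_check(is_scalar_number(incidence_multiplier) && incidence_multiplier >= 0,
           "incidence_multiplier must be >= 0", "nutricost_config_error")
  nc_check(is_fraction(inpatient_fraction), "inpatient_fraction must be in [0,1]",
           "nutricost_config_error")
  nc_check(is_fraction(exclusion_fraction), "exclusion_fraction must be in [0,1]",
           "nutricost_config_error")
  nc_check(is_fraction(expected_reduction), "expected_reduction must be in [0,1]",
           "nutricost_config_error")
  nc_check(isTRUE(endemic_only) || isFALSE(endemic_only),
           "endemic_only must be TRUE/FALSE", "nutricost_config_error")
  nc_check(isTRUE(exclude_govt_workers) || isFALSE(exclude_govt_workers),
           "exclude_govt_workers must be TRUE/FALSE", "nutricost_config_error")
  if (!is.null(subtract_rule)) {
    nc_check(is.character(subtract_rule) && length(subtract_rule) == 1L,
             "subtract_rule must be a single intervention id", "nutricost_config_error")
  }
  structure(list(cohort = cohort, prevalence_filter = prevalence_filter,
                 incidence_multiplier = incidence_multiplier,
                 inpatient_fraction = inpatient_fraction,
                 exclusion_fraction = exclusion_fraction,
                 endemic_only = endemic_only,
                 exclude_govt_workers = exclude_govt_workers,
                 subtract_rule = subtract_rule,
                 expected_reduction = expected_reduction),
            class = "target_rule")
}

region_prevalence <- function(demo, indicator) {
  switch(indicator,
         waz_lt_m3 = demo$prev_waz_lt_m3,
         whz_lt_m3 = demo$prev_whz_lt_m3,
         whz_lt_m2 = demo$prev_whz_lt_m2,
         nc_stop(sprintf("unknown prevalence indicator '%s'", indicator),
                 "nutricost_config_error"))
}

#' Resolve a target rule to a beneficiary count
#'
#' Applies, in order: the prevalence filter, the incidence multiplier, the
#' expected reduction, the inpatient fraction, the exclusion fraction
#' (plus the region's government-employment fraction when
#' `exclude_govt_workers`), the endemic-area restriction, and finally the
#' subtraction of another intervention's resolved target (floored at 0).
#'
#' @param rule a [target_rule()].
#' @param cohorts a [cohort_table()] for the region.
#' @param demo the region's [region_demographics()].
#' @param resolved named numeric vector of already-resolved targets, needed
#'   only when `rule$subtract_rule` is set.
#' @return Persons (possibly fractional), `>= 0`.
#' @export
resolve_target <- function(rule, cohorts, demo, resolved = numeric()) {
  stopifnot(inherits(rule, "target_rule"), inherits(cohorts, "cohort_table"),
            inherits(demo, "region_demographics"))
  if (!rule$cohort %in% names(cohorts$cohorts)) {
    nc_stop(sprintf("cohort '%s' not present in cohort table for region '%s'",
                    rule$cohort, cohorts$region_id), "nutricost_resolution_error")
  }
  tp <- cohorts$cohorts[[rule$cohort]]
  if (!is.null(rule$prevalence_filter)) {
    tp <- tp * region_prevalence(demo, rule$prevalence_filter$indicator) *
      rule$prevalence_filter$multiplier
  }
  tp <- tp * rule$incidence_multiplier * (1 - rule$expected_reduction) *
    rule$inpatient_fraction * (1 - rule$exclusion_fraction)
  if (rule$exclude_govt_workers) tp <- tp * (1 - demo$frac_women_govt)
  if (rule$endemic_only && !demo$malaria_endemic) tp <- 0
  if (!is.null(rule$subtract_rule)) {
    if (!rule$subtract_rule %in% names(resolved)) {
      nc_stop(sprintf("subtract_rule '%s' not resolved before '%s'",
                      rule$subtract_rule, rule$cohort), "nutricost_resolution_error")
    }
    tp <- max(tp - resolved[[rule$subtract_rule]], 0)
  }
  tp
}

# Order rule ids so every subtract_rule dependency resolves first;
# cycles are a configuration error.
topological_rule_order <- function(rules) {
  ids <- names(rules)
  deps <- lapply(rules, function(r) {
    d <- r$subtract_rule
    d[d %in% ids]
  })
  order <- character(0)
  remaining <- ids
  while (length(remaining)) {
    ready <- remaining[vapply(remaining, function(id) {
      all(deps[[id]] %in% order)
    }, logical(1))]
    if (length(ready) == 0L) {
      nc_stop(sprintf("cyclic subtract_rule dependency among: %s",
                      paste(remaining, collapse = ", ")), "nutricost_config_error")
    }
    order <- c(order, ready)
    remaining <- setdiff(remaining, ready)
  }
  order
}

#' Annual SAM caseload, facility-based treatment variant
#'
#' Incident severe-acute-malnutrition cases per year are approximated as
#' twice the severe-wasting prevalence among children 6-59 months;
#' `inpatient_fraction` of these receive facility-based treatment.
#'
#' @param children_6_59m cohort size.
#' @param prev_whz_lt_m3 severe-wasting prevalence, in `[0,1]`.
#' @param incidence_multiplier prevalence-to-annual-incidence factor (default 2).
#' @param inpatient_fraction fraction treated in a facility (default 0.15).
#' @return Treated cases per year.
#' @export
#' @examples
#' sam_caseload_india_plus(1e6, 0.05)  # 15000
sam_caseload_india_plus <- function(children_6_59m, prev_whz_lt_m3,
                                    incidence_multiplier = 2, inpatient_fraction = 0.15) {
  nc_check(is.numeric(children_6_59m) && all(children_6_59m >= 0),
           "children_6_59m must be non-negative")
  nc_check(all(prev_whz_lt_m3 >= 0 & prev_whz_lt_m3 <= 1),
           "prev_whz_lt_m3 must be in [0,1]")
  nc_check(is_scalar_number(incidence_multiplier) && incidence_multiplier >= 0,
           "incidence_multiplier must be >= 0")
  nc_check(is_fraction(inpatient_fraction), "inpatient_fraction must be in [0,1]")
  children_6_59m * prev_whz_lt_m3 * incidence_multiplier * inpatient_fraction
}

#' Annual SAM caseload, community-based management variant
#'
#' Doubles the severe-wasting prevalence to an annual incidence, assumes
#' prior delivery of the preventive package halves it (`reduction`), and
#' defines full coverage as `coverage_cap` of the remainder.
#'
#' @param children_6_59m cohort size.
#' @param prev_whz_lt_m3 severe-wasting prevalence, in `[0,1]`.
#' @param reduction anticipated fractional decrease in SAM prevalence
#'   (default 0.5).
#' @param coverage_cap achievable coverage of the remainder (default 0.8).
#' @return Children treated per year.
#' @export
#' @examples
#' sam_caseload_sun(1e6, 0.05)  # 40000
sam_caseload_sun <- function(children_6_59m, prev_whz_lt_m3,
                             reduction = 0.5, coverage_cap = 0.8) {
  nc_check(is.numeric(children_6_59m) && all(children_6_59m >= 0),
           "children_6_59m must be non-negative")
  nc_check(all(prev_whz_lt_m3 >= 0 & prev_whz_lt_m3 <= 1),
           "prev_whz_lt_m3 must be in [0,1]")
  nc_check(is_fraction(reduction), "reduction must be in [0,1]")
  nc_check(is_fraction(coverage_cap), "coverage_cap must be in [0,1]")
  children_6_59m * prev_whz_lt_m3 * 2 * (1 - reduction) * coverage_cap
}

#' Mothers eligible for the maternity cash transfer
#'
#' Women already covered by government maternity-leave provisions are
#' excluded from the benefit.
#'
#' @param lactating_mothers annual count of mothers in the first six
#'   months after delivery.
#' @param frac_women_govt fraction of women 18-50 in government employment.
#' @return Eligible women per year.
#' @export
eligible_mothers_cash_transfer <- function(lactating_mothers, frac_women_govt) {
  nc_check(is.numeric(lactating_mothers) && all(lactating_mothers >= 0),
           "lactating_mothers must be non-negative")
  nc_check(all(frac_women_govt >= 0 & frac_women_govt <= 1),
           "frac_women_govt must be in [0,1]")
  lactating_mothers * (1 - frac_women_govt)
}

#' Micronutrient-powder target net of complementary-food recipients
#'
#' Children already receiving complementary food for the prevention of
#' moderate malnutrition are not targeted for powders.
#'
#' @param children_6_23m cohort size.
#' @param cf_recipients children receiving complementary food.
#' @return `max(children_6_23m - cf_recipients, 0)`.
#' @export
mnp_target <- function(children_6_23m, cf_recipients) {
  nc_check(is.numeric(children_6_23m) && all(children_6_23m >= 0),
           "children_6_23m must be non-negative")
  nc_check(is.numeric(cf_recipients) && all(cf_recipients >= 0),
           "cf_recipients must be non-negative")
  pmax(children_6_23m - cf_recipients, 0)
}

#' Diarrhoea-treatment target population
#'
#' The target is the full 2-59-month cohort: the three annual episodes,
#' two ORS sachets per episode and 14 days of zinc per episode are folded
#' into the annualized unit cost, not the beneficiary count.
#'
#' @param children_2_59m cohort size.
#' @return The cohort, unchanged.
#' @export
diarrhoea_treatment_target <- function(children_2_59m) {
  nc_check(is.numeric(children_2_59m) && all(children_2_59m >= 0),
           "children_2_59m must be non-negative")
  children_2_59m
}
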