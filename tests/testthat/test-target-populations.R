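# Target-population resolution rules.

test_that("resolve_target applies prevalence, multipliers, exclusions and endemicity in order", {
  demo <- toy_region(endemic = FALSE)
  ct <- derive_cohorts(demo, 2014)
  co <- ct$cohorts

  expect_equal(resolve_target(target_rule("children_6_59m"), ct, demo),
               co[["children_6_59m"]])
  expect_equal(resolve_target(target_rule("children_6_59m", exclusion_fraction = 1),
                              ct, demo), 0)
  # SAM-style rule: prevalence x 2 incidence x 15% inpatient
  got <- resolve_target(target_rule("children_6_59m",
                                    prevalence_filter = list(indicator = "whz_lt_m3",
                                                             multiplier = 1),
                                    incidence_multiplier = 2, inpatient_fraction = 0.15),
                        ct, demo)
  expect_equal(got, co[["children_6_59m"]] * demo$prev_whz_lt_m3 * 2 * 0.15)
  # endemic restriction zeroes non-endemic regions only
  itn <- target_rule("pregnant_women", endemic_only = TRUE)
  expect_equal(resolve_target(itn, ct, demo), 0)
  demo_e <- toy_region(endemic = TRUE)
  expect_equal(resolve_target(itn, derive_cohorts(demo_e, 2014), demo_e),
               co[["pregnant_women"]])
  # government-worker exclusion uses the region's employment share
  cash <- target_rule("lactating_mothers_0_6m", exclude_govt_workers = TRUE)
  expect_equal(resolve_target(cash, ct, demo),
               eligible_mothers_cash_transfer(co[["lactating_mothers_0_6m"]],
                                              demo$frac_women_govt))
  expect_error(resolve_target(target_rule("children_6_59m"),
                              cohort_table("x", 2014, c(pregnant_women = 10)), demo),
               class = "nutricost_resolution_error")
})

test_that("subtraction rules floor at zero and require prior resolution", {
  demo <- toy_region()
  ct <- derive_cohorts(demo, 2014)
  rule <- target_rule("children_6_23m", subtract_rule = "cf")
  small <- resolve_target(rule, ct, demo, resolved = c(cf = 1e3))
  expect_equal(small, ct$cohorts[["children_6_23m"]] - 1e3)
  expect_equal(resolve_target(rule, ct, demo, resolved = c(cf = 1e12)), 0)
  expect_error(resolve_target(rule, ct, demo), class = "nutricost_resolution_error")
})

test_that("cyclic subtraction rules are rejected as configuration errors", {
  ivs <- list(
    a = target_rule("children_6_23m", subtract_rule = "b"),
    b = target_rule("children_6_23m", subtract_rule = "a"))
  expect_error(nutricost:::topological_rule_order(ivs), class = "nutricost_config_error")
  acyclic <- list(a = target_rule("children_6_23m", subtract_rule = "b"),
                  b = target_rule("children_6_23m"))
  expect_equal(nutricost:::topological_rule_order(acyclic), c("b", "a"))
})

test_that("facility-based SAM caseload follows prevalence x incidence x inpatient share", {
  expect_equal(sam_caseload_india_plus(1e6, 0), 0)
  expect_equal(sam_caseload_india_plus(1e6, 0.05), 15000)
  expect_equal(sam_caseload_india_plus(108.143e6, 0.064), 108.143e6 * 0.064 * 0.3)
  expect_error(sam_caseload_india_plus(1e6, 1.2), class = "nutricost_invalid_input")
})

test_that("community-based SAM caseload halves prevalence then caps coverage at 80%", {
  expect_equal(sam_caseload_sun(1e6, 0), 0)
  expect_equal(sam_caseload_sun(1e6, 0.05), 1e6 * 0.05 * 2 * 0.5 * 0.8)
  # parameter limit: no reduction, no cap -> plain doubled-prevalence caseload
  expect_equal(sam_caseload_sun(1e6, 0.05, reduction = 0, coverage_cap = 1),
               1e6 * 0.05 * 2)
  # dominance: treated caseload never exceeds the uncapped caseload
  prevs <- seq(0, 0.12, by = 0.01)
  expect_true(all(sam_caseload_sun(1e6, prevs) <=
                    sam_caseload_sun(1e6, prevs, reduction = 0, coverage_cap = 1)))
})

test_that("cash-transfer eligibility excludes government employees", {
  expect_equal(eligible_mothers_cash_transfer(1e6, 0), 1e6)
  expect_equal(eligible_mothers_cash_transfer(1e6, 1), 0)
  expect_equal(eligible_mothers_cash_transfer(28.185e6, 0.00327),
               28.185e6 * (1 - 0.00327))
  expect_error(eligible_mothers_cash_transfer(1e6, 1.1),
               class = "nutricost_invalid_input")
})

test_that("powder target nets out complementary-food recipients, floored at zero", {
  expect_equal(mnp_target(10, 4), 6)
  expect_equal(mnp_target(4, 10), 0)
  expect_equal(mnp_target(0, 0), 0)
})

test_that("diarrhoea-treatment target is the full cohort (episodes live in the unit cost)", {
  expect_equal(diarrhoea_treatment_target(0), 0)
  expect_equal(diarrhoea_treatment_target(1e6), 1e6)
  expect_error(diarrhoea_treatment_target(-1), class = "nutricost_invalid_input")
})

test_that("resolved targets are monotone in cohorts and bounded by cohort x incidence", {
  demo <- toy_region()
  rules <- list(
    target_rule("children_6_59m"),
    target_rule("children_6_59m", prevalence_filter = list(indicator = "whz_lt_m2",
                                                           multiplier = 2)),
    target_rule("children_6_59m", incidence_multiplier = 2, inpatient_fraction = 0.15),
    target_rule("pregnant_women", exclusion_fraction = 0.3, expected_reduction = 0.1))
  small <- derive_cohorts(toy_region(total = 1e5), 2014)
  large <- derive_cohorts(toy_region(total = 1e7), 2014)
  for (rule in rules) {
    tp_small <- resolve_target(rule, small, demo)
    tp_large <- resolve_target(rule, large, demo)
    expect_lte(tp_small, tp_large)
    mult <- rule$incidence_multiplier *
      (if (is.null(rule$prevalence_filter)) 1 else rule$prevalence_filter$multiplier)
    expect_lte(tp_large, large$cohorts[[rule$cohort]] * mult)
    expect_gte(tp_small, 0)
  }
  # non-increasing in exclusion and expected reduction
  base <- resolve_target(target_rule("pregnant_women"), large, demo)
  for (x in seq(0, 1, 0.25)) {
    expect_lte(resolve_target(target_rule("pregnant_women", exclusion_fraction = x),
                              large, demo), base)
    expect_lte(resolve_target(target_rule("pregnant_women", expected_reduction = x),
                              large, demo), base)
  }
})
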