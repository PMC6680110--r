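# The costing product, aggregation, shares and the per-child package rate.

test_that("a cost line is target x coverage x annual unit cost in US$ million", {
  iv <- intervention("cf", "Complementary food", "supplementation",
                     target_rule("children_6_36m"),
                     unit_cost(29, "USD", "per_beneficiary_year"))
  expect_equal(compute_cost_line(iv, 0)$cost_usd_million, 0)
  expect_equal(compute_cost_line(iv, 32.2e6)$cost_usd_million, 933.8)
  iv2 <- intervention("cf2", "Complementary food", "supplementation",
                      target_rule("children_6_36m"),
                      unit_cost(51.10, "USD", "per_beneficiary_year"))
  expect_equal(compute_cost_line(iv2, 57.9e6)$cost_usd_million, 2958.69)
  half <- intervention("h", "Half coverage", "health", target_rule("children_6_59m"),
                       unit_cost(10, "USD", "per_beneficiary_year"), coverage = 0.5)
  expect_equal(compute_cost_line(half, 1e6)$cost_usd_million, 5)
  expect_error(compute_cost_line(iv, -1), class = "nutricost_invalid_input")
})

test_that("aggregates are exact sums and identical over any complete partition", {
  regions <- list(toy_region("r1", total = 2e6, endemic = TRUE),
                  toy_region("r2", total = 5e5),
                  toy_region("r3", total = 1e6, endemic = TRUE))
  rep <- cost_scenario(toy_scenario(), regions = regions)
  total <- sum(as.data.frame(rep)$cost_usd_million)
  for (by in c("intervention", "category", "region", "scenario")) {
    expect_equal(sum(cost_aggregate(rep, by)), total)
  }
  one <- cost_scenario(toy_scenario(), regions = regions[2])
  expect_equal(cost_aggregate(one, "region")[["r2"]],
               sum(as.data.frame(one)$cost_usd_million))
  expect_error(cost_aggregate(rep, "platform"))
})

test_that("shares are percentages of the grand total and sum to 100 within rounding", {
  rep <- cost_scenario(toy_scenario(), regions = list(toy_region(endemic = TRUE)))
  sh <- cost_shares(rep, "intervention")
  expect_equal(sum(sh), 100, tolerance = 0.0501)
  expect_true(all(sh >= 0 & sh <= 100))
  single <- cost_scenario(
    scenario("one", list(intervention("a", "A", "health", target_rule("children_6_59m"),
                                      unit_cost(1, "USD", "per_beneficiary_year")))),
    target_overrides = c(a = 1e6))
  expect_equal(cost_shares(single, "intervention")[["a"]], 100)
  zero <- cost_scenario(
    scenario("zero", list(intervention("a", "A", "health", target_rule("children_6_59m"),
                                       unit_cost(1, "USD", "per_beneficiary_year")))),
    target_overrides = c(a = 0))
  expect_error(cost_shares(zero), class = "nutricost_invalid_input")
})

test_that("engine is linear in unit costs and in target populations", {
  base <- cost_scenario(toy_scenario(), regions = list(toy_region(endemic = TRUE)))
  # integer factor keeps the scaled rates at cent resolution, so the
  # reported (cent-rounded) unit costs scale exactly
  k <- 3
  scaled_ivs <- lapply(toy_scenario()$interventions, function(iv) {
    iv$unit_cost$amount <- iv$unit_cost$amount * k
    iv
  })
  scaled <- cost_scenario(scenario("scaled", unname(scaled_ivs)),
                          regions = list(toy_region(endemic = TRUE)))
  expect_equal(cost_aggregate(scaled, "category"),
               k * cost_aggregate(base, "category"), tolerance = 1e-9)

  # target scaling is not subject to rounding: any factor works
  k2 <- 3.7
  tp <- as.data.frame(base)
  overrides <- setNames(tp$target_population * k2, tp$intervention_id)
  scaled_tp <- cost_scenario(toy_scenario(), target_overrides = overrides)
  expect_equal(sum(as.data.frame(scaled_tp)$cost_usd_million),
               k2 * sum(tp$cost_usd_million), tolerance = 1e-9)
})

test_that("shares are invariant under currency rescaling", {
  fix_ivs <- function(rate) {
    scenario("inr package", list(
      intervention("a", "A", "supplementation", target_rule("children_6_36m"),
                   unit_cost(6, "INR", "per_day", days_per_year = 300)),
      intervention("b", "B", "supplementation", target_rule("pregnant_women"),
                   unit_cost(7, "INR", "per_day", days_per_year = 150))),
      currency_context(inr_per_usd = rate))
  }
  ov <- c(a = 1e6, b = 2e6)
  s1 <- cost_shares(cost_scenario(fix_ivs(62), target_overrides = ov), "intervention")
  s2 <- cost_shares(cost_scenario(fix_ivs(31), target_overrides = ov), "intervention")
  expect_equal(s1, s2, tolerance = 0.02)  # identical up to cent rounding of the rates
})

test_that("engine totals equal per-beneficiary enumeration on small integer regions", {
  set.seed(7)
  scn <- toy_scenario()
  for (rep_i in 1:5) {
    tps <- setNames(sample(0:1000, length(scn$interventions), replace = TRUE),
                    names(scn$interventions))
    rep <- cost_scenario(scn, target_overrides = tps)
    df <- as.data.frame(rep)
    # oracle: add the annual unit cost once per enumerated beneficiary
    oracle <- sum(vapply(seq_len(nrow(df)), function(i) {
      sum(rep(df$annual_unit_cost[i] * df$coverage[i], df$target_population[i])) / 1e6
    }, numeric(1)))
    expect_equal(sum(df$cost_usd_million), oracle, tolerance = 1e-12)
  }
})

test_that("per-child package cost sums the per-child component rates", {
  expect_equal(per_child_package_cost(numeric()), 0)
  expect_equal(per_child_package_cost(c(0, 0, 0)), 0)
  expect_equal(per_child_package_cost(10), 10)
  expect_equal(per_child_package_cost(c(food = 54.2, cash = 68.4, counselling = 6.8,
                                        micronutrient = 4.7, health = 5.9)), 140.0)
  expect_error(per_child_package_cost(c(1, -2)), class = "nutricost_invalid_input")
})

test_that("rule-based multi-region costing restricts endemic lines to endemic regions", {
  regions <- list(toy_region("end", total = 1e6, endemic = TRUE),
                  toy_region("non", total = 1e6, endemic = FALSE))
  rep <- as.data.frame(cost_scenario(toy_scenario(), regions = regions))
  itn <- rep[rep$intervention_id == "itn", ]
  expect_gt(itn$cost_usd_million[itn$region_id == "end"], 0)
  expect_equal(itn$cost_usd_million[itn$region_id == "non"], 0)
})

test_that("print, summary and plot methods run cleanly", {
  rep <- fixture_report("sun")
  expect_output(print(rep), "Scenario: SUN")
  expect_output(print(summary(rep)), "Total annual cost")
  pdf(NULL)
  on.exit(dev.off())
  expect_invisible(plot(rep))
})
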