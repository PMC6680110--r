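# Synthetic census-style generator and the packaged India 2014 fixture.

test_that("the generator is deterministic under the seed and respects n_regions", {
  p <- generator_params(seed = 1, n_regions = 3)
  expect_identical(generate_regions(p), generate_regions(p))
  expect_identical(generate_regions(generator_params(seed = 0, n_regions = 0)), list())
  different <- generate_regions(generator_params(seed = 2, n_regions = 3))
  expect_false(identical(generate_regions(p), different))
})

test_that("generated regions always satisfy the demographic invariant suite", {
  for (seed in c(1, 7, 23, 99)) {
    p <- generator_params(seed = seed, n_regions = 8)
    regs <- generate_regions(p)
    expect_length(regs, 8)
    for (r in regs) {
      b <- r$population_by_band
      expect_true(all(b$m >= 0 & b$f >= 0))
      expect_equal(b$lo[1], 0)
      expect_equal(b$hi[nrow(b)], 100)
      expect_true(all(b$hi[-nrow(b)] == b$lo[-1]))
      total <- sum(b$m + b$f)
      expect_gte(total, p$population_range[1])
      expect_lte(total, p$population_range[2])
      expect_lte(r$prev_whz_lt_m3, r$prev_whz_lt_m2)
      expect_true(all(c(r$prev_whz_lt_m3, r$prev_whz_lt_m2, r$prev_waz_lt_m3,
                        r$frac_women_govt) >= 0))
      # derived cohorts must validate too (cohort_table enforces nesting)
      expect_s3_class(derive_cohorts(r, 2014), "cohort_table")
    }
  }
})

test_that("summed synthetic population falls inside n x the population range", {
  p <- generator_params(seed = 7, n_regions = 35)
  total <- sum(vapply(generate_regions(p),
                      function(r) sum(r$population_by_band$m + r$population_by_band$f),
                      numeric(1)))
  expect_gte(total, 35 * p$population_range[1])
  expect_lte(total, 35 * p$population_range[2])
})

test_that("degenerate generator ranges are rejected", {
  expect_error(generator_params(population_range = c(10, 5)),
               class = "nutricost_validation_error")
  expect_error(generator_params(endemic_probability = 2),
               class = "nutricost_validation_error")
  expect_error(generator_params(prevalence_ranges = list(whz_lt_m2 = c(0.1, 0.2),
                                                         whz_lt_m3 = c(0.02, 1.5),
                                                         waz_lt_m3 = c(0.1, 0.2))),
               class = "nutricost_validation_error")
})

test_that("back-derivation inverts the costing product", {
  expect_equal(back_derive_target_populations(c(ifa = 56.37), c(ifa = 2.00))[["ifa"]],
               28.185e6)
  expect_equal(back_derive_target_populations(c(cmam = 1107.51), c(cmam = 200))[["cmam"]],
               5.53755e6)
  expect_equal(back_derive_target_populations(c(x = 0), c(x = 3))[["x"]], 0)
  expect_error(back_derive_target_populations(c(x = 5), c(x = 0)),
               class = "nutricost_invalid_input")
  expect_error(back_derive_target_populations(c(x = 5), c(y = 1)),
               class = "nutricost_config_error")
})

test_that("forward-costing the back-derived fixture reproduces every published cost", {
  fix <- india_fix()
  for (s in c("sun", "india_plus")) {
    rep <- as.data.frame(fixture_report(s))
    printed <- fix$printed_costs[fix$printed_costs$scenario == s, ]
    got <- setNames(rep$cost_usd_million, rep$intervention_id)
    expect_equal(got[printed$intervention_id],
                 setNames(printed$cost_usd_million, printed$intervention_id),
                 tolerance = 0.005 / 100)  # +-0.005 US$M on ~100 US$M lines
    expect_true(all(abs(got[printed$intervention_id] - printed$cost_usd_million) < 0.005))
  }
})

test_that("fixture targets match the arithmetic identities implied by published tables", {
  t <- india_fix()$targets
  expect_equal(t$sun[["sun_ifa"]], 28.185e6)          # births / pregnancies
  expect_equal(t$sun[["sun_salt_iod"]], 1275.4e6)     # general population
  expect_equal(t$sun[["sun_cmam"]], 5.53755e6)
  expect_equal(t$sun[["sun_cf"]], 32.2779e6, tolerance = 1e-4)
  expect_equal(t$india_plus[["ip_cf_supp"]], 57.9e6, tolerance = 2e-4)
  expect_equal(t$india_plus[["ip_vita"]], 108.142857e6, tolerance = 1e-6)
  expect_equal(t$india_plus[["ip_itn"]], 5.1157e6, tolerance = 1e-4)
  expect_equal(t$india_plus[["ip_cash"]], 28.0927e6, tolerance = 1e-4)
  expect_equal(t$india_plus[["ip_ifa_adol"]], 100.475e6)
  expect_equal(t$india_plus[["ip_sam_treatment"]], 2.0766e6, tolerance = 1e-4)
})

test_that("national demographic record reproduces its projection anchors", {
  nat <- india_fix()$national
  base <- sum(nat$population_by_band$m + nat$population_by_band$f)
  pop14 <- project_population(base, nat$growth_rate, 2014 - nat$base_year)
  expect_equal(pop14, 1275.4e6, tolerance = 1e-4)
  expect_equal(annual_births(pop14, nat$crude_birth_rate), 28.185e6, tolerance = 1e-4)
})

test_that("zone subtotal anchors equal the sum of member-state anchors within 0.1", {
  fix <- india_fix()
  cols <- c("total_population_million", "counselling", "supplementation",
            "micronutrient_deworming", "health", "cash_transfers")
  for (i in seq_len(nrow(fix$group_subtotals))) {
    zone <- fix$group_subtotals$zone[i]
    members <- fix$states[fix$states$zone == zone, ]
    expect_gt(nrow(members), 0)
    for (col in cols) {
      expect_lte(abs(sum(members[[col]]) - fix$group_subtotals[[col]][i]), 0.1 + 1e-9)
    }
  }
})

test_that("reconciliation table surfaces fixture-vs-formula target gaps without mixing them", {
  fix <- india_fix()
  recon <- fix$reconciliation
  expect_equal(nrow(recon), 25)
  expect_true(all(is.finite(recon$fixture_target)))
  # salt iodization: formula (projected population) and fixture agree closely
  iod <- recon[recon$intervention_id == "sun_salt_iod", ]
  expect_equal(iod$fixture_target, iod$formula_target, tolerance = 1e-3)
  # adolescent and under-five targets differ by design (no mortality model,
  # programme-specific targeting); the report records the gap
  adol <- recon[recon$intervention_id == "ip_ifa_adol", ]
  expect_false(isTRUE(all.equal(adol$fixture_target, adol$formula_target,
                                tolerance = 0.05)))
})
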