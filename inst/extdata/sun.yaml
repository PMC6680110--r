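# Ten-intervention global (SUN) costing package, India-wide.
# Declarative: interventions reference registry unit costs and carry
# target rules; costing itself happens in the engine.
scenario:
  name: SUN
currency:
  inr_per_usd: 62.0
  inflation_factor: 1.0
unit_costs:
  sun_bcc:
    amount: 15.00
    currency: USD
    basis: per_household_year
    children_per_household: 2
    source: "Global costing package; $15 per household-year, two under-fives per household ($7.50/child)"
  sun_vita:
    amount: 1.20
    currency: USD
    basis: per_beneficiary_year
    source: "Global costing package; two doses per year"
  sun_zinc:
    amount: 1.00
    currency: USD
    basis: per_beneficiary_year
    source: "Global costing package; two to three rounds per year"
  sun_mnp:
    amount: 3.60
    currency: USD
    basis: per_beneficiary_year
    source: "Global costing package; 60 sachets per child-year"
  sun_deworming:
    amount: 0.50
    currency: USD
    basis: per_beneficiary_year
    source: "Global costing package; two rounds per year"
  sun_ifa:
    amount: 2.00
    currency: USD
    basis: per_pregnancy
    source: "Global costing package; IFA for the last two trimesters"
  sun_iron_fort:
    amount: 0.20
    currency: USD
    basis: per_beneficiary_year
    source: "Global costing package; staple-food iron fortification"
  sun_salt_iod:
    amount: 0.05
    currency: USD
    basis: per_beneficiary_year
    source: "Global costing package; salt iodization"
  sun_cf:
    amount: 51.10
    currency: USD
    basis: per_beneficiary_year
    source: "Global costing package; ~250 kcal/day complementary food ($0.13/child-day)"
  sun_cmam:
    amount: 200.00
    currency: USD
    basis: per_case
    source: "Global costing package; community-based SAM management, per child treated"
interventions:
  sun_bcc:
    name: "Community nutrition programmes for behaviour change communication"
    category: counselling
    unit_cost: sun_bcc
    target:
      cohort: children_0_59m
  sun_vita:
    name: "Vitamin A supplementation"
    category: micronutrient_deworming
    unit_cost: sun_vita
    target:
      cohort: children_6_59m
  sun_zinc:
    name: "Zinc supplementation"
    category: micronutrient_deworming
    unit_cost: sun_zinc
    target:
      cohort: children_6_59m
  sun_mnp:
    name: "Multiple micronutrient powders"
    category: micronutrient_deworming
    unit_cost: sun_mnp
    target:
      cohort: children_6_23m
      subtract_rule: sun_cf   # excludes children receiving complementary food
  sun_deworming:
    name: "Deworming"
    category: micronutrient_deworming
    unit_cost: sun_deworming
    target:
      cohort: children_12_59m
  sun_ifa:
    name: "IFA supplements"
    category: micronutrient_deworming
    unit_cost: sun_ifa
    target:
      cohort: pregnant_women
  sun_iron_fort:
    name: "Iron fortification of staple foods"
    category: fortification
    unit_cost: sun_iron_fort
    target:
      cohort: general_population
  sun_salt_iod:
    name: "Salt iodization"
    category: fortification
    unit_cost: sun_salt_iod
    target:
      cohort: general_population
  sun_cf:
    name: "Complementary food for prevention or treatment of moderate malnutrition"
    category: supplementation
    unit_cost: sun_cf
    target:
      cohort: children_6_23m
      prevalence_filter:
        indicator: whz_lt_m2
        multiplier: 2   # doubled prevalence absorbs targeting error
  sun_cmam:
    name: "Treatment of SAM using community-based management of acute malnutrition"
    category: health
    unit_cost: sun_cmam
    target:
      cohort: children_6_59m
      prevalence_filter:
        indicator: whz_lt_m3
        multiplier: 1
      incidence_multiplier: 2    # prevalence doubled to annual incidence
      expected_reduction: 0.5    # preventive package halves SAM first
      exclusion_fraction: 0.2    # full coverage defined as 80% of the remainder
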