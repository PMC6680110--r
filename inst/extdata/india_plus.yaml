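# Fifteen-intervention India policy-framework ("India Plus") package.
# Unit costs are local programme norms; INR amounts convert at the
# calibrated 62 INR/USD rate. Composite rows (two per-beneficiary
# component rates published for one cost line) carry the component-sum
# annual rate; ip_cf_supp carries the effective annual rate implied by
# the published line cost and its stated 57.9M-child target.
scenario:
  name: India Plus
currency:
  inr_per_usd: 62.0
  inflation_factor: 1.0
unit_costs:
  ip_counsel_preg:
    amount: 0.43
    currency: USD
    basis: per_visit
    visits_per_year: 4.1
    source: "Interpersonal counselling costing study, South Asia; $0.43/visit x 4.1 visits ($1.76/yr)"
  ip_counsel_bf:
    amount: 0.11
    currency: USD
    basis: per_visit
    visits_per_year: 15.2
    source: "Interpersonal counselling costing study, South Asia; $0.11/visit x 15.2 visits ($1.67/yr)"
  ip_counsel_cfhw:
    amount: 10.27
    currency: USD
    basis: per_beneficiary_year
    source: "Composite: $7.47 (6-12m, 13.3 visits at $0.56) + $2.80 (12-24m, 12.2 visits at $0.23)"
  ip_cf_supp:
    amount: 26.36
    currency: USD
    basis: per_beneficiary_year
    source: "Effective annual ICDS ration rate implied by the published line cost and the 57.9M-child 6-36m target (component norms: Rs 6/day; $14.52 at 150d, $29.03 at 300d)"
  ip_suppl_rations:
    amount: 33.86
    currency: USD
    basis: per_beneficiary_year
    source: "Composite ICDS norm: Rs 7/day for 6 months of pregnancy ($16.93) + 6 months of lactation ($16.93)"
  ip_sam_rations:
    amount: 9
    currency: INR
    basis: per_day
    days_per_year: 90
    source: "ICDS norm: Rs 9/day additional ration for 3 months ($13.06/yr)"
  ip_ifa_plw:
    amount: 1.23
    currency: USD
    basis: per_beneficiary_year
    source: "Composite micronutrient investment plan rates: $0.72/pregnancy + $0.51/lactation"
  ip_ifa_adol:
    amount: 0.40
    currency: USD
    basis: per_beneficiary_year
    source: "School-based weekly IFA + semi-annual deworming, adolescent anaemia programme"
  ip_iron_child:
    amount: 0.37
    currency: USD
    basis: per_beneficiary_year
    source: "Current national expenditure on child iron supplementation per beneficiary"
  ip_vita:
    amount: 0.07
    currency: USD
    basis: per_beneficiary_year
    source: "Micronutrient investment plan; two rounds per year"
  ip_ors_zinc:
    amount: 0.64
    currency: USD
    basis: per_beneficiary_year
    source: "Annualized: 3 diarrhoea episodes/yr, 2 ORS sachets + 14 days zinc per episode"
  ip_deworming:
    amount: 0.23
    currency: USD
    basis: per_beneficiary_year
    source: "National rural health mission implementation plan; two rounds per year"
  ip_sam_treatment:
    amount: 107.38
    currency: USD
    basis: per_case
    source: "Facility-based SAM treatment operational guidelines; ~12.5-day average stay"
  ip_itn:
    amount: 4.84
    currency: USD
    basis: per_beneficiary_year
    source: "Insecticide-treated bed net, per pregnant woman in endemic areas"
  ip_cash:
    amount: 103.22
    currency: USD
    basis: per_beneficiary_year
    source: "Maternity benefit: 6-month conditional cash transfer incl. incentives, per eligible woman"
interventions:
  ip_counsel_preg:
    name: "Counselling during pregnancy"
    category: counselling
    unit_cost: ip_counsel_preg
    target:
      cohort: pregnant_women
  ip_counsel_bf:
    name: "Counselling for breastfeeding"
    category: counselling
    unit_cost: ip_counsel_bf
    target:
      cohort: children_0_6m
  ip_counsel_cfhw:
    name: "Counselling for complementary feeding and hand washing"
    category: counselling
    unit_cost: ip_counsel_cfhw
    target:
      cohort: children_6_23m
  ip_cf_supp:
    name: "Complementary food supplements for children 6-36 months of age"
    category: supplementation
    unit_cost: ip_cf_supp
    target:
      cohort: children_6_36m
  ip_suppl_rations:
    name: "Supplementary food rations for pregnant and lactating women"
    category: supplementation
    unit_cost: ip_suppl_rations
    target:
      cohort: pregnant_women
  ip_sam_rations:
    name: "Additional food rations for severely malnourished children"
    category: supplementation
    unit_cost: ip_sam_rations
    target:
      cohort: children_6_59m
      prevalence_filter:
        indicator: waz_lt_m3
        multiplier: 1
  ip_ifa_plw:
    name: "Iron-folic acid supplements for pregnant and breastfeeding women"
    category: micronutrient_deworming
    unit_cost: ip_ifa_plw
    target:
      cohort: pregnant_women
  ip_ifa_adol:
    name: "IFA supplements and deworming for adolescents"
    category: micronutrient_deworming
    unit_cost: ip_ifa_adol
    target:
      cohort: adolescents_11_18y
  ip_iron_child:
    name: "Iron supplements for children"
    category: micronutrient_deworming
    unit_cost: ip_iron_child
    target:
      cohort: children_6_59m
  ip_vita:
    name: "Vitamin A supplementation"
    category: micronutrient_deworming
    unit_cost: ip_vita
    target:
      cohort: children_6_59m
  ip_ors_zinc:
    name: "ORS and therapeutic zinc supplements for treatment of diarrhoea"
    category: micronutrient_deworming
    unit_cost: ip_ors_zinc
    target:
      cohort: children_2_59m
  ip_deworming:
    name: "Deworming"
    category: micronutrient_deworming
    unit_cost: ip_deworming
    target:
      cohort: children_12_59m
  ip_sam_treatment:
    name: "Treatment of severe acute malnutrition"
    category: health
    unit_cost: ip_sam_treatment
    target:
      cohort: children_6_59m
      prevalence_filter:
        indicator: whz_lt_m3
        multiplier: 1
      incidence_multiplier: 2    # annual incidence ~ twice severe-wasting prevalence
      inpatient_fraction: 0.15   # 15% receive facility-based treatment
  ip_itn:
    name: "Insecticide-treated nets for pregnant women in malaria-endemic areas"
    category: health
    unit_cost: ip_itn
    target:
      cohort: pregnant_women
      endemic_only: true
  ip_cash:
    name: "Cash transfers to women in the first 6 months after delivery"
    category: cash_transfer
    unit_cost: ip_cash
    target:
      cohort: lactating_mothers_0_6m
      exclude_govt_workers: true   # government employees already have maternity leave
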