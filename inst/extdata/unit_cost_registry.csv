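entry_id,package,amount,currency,basis,days_per_year,visits_per_year,children_per_household,annual_usd_printed,note
counsel_pregnancy,india_plus,0.43,USD,per_visit,,4.1,,1.76,"4.1 face-to-face visits per pregnant woman"
counsel_breastfeeding,india_plus,0.11,USD,per_visit,,15.2,,1.67,"15.2 visits between 0-6 months"
counsel_cf_6_12m,india_plus,0.56,USD,per_visit,,13.3,,7.47,"published 7.47; 0.56 x 13.3 = 7.45 (published rounding path unknown; printed value stored)"
counsel_cf_12_24m,india_plus,0.23,USD,per_visit,,12.2,,2.80,"published 2.80; 0.23 x 12.2 = 2.81 (published rounding path unknown; printed value stored)"
cf_ration_6_12m,india_plus,6,INR,per_day,150,,,14.52,"Rs 6/day, six-month entitlement (150 feeding days)"
cf_ration_12_36m,india_plus,6,INR,per_day,300,,,29.03,"Rs 6/day, 300 feeding days/year (calibrates the 62 INR/USD rate)"
plw_ration,india_plus,7,INR,per_day,150,,,16.93,"published 16.93; Rs 7 x 150 / 62 = 16.94 (published rounding path unknown; printed value stored)"
sam_ration,india_plus,9,INR,per_day,90,,,13.06,"Rs 9/day additional ration for 3 months"
ifa_pregnancy,india_plus,0.72,USD,per_beneficiary_year,,,,0.72,"daily IFA, second and third trimesters"
ifa_lactation,india_plus,0.51,USD,per_beneficiary_year,,,,0.51,"daily IFA, 6 months after delivery"
ifa_deworming_adolescents,india_plus,0.40,USD,per_beneficiary_year,,,,0.40,"weekly IFA + semi-annual deworming, school platform"
iron_children,india_plus,0.37,USD,per_beneficiary_year,,,,0.37,"current national expenditure per beneficiary"
vitamin_a,india_plus,0.07,USD,per_beneficiary_year,,,,0.07,"two supplementation rounds per year"
ors_zinc,india_plus,0.64,USD,per_beneficiary_year,,,,0.64,"3 episodes/yr, 2 ORS sachets + 14d zinc per episode, annualized"
deworming_children,india_plus,0.23,USD,per_beneficiary_year,,,,0.23,"two rounds per year"
sam_treatment,india_plus,107.38,USD,per_case,,,,107.38,"facility-based treatment, ~12.5-day stay"
itn,india_plus,4.84,USD,per_beneficiary_year,,,,4.84,"insecticide-treated net per pregnant woman"
cash_transfer,india_plus,103.22,USD,per_beneficiary_year,,,,103.22,"6-month maternity benefit incl. incentives, per eligible woman"
bcc_household,sun,15.00,USD,per_household_year,,,2,7.50,"$15 per household-year, two under-fives per household"
vitamin_a,sun,1.20,USD,per_beneficiary_year,,,,1.20,"two doses per year"
zinc,sun,1.00,USD,per_beneficiary_year,,,,1.00,"two to three rounds per year"
mnp,sun,3.60,USD,per_beneficiary_year,,,,3.60,"60 sachets per child-year"
deworming,sun,0.50,USD,per_beneficiary_year,,,,0.50,"two rounds per year"
ifa_pregnancy,sun,2.00,USD,per_pregnancy,,,,2.00,"IFA for the last two trimesters"
iron_fortification,sun,0.20,USD,per_beneficiary_year,,,,0.20,"staple-food fortification, general population"
salt_iodization,sun,0.05,USD,per_beneficiary_year,,,,0.05,"general population"
complementary_food,sun,51.10,USD,per_beneficiary_year,,,,51.10,"~250 kcal/day, $0.13 per child-day"
cmam,sun,200.00,USD,per_case,,,,200.00,"per child treated"
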