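scenario,intervention_id,cost_usd_million,provenance
sun,sun_bcc,891.42,"published SUN cost table, row: behaviour change communication"
sun,sun_vita,129.79,"published SUN cost table, row: vitamin A supplementation"
sun,sun_zinc,5.54,"published SUN cost table, row: zinc supplementation"
sun,sun_mnp,4.84,"published SUN cost table, row: multiple micronutrient powders"
sun,sun_deworming,59.43,"published SUN cost table, row: deworming"
sun,sun_ifa,56.37,"published SUN cost table, row: IFA supplements"
sun,sun_iron_fort,255.07,"published SUN cost table, row: iron fortification of staple foods"
sun,sun_salt_iod,63.77,"published SUN cost table, row: salt iodization"
sun,sun_cf,1649.4,"published SUN cost table, row: complementary food"
sun,sun_cmam,1107.51,"published SUN cost table, row: CMAM treatment of SAM"
india_plus,ip_counsel_preg,49.61,"published India Plus cost table, row: counselling during pregnancy"
india_plus,ip_counsel_bf,17.87,"published India Plus cost table, row: counselling for breastfeeding"
india_plus,ip_counsel_cfhw,219.56,"published India Plus cost table, row: counselling for complementary feeding and hand washing"
india_plus,ip_cf_supp,1526.01,"published India Plus cost table, row: complementary food supplements 6-36m"
india_plus,ip_suppl_rations,658.35,"published India Plus cost table, row: supplementary food rations for pregnant and lactating women"
india_plus,ip_sam_rations,111.04,"published India Plus cost table, row: additional food rations for severely malnourished children"
india_plus,ip_ifa_plw,19.83,"published India Plus cost table, row: IFA supplements for pregnant and breastfeeding women"
india_plus,ip_ifa_adol,40.19,"published India Plus cost table, row: IFA supplements and deworming for adolescents"
india_plus,ip_iron_child,40.02,"published India Plus cost table, row: iron supplements for children 6-36m"
india_plus,ip_vita,7.57,"published India Plus cost table, row: vitamin A supplementation"
india_plus,ip_ors_zinc,70.99,"published India Plus cost table, row: ORS and therapeutic zinc"
india_plus,ip_deworming,22.41,"published India Plus cost table, row: deworming"
india_plus,ip_sam_treatment,222.98,"published India Plus cost table, row: treatment of severe acute malnutrition"
india_plus,ip_itn,24.76,"published India Plus cost table, row: insecticide-treated nets"
india_plus,ip_cash,2899.73,"published India Plus cost table, row: cash transfers to women"
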