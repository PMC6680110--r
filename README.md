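# nutricost

Costing nutrition-specific intervention packages at full coverage, for
national and subnational budget planning.

Low coverage of proven nutrition interventions — breastfeeding and
complementary-feeding counselling, micronutrient supplementation and
deworming, supplementary feeding, treatment of severe acute malnutrition
(SAM), maternity cash transfers — is as much a financing problem as an
implementation one, and planners need defensible answers to "what would
full delivery cost per year, here?". `nutricost` implements the
*program-experience* costing approach used for that question in India:
for every intervention *i*,

```
cost_i  (US$/yr)  =  UC_i  ×  TP_i  ×  coverage_i
```

where `UC_i` is the per-beneficiary annual unit cost observed in
operating programmes (normalized from per-day, per-visit, per-household,
per-case or per-pregnancy expressions, INR or USD) and `TP_i` is the
target population resolved from demographic cohorts and declarative
eligibility rules (prevalence filters, incidence multipliers,
endemic-area restrictions, programme exclusions). The package ships two
declarative scenario configurations — the 10-intervention global **SUN**
package and the 15-intervention **India Plus** package drawn from India's
policy framework — together with a packaged India 2014 fixture whose
target populations are back-derived from published programme costs, and
a synthetic census-style data generator for property-based testing.

It is aimed at health economists and nutrition programme planners; the
engine is general (any region table + scenario config), the fixture is
India 2014.

## Worked example

```r
library(nutricost)

fix <- india_2014_fixture()
rep <- cost_scenario(fix$scenarios$india_plus,
                     target_overrides = fix$targets$india_plus,
                     region_id = "India")
summary(rep)
#> Scenario: India Plus  (15 lines, 1 regions)
#> Total annual cost: 5930.92 US$ million
#>
#> By category (US$ million, share %):
#>                 category cost (US$M/yr) share (%)
#>              counselling         287.04      4.84
#>          supplementation        2295.40     38.70
#>  micronutrient_deworming         201.01      3.39
#>                   health         247.74      4.18
#>            cash_transfer        2899.73     48.89
```

Delivering the full India Plus package at 100% coverage costs ~US$5.93 bn
per year; cash transfers to breastfeeding mothers (48.89%) and
supplementary food (38.70%) dominate. The SUN package on the same
demographic base costs US$4223.14 M:

```r
sun <- cost_scenario(fix$scenarios$sun, target_overrides = fix$targets$sun,
                     region_id = "India")
compare_scenarios(sun, rep)   # category-level contrast, difference 1707.78 US$M
```

One-way sensitivity: applying the US$29/child-year ICDS ration norm to
the narrower 32.2 M-child target yields 933.80 US$M (~US$0.93 bn), while
the US$51.10 rate on the wider 57.9 M-child target yields 2958.69 US$M
(~US$2.96 bn) — the spread between target definitions matters more than
either rate:

```r
swap <- sensitivity_swap(fix$scenarios$sun, "sun_cf",
                         new_unit_cost = unit_cost(29, "USD", "per_beneficiary_year"),
                         new_target = 32.2e6, report = sun)
```

State disaggregation from the packaged category anchors:

```r
head(state_cost_summary(fix), 3)
#>            state                 zone total_population_million cost_usd_million share_pct
#>    Uttar Pradesh Indo-gangetic plains                    199.6           1164.3     19.63
#>            Bihar Indo-gangetic plains                    103.8            680.0     11.47
#>      Maharashtra       Central states                    112.4            451.3      7.61
```

A rule-of-thumb package rate: `per_child_package_cost(c(54.2, 68.4, 6.8,
4.7, 5.9))` gives **US$140 per child 0–24 months per year**.

A thin CLI wraps the same functions
(`Rscript inst/cli/nutricost.R cost --scenario india_plus --fixture --out reports`),
with `compare`, `sensitivity`, `synth` (seeded synthetic demographics)
and `fixture` subcommands.

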