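---
title: "Program-experience costing of nutrition intervention packages"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Program-experience costing of nutrition intervention packages}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nutricost)
```

## The costing model

`nutricost` implements the *program-experience* approach to budgeting
direct nutrition interventions: for each intervention, the annual cost of
delivery at full coverage is

$$C_i = \mathrm{UC}_i \times \mathrm{TP}_i \times c_i,$$

where $\mathrm{UC}_i$ is the observed per-beneficiary annual unit cost
taken from operating programmes, $\mathrm{TP}_i$ the target population
(eligible beneficiaries per year) and $c_i$ the coverage fraction
(1.0 throughout, on the premise that the costed interventions are to be
universalized; an 80% ceiling enters only where a package folds it into
its own target definition). The model is deliberately static and linear:
no discounting, no economies of scale, no dynamic response of nutritional
status to delivery — it answers "what would one year of full delivery
cost at today's programme norms", not "what will it achieve". Scenario
comparison and one-way sensitivity swaps are therefore exact
recomputations of single lines, never simulations.

## From census inputs to target populations

A region enters the model as a `region_demographics` record: base-year
population by half-open age band and sex, the crude birth rate (CBR,
births/1000/yr), the average annual growth rate, under-five
anthropometric prevalences (WHZ\ <\ −2, WHZ\ <\ −3, WAZ\ <\ −3), the
fraction of women 18–50 in government employment, and a malaria-endemicity
flag. `derive_cohorts()` projects the total population exponentially to
the target year, takes the annual birth flow $B = P \cdot \mathrm{CBR}/1000$,
and builds child cohorts under a **stationary approximation**: the cohort
aged $[l, h)$ months holds $B \times (h - l)/12$ children. This ignores
under-five mortality and recent fertility decline; both would shrink older
child cohorts by a few percent. The choice is intentional: programme cost
norms are budgeted against nominal cohort sizes, and the packaged fixture
(below) overrides formula cohorts with back-derived ones wherever a
published anchor exists, so the approximation never contaminates the
reproduced results. Pregnancies default to $B \times 1.0$
(`pregnancy_multiplier`, configurable; no pregnancy-loss adjustment is
applied because the source cost norms do not state one), lactating mothers
in the six-month postpartum window equal $B$ (each birth admits one mother
to the benefit once), and households with an under-five divide the
under-five cohort by 2 children per household. Adolescents 11–18 come from
the age-band table by uniform within-band interpolation, scaled by the
projection factor.

Eligibility is declarative (`target_rule`): a cohort name plus optional
prevalence filter (indicator × multiplier), incidence multiplier,
expected pre-delivery reduction, inpatient fraction, exclusion fraction,
endemic-area restriction, government-worker exclusion (taken from the
region's own employment share) and subtraction of another intervention's
resolved target (resolved in topological order, floored at zero). Two
caseload conventions deserve note:

* facility-based SAM treatment: annual incident cases ≈ 2 × severe-wasting
  prevalence, 15% treated as inpatients, coverage 1.0 — the published
  national line is only consistent with full coverage, so the 80% ceiling
  is exposed as a knob rather than hard-wired;
* community-based SAM management: the preventive package is assumed to
  halve SAM first and full coverage is defined as 80% of the remainder;
  because the source folds that ceiling into the *target definition*, the
  packaged config expresses it as `expected_reduction = 0.5` plus
  `exclusion_fraction = 0.2`.

The complementary-food prevalence filter uses the WHZ < −2 indicator
with multiplier 2 (the doubled prevalence absorbs targeting error); the
record carries no WAZ < −2 prevalence, so wasting is the filter of
record.

## Unit-cost normalization

`annualize()` reduces every published cost expression to US\$ per
beneficiary-year: per-day rates multiply by the feeding-day convention
(300 days for a full-year ration, 150 for a six-month entitlement, 90 for
the three-month therapeutic ration), per-visit rates by the visit
schedule (4.1 pregnancy visits, 15.2 breastfeeding visits, 13.3 and 12.2
complementary-feeding visits), per-household rates divide by 2 under-five
children per household; per-case and per-pregnancy rates are already
annual. INR converts at 62.0 INR/USD — the rate is not stated alongside
the cost norms, so it is calibrated once so that Rs 6 × 300 days
annualizes to \$29.03 exactly, and it is configurable. The inflation
factor defaults to 1.0 (no index or base year accompanies the norms; all
published annual cells reproduce without one).

**Rounding convention.** The chain runs at full precision and the final
annual rate is rounded to the cent, half-up; that cent-rounded rate is
the rate used in cost products and in back-derivation. This is a
deliberate choice: the published tables are only mutually consistent if
the printed (cent) rate is the costing rate (e.g. \$1.76 = 0.43 × 4.1
rounded, and the pregnancy-counselling line equals 28.19 M × \$1.76). A
corollary worth knowing: engine linearity in unit costs is exact for
integer scale factors (which preserve cent resolution) but can differ in
the last cent for fractional ones. Cost lines are carried unrounded and
reported at 0.01 US\$ million, half-up. Three registry cells
(\$7.47, \$2.80, \$16.93) differ from their recomputed values by one or
two cents; the published rounding path is unrecoverable, so the registry
stores the printed values with a note rather than silently recomputing
them.

## The packaged India 2014 fixture

No deposited microdata exist for this analysis, so the fixture is
**back-derived**: for each of the 25 published intervention cost lines
(10 in the global SUN package, 15 in the India Plus package), the target
population is recovered as
$\mathrm{TP}_i = C_i \times 10^6 / \mathrm{UC}_i$. Running the forward
engine on these targets reproduces every published line to well under
0.005 US\$ million — the round-trip identity on which the whole fixture
rests. The recovered targets are internally coherent: the salt-iodization
line implies a 2014 population of 1275.4 M, the IFA line 28.19 M annual
pregnancies, the adolescent line 100.5 M adolescents, the SAM line 2.08 M
treated cases.

Three rows need a stated convention. The India Plus complementary-food
line publishes both a cost (1526.01 US\$M) and a target (57.9 M children
6–36 months) that are inconsistent with the Rs 6/day × 300-day norm
(\$29.03 × 57.9 M = 1680.8 US\$M); the fixture keeps the published target
and carries the implied effective rate of \$26.36/child-year, with the
per-day mechanics retained in the unit-cost registry. Rows that publish
two per-beneficiary component rates for one cost line (complementary
feeding counselling \$7.47 + \$2.80; pregnancy + lactation rations
\$16.93 + \$16.93; pregnancy + lactation IFA \$0.72 + \$0.51) carry the
component-sum annual rate, interpreted as the full annual package per
beneficiary progression; the composite target is back-derived from it.
Since cost = rate × target by construction, the reproduced costs do not
depend on how the composite is split.

Formula-derived and back-derived targets are **never mixed**: the fixture
exposes a reconciliation table contrasting the two, and the gaps it
records are informative (no mortality adjustment inflates formula child
cohorts by ~15–25%; the adolescent programme is school-based and
girl-focused, so its back-derived target is roughly half the census
11–18 population; the national record is flagged non-endemic, so the
endemic-only bed-net line resolves to zero by formula while the fixture
carries the back-derived 5.12 M endemic pregnancies). The national
demographic record itself is reverse-engineered to hit the anchors
(2011 base 1210.9 M with a census-shaped synthetic age pyramid, growth
1.745%/yr so the 2014 projection is 1275.4 M, CBR 22.099 so births are
28.185 M, severe wasting 6.4%, severe underweight 7.86%, government
employment share 0.327%).

State disaggregation ships as published category anchors only (five
categories × 35 states/union territories plus zone subtotals); the
publication does not decompose state costs to intervention level, so
neither does the fixture. Zone subtotals agree with member sums to the
printed 0.1 US\$M. `state_cost_summary()` turns the anchors into state
totals and national shares — Uttar Pradesh alone is ~20% of the national
India Plus cost.

## The synthetic generator

`generate_regions()` emulates the *statistical shape* of the inputs so
that every pipeline stage can be property-tested without external data:
uniform draws within India-like ranges (state populations 0.5–200 M, CBR
15–30, growth 0.5–2.5%/yr, wasting 10–25% with severe wasting 2–8%
enforced ≤ wasting by rejection, severe underweight 5–20%, government
employment 0.1–5%, 12/35 endemic probability), a geometrically thinning
age pyramid over twenty 5-year bands summing to the drawn population, and
full determinism under the seed. What it does **not** emulate: spatial
correlation between prevalence and fertility, heaping and censoring in
census age reporting, within-state heterogeneity, or any covariance
between indicators. Tests passing on synthetic regions therefore
establish the engine's algebraic correctness (invariants, linearity,
conservation, oracle equivalence against per-beneficiary enumeration),
not the realism of any particular cost estimate — realism enters only
through the published anchors in the fixture.

## Numerical choices and degenerate inputs

Monetary reporting is half-up (cents for rates, 0.01 US\$M for lines)
with full precision inside; targets may be fractional persons (every
back-derived target is); zero cohorts, zero prevalences and
`n_regions = 0` are valid inputs yielding zero costs or empty output;
shares are undefined (an error, not NaN) for a zero grand total; cyclic
subtraction rules, missing convention fields, out-of-range fractions and
band tables that fail to tile [0, 100) are all rejected with classed,
located errors. The reproduction tolerance for published totals is
±0.02 US\$M: the India Plus rows sum to 5930.92 against a printed total
of 5930.91 because the published rows are themselves penny-rounded.

## Problem sizes

Everything here is desk-scale by design: the national runs are 10- and
15-line computations, the state layer is a 35 × 5 table, and the
property suites use a handful of synthetic regions (≤ 35) across a few
seeds — the full test suite and the headline reproduction complete in
seconds on one CPU.

## Known limitations

Constant returns to scale (no economies of scale in unit costs);
national unit costs applied subnationally (published state costs are
anchors, not recomputations from state-specific unit costs); no
opportunity costs of beneficiary time; no mass-media behaviour-change
component; prevalence inputs frozen at their survey vintage; single
target year (no multi-year phasing or discounting); and no
cost-effectiveness linkage — the engine prices delivery, it does not
value outcomes.
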