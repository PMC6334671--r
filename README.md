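# acmscreen

Questionnaire-based screening of residential asbestos-containing
materials (ACMs).

Asbestos cement products were installed in homes in Australia (and many
other countries) from the mid-1940s until their phase-out in the late
1980s, and much of that material is still in place. In-situ ACMs are a
health hazard when they deteriorate or are disturbed — most acutely for
do-it-yourself renovators cutting, drilling or sanding what they cannot
recognise as asbestos cement. Telling old asbestos cement sheeting apart
from modern asbestos-free lookalikes is hard for the untrained eye, so
householders, environmental health officers and tradespeople need a
structured way to screen a property without laboratory sampling.

`acmscreen` implements that screen as a desk-top library and CLI:

* a **declarative instrument** — a three-module questionnaire (household
  information, outside locations, inside locations) shipped as YAML,
  covering eight outside locations (exterior walls and gable ends, eaves
  or soffit linings, roofing, gutters, downpipes, electrical meter box,
  fencing, outbuildings) and five inside locations (interior walls,
  cupboards and backsplashes, ceilings, flooring, heater flues);
* a **branching engine** that routes each dwelling along a custom pathway
  using if–then skip logic: houses built after 1990 (the cutoff after
  which ACMs ceased to be installed in new housing) get an abbreviated,
  outside-only questionnaire, and absent materials skip their follow-up
  questions;
* **classification**: each inspected material is designated one of four
  probabilities of containing asbestos — *not applicable*, *unlikely
  ACM*, *possible ACM* or *likely ACM* — by a per-material decision table
  over four screening factors: house age, install/renovation history,
  the location of the material, and its visual features (e.g. cement
  sheeting with joiner strips);
* **priority scoring**: every possible or likely ACM triggers a
  condition and likelihood-of-disturbance assessment. The qualitative
  condition c ∈ {good, fair, poor, very poor} and disturbance likelihood
  d ∈ {unlikely, somewhat likely, likely, highly likely} are assigned
  numeric scores and summed, s = S_cond(c) + S_dist(d), and s maps
  through a 4×4 risk matrix to a priority level in {very low, low,
  medium, high} with a remediation recommendation;
* **reporting and aggregation**: per-house summary reports (text/HTML,
  colour-coded priorities), a JSON report store, and cross-house survey
  aggregates for mapping the presence and condition of ACMs in the
  housing stock;
* a **seeded housing-stock simulator** that generates
  branching-consistent synthetic dwellings for testing and survey-scale
  simulation.

The screen indicates probability of asbestos content and remediation
priority; it does not measure exposure and does not replace a
professional asbestos inspection or laboratory confirmation.

## Worked example

A pre-1985 house where only the eaves are flagged: cement sheeting with
joiner strips (a visual feature of older asbestos cement), installation
date unknown — the classic situation the *possible ACM* designation
exists for.

```r
library(acmscreen)
inst <- acm_check_instrument()
s <- start_session(inst)
s <- submit_answer(s, "state", "wa")
s <- submit_answer(s, "user_description", "householder")
s <- submit_answer(s, "post_code", 6000L)
s <- submit_answer(s, "construction_period", "pre_1985")
s <- submit_answer(s, "dwelling_type", "separate_house")
s <- submit_answer(s, "occupants_count", 3L)
s <- submit_answer(s, "occupants_age", "adults_only")
# ... eaves: present, install unknown, cement sheeting with joiner strips,
#     fair condition (rating 6/10), disturbance likely; every other
#     material answered "not_present"
report <- generate_report(s)
cat(render_report(report, "text"))
```

```
ACM screening summary report r7a8787270168c79d
Instrument: acm_check v1.0.0   Generated: 2026-09-20T03:00:00Z

Household
  state                  wa
  user_description       householder
  post_code              6000
  construction_period    pre_1985
  dwelling_type          separate_house
  occupants_count        3
  occupants_age          adults_only

Results (13 materials assessed)
  Material                     Designation    Condition  Disturbance    Priority
  Exterior walls and gable ends not_applicable -          -              -
  Eaves or soffit linings      possible_acm   fair       likely         low [yellow]
  Roofing                      not_applicable -          -              -
  ...
Recommendations
  Eaves or soffit linings (low priority): Monitor and minor maintenance and repair
```

Reading the numbers: the unknown installation date makes the eaves a
*possible ACM* despite the suggestive sheeting, which triggers the
priority assessment; condition *fair* scores 2 and disturbance *likely*
scores 3, the sum 5 falls in the *low* band of the risk matrix, and the
report attaches the low-priority recommendation. The 6/10 quantitative
rating is recorded for the survey export but never enters the score.

Survey-scale use:

```r
model <- housing_stock_model(seed = 42)   # synthetic housing stock
store <- simulate_survey(model, n = 200)
aggregate_survey(store)                   # houses, designations, priorities
export_survey_table(store, "survey.csv")  # one row per house x material
```

The same operations are available from a shell via the thin wrapper in
`inst/cli/acmscreen` (subcommands `validate`, `run`, `simulate`,
`report`, `aggregate`, `export-rules`).

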