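---
title: "Screening homes for asbestos-containing materials: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening homes for asbestos-containing materials: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(acmscreen)
```

## The screening problem

Asbestos cement products were installed in homes for decades before
being phased out of residential building products in the late 1980s;
in Australia nearly every house built before 1990 can be expected to
contain some asbestos-containing material (ACM). The materials are
hazardous when damaged, weathered or disturbed — not merely by being
present — and they are visually easy to confuse with modern asbestos-free
products. `acmscreen` implements a structured visual screening
questionnaire for one dwelling at a time, producing for every inspected
location (i) an ordinal probability that it contains asbestos and
(ii), where that probability warrants it, an ordinal priority for
remediation derived from the material's condition and its likelihood of
disturbance.

Two modelling commitments frame everything below:

* **Screening, not measurement.** Outputs are ordinal categories, never
  fibre concentrations or health-risk estimates. Presence of an ACM is
  deliberately decoupled from exposure: a sound, undisturbed asbestos
  cement sheet is a very different object from a crumbling one beside a
  planned renovation.
* **Content is data, engine is code.** Question wording, branch rules,
  decision tables, the risk matrix and the recommendations all live in a
  declarative YAML instrument. The engine interprets; it hard-codes no
  screening knowledge. This keeps the instrument auditable
  (`export_rules()`) and adaptable to other jurisdictions, where
  phase-out years, regulations and typical materials differ.

## The instrument

The shipped instrument (`acm_check_instrument()`) has three modules —
household information, outside locations, inside locations — covering
eight outside and five inside materials. Every material contributes a
block of up to six questions: presence, install/renovation history, a
visual-feature question, and (when triggered) qualitative condition,
a quantitative 1–10 condition rating, and likelihood of disturbance.

The questionnaire's published description fixes the *structure* of the
screen — the four screening factors, the 1985/1990 cutoff years, the
three house-age categories, the four probability designations, the
4-option condition and disturbance scales, the 1–10 rating, additive
scoring into four priority levels, and the four recommendation texts —
but not the full question wording, the visual-feature option lists, or
the individual decision cells. Those are reconstructions here, and the
instrument says so in its metadata (`reconstructed_tables: true`). The
reconstruction is constrained to reproduce every documented behaviour:
eaves of cement sheeting with joiner strips and an unknown installation
date must come out *possible ACM*; materials replaced after 1990 with
asbestos-free features must come out *unlikely ACM*; absent materials
are always *not applicable*.

## Branching

Routing is first-match over each question's declared rules, falling
through to the next question in module order. Predicates are `equals`,
`in_set`, `band_before`/`band_after` (for year-band questions, matching
options whose band lies strictly before/after the operand year), and
`category_in`. The last deserves a note: the trigger rule — condition
and disturbance are asked *only* for materials designated possible or
likely ACM — branches on a classification computed from answers so far,
not on any single answer. Expressing it as a declarative predicate keeps
the trigger in the instrument file rather than in engine code, at the
cost of one predicate kind beyond the usual answer-matching set.

Two structural choices:

* **The abbreviated pathway is a module gate.** Houses built after 1990
  skip the entire inside module. A question-level rule cannot express
  this, because the rule would need to fire from whatever the *last*
  outside question on a given dwelling's dynamic pathway happens to be.
  The inside module therefore carries a `presented_when` condition on
  the construction-period answer; `select_pathway()` is the canonical
  band-to-pathway mapping and the test suite asserts the two agree.
* **Unknown construction period routes to the full questionnaire.**
  The screen is conservative throughout (the 1990 cutoff itself is a
  conservative extension of the 1987 manufacturing phase-out); not
  knowing the build year must not hide the inside of the house from
  inspection. An unanswered module gate likewise leaves the module
  presented.

The question-transition graph (rule targets plus lexical successors) is
required to be acyclic, checked at validation by depth-first search and,
in the tests, against a brute-force walk enumerator on small
instruments. Acyclicity gives termination for free: any session reaches
the terminal marker in at most as many steps as there are questions.
Re-answering an earlier question truncates the pathway after it and
re-routes — the behaviour a CLI user expects from "going back", and the
only revision semantics consistent with branch rules that depend on the
revised answer.

## Classification

Each material's designation is a first-match decision table over four
factors: house-age band, install history, presence, and a visual class.
Visual options carry one of three classes — `suggestive` (features
typical of older asbestos cement, e.g. joiner strips over sheet joins),
`ambiguous` (including "cannot tell"), `non_acm` (clearly modern or
inherently asbestos-free construction). When a material has several
visual questions the most suggestive class wins; no visual answer counts
as ambiguous.

The shipped table, shared by all thirteen materials, reads in order:

1. not present → **not applicable** (dominates everything);
2. visually asbestos-free → **unlikely ACM**;
3. installed/replaced after 1990 → **unlikely ACM**, except **possible
   ACM** when the visual features are suggestive (a contradiction
   between a claimed post-1990 replacement and classic asbestos-cement
   appearance is resolved conservatively);
4. original pre-1990 install → **likely ACM** if suggestive, else
   **possible ACM**;
5. unknown install in a post-1990 house with ambiguous features →
   **unlikely ACM** (nothing positive indicates asbestos, and the
   house-age category is already "unlikely");
6. otherwise → **possible ACM** (the unconditional default that makes
   the table total).

Consequences worth stating: *likely ACM* requires both a known pre-1990
installation and suggestive visual features; unknown visual features
with a pre-1990 install yield *possible ACM* even in a pre-1985 house.
That is the designation doing its stated job — flagging exactly the
situations where the probability can be neither confirmed nor ruled out.
The table satisfies a knowledge-monotonicity property checked
exhaustively in the tests: learning that a material was replaced after
1990 can lower its designation (possible → unlikely) but never raise it.
Every table must end in an unconditional rule; the validator enforces
this, so totality holds by construction rather than by enumeration.

House-age classification is the fixed three-category mapping: before
1985 → *likely*, 1985–1990 → *possible*, after 1990 → *unlikely*,
unknown → *possible*. The boundary between the likely and possible bands
is 1985, exposed as instrument metadata (`cutoff_year_early`) so a
jurisdiction adaptation can move it without touching code.

## Priority scoring

For each possible or likely ACM, the qualitative condition and the
disturbance likelihood are scored and summed. The shipped tables score
both 4-level ordinal axes 1/2/3/4 and band the sums 2–3 / 4–5 / 6–7 / 8
into very low / low / medium / high. The exact published cell values are
not available, so these defaults were chosen as the simplest tables
satisfying every documented constraint — additive scoring, four ordered
priority levels, monotone in each axis, best pair anchored to *very
low*, worst pair anchored to *high* — and they are configuration
(`scoring:` in the YAML), not code. `risk_matrix()` validates any
override at load: all 16 condition × disturbance pairs must be covered
by exactly one band, priorities must be non-decreasing along each axis,
endpoints must anchor, and scores must strictly increase along each
ordinal scale. Malformed matrices are rejected outright rather than
clamped, on the view that a silently repaired scoring table is worse
than a loud failure.

The quantitative 1–10 condition rating is captured and exported but
excluded from the score: the documented algorithm sums the qualitative
condition and disturbance values only. Keeping the rating as data costs
nothing and preserves a finer-grained condition measure for
epidemiologic use; a test asserts it can never move the priority.

Each priority level maps to one fixed recommendation, in severity order
from "Monitor and no immediate action necessary" to "Consult an asbestos
professional for removal, disposal and replacement of the ACM."
Renderers tag priorities with a documented colour code (very low =
green, low = yellow, medium = orange, high = red).

## Reports and aggregation

A report contains one result per material *presented* on the session's
pathway — skipped materials (e.g. the inside module of an abbreviated
session) yield no row, as distinct from present-but-unlikely materials,
which yield a row without a priority. Report identifiers default to a
content hash of the instrument identity plus the answers, so identical
sessions produce identical reports; timestamps (ISO-8601 UTC) are the
one deliberately non-deterministic field and are excluded from all
determinism checks. The store is a single JSON document — portable,
diff-able, and exactly round-tripping — and `aggregate_survey()` reduces
it to the survey-level counts whose conservation laws (per-material
category counts sum to houses assessing the material; priority counts
sum to triggered assessments) the tests verify on simulated surveys.

## The synthetic housing stock

`housing_stock_model()` defines the generative model used for end-to-end
testing and survey simulation. Generation is *pathway-aware*: answers
are sampled question by question while replaying the engine, never as an
unconditional table, so every synthetic answer set is
branching-consistent by construction and doubles as a fuzzing surface
for the engine. A single master seed plus counter-based per-household
seed splitting makes any `(model, index)` pair reproducible in
isolation, and the caller's RNG state is left untouched.

The defaults sketch an older Australian stock: 45% of dwellings built
before 1985, 15% in 1985–1990, 30% after 1990, 10% unknown; structural
locations present in 95% of houses, with fences (60%/35% for
pre/post-1990 stock), outbuildings (40%/25%) and fixed heater flues
(30%/10%) optional; pre-1990 houses mostly retaining original materials
(55% original, 25% unknown history); visual classes at 40/35/25%
non-ACM/ambiguous/suggestive; conditions 40/30/20/10% from good to very
poor with the 1–10 rating drawn around per-level centres (9/7/4/2) with
unit jitter; disturbance 40/30/20/10% from unlikely to highly likely.
These are illustrative round numbers of the right order for an older
suburb, chosen once for the study conditions; they are not calibrated to
any housing census, and nothing in the package's correctness depends on
them.

What the simulator emulates is the *response structure* — periods,
presence, histories, visual classes, conditions — under conditional
independence given the construction period. Real housing stocks are
spatially clustered, correlated across materials within a house (a
neglected house is neglected everywhere), and full of answer styles
(digit preference, "don't know" inflation) that the model does not
attempt. Passing tests therefore demonstrate that the pipeline is
correct and its invariants hold under realistic volumes, not that the
default aggregates resemble any particular real survey.

One convergence check closes the loop analytically: for a single
material, the exact category distribution implied by pushing the model's
probabilities through the decision table is computed by enumeration and
compared with the empirical distribution of a 400-house simulated
survey, within three binomial standard errors per category.

## Numerical and engineering choices

* Rule precedence is declaration order, first match wins; no match falls
  through lexically. Decision-table totality is enforced structurally
  (final unconditional rule) at validation.
* Structural defects that make a definition unusable (unknown schema
  version, dangling references) are load-time errors naming the
  offending identifier; every other invariant violation is a *finding*
  from `validate_instrument()`, so a broken instrument can still be
  inspected. Sessions refuse to start on an instrument with findings.
* Probability vectors in the stock model must sum to 1 within 1e-9.
* Corrupt persistence files (truncated JSON, wrong document shape) raise
  explicit corruption errors; stores never load partially.
* Test problem sizes: exhaustive factor-space enumeration runs all
  1,248 combinations across the thirteen materials; engine/path-oracle
  comparisons enumerate every answer assignment on 3-question toys;
  survey properties use 500 houses for count conservation, 200 twice for
  seed determinism, and 400 for the convergence check. The full suite
  runs in about a minute on one core.

## Limitations

The screen inherits the limits of any visual inspection: it cannot
capture every historical use of asbestos, it cannot confirm asbestos
content (only sampling and laboratory analysis can), and its decision
cells — faithful to every documented constraint — remain a
reconstruction wherever the original cells were never published. The
jurisdictional constants (1985/1990, the material lists, the
recommendations) are Australian; adapting the instrument file, not the
code, is the intended route to other countries.
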