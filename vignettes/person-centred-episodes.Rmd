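---
title: "Person-centred episodes of care: model, conventions, and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Person-centred episodes of care: model, conventions, and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pcekit)
library(data.table)
```

## The problem

Health-system spending is heavily concentrated: the top 5% of users account
for a large majority of publicly funded expenditures. Sector-by-sector
accounting (hospital budgets, physician billings, drug plans) obscures what
that spending *is* from the patient's point of view: a hip fracture is an
ambulance, an acute admission, a rehabilitation stay, home care, and a trail
of physician visits and prescriptions, spread across five payment silos.

`pcekit` implements a person-centred episode (PCE) methodology for linked
administrative encounter records. An episode is anchored on an admission to an
acute care setting and persists through subsequent institutional care until
the person has been back in the community for a full stabilization window
(default 30 days) with no institutional contact. Community services delivered
during the episode span are attached to it. Each episode is classified into
one of twelve mutually exclusive clinical groupings from the anchor admission,
and every dollar in the input is accounted for as either inside some episode
or explicitly remaining outside — an exact-conservation ledger per sector.

The intended users are health-services researchers and system planners
working with claims-like extracts (one costed row per encounter), for
example when designing bundled-payment or quality-monitoring schemes around
episodes rather than sectors.

## Episode construction

Encounters belong to a fixed 15-sector vocabulary (`pce_sectors()`). Eight are
*institutional* (admitted/facility-based) and can extend an episode; seven are
*community* (point-in-time services) and attach by date. Four sectors can
*anchor* an episode: inpatient acute care, same-day surgery, designated
inpatient mental health, and — configurably — the emergency department.

The builder scans each person's institutional encounters in time order
(ties broken by discharge date, sector priority, encounter id):

1. The first unconsumed acute-start admission opens an episode; the window end
   is its effective discharge plus `window_days`.
2. Any institutional encounter (except `inpatient_nonacute`, see below)
   admitted **on or before** the window end is absorbed, and the window end
   advances to `max(window end, its effective discharge + window_days)`.
3. When the next institutional admission falls beyond the window end, the
   episode closes; its end date is `final discharge + window_days`, censored
   at death and study end.

All arithmetic is in whole days with closed intervals: a readmission gap of
exactly `window_days` chains, `window_days + 1` does not, and both the
generator and the builder share this single boundary convention. Effective
discharge is `min(discharge, study_end, death_date)`, with a missing discharge
read as "still admitted at study end". Same-day transfers (admit equal to the
prior discharge) chain; overlapping stays chain and can extend the window
beyond the stay that admitted them (the max rule in step 2).

Institutional encounters not reachable from an anchor (for example a
long-term-care admission with no preceding acute care) are returned
*unallocated*, as is every `inpatient_nonacute` stay: that sector neither
anchors, extends, nor joins episodes. Episodes still open at study end are
kept and censored rather than dropped — discarding them would silently lose
their costs from the conservation ledger.

Community encounters whose service date falls in the closed span
`[anchor admit, episode end]` of an episode of the same person attach to it.
This includes dates in gaps *between* chained institutional stays: the episode
is a single span of elevated need, and care in a readmission gap belongs to
it just as the post-discharge tail does. (The methodology's published
description states the tail explicitly; mid-episode inclusion follows from
span attribution and is our design choice.)

```{r episode-demo}
cfg <- study_config()
enc <- data.frame(
  encounter_id = c("A1", "R1"), person_id = "P1",
  sector = c("inpatient_acute", "inpatient_rehab"),
  admit_date = as.Date(c("2010-05-01", "2010-06-04")),
  discharge_date = as.Date(c("2010-05-05", "2010-06-10")),
  cost = c(9000, 12000), mrd_code = "FRC031", dx_codes = "",
  admission_type = "unplanned", service_type = "medical",
  provider_id = NA, ambulatory_flag = FALSE
)
per <- data.frame(person_id = "P1", age_at_index = 81, sex = "female",
                  rurality_score = 12, primary_care_model = "fee_for_service",
                  drug_benefit_eligible = TRUE, death_date = as.Date(NA),
                  ltc_resident_at_index = FALSE, palliative_flag = FALSE,
                  morbidity_adg_count = 9, prior_year_drug_count = 11)
built <- build_episodes(enc, per, cfg)
built$episodes[, .(episode_key, start_date, final_discharge_date, end_date, n_institutional)]
```

The rehabilitation admission on June 4 is exactly 30 days after the May 5
discharge, so it chains; one day later it would not, and — because
rehabilitation cannot anchor — it would be unallocated.

## Clinical classification

Each episode is classified once, from its anchor encounter, by the first
matching rule in rank order: (1) pregnancy and (2) perinatal/congenital/low
birth weight, by most responsible diagnosis (MRD) prefix; (3) post-admission
events, triggered by *any* diagnosis flagged as arising after admission,
irrespective of the MRD but assessed only after ranks 1–2; (4) trauma,
accidents, injuries and poisonings, matched against *all* diagnosis codes on
the anchor, not only the MRD; (5) mental illness and addictions, by
mental-health facility or MRD; (6) ambulatory care sensitive conditions and
(7) cancer, by MRD; (8–11) the admission-type × service-type quadrants
(planned/unplanned × surgical/medical); (12) other causes.

Three consequences worth noting:

* the function is total — a missing MRD falls through to the
  admission/service-type rules (and is counted in a message), a design choice
  where the published methodology is silent;
* permuting the order of secondary diagnoses can never change the result;
* outpatient-oncology costs attached to an episode are *tallied* under the
  Cancer grouping in the grouping-by-sector cost breakdown
  (`grouping_sector_costs()`) without reclassifying the episode, reflecting
  that oncology treatment visits are cancer spending regardless of what
  anchored the episode.

Code-to-category mapping is a configurable prefix map (`read_code_map()`).
The bundled default is deliberately synthetic (`PRG`, `TRM`, `CAN`, ...):
real deployments substitute their jurisdiction's ICD lists; the hierarchy
logic is independent of the lists' content.

## Costs, conservation, and the ledger

Money is held in integer cents internally; every report renders dollars. The
allocation ledger (`allocate_costs()`) guarantees, exactly and on every run,
that per sector and overall

\[
\text{allocated} + \text{remaining} = \text{total encounter cost},
\]

to the cent. Per-diem stays (long-term care, complex continuing care) carry
one row per stay with the total stay cost; when such a stay extends past the
episode end (censoring at death or fiscal year end), the episode receives
`cost × days inside / stay days`, rounded to cents, and the remainder stays
on the unallocated side — the one case where a single encounter's cost is
split.

Percentages in all report tables are rounded half away from zero to one
decimal (`share_percent()`, `allocation_percent()`), matching the convention
of published summary tables; base R's round-half-to-even would print 94.95 as
94.9.

## High-cost cohort and characteristics

Person-level annual costs are summed over all sectors. The cohort threshold
is the configured percentile (default 95) of person totals; selection is
strictly greater-than, and the cohort further requires community dwelling
(not a long-term-care resident at index) and being alive at the index date.
The quantile convention is configurable (`linear_interpolation`, R type 7,
the default; or `lower_value`, type 1) because the published methodology does
not state one and its empirical threshold is not reproducible without the
source holdings. We threshold over all persons and then apply the residence
filter, following the order of the published text; the alternative
(threshold after filtering) is a one-line change in `run_pipeline()` callers.

The usual-provider-of-care (UPC) index is the share of a person's ambulatory
visits made to their most-visited provider, defined only for persons with at
least three such visits; 0.75 or more denotes high continuity. Persons with
one or two visits ("insufficient") are merged into the low-continuity display
bin unless they had no ambulatory contact at all; both raw counts are kept in
the `upc_detail` attribute, since the published table does not state the
split. The look-back period is whatever the supplied encounter table covers —
the two-year look-back of the original design is a property of the extract,
not of the index arithmetic.

## The synthetic generator

No real administrative holdings ship with the package. The generator
(`scenario_config()`, `simulate_scenario()`) exists so that every downstream
stage is testable against *planted ground truth*: episodes are planted first
and serialized into encounters afterwards, never labelled post hoc, so the
generator's labels are an exact oracle for the builder.

What it emulates, and the defaults chosen as the study conditions:

* **Readmission chains** with inter-stay gaps uniform on 1–45 days,
  deliberately straddling the 30-day boundary so both chaining and splitting
  occur; continuation probability `p_readmit = 0.35`, at most 6 stays per
  chain; Poisson(1.2) chain starts per person, so a realistic minority of
  persons have no episode at all.
* **A 12-category grouping mix** defaulting to the episode shares reported in
  the province-wide application of the methodology (35.2% planned surgical,
  21.0% unplanned medical, 10.8% post-admission events, ...); anchor
  attributes (MRD prefix, post-admission flag, facility, admission/service
  type) are drawn so the anchor classifies deterministically into the
  intended grouping.
* **Per-sector log-normal costs** with heavier institutional than community
  tails (acute meanlog 9.2 ≈ \$13.7k mean); per-diem sectors draw a daily
  rate and multiply by stay days.
* **Community visits** at 0.4/day inside planted spans and 0.12/day outside —
  the outside rate chosen so that a substantial minority of total cost falls
  outside episodes, as in the real system where maintenance drugs, dialysis
  and oncology care dominate the unallocated side.
* **Demographics, mortality (5%/yr), drug-benefit eligibility (52%)** and a
  per-person main provider with a continuity parameter driving the UPC
  distribution.
* **Strays**: 8% of persons carry an isolated rehabilitation/LTC/non-acute
  stay with no anchor, exercising the unallocated path. Non-acute strays are
  planted only outside open chains, since that sector's window bookkeeping is
  intentionally ignored by the builder.

What it does **not** emulate: real ICD coding, seasonal admission patterns,
sector-specific cost calibration to any jurisdiction, transfers recorded as
overlapping stays (covered by crafted fixtures instead), and within-person
cost correlation beyond the episode structure. Passing tests therefore
demonstrate the *algorithmic* guarantees — exact recovery, conservation,
boundary behaviour — not epidemiological realism of any particular number.

Determinism: a scenario plus seed reproduces byte-identical person, encounter
and ground-truth files; the population and encounter stages consume `seed`
and `seed + 1` respectively.

## Validation strategy and problem sizes

The test suite checks, among others:

* exact recovery of the planted episode partition on the default scenario
  (500 persons, ~800 institutional encounters);
* agreement with an independently formulated grouper — pairwise
  within-window adjacency, Floyd–Warshall transitive closure, forward
  reachability from anchors — over 20 seeds × 100 persons;
* cent-exact conservation of the ledger on every synthetic run;
* the 30/31-day boundary fixture, the per-diem proration fixture, and the
  four classification hierarchy cases;
* property tests: partition/separation/censoring invariants, window
  monotonicity, UPC bounds, bin exhaustiveness, and grouping-mix recovery
  within three binomial standard errors at 2,000 persons.

These sizes keep the full suite under a minute on one CPU while giving the
closure oracle thousands of encounters to disagree on (it never does).

Published aggregate tables from the province-scale application (587,982
persons; 697,059 episodes) are bundled as `reference_table()`. Their role is
arithmetic, not empirical: the package's share/percent operations must
reproduce each table's derived column from its printed counts to within the
printed precision. Two rows of the source are internally inconsistent (the
family-health-team count implies 18.9%, not the printed 17.9%; the
physician+laboratory allocation row implies 60.7%, not 60.4%) and are
asserted at our recomputed values, documented here rather than silently
tolerated.

## Numerical choices and degenerate inputs

* Quantiles: linear interpolation (type 7) throughout the summaries; the
  generator/oracle consistency mattered more than the source's unstated
  choice.
* Rounding: half away from zero at one decimal for percents; costs rounded
  to cents at sampling and summation boundaries.
* Ties in the scan order: admit date, then discharge (open stays last), then
  sector vocabulary order (acute-start sectors first), then encounter id —
  so an acute admission and a rehabilitation admission on the same day
  anchor/extend deterministically.
* Death before an encounter's discharge censors the effective discharge; a
  death date earlier than an admission is floored so intervals stay valid.
* Empty inputs (zero persons, header-only files, empty groupings) produce
  empty-but-valid tables, never errors.

## Known limitations

* The builder is a per-person sequential scan in R; at hundreds of thousands
  of persons one would chunk by person batches or port the scan to C++. The
  design (sorting plus a single pass) is linear after the sort.
* The emergency-department question is exposed, not resolved: the published
  methodology lists the ED among episode-starting settings yet reports only
  56.7% of ED costs allocated, which those settings' definitions cannot
  jointly produce. `ed_starts_episode` defaults to `TRUE` (the stated
  definition) and may be set `FALSE` to explore the alternative.
* Costs are taken as given per encounter; resource-intensity weighting,
  morbidity grouping (ADG counts) and rurality scoring are inputs, not
  computations, here.
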