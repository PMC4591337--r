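---
title: "Model and methods: nurse-led continence care cost-effectiveness"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Model and methods: nurse-led continence care cost-effectiveness}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(contcea)
```

## Scope and structure

`contcea` models urinary-incontinence (UI) care for community-dwelling
people aged 65+ with four or more chronic diseases, comparing usual Dutch
primary care with a pathway led by a continence nurse specialist (NS)
placed in the GP practice. The model is a decision tree feeding a
three-state Markov cohort process:

* **Decision tree** — detection (GP, or GP+NS), initial assessment
  (GP/pelvic physiotherapist, or NS), treatment strategy (treatment for
  cure alongside containment; containment only; self-management; never
  detected).
* **Markov process** — health states *incontinent*, *improvement* (at
  least 50% fewer episodes) and *success* (continent), in 3-month cycles
  over 3 years (12 cycles). Success is absorbing; improvement never
  reverts to incontinence within the horizon. Patients who are never
  detected, containment-only or self-managing stay incontinent.

The cure pathway tracks compound states (provider lane x treatment phase
x health state): GP treatment mixes (medication 79%, lifestyle advice
17%, UTI treatment 4%), the NS initial behavioural programme (three
consultations) followed by medication for failures who continue (40%),
physiotherapy (PFMT 95%, with biofeedback 5%), and specialist care
(surgery 17%, conservative 2%, medication 81%), with second-cycle
medication (76% of users) and a second training cycle for improved
trainees. Failures are referred onward (GP failures: 51%, split 57/43 to
physiotherapist/specialist; physiotherapist failures all referred 33/67
to GP/specialist; specialist failures return to primary care; NS
failures: 60% referred 33/67); failures who are not referred stop active
treatment and keep insured containment.

## Timing conventions

Patients occupy their start-of-cycle state for the full cycle: costs and
QALYs are booked at full cycle occupancy with no half-cycle correction
(none is warranted at a 3-month cycle length over 3 years), and treatment
during cycle *t* changes the state from cycle *t+1*. Referral consumes no
extra cycle; mass redirected inside the specialist node (40% to
physiotherapy before treatment, for patients without prior PFMT) is
treated in the same cycle. Nothing is discounted: the analysis uses a
zero rate over its 3-year horizon.

## Structural choices where the evidence tables are silent

The input tables fix transition probabilities but not every piece of
pathway wiring. Three choices were genuinely open; they were fixed once
by anchoring to the published intermediate quantities (the derived
prevalent-cohort distribution, the outcome shares and the per-patient
incremental results), and are not runtime options:

1. **Referral timing.** The GP's immediate-referral split (51%; 57/43)
   takes effect for patients whose first GP treatment attempt fails,
   rather than diverting mass before any attempt. This reproduces the
   derived prevalent distribution (never-detected 62.3% vs the published
   62.8%, containment 36.4% vs 36.0%) and the incremental results; the
   cost is that cumulative incident success under usual care computes to
   5.5% where the published outcome table prints 9% (the incremental
   outcomes, which drive costs and QALYs, match within tolerance).
2. **NS improvers.** Patients improved after the NS's initial behavioural
   programme receive one continuation training cycle at the second-cycle
   training effectiveness (46% improvement / 54% success). Without it the
   new-care incident success share falls about two points short of the
   published 14%; with indefinite repetition it overshoots.
3. **Medication and training continuation are single second cycles** —
   the evidence rows are explicitly labelled "second cycle" and
   "cycle 3"; improvement is retained afterwards without further
   conversion.

## The prevalent cohort

Prevalent patients are already distributed along the pathway. Their
starting allocation is derived, not assumed: the incident model runs for
one year (4 cycles) under usual care; the mass whose treatment succeeded
(success *plus* improvement, about 16% — matching the published "16 of
100 patients" removed) leaves the pathway; the remainder is renormalized
over never-detected (including patients who failed out of active
treatment), treatment-for-cure (still active, split in equal thirds over
GP/physiotherapist/specialist), containment-only and self-management.
Under new care the NS additionally detects 14 percentage points of the
never-detected pool at model start (allocated 39/61 to cure/containment)
and re-engages self-managers into the cure pathway.

## Costing

Costs (2013 euros) accrue per cycle from two sources. *State-based*:
containment pads (€97.70 incontinent / €71.22 improved / €0 success per
cycle; insured for detected patients, out-of-pocket for never-detected
and self-managers), adverse events applied to all non-success mass
(UTI 30.3%/year excess -> 7.575% per cycle x €2.51; fractures 0.41% falls
x 5.7% fracture-given-fall = 0.023% per cycle x €2,944.36; skin damage 8%
x €6.49), formal home care (47% of patients; €3,859.38 per cycle at
failure, reduced 10% on improvement and 25% on success) and informal care
(43%; €2,128.99, same reductions). *Activity-based*: consultations (GP
€30.48, NS €41.39 — a pro-rated €29.05/h wage from a €44,736 annual
salary over 1,540 workable hours —, physiotherapist €39.19, specialist
€130.62), therapies (medication €114.96 in primary care / €317.16 at the
specialist, PFMT €205.73, biofeedback €216.23, surgery €317.97,
conservative €137.74), and travel per visit (€3.51 / €13.94 / €4.79).
The NS initial programme books three consultations.

Implementation of the new pathway costs €426,496 per year at the
base-case attribution share (23.8% of the national NS training cost);
divided by the yearly patient pool (58,306 prevalent + 25,872 incident)
this is €5.07, booked once per patient in the new arm — the convention
that reproduces the published per-patient table. The budget-impact
projection instead books the full annual amount nationally each year.

The payer perspective sums consultations/therapies, insured containment,
adverse events, formal home care and implementation; the societal
perspective adds travel, out-of-pocket containment and informal care.

## Sensitivity analyses

**One-way (tornado):** every non-structural scalar is set to mean ± 40%
(probabilities capped at one; other members of a branch group rescaled to
the remaining mass; improvement+success outcome pairs rescaled when a
perturbation pushes their sum above one), and the per-patient model is
rerun. At every endpoint the societal incremental cost stays negative.

**Probabilistic:** parameters bounded to [0,1] take beta distributions
with mean at the base value and SE equal to 20% (or 40%) of the mean,
with method-of-moments shapes (`a+b = m(1-m)/s² − 1`); when the requested
variance is infeasible the SD is clamped to 95% of the feasible maximum.
Costs vary uniformly on mean ± 20% (40%). Branch groups are renormalized
after sampling. Two quantities are sampled as *constructed contrasts*
rather than independently:

* the NS's extra detection among prevalent cases equals the sampled gap
  between new-care and usual-care detection (floored at zero, rescaled to
  the 14-point base case), so detection uncertainty propagates coherently
  to both cohorts;
* the success utility equals the failure utility plus a sampled
  continence decrement (0.0349): both utilities come from the same
  survey, and it is their contrast, not their levels, that carries the
  health gain. Sampling the two utilities independently at SE = 20% would
  make the sign of the decrement essentially random, which contradicts
  every reported uncertainty result.

With this structure the model reproduces the published uncertainty
profile at both SE levels (probability of societal cost savings ≈ 97% vs
96% published at SE 20% and ≈ 81% vs 80% at SE 40%, with matching
dominance and QALY-loss probabilities), which the tests check at the
published tolerance.

## Scenarios

* `full_implementation` — the whole training cost is attributed to the
  modelled population (share 100% instead of 23.8%); a pure parameter
  change.
* `detection_only` — the NS detects and assesses (consultations at the
  NS tariff, implementation cost included, 64% incident detection and
  +14 points prevalent) but delivery and effectiveness are those of the
  usual pathway; newly detected prevalent cases follow the usual-care
  cure/containment split and self-managers are not re-engaged. This
  reproduces the published societal saving and QALY gain. The published
  *payer* increase (+€58) is about twice what this reconstruction yields
  (+€31), so the payer ICER computes to roughly €10,300/QALY against the
  published €14,500/QALY: the original analysis evidently loaded more
  NS delivery cost into this scenario than its description specifies. The
  alternative reading — full NS delivery costed while only the outcome
  probabilities revert to GP values — was implemented and measured during
  development and collapses into the base case (the GP composite outcome
  is improvement-heavy and the continuation rules convert improvement to
  success), matching none of the published scenario results.
* `effectiveness_only` — NS-led treatment retained, detection at the
  usual-care level with no extra prevalent detection.

ICERs classify dominance (`Δcost ≤ 0` and `ΔQALY ≥ 0`, not both zero),
dominated and equivalent cases and report `Δcost/ΔQALY` only where
defined.

## Synthetic data and the microsimulation oracle

Two inputs the analysis takes from external sources are generated
synthetically, and are **not** real national data:

* `generate_life_table()` — a Gompertz-type curve `q(age) = q65 ·
  exp(slope · (age − 65))` by 5-year band and sex (male excess 1.5, base
  `q65` 0.025, slope 0.085/year, seeded level jitter), giving yearly
  death probabilities around 4–20% across bands, plausible for a
  multimorbid elderly population. Budget impact computed from it is
  indicative — sign and order of magnitude — only.
* `build_demography()` — a synthetic age pyramid with the 23/77 male/female
  split of the prevalent cases and a 4%/year nursing-home admission rate;
  attrition applies at year boundaries, uniformly across pathway states,
  and exits accrue no further costs.

`microsim_oracle()` re-implements the whole pathway at the individual
level — one random draw per decision node per patient, none of the cohort
engine's code — so the cohort occupancies can be checked against an
independent implementation at Monte-Carlo precision. The tests compare
the two on the base case (100,000 patients, 3-SE bound) and on 20
randomized valid parameter sets (20,000 patients each; 4-SE
per-comparison bound, appropriate for 60 simultaneous comparisons).
`generate_random_parameter_set()` draws valid but deliberately extreme
sets (probabilities uniform on [0,1], costs log-scattered) to exercise
mass conservation and the engine invariants far from the base case.

What passing these tests shows — and does not show: the deterministic
engine and the microsimulation agree as distributions over the *modelled*
pathway; none of this validates the pathway against real patients, real
detection behaviour or real relapse.

## Numerical choices and problem sizes

Cohort propagation is exact (closed-form flows on unit mass; mass
conservation enforced at 10⁻⁹ per cycle). The per-cycle UTI probability
uses the yearly excess divided by four (7.575%, the printed value being
the rounded 8%); a settings switch can force the rounded figure.
Equal thirds for the prevalent provider split are exact 1/3's. The test
suite uses 1,000 PSA draws at SE 20% (the published design), 100,000
microsimulated patients for the base-case comparison and 20,000 per
random set, sizes at which every check runs in seconds on one CPU.

## Known limitations

* No relapse from success or improvement, and no mortality inside the
  3-year per-patient model (mortality enters only the budget-impact
  attrition) — both inherited from the analysis design.
* No patient heterogeneity (age, sex, UI subtype or severity) inside the
  cohort engine; faecal incontinence is out of scope.
* The current-care incident success share computes below the published
  outcome table (5.5% vs 9%) under the wiring that reproduces the
  published incremental results and derived prevalent distribution; the
  two published quantities could not be reconciled under any wiring
  examined.
* Budget impact depends on the synthetic life table and on the full
  prevalent pool (202,126); only sign and order of magnitude are
  meaningful.
* The detection-only scenario's payer-perspective cost increase is not
  fully reconstructible (see Scenarios above).
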