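# contcea

A decision-analytic cost-effectiveness model of nurse-led continence care
in Dutch primary care.

## The problem

Urinary incontinence (UI) in community-dwelling elderly with multiple
chronic diseases is common, under-detected and under-treated. Care is
costly — mostly through containment pads, formal home care and informal
care — and effective first-line treatment is often never offered because
patients do not raise the problem with their GP. `contcea` models the
consequences of placing a **continence nurse specialist (NS)** in the GP
practice: the NS actively detects cases, performs the initial assessment,
delivers first-line treatment (behavioural training, medication) and
refers failures onward to pelvic physiotherapy or specialist care.

The package is aimed at health-economic modellers: every input is a named
parameter with a provenance tag and a distribution for sensitivity
analysis, every result is recomputed from those inputs, and an independent
individual-level microsimulation cross-validates the cohort engine.

## The model

A decision tree allocates each cohort over *detection -> initial
assessment -> treatment strategy* (treatment for cure alongside
containment; containment only; self-management; never detected). Patients
treated for cure enter a Markov process over three health states —
incontinent, improvement (≥50% fewer episodes) and success (continent) —
in cycles of 3 months over a 3-year horizon (12 cycles):

- state occupancy `x_{t+1} = T_t(θ) x_t`, where the one-cycle transition
  is built from provider-specific treatment mixes and outcome
  probabilities (GP: medication/lifestyle/UTI treatment; NS: behavioural
  programme then medication; physiotherapist: PFMT ± biofeedback;
  specialist: surgery/medication/conservative), continuation rules
  (second-cycle medication, second training cycle) and referral rules for
  failures. Success is absorbing; improvement never reverts.
- QALYs: `Q = Σ_t 0.25 · Σ_s x_t(s) · u(s)` with `u = (0.8246, 0.84205,
  0.8595)` for incontinent/improvement/success; no discounting over the
  3-year horizon.
- Costs per cycle = state-based costs (pads, adverse events, formal and
  informal home care) + activity-based costs (consultations, therapies,
  travel), accumulated per category and reported from the health-care
  payer and the societal perspective.
- The prevalent cohort's starting allocation is derived by running the
  incident model for one year, removing the successfully treated mass and
  renormalizing; national budget impact adds yearly incident inflow with
  mortality and nursing-home attrition.
- Uncertainty: one-way sensitivity (±40%), probabilistic sensitivity
  analysis (beta distributions with SE = 20% or 40% of the mean for
  [0,1]-bounded parameters, uniform ±20%/40% for costs), scenario analyses
  and ICERs with dominance classification.

## Worked example

```r
library(contcea)
ps <- base_case_parameters()   # the complete published base case
per_patient_results(ps)
```

```
Costs and QALYs per patient over 3 years (euro; QALYs unrounded)
                  quantity    current        new difference
                     gp_ns    15.0000    32.0000    17.0000
                       ppt     4.0000    13.0000     9.0000
                specialist     3.0000    23.0000    20.0000
       containment_insured   448.0000   568.0000   120.0000
            adverse_events    17.0000    16.0000    -1.0000
          formal_home_care 21626.0000 21352.0000  -274.0000
            implementation     0.0000     5.0000     5.0000
                    travel     1.0000     3.0000     2.0000
 out_of_pocket_containment   698.0000   522.0000  -176.0000
             informal_care 10914.0000 10776.0000  -138.0000
          total_healthcare 22113.0000 22009.0000  -104.0000
            total_societal 33726.0000 33311.0000  -416.0000
                     qalys     2.4768     2.4823     0.0055
```

Per mixed (prevalent + incident) patient over 3 years, nurse-led care
saves about €416 from the societal perspective and €104 from the payer
perspective while gaining 0.0055 QALYs — it *dominates* usual care:

```r
outcome_summary(run_cohort("new", "incident", ps))
#> success 14.7% | improved 9.7% | not improved 75.6%

inc <- incrementals(per_patient_results(ps))
icer(inc$delta_cost_societal, inc$delta_qalys)
#> dCost -415.53, dQALY 0.00545 -> dominant
```

The costs are dominated by formal home care (~€21.6k) and informal care
(~€10.9k); the saving comes from patients who reach improvement or
success and therefore need less of both, while insured containment cost
rises (newly detected patients shift pad costs from out-of-pocket to the
insurer). Sensitivity and scenario analyses:

```r
one_way_sensitivity(ps, range_frac = 0.4)        # tornado, all endpoints cost-saving
probabilistic_sensitivity(ps, n_draws = 1000, se_frac = 0.2, seed = 42)
run_scenario("full_implementation", ps)          # 100% of training costs
project_budget_impact(ps, build_demography(generate_life_table(seed = 1)))
```

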