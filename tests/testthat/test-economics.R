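test_that("a two-cycle one-lane cohort matches the hand-expanded costs", {
  ps <- one_lane_ps()
  tr <- run_cohort("current", "incident", ps, horizon = 2)
  cm <- cycle_cost_matrix(tr, ps)

  # independent spreadsheet-style expansion with the printed unit costs:
  # cycle 1: everyone incontinent, assessed by the GP and given medication
  ae_rate <- (0.303 / 4) * 2.51 + (0.0041 * 0.057) * 2944.36 + 0.08 * 6.49
  expect_equal(unname(cm[1, "gp_ns"]), 30.48 + 30.48 + 114.96)
  expect_equal(unname(cm[1, "travel"]), 2 * 3.51)
  expect_equal(unname(cm[1, "containment_insured"]), 97.70)
  expect_equal(unname(cm[1, "out_of_pocket_containment"]), 0)
  expect_equal(unname(cm[1, "adverse_events"]), ae_rate)
  expect_equal(unname(cm[1, "formal_home_care"]), 0.47 * 3859.38)
  expect_equal(unname(cm[1, "informal_care"]), 0.43 * 2128.99)
  expect_equal(unname(cm[1, "ppt"]), 0)
  expect_equal(unname(cm[1, "specialist"]), 0)

  # cycle 2: 16% cured, 63% improved (76% of whom continue medication),
  # 21% failed out of treatment and keep insured pads
  q <- 0.63 * 0.76
  expect_equal(unname(cm[2, "gp_ns"]), q * (30.48 + 114.96))
  expect_equal(unname(cm[2, "travel"]), q * 3.51)
  expect_equal(unname(cm[2, "containment_insured"]), 0.21 * 97.70 + 0.63 * 71.22)
  expect_equal(unname(cm[2, "adverse_events"]), (1 - 0.16) * ae_rate)
  expect_equal(unname(cm[2, "formal_home_care"]),
               0.47 * (0.21 * 3859.38 + 0.63 * 3859.38 * 0.9 +
                         0.16 * 3859.38 * 0.75))
  expect_equal(unname(cm[2, "informal_care"]),
               0.43 * (0.21 * 2128.99 + 0.63 * 2128.99 * 0.9 +
                         0.16 * 2128.99 * 0.75))

  expect_equal(unclass(cost_vector(tr, ps)), colSums(cm))
  expect_equal(unclass(cycle_cost_vector(tr, 2, ps)), cm[2, ])

  expect_equal(total_qalys(tr, ps),
               0.25 * 0.8246 +
                 0.25 * (0.21 * 0.8246 + 0.63 * 0.84205 + 0.16 * 0.8595))
})

test_that("cured patients generate no containment or adverse-event costs", {
  ps <- ps_set(one_lane_ps(), gp_meds_success = 1, gp_meds_improvement = 0)
  tr <- run_cohort("current", "incident", ps, horizon = 2)
  cm <- cycle_cost_matrix(tr, ps)
  expect_equal(unname(tr$occupancy[2, "succ"]), 1)
  expect_equal(unname(cm[2, "containment_insured"]), 0)
  expect_equal(unname(cm[2, "adverse_events"]), 0)
  expect_equal(unname(cm[2, "formal_home_care"]), 0.47 * 3859.38 * 0.75)
})

test_that("state-dependent care costs regenerate the printed unit costs", {
  v <- base_ps$values
  expect_equal(v[["cost_formal_improvement"]], 3473.44, tolerance = 1e-5)
  expect_equal(v[["cost_formal_success"]], 2894.53, tolerance = 1e-5)
  expect_equal(v[["cost_informal_improvement"]], 1916.09, tolerance = 1e-5)
  expect_equal(v[["cost_informal_success"]], 1596.74, tolerance = 1e-5)
})

test_that("QALY totals respect the closed-form bounds", {
  ps <- zero_effectiveness(base_ps)
  tr <- run_cohort("current", "incident", ps)
  expect_equal(total_qalys(tr, ps), 3 * 0.8246)
  for (seed in 1:8) {
    rps <- generate_random_parameter_set(seed)
    q <- total_qalys(run_cohort("new", "incident", rps), rps)
    expect_gte(q, 3 * rps$values[["utility_failure"]] - 1e-9)
    expect_lte(q, 3 * rps$values[["utility_success"]] + 1e-9)
  }
})

test_that("the societal perspective always nests the payer perspective", {
  for (seed in 1:8) {
    rps <- generate_random_parameter_set(seed)
    cv <- cost_vector(run_cohort("current", "incident", rps), rps)
    expect_gte(societal_total(cv), payer_total(cv))
  }
})

test_that("shifting self-managers to insured containment moves payer, not societal, pad costs", {
  ps_self <- base_ps
  ps_insured <- ps_set(base_ps, cur_strat_self = 0,
                       cur_strat_containment = 0.63)
  cv_a <- cost_vector(run_cohort("current", "incident", ps_self), base_ps)
  cv_b <- cost_vector(run_cohort("current", "incident", ps_insured),
                      ps_insured)
  pads <- function(cv) cv[["containment_insured"]] +
    cv[["out_of_pocket_containment"]]
  expect_equal(pads(cv_a), pads(cv_b), tolerance = 1e-9)
  expect_gt(payer_total(cv_b), payer_total(cv_a))
})

test_that("per-patient results are componentwise consistent", {
  res <- per_patient_results(base_ps)
  expect_equal(res$difference, res$new - res$current)
  cats <- c("gp_ns", "ppt", "specialist", "containment_insured",
            "adverse_events", "formal_home_care", "implementation",
            "travel", "out_of_pocket_containment", "informal_care")
  for (col in c("current", "new", "difference")) {
    comp <- res[[col]][match(cats, res$quantity)]
    expect_equal(sum(comp), res[[col]][res$quantity == "total_societal"])
  }
  payer_cats <- setdiff(cats, c("travel", "out_of_pocket_containment",
                                "informal_care"))
  expect_equal(sum(res$current[match(payer_cats, res$quantity)]),
               res$current[res$quantity == "total_healthcare"])
})

test_that("per-patient cost levels sit near the published table", {
  res <- per_patient_results(base_ps)
  g <- function(q, col) res[[col]][res$quantity == q]
  expect_equal(g("formal_home_care", "current"), 21576, tolerance = 0.02)
  expect_equal(g("out_of_pocket_containment", "current") +
                 g("travel", "current"), 700, tolerance = 0.05)
  expect_equal(g("informal_care", "current"), 10889, tolerance = 0.02)
  expect_equal(g("qalys", "current"), 2.4777, tolerance = 0.002)
  expect_equal(g("containment_insured", "current"), 436, tolerance = 0.1)
})

test_that("implementation cost per patient matches the national arithmetic", {
  expect_equal(implementation_cost_per_patient(base_ps), 426496 / 84178)
  ps_full <- base_ps
  ps_full$settings$implementation_share <- 1
  expect_equal(implementation_cost_per_patient(ps_full),
               426496 / 0.238 / 84178)
  expect_error(implementation_cost_per_patient(base_ps, population = 0),
               "positive")
})
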