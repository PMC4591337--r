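zero_attrition_demo <- function() {
  lt <- generate_life_table(seed = 1)
  lt$q_yearly <- 0
  build_demography(lt, nursing_home_rate = 0)
}

test_that("with zero attrition the budget equals population-scaled per-patient costs", {
  demo <- zero_attrition_demo()
  bi <- project_budget_impact(base_ps, demo, years = 1,
                              cohorts = "prevalent")
  tr <- run_cohort("current", "prevalent", base_ps)
  cm <- cycle_cost_matrix(tr, base_ps)
  n <- ps_get(base_ps, "n_prevalent_national")
  expected <- n * colSums(cm[1:4, ])
  expect_equal(bi$current[bi$perspective == "societal"],
               societal_total(structure(expected, class = "ui_costs")))
  expect_equal(bi$current[bi$perspective == "payer"],
               payer_total(structure(expected, class = "ui_costs")))
})

test_that("national and per-patient incrementals agree in sign", {
  demo <- build_demography(generate_life_table(seed = 1))
  bi <- project_budget_impact(base_ps, demo)
  inc <- incrementals(per_patient_results(base_ps))
  expect_equal(sign(bi$incremental[bi$perspective == "societal"]),
               sign(inc$delta_cost_societal))
  expect_equal(sign(bi$incremental[bi$perspective == "payer"]),
               sign(inc$delta_cost_payer))
})

test_that("faster nursing-home exit shrinks totals and the incremental", {
  lt <- generate_life_table(seed = 1)
  totals <- lapply(c(0, 0.04, 0.08), function(nh) {
    project_budget_impact(base_ps, build_demography(lt,
                                                    nursing_home_rate = nh))
  })
  soc <- vapply(totals, function(b) b$current[b$perspective == "societal"],
                numeric(1))
  incs <- vapply(totals,
                 function(b) abs(b$incremental[b$perspective == "societal"]),
                 numeric(1))
  expect_true(all(diff(soc) < 0))
  expect_true(all(diff(incs) < 0))
})

test_that("invalid death probabilities are rejected", {
  lt <- generate_life_table(seed = 1)
  lt$q_yearly[3] <- 1.4
  expect_error(build_demography(lt), "outside")
})

test_that("demography files round-trip through CSV", {
  demo <- build_demography(generate_life_table(seed = 2))
  path <- tempfile(fileext = ".csv")
  on.exit(unlink(path))
  utils::write.csv(as.data.frame(demo), path, row.names = FALSE)
  demo2 <- read_demography(path)
  expect_equal(demo2$q3, demo$q3)
  expect_equal(sum(demo2$weight), 1)
})
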