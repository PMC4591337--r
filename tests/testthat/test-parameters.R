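test_that("base case holds the published input values", {
  ps <- base_ps
  expect_equal(ps_get(ps, "detection_incident_current"), 0.504)
  expect_equal(ps_get(ps, "detection_incident_new"), 0.64)
  expect_equal(ps_get(ps, "utility_success"), 0.8595)
  expect_equal(ps_get(ps, "utility_failure"), 0.8246)
  expect_equal(ps_get(ps, "cost_pads_failure"), 97.70)
  expect_equal(ps_get(ps, "cost_consult_ns"), 41.39)
  expect_equal(ps_get(ps, "cost_implementation_annual"), 426496)
  expect_error(ps_get(ps, "no_such_parameter"), "unknown parameter")
})

test_that("the packaged base case passes validation", {
  rep <- validate_parameter_set(base_ps)
  expect_s3_class(rep, "ui_validation")
  expect_identical(nrow(rep), 0L)
})

test_that("validation flags broken branch sums, domains and missing names", {
  ps <- ps_set(base_ps, gp_mix_meds = 0.9, gp_mix_lifestyle = 0.17,
               gp_mix_uti = 0.04)
  rep <- validate_parameter_set(ps)
  expect_true(any(rep$rule == "branch sum != 1" & rep$where == "gp_mix"))

  ps2 <- base_ps
  ps2$values[["utility_success"]] <- 1.2
  rep2 <- validate_parameter_set(ps2)
  expect_true(any(grepl("out of \\[0,1\\]", rep2$rule) &
                    rep2$where == "utility_success"))

  ps3 <- base_ps
  keep <- setdiff(names(ps3$values), "gp_meds_improvement")
  ps3$values <- ps3$values[keep]
  ps3$meta <- ps3$meta[ps3$meta$name %in% keep, ]
  rep3 <- validate_parameter_set(ps3)
  expect_true(any(rep3$rule == "incomplete set"))

  expect_match(validation_to_json(validate_parameter_set(base_ps)),
               "\"valid\": true")
  expect_match(validation_to_json(rep), "\"valid\": false")
})

test_that("cycle probabilities derive from the yearly rates", {
  v <- base_ps$values
  expect_equal(v[["uti_excess_yearly"]], 0.457 - 0.154)
  expect_equal(v[["uti_per_cycle"]], 0.303 / 4)
  expect_equal(v[["fracture_per_cycle"]], 0.0041 * 0.057)

  ps <- ps_set(base_ps, fall_per_cycle = 0)
  expect_equal(ps_get(ps, "fracture_per_cycle"), 0)

  ps2 <- base_ps
  ps2$values[["uti_yearly_oab"]] <- 1.2
  expect_error(derive_cycle_probabilities(ps2), "exceed 1")
})

test_that("the improvement utility is the mean of its neighbours", {
  expect_equal(derive_improvement_utility(0.8595, 0.8246), 0.84205)
  expect_equal(ps_get(base_ps, "utility_improvement"), 0.84205)
  expect_equal(derive_improvement_utility(0.7, 0.7), 0.7)
  expect_equal(derive_improvement_utility(1, 0), 0.5)
  set.seed(11)
  for (i in 1:50) {
    u <- sort(runif(2))
    m <- derive_improvement_utility(u[2], u[1])
    expect_true(m >= u[1] && m <= u[2])
  }
})

test_that("target population arithmetic reproduces the published counts", {
  tp <- target_population(base_ps)
  expect_identical(tp$n_incident, 25872)
  expect_identical(tp$n_prevalent, 58306)
  expect_identical(tp$n_women, 44896)
  expect_identical(tp$n_men, 13410)
  expect_equal(target_population(ps_set(base_ps,
                                        incidence_yearly = 0))$n_incident, 0)
})

test_that("config files round-trip every value exactly", {
  path <- tempfile(fileext = ".yaml")
  on.exit(unlink(path))
  ps <- ps_set(base_ps, gp_meds_improvement = 1 / 3)  # non-terminating decimal
  write_parameters(ps, path)
  ps2 <- read_parameters(path)
  expect_identical(ps2$values[names(ps$values)], ps$values)
  expect_identical(ps2$settings$horizon_cycles, ps$settings$horizon_cycles)
  expect_error(read_parameters({
    p <- tempfile(fileext = ".yaml")
    yaml::write_yaml(list(values = list(bogus_name = 1)), p); p
  }), "unknown parameter")
})

test_that("the shipped default config reproduces the base case", {
  path <- system.file("extdata", "base_case.yaml", package = "contcea")
  expect_true(nzchar(path))
  ps <- read_parameters(path)
  expect_identical(nrow(validate_parameter_set(ps)), 0L)
  expect_equal(ps$values, base_ps$values)
})

test_that("strategy allocations sum to one in any valid set", {
  for (seed in 1:10) {
    ps <- generate_random_parameter_set(seed)
    for (g in c("cur_strat", "new_strat")) {
      nms <- ps$meta$name[!is.na(ps$meta$group) & ps$meta$group == g]
      expect_lt(abs(sum(ps$values[nms]) - 1), 0.01)
    }
  }
})
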