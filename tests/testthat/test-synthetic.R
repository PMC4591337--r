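test_that("the synthetic life table is deterministic, bounded and monotone", {
  a <- generate_life_table(seed = 4)
  b <- generate_life_table(seed = 4)
  expect_identical(a, b)
  expect_true(all(a$q_yearly > 0 & a$q_yearly < 1))
  for (s in c("male", "female")) {
    expect_true(all(diff(a$q_yearly[a$sex == s]) >= 0))
  }
  c2 <- generate_life_table(seed = 5)
  expect_false(identical(a$q_yearly, c2$q_yearly))
  expect_error(generate_life_table(base_q65 = 1.2), "base_q65")
})

test_that("a flat slope gives constant mortality across ages", {
  lt <- generate_life_table(seed = 1, slope = 0)
  for (s in c("male", "female")) {
    q <- lt$q_yearly[lt$sex == s]
    expect_true(all(abs(q - q[1]) < 1e-12))
  }
})

test_that("cumulative death probabilities follow the closed form", {
  lt <- generate_life_table(seed = 3)
  demo <- build_demography(lt)
  expect_equal(demo$q3, 1 - (1 - lt$q_yearly)^3)
  expect_equal(demo$q2, 1 - (1 - lt$q_yearly)^2)
  expect_equal(sum(demo$weight), 1)
})

test_that("random parameter sets are always valid and seed-distinct", {
  vals <- list()
  for (seed in 1:20) {
    ps <- generate_random_parameter_set(seed)
    expect_identical(nrow(validate_parameter_set(ps)), 0L)
    vals[[seed]] <- ps$values
  }
  expect_false(identical(vals[[1]], vals[[2]]))
})

test_that("the microsimulation is reproducible and honours degenerate inputs", {
  a <- microsim_oracle("current", "incident", base_ps, n_patients = 1,
                       seed = 42)
  b <- microsim_oracle("current", "incident", base_ps, n_patients = 1,
                       seed = 42)
  expect_identical(a$occupancy, b$occupancy)

  ps0 <- zero_effectiveness(base_ps)
  m0 <- microsim_oracle("new", "incident", ps0, n_patients = 500, seed = 9)
  expect_equal(m0$occupancy[nrow(m0$occupancy), "success"], c(success = 0))
  expect_true(all(abs(rowSums(m0$occupancy) - 1) < 1e-12))
})

test_that("engine occupancies aggregate to unit mass", {
  agg <- aggregate_occupancy(run_cohort("new", "prevalent", base_ps))
  expect_true(all(abs(rowSums(agg) - 1) < 1e-9))
})

test_that("cohort engine and microsimulation agree on the base case", {
  for (arm in c("current", "new")) {
    ms <- microsim_oracle(arm, "incident", base_ps, n_patients = 60000,
                          seed = 17)
    agg <- aggregate_occupancy(run_cohort(arm, "incident", base_ps))
    f <- nrow(agg)
    for (state in colnames(agg)) {
      tol <- 3 * max(ms$se[f, state], 1e-4)
      expect_lt(abs(ms$occupancy[f, state] - agg[f, state]), tol)
    }
  }
})
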