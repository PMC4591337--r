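test_that("method-of-moments beta shapes reproduce the requested moments", {
  sh <- beta_moments(0.5, 0.1)
  expect_equal(unname(sh[["alpha"]] + sh[["beta"]]),
               0.5 * 0.5 / 0.1^2 - 1)  # = 24
  expect_equal(unname(sh[["alpha"]]), 12)
  set.seed(99)
  x <- rbeta(10000, sh[["alpha"]], sh[["beta"]])
  expect_equal(mean(x), 0.5, tolerance = 3 * 0.1 / sqrt(10000) / 0.5)
  expect_equal(sd(x), 0.1, tolerance = 0.05)
  # infeasible variance is clamped below the feasible maximum
  sh2 <- beta_moments(0.02, 0.5)
  expect_true(all(sh2 > 0))
})

test_that("sampled parameter sets recover their means and stay in domain", {
  set.seed(1)
  n <- 2000
  gp <- numeric(n); cost <- numeric(n)
  for (i in seq_len(n)) {
    s <- sample_parameter_set(base_ps, 0.2)
    gp[i] <- s$values[["gp_meds_improvement"]]
    cost[i] <- s$values[["cost_formal_failure"]]
    if (i <= 50) {
      bounded <- s$meta$name[s$meta$domain %in%
                               c("probability", "utility", "fraction")]
      expect_true(all(s$values[bounded] >= 0 & s$values[bounded] <= 1))
    }
  }
  expect_equal(mean(gp), 0.63, tolerance = 3 * 0.2 * 0.63 / sqrt(n) / 0.63)
  expect_equal(sd(gp), 0.2 * 0.63, tolerance = 0.05)
  expect_equal(mean(cost), 3859.38, tolerance = 0.01)
})

test_that("sampling keeps branch groups normalized and is seed-reproducible", {
  set.seed(7); a <- sample_parameter_set(base_ps, 0.4)
  set.seed(7); b <- sample_parameter_set(base_ps, 0.4)
  expect_identical(a$values, b$values)
  for (g in unique(stats::na.omit(a$meta$group))) {
    nms <- a$meta$name[!is.na(a$meta$group) & a$meta$group == g]
    expect_equal(sum(a$values[nms]), 1, tolerance = 1e-9)
  }
  expect_identical(sample_parameter_set(base_ps, 0)$values, base_ps$values)
})

test_that("PSA draws converge to the base case as the spread vanishes", {
  base_inc <- incrementals(per_patient_results(base_ps))
  psa <- probabilistic_sensitivity(base_ps, n_draws = 5, se_frac = 1e-4,
                                   seed = 3)
  expect_equal(mean(psa$draws$dcost_societal), base_inc$delta_cost_societal,
               tolerance = 0.01)
  expect_equal(mean(psa$draws$dqaly), base_inc$delta_qalys, tolerance = 0.01)
})

test_that("PSA is bitwise reproducible for a given seed", {
  a <- probabilistic_sensitivity(base_ps, n_draws = 25, se_frac = 0.2,
                                 seed = 11)
  b <- probabilistic_sensitivity(base_ps, n_draws = 25, se_frac = 0.2,
                                 seed = 11)
  expect_identical(a$draws, b$draws)
  expect_identical(a$summary, b$summary)
  expect_true(all(diff(a$summary$ci_dcost_societal) >= 0))
  expect_true(a$summary$prob_cost_saving >= 0 &&
                a$summary$prob_cost_saving <= 1)
})

test_that("a zero-range one-way analysis collapses to the base case", {
  base_inc <- incrementals(per_patient_results(base_ps))
  tor <- one_way_sensitivity(base_ps, range_frac = 0)
  expect_equal(tor$dcost_societal_low, tor$dcost_societal_high)
  expect_true(all(abs(tor$dcost_societal_low -
                        base_inc$delta_cost_societal) < 1e-6))
})

test_that("perturbing a zero-valued parameter leaves the outcome unchanged", {
  base_inc <- incrementals(per_patient_results(base_ps))
  tor <- one_way_sensitivity(base_ps, range_frac = 0.4)
  row <- tor[tor$parameter == "gp_mix_training", ]
  expect_equal(row$dcost_societal_low, base_inc$delta_cost_societal,
               tolerance = 1e-8)
  expect_equal(row$dcost_societal_low, row$dcost_societal_high)
  # ordering: results sorted by decreasing societal-cost range
  expect_true(all(diff(tor$range) <= 1e-9))
})
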