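test_that("configuration is validated", {
  expect_error(sim_config(0), class = "sepsafe_config_error")
  expect_error(sim_config(10, max_steps = 0), class = "sepsafe_config_error")
  expect_error(sim_config(10, step_hours = -1), class = "sepsafe_config_error")
  expect_error(sim_config(10, unsafe_propensity = c(A = 1.5)),
               class = "sepsafe_config_error")
})

test_that("zero unsafe propensity yields zero realized unsafe decisions", {
  sim <- generate_cohort(sim_config(
    n_stays = 150, seed = 3,
    unsafe_propensity = c(A = 0, B = 0, C = 0, D = 0)))
  expect_true(all(sim$ground_truth$unsafe == 0))
})

test_that("generation is byte-identical under a fixed seed", {
  a <- generate_cohort(sim_config(n_stays = 80, seed = 7))
  b <- generate_cohort(sim_config(n_stays = 80, seed = 7))
  expect_identical(a$cohort, b$cohort)
  expect_identical(a$ground_truth, b$ground_truth)
})

test_that("realized scenario-A unsafe fraction matches the configured propensity", {
  sim <- generate_cohort(sim_config(n_stays = 2000, seed = 21))
  gt <- sim$ground_truth
  n_risk <- gt$at_risk[["A"]]
  expect_gt(n_risk, 50)
  # exact central binomial 99% interval given the realized at-risk count
  bounds <- qbinom(c(0.005, 0.995), n_risk, 0.5)
  expect_gte(gt$unsafe[["A"]], bounds[1])
  expect_lte(gt$unsafe[["A"]], bounds[2])
})

test_that("cumulative balance conserves inputs minus urine within each stay", {
  co <- fixture_sim()$cohort
  for (id in unique(co$stay_id)[1:50]) {
    rows <- co[co$stay_id == id, ]
    expect_equal(rows$cumulative_balance,
                 cumsum(rows$action_fluid - rows$urine_output),
                 tolerance = 1e-12)
    expect_equal(rows$total_fluid_input, cumsum(rows$action_fluid),
                 tolerance = 1e-12)
  }
})

test_that("raising the hypotension mortality weight never lowers mortality", {
  deaths <- vapply(1:20, function(seed) {
    lo <- generate_cohort(sim_config(
      n_stays = 500, seed = seed,
      mortality = list(hypotension = 0.2)))$ground_truth$realized_mortality
    hi <- generate_cohort(sim_config(
      n_stays = 500, seed = seed,
      mortality = list(hypotension = 2.0)))$ground_truth$realized_mortality
    c(lo, hi)
  }, numeric(2))
  # per-seed comparison under common random numbers
  expect_true(all(deaths[2, ] >= deaths[1, ]))
})

test_that("ground-truth summary reports rates and marks empty scenarios absent", {
  gt <- structure(list(configured_propensity = c(A = 0.5, B = 0.1),
                       at_risk = c(A = 100, B = 0),
                       unsafe = c(A = 50, B = 0)),
                  class = "sepsafe_ground_truth")
  s <- ground_truth_summary(gt)
  expect_equal(s$rate[s$scenario == "A"], 0.5)
  expect_true(is.na(s$rate[s$scenario == "B"]))
})

test_that("ground truth agrees with an independent audit of the emitted table", {
  sim <- fixture_sim()
  flags <- flag_cohort(sim$cohort)
  counts <- flag_counts(flags)
  hum <- counts[counts$agent == "human" & counts$scenario != "any", ]
  expect_equal(setNames(hum$N, hum$scenario),
               setNames(as.integer(sim$ground_truth$at_risk),
                        names(sim$ground_truth$at_risk)))
  expect_equal(setNames(hum$x, hum$scenario),
               setNames(as.integer(sim$ground_truth$unsafe),
                        names(sim$ground_truth$unsafe)))
})
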