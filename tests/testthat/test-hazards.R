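step_row <- function(map = 75, cvp = 8, balance = 0) {
  data.frame(map = map, cvp = cvp, cumulative_balance = balance)
}

test_that("at-risk boundaries follow the printed comparators exactly", {
  sc <- default_scenarios()
  expect_true(at_risk(step_row(map = 54.9), sc$A))
  expect_false(at_risk(step_row(map = 55.0), sc$A))         # strict <
  expect_true(at_risk(step_row(map = 55.0, cvp = 5.0), sc$C))  # <= on both
  expect_false(at_risk(step_row(map = 55.1, cvp = 5.0), sc$C))
  expect_false(at_risk(step_row(map = 95.0), sc$B))         # strict >
  expect_true(at_risk(step_row(map = 95.1), sc$B))
  expect_false(at_risk(step_row(map = 80, balance = 5000, cvp = 16), sc$D))
  expect_true(at_risk(step_row(map = 75, balance = 10001, cvp = 15), sc$D))
})

test_that("unsafe-action boundaries match the scenario definitions", {
  sc <- default_scenarios()
  # A: <= 20 mL/hour is inclusive; any vasopressor dose clears the flag
  expect_true(is_unsafe(step_row(map = 50), fluid_rate = 20, vaso = 0, sc$A))
  expect_false(is_unsafe(step_row(map = 50), fluid_rate = 20.1, vaso = 0, sc$A))
  expect_false(is_unsafe(step_row(map = 50), fluid_rate = 0, vaso = 0.1, sc$A))
  # B: > 0.65 ug/kg/min strict
  expect_false(is_unsafe(step_row(map = 100), fluid_rate = 0, vaso = 0.65, sc$B))
  expect_true(is_unsafe(step_row(map = 100), fluid_rate = 0, vaso = 0.651, sc$B))
  # C: exactly zero fluids
  expect_true(is_unsafe(step_row(map = 55, cvp = 5), 0, 0.2, sc$C))
  expect_false(is_unsafe(step_row(map = 55, cvp = 5), 1, 0.2, sc$C))
  # D: > 240 mL/hour strict
  expect_false(is_unsafe(step_row(80, 16, 12000), 240, 0, sc$D))
  expect_true(is_unsafe(step_row(80, 16, 12000), 240.5, 0, sc$D))
  # never unsafe when not at risk
  expect_false(is_unsafe(step_row(map = 70), 0, 0, sc$A))
})

test_that("invalid inputs raise flagging errors", {
  sc <- default_scenarios()
  expect_error(is_unsafe(step_row(), -1, 0, sc$A), class = "sepsafe_flag_error")
  expect_error(at_risk(data.frame(map = 50), sc$C), "cvp",
               class = "sepsafe_flag_error")
})

test_that("an identity policy reproduces the human flags at bin resolution", {
  # doses take a single non-zero value per drug so the representative dose
  # equals the recorded dose and bin resolution is lossless
  co <- validate_cohort(data.frame(
    stay_id = 1L, step_index = 1:6,
    map = c(50, 50, 100, 100, 52, 75),
    cvp = c(4, 4, 8, 8, 5, 8),
    cumulative_balance = 0, urine_output = 100, sofa = 6L, lactate = 2,
    sedation = 0L, total_fluid_input = 0, weight = 80,
    action_fluid = c(0, 1200, 0, 0, 0, 1200),
    action_vaso = c(0, 0, 0.9, 0, 0.9, 0),
    survived_90d = 1L
  ))
  grid <- suppressWarnings(discretize_actions(co))
  flags <- flag_cohort(co, step_hours = 4,
                       policies = list(id = grid$action_index), grid = grid)
  for (s in c("A", "B", "C", "D")) {
    expect_equal(flags[[paste0("unsafe_id_", s)]],
                 flags[[paste0("unsafe_human_", s)]], info = s)
  }
})

test_that("a cohort with no at-risk steps produces all-zero counts", {
  co <- tiny_cohort()
  co$map <- rep(80, 5)
  co$cumulative_balance <- rep(0, 5)
  counts <- flag_counts(flag_cohort(co))
  expect_true(all(counts$N == 0))
  expect_true(all(counts$x == 0))
})

test_that("flag counts equal an independent row-by-row recount", {
  co <- fixture_sim()$cohort
  flags <- flag_cohort(co)
  counts <- flag_counts(flags)
  rate <- co$action_fluid / 4
  manual <- list(
    A = cbind(co$map < 55, co$map < 55 & co$action_vaso == 0 & rate <= 20),
    B = cbind(co$map > 95, co$map > 95 & co$action_vaso > 0.65),
    C = cbind(co$map <= 55 & co$cvp <= 5,
              co$map <= 55 & co$cvp <= 5 & rate == 0),
    D = cbind(co$map >= 75 & co$cumulative_balance > 10000 & co$cvp >= 15,
              co$map >= 75 & co$cumulative_balance > 10000 & co$cvp >= 15 &
                rate > 240))
  for (s in names(manual)) {
    expect_equal(counts$N[counts$scenario == s & counts$agent == "human"],
                 sum(manual[[s]][, 1]), info = s)
    expect_equal(counts$x[counts$scenario == s & counts$agent == "human"],
                 sum(manual[[s]][, 2]), info = s)
  }
  # union counts each step once, so it is bounded by the per-scenario sum
  any_x <- counts$x[counts$scenario == "any" & counts$agent == "human"]
  expect_equal(any_x, sum(Reduce(`|`, lapply(manual, function(m) m[, 2]))))
  expect_lte(any_x, sum(vapply(manual, function(m) sum(m[, 2]), numeric(1))))
})

test_that("unsafe implies at-risk for every scenario and every row", {
  flags <- flag_cohort(fixture_sim()$cohort)
  for (s in c("A", "B", "C", "D")) {
    expect_true(all(flags[[paste0("at_risk_", s)]][
      flags[[paste0("unsafe_human_", s)]]]), info = s)
  }
})

test_that("threshold sweeps match pointwise flagging and are monotone", {
  co <- fixture_sim()$cohort
  sc <- default_scenarios()
  grid_a <- seq(45, 60, by = 2.5)
  sw <- sweep_thresholds(co, sc$A, grid_a)
  expect_true(all(diff(sw$N) >= 0))          # A: N non-decreasing in theta
  sw_b <- sweep_thresholds(co, sc$B, seq(85, 105, by = 5))
  expect_true(all(diff(sw_b$N) <= 0))        # B: N non-increasing in theta
  # pointwise agreement with direct flag_cohort runs
  for (th in c(45, 52.5, 60)) {
    fl <- flag_cohort(co, scenarios = list(A = set_map_threshold(sc$A, th)))
    cnt <- flag_counts(fl)
    expect_equal(sw$N[sw$threshold == th],
                 cnt$N[cnt$scenario == "A" & cnt$agent == "human"])
    expect_equal(sw$x_human[sw$threshold == th],
                 cnt$x[cnt$scenario == "A" & cnt$agent == "human"])
  }
  expect_error(sweep_thresholds(co, sc$A, numeric(0)),
               class = "sepsafe_config_error")
})
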