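soft_policy <- function(mat) {
  structure(mat, class = "sepsafe_soft_policy")
}

test_that("behaviour-policy frequencies follow observed counts", {
  # state 1: actions 1/2 observed 3 and 1 times
  m <- mdp_from_transitions(rep(1L, 4), c(1L, 1L, 1L, 2L),
                            rep(2L, 4), 1:4, nS = 3L, nA = 2L,
                            terminal_survival = 2L, terminal_death = 3L)
  b0 <- estimate_behaviour_policy(m, smoothing = 0)
  expect_equal(b0[1, ], c(0.75, 0.25))
  b <- estimate_behaviour_policy(m, smoothing = 0.01)
  expect_equal(sum(b[1, ]), 1)
  expect_true(all(b[1, ] > 0))
})

test_that("behaviour rows sum to one on a full cohort", {
  run <- fixture_run()
  b <- estimate_behaviour_policy(run$mdp)
  non_term <- setdiff(seq_len(run$mdp$nS),
                      c(run$mdp$terminal_survival, run$mdp$terminal_death))
  sums <- rowSums(b[non_term, , drop = FALSE])
  expect_true(all(abs(sums - 1) < 1e-12))
})

test_that("greedy softening spreads epsilon over the other admissible actions", {
  m <- mdp_from_transitions(rep(1L, 4), c(1L, 1L, 2L, 2L), rep(2L, 4), 1:4,
                            nS = 3L, nA = 2L, terminal_survival = 2L,
                            terminal_death = 3L)
  pol <- structure(c(0L, NA, NA), class = "sepsafe_policy")
  s_eps <- soften_greedy(pol, m, epsilon = 0.1)
  expect_equal(s_eps[1, ], c(0.9, 0.1))
  s0 <- soften_greedy(pol, m, epsilon = 0)
  expect_equal(s0[1, ], c(1, 0))
  expect_error(soften_greedy(pol, m, epsilon = 1),
               class = "sepsafe_config_error")
})

test_that("evaluating the behaviour against itself gives the mean return exactly", {
  run <- fixture_run()
  b <- estimate_behaviour_policy(run$mdp)
  traj <- trajectories(run$mdp, run$rewards$original)
  est <- wis_value(traj, b, b, gamma = 0.99)
  g <- tapply(traj$r * 0.99^(traj$t - 1), traj$stay, sum)
  expect_equal(est$estimate, mean(g), tolerance = 1e-10)
  expect_equal(est$ess, length(unique(traj$stay)), tolerance = 1e-8)
})

test_that("WIS reproduces a hand-computed weighted mean", {
  traj <- structure(
    data.frame(stay = c(1L, 2L), s = c(1L, 2L), a = c(1L, 1L),
               t = c(1L, 1L), r = c(100, 0)),
    class = c("sepsafe_trajectories", "data.frame"))
  ev <- soft_policy(rbind(c(0.6, 0.4), c(0.5, 0.5)))
  bh <- soft_policy(rbind(c(0.2, 0.8), c(0.5, 0.5)))
  est <- wis_value(traj, ev, bh, gamma = 1)
  expect_equal(est$estimate, (3 * 100 + 1 * 0) / 4)   # weights 3 and 1
  # weighted means stay inside the observed return range
  expect_gte(est$estimate, 0)
  expect_lte(est$estimate, 100)
})

test_that("zero behaviour probability on an observed action is an error", {
  traj <- structure(
    data.frame(stay = 1L, s = 1L, a = 2L, t = 1L, r = 1),
    class = c("sepsafe_trajectories", "data.frame"))
  ev <- soft_policy(matrix(c(0.5, 0.5), 1))
  bh <- soft_policy(matrix(c(1, 0), 1))
  expect_error(wis_value(traj, ev, bh), class = "sepsafe_ope_error")
})

test_that("stay-level bootstrap is seeded, consistent and degenerate-safe", {
  run <- fixture_run()
  b <- estimate_behaviour_policy(run$mdp)
  traj <- trajectories(run$mdp, run$rewards$original)
  o1 <- bootstrap_value(traj, b, b, gamma = 0.99, B = 300, seed = 42)
  o2 <- bootstrap_value(traj, b, b, gamma = 0.99, B = 300, seed = 42)
  expect_identical(o1$replicates, o2$replicates)
  expect_identical(o1$median, o2$median)
  expect_equal(o1$iqr, sort(o1$iqr))
  expect_gte(o1$median, min(o1$replicates, na.rm = TRUE))
  # constant returns: IQR width collapses to zero
  traj_c <- structure(
    data.frame(stay = rep(1:5, each = 1), s = 1L, a = 1L, t = 1L, r = 7),
    class = c("sepsafe_trajectories", "data.frame"))
  ev <- soft_policy(matrix(1, 1, 1))
  oc <- bootstrap_value(traj_c, ev, ev, gamma = 1, B = 50, seed = 1)
  expect_equal(unname(diff(oc$iqr)), 0)
  expect_equal(oc$median, 7)
})

test_that("simulated on-policy value agrees with the exact policy value", {
  fx <- random_mdp_fixture(99, nS_core = 6, nA = 3)
  ex <- exact_solve(fx$mdp, fx$rewards)
  pol <- greedy_policy(ex, fx$mdp)
  target <- soften_greedy(pol, fx$mdp, epsilon = 0.05)
  truth <- exact_policy_value(fx$mdp, fx$rewards, target)$value
  traj <- simulate_stays(fx$mdp, fx$rewards, target, n_stays = 3000,
                         max_steps = 400, seed = 17)
  est <- wis_value(traj, target, target, gamma = fx$mdp$gamma)
  g <- tapply(traj$r * fx$mdp$gamma^(traj$t - 1), traj$stay, sum)
  se <- sd(g) / sqrt(length(g))
  expect_lt(abs(est$estimate - truth), 3 * se)
})
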