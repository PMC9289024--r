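test_that("transition probabilities are empirical frequencies", {
  # single observed transition
  m1 <- mdp_from_transitions(1L, 1L, 2L, 1L, nS = 3L, nA = 1L,
                             terminal_survival = 2L, terminal_death = 3L)
  expect_equal(m1$transitions$p, 1)
  # counts (2, 1, 1) over three successors
  m2 <- mdp_from_transitions(rep(1L, 4), rep(1L, 4), c(2L, 2L, 3L, 4L),
                             1:4, nS = 5L, nA = 1L,
                             terminal_survival = 4L, terminal_death = 5L)
  p <- m2$transitions$p[order(m2$transitions$s2)]
  expect_equal(p, c(0.5, 0.25, 0.25))
})

test_that("estimated transition rows are normalized and terminals absorb", {
  sim <- fixture_sim()
  co <- sim$cohort
  grid <- discretize_actions(co)
  sm <- fit_state_clusters(co, k = 12, seed = 3)
  mdp <- estimate_mdp(co, sm, grid, min_count = 5)
  sums <- tapply(mdp$transitions$p,
                 paste(mdp$transitions$s, mdp$transitions$a), sum)
  expect_true(all(abs(sums - 1) < 1e-12))
  expect_false(any(mdp$transitions$s %in%
                     c(mdp$terminal_survival, mdp$terminal_death)))
  # last transition of each stay enters the outcome terminal
  last <- !duplicated(co$stay_id, fromLast = TRUE)
  expect_equal(mdp$trans_rows$s2[last],
               ifelse(co$survived_90d[last] == 1,
                      mdp$terminal_survival, mdp$terminal_death))
})

test_that("a state with no admissible action is a modelling error", {
  expect_error(
    mdp_from_transitions(c(1L, 2L), c(1L, 1L), c(2L, 3L), c(1L, 1L),
                         nS = 4L, nA = 2L, terminal_survival = 3L,
                         terminal_death = 4L, min_count = 2L),
    "no admissible action", class = "sepsafe_model_error")
})

test_that("reward reshaping subtracts exactly the expected penalty", {
  toy <- toy_reshaping_mdp()
  rw0 <- build_reward(toy$mdp, toy$flags, reward_spec(100, 0))
  rw30 <- build_reward(toy$mdp, toy$flags, reward_spec(100, 30))
  expect_true(all(rw0$r_sa == 0))
  expect_equal(rw30$r_sa[1, 1], -30)     # fully flagged action
  expect_equal(rw30$r_sa[1, 2], 0)
  # bookkeeping: difference is exactly -penalty * f(s, a) everywhere
  expect_equal(rw30$r_sa - rw0$r_sa, -30 * rw30$f_sa)
  # half-flagged pair
  half <- build_reward(
    toy$mdp, data.frame(unsafe_human_any = rep(c(TRUE, FALSE), 10)),
    reward_spec(100, 30))
  expect_equal(half$r_sa[1, 1], -15)
  expect_error(build_reward(toy$mdp, toy$flags[1:3, , drop = FALSE]),
               class = "sepsafe_model_error")
})

test_that("Q-learning solves hand-checkable MDPs", {
  # one state, one action, sure terminal +100
  m1 <- mdp_from_transitions(rep(1L, 6), rep(1L, 6), rep(2L, 6), 1:6,
                             nS = 3L, nA = 1L, terminal_survival = 2L,
                             terminal_death = 3L, gamma = 0.99)
  rw <- structure(list(r_sa = matrix(0, 3, 1), f_sa = matrix(0, 3, 1),
                       terminal_bonus = c(0, 100, -100),
                       spec = reward_spec(100, 0)),
                  class = "sepsafe_reward")
  q <- q_learning(m1, rw, tol = 1e-8, seed = 4)
  expect_equal(q$Q[1, 1], 100, tolerance = 1e-6)

  # two-state chain, gamma = 0.5: Q(s1) = 50, Q(s2) = 100
  m2 <- mdp_from_transitions(rep(c(1L, 2L), 6), rep(1L, 12),
                             rep(c(2L, 3L), 6), rep(1:6, each = 2),
                             nS = 4L, nA = 1L, terminal_survival = 3L,
                             terminal_death = 4L, gamma = 0.5)
  rw2 <- structure(list(r_sa = matrix(0, 4, 1), f_sa = matrix(0, 4, 1),
                        terminal_bonus = c(0, 0, 100, -100),
                        spec = reward_spec(100, 0)),
                   class = "sepsafe_reward")
  q2 <- q_learning(m2, rw2, tol = 1e-8, seed = 4)
  expect_equal(q2$Q[1, 1], 50, tolerance = 1e-5)
  expect_equal(q2$Q[2, 1], 100, tolerance = 1e-5)
  ex2 <- exact_solve(m2, rw2)
  expect_equal(ex2$Q[1, 1], 50, tolerance = 1e-9)
  expect_equal(ex2$Q[2, 1], 100, tolerance = 1e-9)
})

test_that("the exact solver handles myopic and reward-free limits", {
  toy <- toy_reshaping_mdp()
  rw <- build_reward(toy$mdp, toy$flags, reward_spec(100, 0))
  myopic <- toy$mdp
  myopic$gamma <- 0
  ex <- exact_solve(myopic, rw)
  # gamma = 0: Q is the expected immediate reward incl. terminal bonus
  expect_equal(ex$Q[1, 1], 100, tolerance = 1e-9)
  expect_equal(ex$Q[1, 2], 0.9 * 100 + 0.1 * (-100), tolerance = 1e-9)
  rw_zero <- structure(list(r_sa = matrix(0, 3, 2), f_sa = matrix(0, 3, 2),
                            terminal_bonus = numeric(3),
                            spec = reward_spec(0, 0)),
                       class = "sepsafe_reward")
  ex0 <- exact_solve(toy$mdp, rw_zero)
  expect_true(all(ex0$Q[1, ] == 0))
})

test_that("greedy policies break exact ties toward the lowest action", {
  q <- structure(list(
    Q = rbind(c(1, 5, 5, 2), matrix(-Inf, 2, 4)),
    admissible = rbind(rep(TRUE, 4), matrix(FALSE, 2, 4))),
    class = "sepsafe_qtable")
  mdp <- list(nS = 3L, nA = 4L, terminal_survival = 2L, terminal_death = 3L)
  class(mdp) <- "sepsafe_mdp"
  pol <- greedy_policy(q, mdp)
  expect_equal(unclass(pol)[1], 1L)   # actions 2 and 3 tie; 0-based index 1
})

test_that("a 30-point penalty steers the policy away from the flagged action", {
  toy <- toy_reshaping_mdp()
  rw0 <- build_reward(toy$mdp, toy$flags, reward_spec(100, 0))
  rw30 <- build_reward(toy$mdp, toy$flags, reward_spec(100, 30))
  p0 <- greedy_policy(exact_solve(toy$mdp, rw0), toy$mdp)
  p30 <- greedy_policy(exact_solve(toy$mdp, rw30), toy$mdp)
  expect_equal(unclass(p0)[1], 0L)    # flagged action (index 0) preferred
  expect_equal(unclass(p30)[1], 1L)   # penalty exceeds the 20-point deficit
  q0 <- greedy_policy(q_learning(toy$mdp, rw0, seed = 2), toy$mdp)
  q30 <- greedy_policy(q_learning(toy$mdp, rw30, seed = 2), toy$mdp)
  expect_identical(unclass(q0), unclass(p0))
  expect_identical(unclass(q30), unclass(p30))
})

test_that("Q-learning and the exact solver agree on random MDPs", {
  for (seed in 1:10) {
    fx <- random_mdp_fixture(seed)
    ql <- q_learning(fx$mdp, fx$rewards, max_sweeps = 20000,
                     seed = seed + 100)
    ex <- exact_solve(fx$mdp, fx$rewards)
    expect_identical(unclass(greedy_policy(ql, fx$mdp)),
                     unclass(greedy_policy(ex, fx$mdp)),
                     info = paste("seed", seed))
  }
})
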