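# Shared fixtures, built lazily and cached for the whole test run.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(name, build) {
  if (!exists(name, envir = .fixture_cache)) {
    assign(name, build(), envir = .fixture_cache)
  }
  get(name, envir = .fixture_cache)
}

# A moderate synthetic cohort reused by several files.
fixture_sim <- function() {
  cached("sim_mid", function() {
    generate_cohort(sim_config(n_stays = 400, seed = 11))
  })
}

# A small end-to-end pipeline run (fast settings).
fixture_run <- function() {
  cached("run_small", function() {
    run_pipeline(pipeline_config(
      n_stays = 400, k = 12, seed = 5, min_count = 5, B = 200,
      run_sweeps = FALSE, run_attribution = FALSE))
  })
}

# The small run with the safety penalty switched off.
fixture_run0 <- function() {
  cached("run_small_p0", function() {
    cfg <- fixture_run()$config
    cfg$penalty <- 0
    run_pipeline(cfg)
  })
}

# Study-scale audit run: 2000 stays, 20 patient states.
fixture_run_big <- function() {
  cached("run_big", function() {
    run_pipeline(pipeline_config(
      n_stays = 2000, k = 20, seed = 1, B = 2000,
      run_sweeps = FALSE, run_attribution = FALSE))
  })
}

# Hand-built cohort: deterministic values, two stays.
tiny_cohort <- function() {
  co <- data.frame(
    stay_id = c(1L, 1L, 1L, 2L, 2L),
    step_index = c(1L, 2L, 3L, 1L, 2L),
    map = c(50, 60, 80, 100, 70),
    cvp = c(4, 6, 8, 12, 16),
    cumulative_balance = c(500, 900, 1200, 11000, 12000),
    urine_output = c(100, 150, 200, 80, 90),
    sofa = c(10L, 8L, 5L, 6L, 7L),
    lactate = c(4.2, 3.1, 1.8, 2.2, 2.5),
    sedation = c(1L, 1L, 0L, 0L, 1L),
    total_fluid_input = c(600, 1150, 1550, 11080, 12170),
    weight = c(70, 70, 70, 92, 92),
    action_fluid = c(600, 550, 400, 1080, 1090),
    action_vaso = c(0.4, 0.2, 0, 0.9, 0),
    survived_90d = c(1L, 1L, 1L, 0L, 0L)
  )
  validate_cohort(co)
}

# Random episodic MDP expressed as an observed transition list: a core of
# nS_core transient states, two terminals, random behaviour data. Returns
# the estimated MDP plus a random reward object.
random_mdp_fixture <- function(seed, nS_core = NULL, nA = NULL) {
  set.seed(seed)
  nS_core <- nS_core %||% sample(3:18, 1)
  nA <- nA %||% sample(2:4, 1)
  nS <- nS_core + 2L
  term_s <- nS_core + 1L
  term_d <- nS_core + 2L
  n_stays <- 60L
  s_all <- integer(0); a_all <- integer(0); s2_all <- integer(0)
  stay_all <- integer(0)
  for (i in seq_len(n_stays)) {
    s <- sample.int(nS_core, 1)
    for (t in 1:30) {
      a <- sample.int(nA, 1)
      # terminal with prob 0.25, else uniform core successor
      s2 <- if (runif(1) < 0.25) sample(c(term_s, term_d), 1) else
        sample.int(nS_core, 1)
      s_all <- c(s_all, s); a_all <- c(a_all, a); s2_all <- c(s2_all, s2)
      stay_all <- c(stay_all, i)
      if (s2 > nS_core) break
      s <- s2
    }
  }
  mdp <- mdp_from_transitions(s_all, a_all, s2_all, stay_all,
                              nS = nS, nA = nA,
                              terminal_survival = term_s,
                              terminal_death = term_d,
                              gamma = 0.9, min_count = 1L)
  r_sa <- matrix(0, nS, nA)
  r_sa[seq_len(nS_core), ] <- matrix(rnorm(nS_core * nA), nS_core, nA)
  bonus <- numeric(nS)
  bonus[term_s] <- 100
  bonus[term_d] <- -100
  rewards <- structure(
    list(r_sa = r_sa, f_sa = matrix(0, nS, nA), terminal_bonus = bonus,
         spec = reward_spec(100, 0)),
    class = "sepsafe_reward")
  list(mdp = mdp, rewards = rewards)
}

# Three-state toy MDP for reward reshaping: in state 1 action 1 is always
# flagged unsafe and leads surely to survival (+100); action 2 is clean but
# survives only with probability 0.9 (value 80). The clean action's value
# deficit (20 points) is below the default 30-point penalty.
toy_reshaping_mdp <- function() {
  s <- rep(1L, 20L)
  a <- rep(c(1L, 2L), each = 10L)
  s2 <- c(rep(2L, 10L), rep(2L, 9L), 3L)
  stay <- seq_len(20L)
  mdp <- mdp_from_transitions(s, a, s2, stay, nS = 3L, nA = 2L,
                              terminal_survival = 2L, terminal_death = 3L,
                              gamma = 0.99, min_count = 1L)
  flags <- data.frame(unsafe_human_any = a == 1L)
  list(mdp = mdp, flags = flags)
}
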