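#' Configuration for the end-to-end safety-assurance pipeline
#'
#' Bundles every stage's parameters: cohort simulation, action/state
#' discretization, hazard flagging, reward reshaping, Q-learning, the audit
#' statistics, attribution, and off-policy evaluation. Every stochastic
#' stage draws its own seed deterministically from the single `seed`, so a
#' fixed configuration reproduces the whole run.
#'
#' @param n_stays,max_steps,step_hours,unsafe_propensity,physiology,mortality
#'   passed to [sim_config()].
#' @param k cluster count for the patient-state model.
#' @param seed master seed.
#' @param min_count admissibility threshold for [estimate_mdp()]. The
#'   pipeline default is deliberately stricter than the module-level default
#'   so that greedy policies cannot select dose combinations observed only a
#'   handful of times — with few patient states, rarely tried actions carry
#'   enough sampling noise in their estimated outcomes to dominate an argmax
#'   and to wreck importance-sampling overlap downstream.
#' @param gamma discount factor.
#' @param terminal_magnitude,penalty reward parameters; `penalty` applies to
#'   the safety-constrained retraining only.
#' @param smoothing,epsilon,B off-policy evaluation parameters.
#' @param qlearn list of Q-learning schedule parameters
#'   (`alpha0`, `decay`, `tol`, `max_sweeps`).
#' @param run_sweeps,run_attribution switch off the threshold sweeps or the
#'   attribution stage for faster runs.
#' @return a `sepsafe_pipeline_config`.
#' @export
pipeline_config <- function(n_stays = 2000L, max_steps = 18L, step_hours = 4,
                            k = 20L, seed = 1L,
                            unsafe_propensity = c(A = 0.5, B = 0.03,
                                                  C = 0.5, D = 0.35),
                            physiology = list(), mortality = list(),
                            min_count = 50L, gamma = 0.99,
                            terminal_magnitude = 100, penalty = 30,
                            smoothing = 0.01, epsilon = 0.01, B = 2000L,
                            qlearn = list(alpha0 = 0.6, decay = 0.03,
                                          tol = 1e-4, max_sweeps = 20000L),
                            run_sweeps = TRUE, run_attribution = TRUE) {
  structure(as.list(environment()), class = "sepsafe_pipeline_config")
}

#' Run the full safety-assurance pipeline
#'
#' Stages, in order: simulate the synthetic cohort; discretize doses and fit
#' the patient-state model; flag recorded decisions against the four hazard
#' scenarios; estimate the discrete MDP; train the original policy
#' (terminal-only reward) and the safety-constrained policy (reward with the
#' intermediate unsafe-decision penalty) by Q-learning with a shared seed;
#' audit all three agents on the shared at-risk sets with two-proportion
#' z-tests; attribute unsafe clinician behaviour to patient features with
#' gradient boosting + SHAP; and evaluate all three policies by weighted
#' importance sampling with stay-level bootstrap bounds (on the unpenalized
#' reward scale, so values are comparable across agents).
#'
#' @param config a [pipeline_config()].
#' @return a `sepsafe_pipeline_run` list with every stage's outputs and a
#'   `manifest` recording parameters and derived seeds.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "sepsafe_pipeline_config"))
  seeds <- list(
    simulate = derive_seed(config$seed, 1L),
    cluster = derive_seed(config$seed, 2L),
    qlearn = derive_seed(config$seed, 3L),
    attribution = derive_seed(config$seed, 4L),
    ope = derive_seed(config$seed, 5L)
  )

  sim <- generate_cohort(sim_config(
    n_stays = config$n_stays, max_steps = config$max_steps,
    step_hours = config$step_hours, seed = seeds$simulate,
    unsafe_propensity = config$unsafe_propensity,
    physiology = config$physiology, mortality = config$mortality))
  cohort <- sim$cohort

  grid <- discretize_actions(cohort)
  state_model <- fit_state_clusters(cohort, k = config$k,
                                    seed = seeds$cluster)
  scenarios <- default_scenarios()
  flags_human <- flag_cohort(cohort, scenarios,
                             step_hours = config$step_hours)

  mdp <- estimate_mdp(cohort, state_model, grid,
                      min_count = config$min_count, gamma = config$gamma)
  rw_orig <- build_reward(mdp, flags_human,
                          reward_spec(config$terminal_magnitude, 0))
  rw_safe <- build_reward(mdp, flags_human,
                          reward_spec(config$terminal_magnitude,
                                      config$penalty))
  ql <- config$qlearn
  q_orig <- q_learning(mdp, rw_orig, alpha0 = ql$alpha0, decay = ql$decay,
                       tol = ql$tol, max_sweeps = ql$max_sweeps,
                       seed = seeds$qlearn)
  q_safe <- q_learning(mdp, rw_safe, alpha0 = ql$alpha0, decay = ql$decay,
                       tol = ql$tol, max_sweeps = ql$max_sweeps,
                       seed = seeds$qlearn)
  pol_orig <- greedy_policy(q_orig, mdp)
  pol_safe <- greedy_policy(q_safe, mdp)

  recs <- list(original = policy_recommendations(pol_orig, mdp),
               safe = policy_recommendations(pol_safe, mdp))
  flags_all <- flag_cohort(cohort, scenarios,
                           step_hours = config$step_hours,
                           policies = recs, grid = grid)
  audit <- compare_policies(flags_all)

  sweeps <- NULL
  if (isTRUE(config$run_sweeps)) {
    sweeps <- lapply(names(scenarios), function(s) {
      sw <- sweep_thresholds(cohort, scenarios[[s]],
                             default_threshold_grid(s),
                             step_hours = config$step_hours,
                             policy = recs$original, grid = grid)
      significance_sweep(sw)
    })
    names(sweeps) <- names(scenarios)
  }

  attributions <- NULL
  if (isTRUE(config$run_attribution)) {
    feats <- c("cvp", "cumulative_balance", "urine_output", "sofa",
               "lactate", "sedation", "total_fluid_input", "weight")
    attributions <- list()
    for (i in seq_along(scenarios)) {
      s <- names(scenarios)[i]
      risk <- flags_human[[paste0("at_risk_", s)]]
      lab <- flags_human[[paste0("unsafe_human_", s)]][risk]
      if (sum(risk) < 20 || length(unique(lab)) < 2) next
      x <- as.data.frame(cohort)[risk, feats]
      mod <- fit_unsafe_classifier(x, lab,
                                   seed = derive_seed(seeds$attribution, i))
      attributions[[s]] <- attribution(mod, x)
    }
  }

  behaviour <- estimate_behaviour_policy(mdp, smoothing = config$smoothing)
  traj <- trajectories(mdp, rw_orig)
  soft_orig <- soften_greedy(pol_orig, mdp, epsilon = config$epsilon)
  soft_safe <- soften_greedy(pol_safe, mdp, epsilon = config$epsilon)
  ope <- list(
    behaviour = bootstrap_value(traj, behaviour, behaviour,
                                gamma = config$gamma, B = config$B,
                                seed = seeds$ope),
    original = bootstrap_value(traj, soft_orig, behaviour,
                               gamma = config$gamma, B = config$B,
                               seed = seeds$ope),
    safe = bootstrap_value(traj, soft_safe, behaviour,
                           gamma = config$gamma, B = config$B,
                           seed = seeds$ope)
  )

  structure(
    list(config = config, cohort = cohort, ground_truth = sim$ground_truth,
         grid = grid, state_model = state_model, scenarios = scenarios,
         flags = flags_all, mdp = mdp,
         rewards = list(original = rw_orig, safe = rw_safe),
         policies = list(original = pol_orig, safe = pol_safe),
         recommendations = recs, audit = audit, sweeps = sweeps,
         attributions = attributions, ope = ope,
         manifest = c(list(seeds = seeds),
                      config[setdiff(names(config), "physiology")])),
    class = "sepsafe_pipeline_run"
  )
}

#' Summary report of a pipeline run
#'
#' Collates the per-scenario proportions for the three agents, the
#' any-scenario union counts with relative reductions versus the human
#' behaviour, the 25-action recommendation histograms of the original and
#' safe policies, the OPE medians and IQRs, and the attribution rankings.
#'
#' @param run a `sepsafe_pipeline_run`.
#' @return a `sepsafe_pipeline_report` list of data frames.
#' @export
pipeline_report <- function(run) {
  stopifnot(inherits(run, "sepsafe_pipeline_run"))
  counts <- run$audit$proportions
  any_row <- counts[counts$scenario == "any", ]
  n_steps <- nrow(run$cohort)
  hum <- any_row$x[any_row$agent == "human"]
  union <- data.frame(
    agent = any_row$agent,
    unsafe = any_row$x,
    pct_of_steps = proportion_pct(any_row$x, n_steps),
    relative_reduction_vs_human_pct =
      ifelse(any_row$agent == "human", 0,
             relative_reduction_pct(hum, any_row$x))
  )
  action_hist <- lapply(run$policies, function(p) {
    a <- unclass(p)
    as.integer(table(factor(a[!is.na(a)], levels = 0:24)))
  })
  ope <- do.call(rbind, lapply(names(run$ope), function(nm) {
    e <- run$ope[[nm]]
    data.frame(agent = nm, estimate = e$estimate, median = e$median,
               iqr_lo = e$iqr[1], iqr_hi = e$iqr[2], B = e$B)
  }))
  not_evaluable <- counts$scenario[counts$agent == "human" & counts$N == 0]
  structure(
    list(proportions = counts, tests = run$audit$tests, union = union,
         action_histograms = action_hist, ope = ope,
         attribution_rankings = lapply(run$attributions,
                                       function(a) a$ranking),
         not_evaluable = not_evaluable),
    class = "sepsafe_pipeline_report"
  )
}
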