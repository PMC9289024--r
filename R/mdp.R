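#' Estimate a discrete MDP from recorded trajectories
#'
#' States are the patient clusters of a [fit_state_clusters()] model plus
#' the two absorbing terminals; actions are the 25 composed dose bins. The
#' transition table is the empirical frequency
#' `P(s'|s,a) = count(s,a,s') / count(s,a)`; the final transition of each
#' stay enters the terminal matching its outcome. State-action pairs seen
#' fewer than `min_count` times are marked inadmissible so that policies
#' never recommend essentially unobserved dose combinations — a
#' safety-relevant choice, not a numerical one.
#'
#' @param cohort a validated cohort.
#' @param state_model a `sepsafe_state_model` fitted on (or applicable to)
#'   this cohort.
#' @param grid a `sepsafe_action_grid` whose `action_index` covers this
#'   cohort's rows (or supply `action_index` directly).
#' @param min_count admissibility threshold on per-(s,a) visit counts.
#' @param gamma discount factor.
#' @param action_index optional explicit per-row composed action indices.
#' @return a `sepsafe_mdp`: counts, normalized transition table, the
#'   admissibility mask, per-row state/action assignments, and the row-level
#'   transition list used by [q_learning()].
#' @export
estimate_mdp <- function(cohort, state_model, grid, min_count = 5L,
                         gamma = 0.99, action_index = NULL) {
  validate_cohort(cohort)
  stopifnot(inherits(state_model, "sepsafe_state_model"))
  states <- assign_states(state_model, cohort)
  actions <- action_index %||% grid$action_index
  if (length(actions) != nrow(cohort)) {
    stop_sepsafe("action indices do not cover the cohort")
  }
  k <- state_model$k
  nS <- k + 2L
  nA <- 25L
  term_surv <- state_model$terminal_survival
  term_death <- state_model$terminal_death

  # Row-level transition list: within a stay s' is the next row's state;
  # the last row transitions to the outcome terminal.
  n <- nrow(cohort)
  stay <- cohort$stay_id
  last_of_stay <- c(stay[-1] != stay[-n], TRUE)
  s2 <- c(states[-1], NA_integer_)
  s2[last_of_stay] <- ifelse(cohort$survived_90d[last_of_stay] == 1,
                             term_surv, term_death)

  a1 <- as.integer(actions) + 1L   # 1-based internally
  mdp <- mdp_from_transitions(states, a1, s2, stay, nS = nS, nA = nA,
                              terminal_survival = term_surv,
                              terminal_death = term_death,
                              gamma = gamma, min_count = min_count)
  mdp$k <- k
  mdp$survived <- cohort$survived_90d
  mdp
}

#' Build a discrete MDP directly from a transition list
#'
#' Lower-level constructor behind [estimate_mdp()], also convenient for
#' hand-built toy MDPs: supply the observed transitions (1-based states and
#' actions) and the stay each belongs to, and get back the same estimated
#' MDP structure — empirical transition probabilities, visit counts and the
#' admissibility mask.
#'
#' @param s,a,s2 integer vectors: state, action (1-based), successor state.
#' @param stay stay/episode id per transition (consecutive rows of a stay
#'   must be contiguous and in time order).
#' @param nS,nA state/action space sizes.
#' @param terminal_survival,terminal_death terminal state ids.
#' @param gamma discount factor.
#' @param min_count admissibility threshold.
#' @return a `sepsafe_mdp`.
#' @export
mdp_from_transitions <- function(s, a, s2, stay, nS, nA,
                                 terminal_survival = nS - 1L,
                                 terminal_death = nS,
                                 gamma = 0.99, min_count = 1L) {
  stopifnot(length(s) == length(a), length(a) == length(s2),
            length(s2) == length(stay))
  sa_counts <- matrix(0L, nS, nA)
  tab <- table(factor(s, levels = seq_len(nS)),
               factor(a, levels = seq_len(nA)))
  sa_counts[] <- as.integer(tab)
  admissible <- sa_counts >= min_count

  visited <- sort(unique(s))
  bad <- visited[!apply(admissible[visited, , drop = FALSE], 1, any)]
  if (length(bad)) {
    stop_sepsafe("state(s) with no admissible action (min_count = ",
                 min_count, "): ", paste(bad, collapse = ", "),
                 class = "sepsafe_model_error")
  }

  trans <- data.frame(s = as.integer(s), a = as.integer(a),
                      s2 = as.integer(s2))
  agg <- stats::aggregate(count ~ s + a + s2,
                          data = cbind(trans, count = 1L), FUN = sum)
  agg$p <- agg$count / sa_counts[cbind(agg$s, agg$a)]

  first_of_stay <- c(TRUE, stay[-1] != stay[-length(stay)])
  structure(
    list(nS = as.integer(nS), nA = as.integer(nA), k = NA_integer_,
         gamma = gamma,
         terminal_survival = as.integer(terminal_survival),
         terminal_death = as.integer(terminal_death),
         min_count = as.integer(min_count),
         sa_counts = sa_counts, admissible = admissible,
         transitions = agg, trans_rows = trans,
         initial_states = as.integer(s[first_of_stay]),
         row_stay = stay),
    class = "sepsafe_mdp"
  )
}

#' Reward specification: terminal outcome signal plus unsafe-decision penalty
#'
#' The base reward is terminal only: `+terminal_magnitude` on entering the
#' survival terminal, the negative on entering the death terminal. Safety
#' reshaping subtracts an intermediate penalty from every state-action pair
#' in proportion to the share `f(s,a)` of its observed instances flagged
#' unsafe under *any* hazard scenario (`mode = "expected"`, the default —
#' clusters aggregate heterogeneous steps and the expected per-instance
#' penalty preserves the mean of the instance-level reward); `mode =
#' "majority"` instead applies the full penalty iff `f(s,a) > 0.5`.
#' `penalty = 0` reproduces the original reward exactly.
#'
#' @param terminal_magnitude magnitude of the terminal reward (points).
#' @param penalty non-negative intermediate penalty per unsafe instance.
#' @param mode `"expected"` or `"majority"`.
#' @return a `sepsafe_reward_spec`.
#' @export
reward_spec <- function(terminal_magnitude = 100, penalty = 30,
                        mode = c("expected", "majority")) {
  if (penalty < 0) stop_sepsafe("penalty must be >= 0",
                                class = "sepsafe_config_error")
  structure(list(terminal_magnitude = terminal_magnitude,
                 penalty = penalty, mode = match.arg(mode)),
            class = "sepsafe_reward_spec")
}

#' Build per-(s,a) rewards from hazard flags
#'
#' @param mdp a `sepsafe_mdp`.
#' @param flags the `sepsafe_flag_table` computed on the *same* cohort (same
#'   rows, same order) as the MDP.
#' @param spec a [reward_spec()].
#' @return a `sepsafe_reward`: intermediate reward matrix `r_sa` (equal to
#'   `-penalty * f(s,a)`), flagged fraction `f_sa`, and the per-state
#'   terminal bonus vector.
#' @export
build_reward <- function(mdp, flags, spec = reward_spec()) {
  stopifnot(inherits(mdp, "sepsafe_mdp"),
            inherits(spec, "sepsafe_reward_spec"))
  if (nrow(flags) != nrow(mdp$trans_rows)) {
    stop_sepsafe("flag table does not match the MDP's cohort (",
                 nrow(flags), " vs ", nrow(mdp$trans_rows), " rows)",
                 class = "sepsafe_model_error")
  }
  unsafe <- as.numeric(flags[["unsafe_human_any"]])
  f_sa <- matrix(0, mdp$nS, mdp$nA)
  num <- tapply(unsafe, list(factor(mdp$trans_rows$s, levels = seq_len(mdp$nS)),
                             factor(mdp$trans_rows$a, levels = seq_len(mdp$nA))),
                sum, default = 0)
  f_sa[] <- as.numeric(num)
  pos <- mdp$sa_counts > 0
  f_sa[pos] <- f_sa[pos] / mdp$sa_counts[pos]

  r_sa <- if (spec$mode == "expected") -spec$penalty * f_sa else
    -spec$penalty * (f_sa > 0.5)
  bonus <- numeric(mdp$nS)
  bonus[mdp$terminal_survival] <- spec$terminal_magnitude
  bonus[mdp$terminal_death] <- -spec$terminal_magnitude
  structure(list(r_sa = r_sa, f_sa = f_sa, terminal_bonus = bonus,
                 spec = spec),
            class = "sepsafe_reward")
}

#' Q-learning on the observed transition list
#'
#' Model-free tabular Q-learning: repeated sweeps over the recorded
#' transitions in seeded shuffled order, learning rate
#' `alpha0 / (1 + decay * n(s,a))` with `n(s,a)` the pair's update count,
#' stopping when the largest absolute Q change over a full sweep falls below
#' `tol`. Inadmissible pairs keep a `-Inf` sentinel and are never updated or
#' backed up through.
#'
#' @param mdp a `sepsafe_mdp`.
#' @param rewards a `sepsafe_reward`.
#' @param alpha0,decay learning-rate schedule parameters.
#' @param tol convergence tolerance on the per-sweep max Q change.
#' @param max_sweeps sweep budget; exceeding it without converging is an
#'   error carrying the residual as a diagnostic.
#' @param seed integer seed for the sweep shuffles.
#' @return a `sepsafe_qtable` with the Q matrix and admissibility mask.
#' @export
q_learning <- function(mdp, rewards, alpha0 = 0.6, decay = 0.03,
                       tol = 1e-4, max_sweeps = 20000L, seed = 1L) {
  stopifnot(inherits(mdp, "sepsafe_mdp"), inherits(rewards, "sepsafe_reward"))
  tr <- mdp$trans_rows
  keep <- mdp$admissible[cbind(tr$s, tr$a)]
  tr <- tr[keep, , drop = FALSE]
  r <- rewards$r_sa[cbind(tr$s, tr$a)] + rewards$terminal_bonus[tr$s2]
  terminal <- seq_len(mdp$nS) %in%
    c(mdp$terminal_survival, mdp$terminal_death)
  res <- qlearn_cpp(tr$s, tr$a, tr$s2, r, mdp$nS, mdp$nA,
                    mdp$admissible, terminal, mdp$gamma,
                    alpha0, decay, tol, as.integer(max_sweeps),
                    as.integer(seed))
  if (!res$converged) {
    stop_sepsafe("Q-learning did not converge within ", max_sweeps,
                 " sweeps (last max change ",
                 format(res$max_change, digits = 4), ")",
                 class = "sepsafe_model_error")
  }
  structure(list(Q = res$Q, admissible = mdp$admissible,
                 sweeps = res$sweeps, method = "q_learning"),
            class = "sepsafe_qtable")
}

#' Exact solution of the estimated MDP (value-iteration oracle)
#'
#' Iterates the Bellman optimality operator on the *estimated* transition
#' table to a sup-norm fixed point. Q-learning run on the same transition
#' list converges to the same fixed point, so this solver serves as an
#' independent verification oracle for [q_learning()].
#'
#' @inheritParams q_learning
#' @param tol sup-norm convergence tolerance.
#' @param max_iter iteration budget.
#' @return a `sepsafe_qtable`.
#' @export
exact_solve <- function(mdp, rewards, tol = 1e-10, max_iter = 100000L) {
  stopifnot(inherits(mdp, "sepsafe_mdp"), inherits(rewards, "sepsafe_reward"))
  agg <- mdp$transitions
  agg <- agg[mdp$admissible[cbind(agg$s, agg$a)], , drop = FALSE]
  sa_key <- (agg$a - 1L) * mdp$nS + agg$s
  # rowsum() returns groups in sorted key order; align everything to that.
  keys <- sort(unique(sa_key))
  key_s <- (keys - 1L) %% mdp$nS + 1L
  key_a <- (keys - 1L) %/% mdp$nS + 1L
  base <- rewards$r_sa[cbind(key_s, key_a)] +
    as.numeric(rowsum(agg$p * rewards$terminal_bonus[agg$s2], sa_key))

  terminal <- seq_len(mdp$nS) %in%
    c(mdp$terminal_survival, mdp$terminal_death)
  Q <- matrix(-Inf, mdp$nS, mdp$nA)
  Q[mdp$admissible] <- 0
  v <- numeric(mdp$nS)
  for (it in seq_len(max_iter)) {
    ev <- as.numeric(rowsum(agg$p * v[agg$s2], sa_key))
    q_new <- base + mdp$gamma * ev
    Qn <- Q
    Qn[cbind(key_s, key_a)] <- q_new
    v_new <- ifelse(terminal, 0, suppressWarnings(apply(Qn, 1, max)))
    v_new[!is.finite(v_new)] <- 0   # unvisited states
    delta <- max(abs(Qn[mdp$admissible] - Q[mdp$admissible]))
    Q <- Qn
    v <- v_new
    if (delta < tol) break
  }
  structure(list(Q = Q, admissible = mdp$admissible, iterations = it,
                 method = "value_iteration"),
            class = "sepsafe_qtable")
}

#' Greedy policy from a Q table
#'
#' Argmax over admissible actions per non-terminal state; exact ties break
#' to the lowest action index, i.e. the lowest composed doses.
#'
#' @param q a `sepsafe_qtable`.
#' @param mdp the `sepsafe_mdp` it was computed on (for terminal ids).
#' @return a `sepsafe_policy`: integer vector of composed action indices
#'   (0-24), `NA` at terminals and unvisited states.
#' @export
greedy_policy <- function(q, mdp) {
  stopifnot(inherits(q, "sepsafe_qtable"), inherits(mdp, "sepsafe_mdp"))
  acts <- rep(NA_integer_, mdp$nS)
  terminals <- c(mdp$terminal_survival, mdp$terminal_death)
  for (s in seq_len(mdp$nS)) {
    if (s %in% terminals) next
    adm <- which(q$admissible[s, ])
    if (!length(adm)) next
    qs <- q$Q[s, adm]
    if (all(!is.finite(qs))) {
      stop_sepsafe("state ", s, " has no finite Q value",
                   class = "sepsafe_model_error")
    }
    acts[s] <- adm[which.max(qs)] - 1L
  }
  structure(acts, class = "sepsafe_policy")
}

#' Per-row policy recommendations for a cohort
#'
#' Maps each timestep's state to the policy's composed action index.
#'
#' @param policy a `sepsafe_policy`.
#' @param mdp the `sepsafe_mdp` whose state assignments to use.
#' @return integer vector of composed action indices, one per cohort row.
#' @export
policy_recommendations <- function(policy, mdp) {
  stopifnot(inherits(policy, "sepsafe_policy"), inherits(mdp, "sepsafe_mdp"))
  as.integer(unclass(policy)[mdp$trans_rows$s])
}
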