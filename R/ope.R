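#' Extract per-stay trajectories in state-action-reward form
#'
#' Converts an estimated MDP (which carries the row-level state/action
#' assignments of its cohort) plus a reward specification into the flat
#' trajectory table consumed by the off-policy evaluators: one row per
#' timestep with stay id, state, 1-based action, step number and immediate
#' reward (intermediate penalty plus terminal bonus on the last step).
#'
#' @param mdp a `sepsafe_mdp`.
#' @param rewards a `sepsafe_reward`; pass one built with `penalty = 0` to
#'   value policies on the unpenalized outcome scale.
#' @return a `sepsafe_trajectories` data frame with columns `stay`, `s`,
#'   `a`, `t`, `r`.
#' @export
trajectories <- function(mdp, rewards) {
  stopifnot(inherits(mdp, "sepsafe_mdp"), inherits(rewards, "sepsafe_reward"))
  tr <- mdp$trans_rows
  r <- rewards$r_sa[cbind(tr$s, tr$a)] + rewards$terminal_bonus[tr$s2]
  t_within <- stats::ave(seq_along(mdp$row_stay), mdp$row_stay,
                         FUN = seq_along)
  structure(data.frame(stay = mdp$row_stay, s = tr$s, a = tr$a,
                       t = t_within, r = r),
            class = c("sepsafe_trajectories", "data.frame"))
}

#' Empirical behaviour policy with additive smoothing
#'
#' Per-state action frequencies of the recorded behaviour, with additive
#' smoothing `lambda` spread over the actions actually observed at each
#' state, renormalized. Every observed action therefore has strictly
#' positive probability, which keeps importance ratios finite. States never
#' visited are excluded (`NA` row) with a warning.
#'
#' @param mdp a `sepsafe_mdp`.
#' @param smoothing additive smoothing constant `lambda`.
#' @return a `sepsafe_soft_policy`: `nS x 25` matrix of action
#'   probabilities; terminal and unvisited rows are `NA`.
#' @export
estimate_behaviour_policy <- function(mdp, smoothing = 0.01) {
  stopifnot(inherits(mdp, "sepsafe_mdp"))
  probs <- matrix(NA_real_, mdp$nS, mdp$nA)
  terminals <- c(mdp$terminal_survival, mdp$terminal_death)
  unvisited <- integer(0)
  for (s in setdiff(seq_len(mdp$nS), terminals)) {
    cnt <- mdp$sa_counts[s, ]
    obs <- cnt > 0
    if (!any(obs)) {
      unvisited <- c(unvisited, s)
      next
    }
    p <- numeric(mdp$nA)
    p[obs] <- (cnt[obs] + smoothing) / (sum(cnt[obs]) + smoothing * sum(obs))
    probs[s, ] <- p
  }
  if (length(unvisited)) {
    warning("state(s) never visited, excluded from the behaviour policy: ",
            paste(unvisited, collapse = ", "))
  }
  structure(probs, smoothing = smoothing, class = "sepsafe_soft_policy")
}

#' Soften a greedy policy for importance sampling
#'
#' The greedy action keeps probability `1 - epsilon`; the remainder is
#' uniform over the other admissible actions of the state (all of it on the
#' greedy action when it is the only admissible one).
#'
#' @param policy a `sepsafe_policy`.
#' @param mdp the `sepsafe_mdp` (for the admissibility mask).
#' @param epsilon softening parameter in `[0, 1)`.
#' @return a `sepsafe_soft_policy`.
#' @export
soften_greedy <- function(policy, mdp, epsilon = 0.01) {
  stopifnot(inherits(policy, "sepsafe_policy"), inherits(mdp, "sepsafe_mdp"))
  if (epsilon < 0 || epsilon >= 1) {
    stop_sepsafe("epsilon must lie in [0, 1)", class = "sepsafe_config_error")
  }
  probs <- matrix(NA_real_, mdp$nS, mdp$nA)
  acts <- unclass(policy)
  for (s in seq_len(mdp$nS)) {
    if (is.na(acts[s])) next
    adm <- which(mdp$admissible[s, ])
    p <- numeric(mdp$nA)
    g <- acts[s] + 1L
    if (length(adm) == 1L) {
      p[g] <- 1
    } else {
      p[g] <- 1 - epsilon
      others <- setdiff(adm, g)
      p[others] <- epsilon / length(others)
    }
    probs[s, ] <- p
  }
  structure(probs, epsilon = epsilon, class = "sepsafe_soft_policy")
}

# Per-stay importance weights and discounted returns.
.stay_weights_returns <- function(traj, eval_policy, behaviour, gamma) {
  p_eval <- eval_policy[cbind(traj$s, traj$a)]
  p_beh <- behaviour[cbind(traj$s, traj$a)]
  if (any(is.na(p_beh)) || any(p_beh <= 0)) {
    stop_sepsafe("behaviour policy assigns zero probability to an observed ",
                 "action; increase smoothing", class = "sepsafe_ope_error")
  }
  p_eval[is.na(p_eval)] <- 0
  ratio <- p_eval / p_beh
  stays <- unique(traj$stay)
  f <- factor(traj$stay, levels = stays)
  w <- as.numeric(tapply(ratio, f, prod))
  g <- as.numeric(tapply(traj$r * gamma^(traj$t - 1), f, sum))
  list(stay = stays, w = w, g = g)
}

#' Weighted importance sampling value of a policy
#'
#' Self-normalized importance sampling over whole stays: each stay carries
#' the product of per-step probability ratios between the evaluation and
#' behaviour policies, and the estimate is the weight-normalized mean of the
#' discounted returns,
#' \deqn{\hat V = \sum_i w_i G_i / \sum_i w_i .}
#' The estimate always lies within the range of observed returns, and
#' evaluating the behaviour policy against itself returns the plain mean
#' discounted return exactly.
#'
#' @param traj a `sepsafe_trajectories` table.
#' @param eval_policy,behaviour `sepsafe_soft_policy` matrices.
#' @param gamma discount factor.
#' @return list with `estimate`, `ess` (effective sample size of the
#'   weights) and `n_stays`.
#' @export
wis_value <- function(traj, eval_policy, behaviour, gamma = 0.99) {
  wr <- .stay_weights_returns(traj, eval_policy, behaviour, gamma)
  if (sum(wr$w) <= 0) {
    stop_sepsafe("all importance weights are zero; the evaluation policy ",
                 "never overlaps the behaviour support",
                 class = "sepsafe_ope_error")
  }
  list(estimate = sum(wr$w * wr$g) / sum(wr$w),
       ess = sum(wr$w)^2 / sum(wr$w^2),
       n_stays = length(wr$w))
}

#' Bootstrap confidence bounds on an off-policy value
#'
#' Stay-level bootstrap (stays are the independent units): resamples stays
#' with replacement `B` times, recomputing the WIS estimate on each
#' replicate, and reports the median and interquartile range of the
#' replicate values.
#'
#' @inheritParams wis_value
#' @param B number of bootstrap resamples.
#' @param seed integer seed.
#' @return a `sepsafe_ope_estimate`: list with `estimate`, `replicates`,
#'   `median`, `iqr` (25th/75th percentiles), `B`, `seed`, and the number of
#'   degenerate replicates (all-zero weights) dropped.
#' @export
bootstrap_value <- function(traj, eval_policy, behaviour, gamma = 0.99,
                            B = 2000L, seed = 1L) {
  B <- check_count(B, "B")
  wr <- .stay_weights_returns(traj, eval_policy, behaviour, gamma)
  n <- length(wr$w)
  if (n == 0) stop_sepsafe("empty trajectory set", class = "sepsafe_ope_error")
  set.seed(seed)
  reps <- numeric(B)
  for (b in seq_len(B)) {
    idx <- sample.int(n, n, replace = TRUE)
    sw <- sum(wr$w[idx])
    reps[b] <- if (sw > 0) sum(wr$w[idx] * wr$g[idx]) / sw else NA_real_
  }
  dropped <- sum(is.na(reps))
  ok <- reps[!is.na(reps)]
  structure(
    list(estimate = sum(wr$w * wr$g) / sum(wr$w),
         replicates = reps,
         median = median(ok),
         iqr = unname(quantile(ok, c(0.25, 0.75))),
         B = B, seed = as.integer(seed), dropped = dropped),
    class = "sepsafe_ope_estimate"
  )
}

#' Exact value of a stochastic policy on the estimated MDP
#'
#' Solves the policy-evaluation fixed point
#' `V(s) = sum_a pi(a|s) [ r(s,a) + sum_s' P(s'|s,a) (bonus(s') + gamma V(s')) ]`
#' by iteration and returns the value of the empirical initial-state
#' distribution — the ground truth against which sampling-based off-policy
#' estimates are checked.
#'
#' @param mdp a `sepsafe_mdp`.
#' @param rewards a `sepsafe_reward`.
#' @param policy a `sepsafe_soft_policy`.
#' @param tol sup-norm convergence tolerance.
#' @return list with `v` (per-state values) and `value` (initial-state
#'   expectation).
#' @export
exact_policy_value <- function(mdp, rewards, policy, tol = 1e-12) {
  stopifnot(inherits(mdp, "sepsafe_mdp"))
  agg <- mdp$transitions
  pi_sa <- policy[cbind(agg$s, agg$a)]
  pi_sa[is.na(pi_sa)] <- 0
  contrib_r <- pi_sa * (agg$p * rewards$terminal_bonus[agg$s2] +
                          agg$p * rewards$r_sa[cbind(agg$s, agg$a)])
  base <- as.numeric(rowsum(contrib_r, agg$s))
  srows <- sort(unique(agg$s))
  v <- numeric(mdp$nS)
  repeat {
    ev <- as.numeric(rowsum(pi_sa * agg$p * v[agg$s2], agg$s))
    v_new <- v
    v_new[srows] <- base + mdp$gamma * ev
    if (max(abs(v_new - v)) < tol) {
      v <- v_new
      break
    }
    v <- v_new
  }
  list(v = v, value = mean(v[mdp$initial_states]))
}

#' Simulate stays from an estimated MDP under a stochastic policy
#'
#' Rolls out trajectories from the estimated transition table: initial
#' states are drawn from the empirical initial-state distribution, actions
#' from the supplied soft policy, successors from `P(s'|s,a)`, and rewards
#' from the reward model, until a terminal state or `max_steps`. Used to
#' validate the off-policy estimators against ground truth computable by
#' [exact_solve()] on the same MDP.
#'
#' @param mdp a `sepsafe_mdp`.
#' @param rewards a `sepsafe_reward`.
#' @param policy a `sepsafe_soft_policy` to roll out.
#' @param n_stays number of stays to simulate.
#' @param max_steps step cap per stay.
#' @param seed integer seed.
#' @return a `sepsafe_trajectories` data frame.
#' @export
simulate_stays <- function(mdp, rewards, policy, n_stays, max_steps = 18L,
                           seed = 1L) {
  stopifnot(inherits(mdp, "sepsafe_mdp"), inherits(rewards, "sepsafe_reward"))
  n_stays <- check_count(n_stays, "n_stays")
  terminals <- c(mdp$terminal_survival, mdp$terminal_death)
  # successor tables per (s,a) for fast sampling
  agg <- mdp$transitions
  key <- paste(agg$s, agg$a)
  succ <- split(seq_len(nrow(agg)), key)
  set.seed(seed)
  out_stay <- list(); out_s <- list(); out_a <- list(); out_r <- list()
  init <- mdp$initial_states
  for (i in seq_len(n_stays)) {
    s <- init[sample.int(length(init), 1L)]
    ss <- integer(0); aa <- integer(0); rr <- numeric(0)
    for (t in seq_len(max_steps)) {
      p <- policy[s, ]
      if (any(is.na(p))) {
        stop_sepsafe("policy undefined at state ", s,
                     class = "sepsafe_ope_error")
      }
      a <- sample.int(mdp$nA, 1L, prob = p)
      rows <- succ[[paste(s, a)]]
      if (is.null(rows)) {
        # action admissible but never observed at s under this estimate
        stop_sepsafe("no estimated transition for state ", s, ", action ", a,
                     class = "sepsafe_ope_error")
      }
      s2 <- agg$s2[rows][sample.int(length(rows), 1L,
                                    prob = agg$p[rows])]
      ss <- c(ss, s); aa <- c(aa, a)
      rr <- c(rr, rewards$r_sa[s, a] + rewards$terminal_bonus[s2])
      s <- s2
      if (s %in% terminals) break
    }
    out_stay[[i]] <- rep.int(i, length(ss))
    out_s[[i]] <- ss; out_a[[i]] <- aa; out_r[[i]] <- rr
  }
  len <- lengths(out_s)
  structure(data.frame(stay = unlist(out_stay), s = unlist(out_s),
                       a = unlist(out_a),
                       t = unlist(lapply(len, seq_len)),
                       r = unlist(out_r)),
            class = c("sepsafe_trajectories", "data.frame"))
}
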