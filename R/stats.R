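#' Two-proportion z-test for human vs AI unsafe-decision rates
#'
#' Both agents are judged on the same `n` at-risk steps, so their unsafe
#' counts are modelled as Binomial(`n`, p) with a common `n`. The statistic
#' is
#' \deqn{z = \frac{\hat p_{AI} - \hat p_{Human}}
#'                {\sqrt{\hat p (1 - \hat p) \cdot 2 / n}}}
#' with the pooled proportion \eqn{\hat p = (\hat p_{Human} + \hat p_{AI})/2}
#' (equivalent to the usual pooled two-sample proportion under equal
#' denominators). Under the null of equal rates and large `n`, `z` is
#' standard normal and p values come from the Gaussian CDF. The default
#' sidedness is one-sided *lower* — the alternative that the AI takes fewer
#' unsafe decisions than humans — with the two-sided p value
#' `2 * pnorm(-|z|)` available.
#'
#' Degenerate pooled proportions (0 or 1) give `z = 0` when the counts are
#' equal and `±Inf` (p of 0 or 1) otherwise.
#'
#' @param x_human unsafe-decision count for the human behaviour policy.
#' @param x_ai unsafe-decision count for the AI policy.
#' @param n shared at-risk denominator (> 0).
#' @param sidedness `"one_sided"` (AI < human) or `"two_sided"`.
#' @return a `sepsafe_proportion_test`: list with `n`, `x_human`, `x_ai`,
#'   `p_human`, `p_ai`, `p_pooled`, `z`, `p_value`, `sidedness`.
#' @export
two_proportion_ztest <- function(x_human, x_ai, n,
                                 sidedness = c("one_sided", "two_sided")) {
  sidedness <- match.arg(sidedness)
  if (length(n) != 1 || n <= 0) {
    stop_sepsafe("the test is undefined for n = 0",
                 class = "sepsafe_test_error")
  }
  if (x_human < 0 || x_ai < 0 || x_human > n || x_ai > n) {
    stop_sepsafe("counts must lie in [0, n]", class = "sepsafe_test_error")
  }
  p_h <- x_human / n
  p_a <- x_ai / n
  p_pool <- (p_h + p_a) / 2
  if (p_pool %in% c(0, 1)) {
    z <- if (x_human == x_ai) 0 else if (x_ai > x_human) Inf else -Inf
  } else {
    z <- (p_a - p_h) / sqrt(p_pool * (1 - p_pool) * 2 / n)
  }
  p_value <- switch(sidedness,
    one_sided = pnorm(z),
    two_sided = 2 * pnorm(-abs(z))
  )
  structure(list(n = n, x_human = x_human, x_ai = x_ai,
                 p_human = p_h, p_ai = p_a, p_pooled = p_pool,
                 z = z, p_value = p_value, sidedness = sidedness),
            class = "sepsafe_proportion_test")
}

#' Printed-count arithmetic helpers
#'
#' `proportion_pct()` expresses a count over a denominator as a percentage;
#' `relative_reduction_pct()` gives the relative reduction of a new count
#' with respect to a reference count, in percent. These are the arithmetic
#' behind prevalence rates ("x at-risk steps out of N data points") and
#' headline claims such as "a 12% relative reduction in unsafe decisions".
#'
#' @param x,n count and denominator.
#' @param x_ref,x_new reference (e.g. human) and new (e.g. AI) counts.
#' @return a percentage (already scaled by 100).
#' @export
proportion_pct <- function(x, n) {
  if (any(n <= 0)) stop_sepsafe("denominator must be positive")
  100 * x / n
}

#' @rdname proportion_pct
#' @export
relative_reduction_pct <- function(x_ref, x_new) {
  if (any(x_ref <= 0)) stop_sepsafe("reference count must be positive")
  100 * (x_ref - x_new) / x_ref
}

#' Reference scenario prevalence counts
#'
#' At-risk and unsafe-decision counts for the four hazard scenarios as
#' reported for the MIMIC-III sepsis cohort of the AI Clinician line of
#' work (984,269 data points), shipped as a plain-text table. Used as a
#' worked-example input for the rate arithmetic; no patient-level data is
#' included or required.
#'
#' @return data frame with columns `scenario` (A-D plus the any-scenario
#'   union), `total_steps`, `at_risk`, `unsafe_human`, and — for the union
#'   row — `unsafe_original_ai` and `unsafe_safe_ai`.
#' @export
reference_scenario_counts <- function() {
  path <- system.file("extdata", "reference_counts.csv", package = "sepsafe")
  read.csv(path, stringsAsFactors = FALSE)
}

#' Compare unsafe-decision proportions across agents
#'
#' Builds the per-scenario, per-agent table of at-risk denominators, unsafe
#' counts and proportions from a flag table, plus pairwise human-vs-policy
#' z-tests for every policy agent. Errors if any agent's denominator differs
#' from the human one (that would violate the shared-N assumption of the
#' test).
#'
#' @param flags a `sepsafe_flag_table` computed with policy recommendations.
#' @param sidedness passed to [two_proportion_ztest()].
#' @return list with `proportions` (data frame) and `tests` (data frame of
#'   scenario, agent, z, p_value; `NA` where a scenario has no at-risk
#'   step).
#' @export
compare_policies <- function(flags, sidedness = "one_sided") {
  counts <- flag_counts(flags)
  agents <- setdiff(attr(flags, "agents"), "human")
  tests <- expand.grid(scenario = unique(counts$scenario), agent = agents,
                       stringsAsFactors = FALSE)
  tests$N <- NA_integer_; tests$z <- NA_real_; tests$p_value <- NA_real_
  for (i in seq_len(nrow(tests))) {
    s <- tests$scenario[i]; ag <- tests$agent[i]
    hum <- counts[counts$scenario == s & counts$agent == "human", ]
    pol <- counts[counts$scenario == s & counts$agent == ag, ]
    if (hum$N != pol$N) {
      stop_sepsafe("at-risk N differs between human (", hum$N, ") and '",
                   ag, "' (", pol$N, ") in scenario ", s,
                   class = "sepsafe_test_error")
    }
    tests$N[i] <- hum$N
    if (hum$N > 0) {
      tt <- two_proportion_ztest(hum$x, pol$x, hum$N, sidedness)
      tests$z[i] <- tt$z
      tests$p_value[i] <- tt$p_value
    }
  }
  list(proportions = counts, tests = tests)
}

#' Significance of the human-vs-policy difference across a threshold sweep
#'
#' One z-test per MAP threshold of a [sweep_thresholds()] output; thresholds
#' with an empty at-risk set are recorded as undefined (`NA`). No
#' multiplicity adjustment is applied by default — per-threshold raw
#' significance is the quantity of interest in the sensitivity analysis —
#' but a Bonferroni correction over the grid is available.
#'
#' @param sweep data frame from [sweep_thresholds()] including `x_policy`.
#' @param sidedness passed to [two_proportion_ztest()].
#' @param adjust `"none"` or `"bonferroni"`.
#' @return the sweep with `z` and `p_value` columns appended.
#' @export
significance_sweep <- function(sweep, sidedness = "one_sided",
                               adjust = c("none", "bonferroni")) {
  adjust <- match.arg(adjust)
  if (is.null(sweep$x_policy)) {
    stop_sepsafe("sweep must carry policy counts (run sweep_thresholds ",
                 "with a policy)")
  }
  sweep$z <- NA_real_
  sweep$p_value <- NA_real_
  for (i in seq_len(nrow(sweep))) {
    if (sweep$N[i] > 0) {
      tt <- two_proportion_ztest(sweep$x_human[i], sweep$x_policy[i],
                                 sweep$N[i], sidedness)
      sweep$z[i] <- tt$z
      sweep$p_value[i] <- tt$p_value
    }
  }
  if (adjust == "bonferroni") {
    sweep$p_value <- pmin(1, sweep$p_value * sum(!is.na(sweep$p_value)))
  }
  sweep
}
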