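#' Configuration for the synthetic ICU sepsis cohort generator
#'
#' Builds the full parameter set of the trajectory simulator. The simulator
#' emulates the statistical structure of an ICU sepsis cohort sampled on a
#' 4-hour grid: hypotension episodes that respond to fluids and vasopressors,
#' cumulative fluid balance driving central venous pressure, severity-linked
#' mortality, and a guideline-like behaviour policy that takes each hazard
#' scenario's unsafe action with a configurable propensity whenever the
#' patient is at risk.
#'
#' @param n_stays number of ICU stays to simulate.
#' @param max_steps maximum number of timesteps per stay; the default of 18
#'   steps of 4 hours covers the first 72 hours of resuscitation.
#' @param step_hours duration of one timestep in hours.
#' @param seed integer seed; identical configuration and seed produce a
#'   byte-identical cohort.
#' @param unsafe_propensity named probabilities (scenarios `A`, `B`, `C`,
#'   `D`) that the behaviour policy takes the scenario's unsafe action when
#'   the patient is at risk. Defaults sit near the unsafe-decision rates
#'   reported for the four scenarios in the MIMIC-III sepsis cohort
#'   (A 53.7%, B 2.5%, C 53.8%, D 37.4%).
#' @param physiology named list of physiology coefficients; any subset may be
#'   supplied to override a default. Members: `map_setpoint` (mm Hg),
#'   `map_reversion` (fraction/step), `fluid_map_gain` (mm Hg per log-unit of
#'   scaled fluid volume), `vaso_map_gain` (mm Hg per ug/kg/min),
#'   `severity_map_drain` (mm Hg/step at severity 1), `cvp_baseline` (mm Hg),
#'   `balance_cvp_gain` (mm Hg/L), `map_noise_sd`, `cvp_noise_sd`,
#'   `urine_noise_sd`, `lactate_noise_sd`, `severity_drift_sd`.
#' @param mortality named list of per-step logistic death-hazard
#'   coefficients: `intercept`, `severity` (weight on latent severity),
#'   `hypotension` (weight on MAP < 55 mm Hg exposure this step),
#'   `fluid_overload` (weight on cumulative balance > 10 L).
#'
#' @return an object of class `sepsafe_sim_config`.
#' @seealso [generate_cohort()]
#' @export
sim_config <- function(n_stays,
                       max_steps = 18L,
                       step_hours = 4,
                       seed = 1L,
                       unsafe_propensity = c(A = 0.5, B = 0.03, C = 0.5, D = 0.35),
                       physiology = list(),
                       mortality = list()) {
  n_stays <- check_count(n_stays, "n_stays")
  max_steps <- check_count(max_steps, "max_steps")
  if (!is.numeric(step_hours) || length(step_hours) != 1L || step_hours <= 0) {
    stop_sepsafe("step_hours must be > 0", class = "sepsafe_config_error")
  }
  prop <- c(A = 0.5, B = 0.03, C = 0.5, D = 0.35)
  prop[names(unsafe_propensity)] <- unsafe_propensity
  check_prob(prop, "unsafe_propensity")

  phys <- list(
    map_setpoint = 78, map_reversion = 0.18,
    fluid_map_gain = 9, vaso_map_gain = 16, severity_map_drain = 14,
    cvp_baseline = 6, balance_cvp_gain = 1.0,
    map_noise_sd = 6, cvp_noise_sd = 1.5, urine_noise_sd = 25,
    lactate_noise_sd = 0.3, severity_drift_sd = 0.04
  )
  phys[names(physiology)] <- physiology
  mort <- list(intercept = -5.2, severity = 2.2,
               hypotension = 1.3, fluid_overload = 0.8)
  mort[names(mortality)] <- mortality

  structure(
    list(n_stays = n_stays, max_steps = max_steps, step_hours = step_hours,
         seed = as.integer(seed), unsafe_propensity = prop,
         physiology = phys, mortality = mort),
    class = "sepsafe_sim_config"
  )
}

# Guideline-like dose selection targeting MAP 65-90 mm Hg, given the
# currently observed MAP. Returns per-stay fluid volume (mL/step) and
# vasopressor dose (ug/kg/min). All random draws are made for every stay so
# the random-number stream stays aligned across configurations that share a
# seed (common random numbers).
.behaviour_doses <- function(map, sev, step_hours) {
  n <- length(map)
  u_vaso <- runif(n)
  fluid <- numeric(n)
  vaso <- numeric(n)

  severe <- map < 55
  low <- map >= 55 & map < 65
  target <- map >= 65 & map <= 90
  high <- map > 90

  fluid_severe <- runif(n, 600, 1600)
  fluid_low <- runif(n, 300, 900)
  fluid_target <- runif(n, 0, 250)
  fluid_high <- runif(n, 0, 100)
  vaso_severe <- runif(n, 0.3, 0.8)
  vaso_low <- runif(n, 0.05, 0.4)
  vaso_target <- runif(n, 0.02, 0.1)

  fluid[severe] <- fluid_severe[severe]
  fluid[low] <- fluid_low[low]
  fluid[target] <- fluid_target[target]
  fluid[high] <- fluid_high[high]
  vaso[severe] <- vaso_severe[severe]
  vaso[low] <- ifelse(u_vaso[low] < 0.7, vaso_low[low], 0)
  vaso[target] <- ifelse(u_vaso[target] < 0.2, vaso_target[target], 0)
  vaso[high] <- 0

  # severity-driven maintenance/replacement fluids on top of the
  # MAP-targeted doses (sicker patients are resuscitated more liberally)
  fluid <- fluid + runif(n, 0, 1200) * sev

  list(fluid = fluid * step_hours / 4, vaso = vaso)
}

#' Generate a synthetic ICU sepsis cohort with known ground truth
#'
#' Simulates `n_stays` trajectories on a fixed time grid. Each stay carries a
#' latent severity that drifts per step (worsening under untreated
#' hypotension); mean arterial pressure follows the previous value plus a
#' homeostatic pull toward the setpoint, a concave fluid response, a linear
#' vasopressor response and a severity drain, with Gaussian noise, clipped to
#' a physiologic range. Central venous pressure tracks cumulative fluid
#' balance; urine output falls with severity and rises with MAP above a
#' perfusion floor; lactate rises with accumulated hypotensive steps; SOFA is
#' a bounded integer transform of severity, MAP, urine and lactate. Death is
#' drawn per step from a logistic hazard in severity, hypotension exposure
#' and fluid overload; stays that reach `max_steps` are labelled as having
#' survived. Severity itself is never emitted, so downstream state models see
#' only observables (realistic partial observability).
#'
#' The behaviour policy targets MAP 65-90 mm Hg; whenever a hazard scenario's
#' at-risk condition holds, it is replaced by that scenario's unsafe action
#' with the configured propensity.
#'
#' @param config a [sim_config()] object.
#' @return a list with elements `cohort` (see [validate_cohort()] for the
#'   column dictionary) and `ground_truth`, a `sepsafe_ground_truth` record
#'   with configured propensities, realized per-scenario at-risk and unsafe
#'   counts (recounted from the emitted rows), and realized mortality.
#' @export
generate_cohort <- function(config) {
  if (!inherits(config, "sepsafe_sim_config")) {
    stop_sepsafe("config must come from sim_config()",
                 class = "sepsafe_config_error")
  }
  set.seed(config$seed)
  n <- config$n_stays
  ph <- config$physiology
  mo <- config$mortality
  prop <- config$unsafe_propensity
  sh <- config$step_hours

  sev <- rbeta(n, 2, 3)
  weight <- clip(rnorm(n, 80, 15), 40, 140)
  # per-stay renal function scaling urine output; oliguric stays accumulate
  # fluid even under maintenance volumes
  renal <- 0.25 + 0.75 * rbeta(n, 2, 2)
  map <- clip(rnorm(n, 82 - 22 * sev, 9), 35, 130)
  bal <- numeric(n)            # cumulative balance incl. current step, mL
  tot_in <- numeric(n)
  hypo_steps <- integer(n)
  alive <- rep(TRUE, n)
  died <- rep(FALSE, n)
  rows <- vector("list", config$max_steps)

  for (t in seq_len(config$max_steps)) {
    cvp <- clip(ph$cvp_baseline + ph$balance_cvp_gain * bal / 1000 +
                  rnorm(n, 0, ph$cvp_noise_sd), 0, 30)
    hypo_steps <- hypo_steps + as.integer(map < 65)
    lactate <- clip(0.8 + 1.8 * sev + 0.3 * hypo_steps +
                      rnorm(n, 0, ph$lactate_noise_sd), 0.2, 25)
    urine <- clip(renal * (120 * (1 - 0.7 * sev) +
                             2.0 * pmax(map - 55, 0)) * sh / 4 +
                    rnorm(n, 0, ph$urine_noise_sd), 0, 2000)
    sofa <- as.integer(clip(round(13 * sev + 0.12 * pmax(65 - map, 0) +
                                    2 * (urine < 60) + 1.5 * (lactate > 4)),
                            0, 24))
    sedation <- as.integer(runif(n) < 0.25 + 0.4 * sev)

    act <- .behaviour_doses(map, sev, sh)
    fluid <- act$fluid
    vaso <- act$vaso

    # At-risk conditions on the observed (pre-action) state; the unsafe
    # action replaces the guideline dose with the configured propensity.
    risk_a <- map < 55
    risk_b <- map > 95
    risk_c <- map <= 55 & cvp <= 5
    risk_d <- map >= 75 & bal > 10000 & cvp >= 15
    u <- matrix(runif(4L * n), ncol = 4L)
    fire_a <- risk_a & u[, 1L] < prop[["A"]]
    fire_b <- risk_b & u[, 2L] < prop[["B"]]
    fire_c <- risk_c & u[, 3L] < prop[["C"]]
    fire_d <- risk_d & u[, 4L] < prop[["D"]]
    low_fluid <- runif(n, 0, 20 * sh)
    high_fluid <- runif(n, 241, 400) * sh
    high_vaso <- runif(n, 0.66, 1.2)
    # C before A: "no fluids" is the stricter fluid condition.
    fluid[fire_a] <- low_fluid[fire_a]
    vaso[fire_a] <- 0
    fluid[fire_c] <- 0
    vaso[fire_b] <- high_vaso[fire_b]
    fluid[fire_d] <- high_fluid[fire_d]

    bal_new <- bal + fluid - urine
    tot_new <- tot_in + fluid

    p_death <- plogis(mo$intercept + mo$severity * sev +
                        mo$hypotension * (map < 55) +
                        mo$fluid_overload * (bal_new > 10000))
    death_draw <- runif(n) < p_death

    idx <- which(alive)
    rows[[t]] <- data.frame(
      stay_id = idx, step_index = t,
      map = map[idx], cvp = cvp[idx],
      cumulative_balance = bal_new[idx], urine_output = urine[idx],
      sofa = sofa[idx], lactate = lactate[idx], sedation = sedation[idx],
      total_fluid_input = tot_new[idx], weight = weight[idx],
      action_fluid = fluid[idx], action_vaso = vaso[idx]
    )

    died <- died | (alive & death_draw)
    alive <- alive & !death_draw
    bal <- bal_new
    tot_in <- tot_new

    # Transition to the next observed state.
    # vasoplegia: fluids hold blood pressure less well as severity rises
    map_next <- clip(map + ph$map_reversion * (ph$map_setpoint - map) +
                       ph$fluid_map_gain * (1 - 0.5 * sev) *
                         log1p(fluid / 250) +
                       ph$vaso_map_gain * vaso -
                       ph$severity_map_drain * sev +
                       rnorm(n, 0, ph$map_noise_sd), 30, 140)
    sev <- clip(sev + rnorm(n, 0, ph$severity_drift_sd) +
                  0.02 * (map < 60) - 0.01 * (map >= 65 & map <= 90), 0, 1)
    map <- map_next
  }

  cohort <- do.call(rbind, rows)
  cohort <- cohort[order(cohort$stay_id, cohort$step_index), , drop = FALSE]
  rownames(cohort) <- NULL
  cohort$survived_90d <- as.integer(!died[cohort$stay_id])
  attr(cohort, "provenance") <- sprintf(
    "synthetic sepsafe cohort: n_stays=%d max_steps=%d step_hours=%g seed=%d",
    n, config$max_steps, sh, config$seed)
  class(cohort) <- c("sepsafe_cohort", "data.frame")
  validate_cohort(cohort)

  gt <- .recount_ground_truth(cohort, prop, sh)
  gt$realized_mortality <- mean(died)
  list(cohort = cohort, ground_truth = gt)
}

# Realized at-risk / unsafe counts recounted from the emitted rows with the
# default scenario definitions, so ground truth always agrees with what a
# downstream audit of the same table will see.
.recount_ground_truth <- function(cohort, prop, step_hours) {
  rate <- cohort$action_fluid / step_hours
  risk <- cbind(
    A = cohort$map < 55,
    B = cohort$map > 95,
    C = cohort$map <= 55 & cohort$cvp <= 5,
    D = cohort$map >= 75 & cohort$cumulative_balance > 10000 & cohort$cvp >= 15
  )
  unsafe <- cbind(
    A = risk[, "A"] & cohort$action_vaso == 0 & rate <= 20,
    B = risk[, "B"] & cohort$action_vaso > 0.65,
    C = risk[, "C"] & rate == 0,
    D = risk[, "D"] & rate > 240
  )
  structure(
    list(configured_propensity = prop,
         at_risk = colSums(risk), unsafe = colSums(unsafe)),
    class = "sepsafe_ground_truth"
  )
}

#' Summarise simulator ground truth per hazard scenario
#'
#' @param gt the `ground_truth` element returned by [generate_cohort()].
#' @return a data frame with one row per scenario: configured propensity,
#'   realized at-risk count, realized unsafe count, and realized rate
#'   (`NA` where no step was at risk).
#' @export
ground_truth_summary <- function(gt) {
  if (!inherits(gt, "sepsafe_ground_truth")) {
    stop_sepsafe("gt must come from generate_cohort()")
  }
  rate <- ifelse(gt$at_risk > 0, gt$unsafe / gt$at_risk, NA_real_)
  data.frame(
    scenario = names(gt$at_risk),
    configured_propensity = unname(gt$configured_propensity[names(gt$at_risk)]),
    at_risk = unname(gt$at_risk),
    unsafe = unname(gt$unsafe),
    rate = unname(rate)
  )
}
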