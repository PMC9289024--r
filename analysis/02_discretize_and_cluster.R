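#!/usr/bin/env Rscript
# Discretize the recorded doses onto the 5 x 5 action grid and cluster the
# clinical features into patient states — the discrete MDP scaffolding.

source("analysis/00_config.R")

cohort <- read_cohort(file.path(results_dir, "cohort.csv"))
cfg <- analysis_config

grid <- discretize_actions(cohort)
bins <- data.frame(
  drug = rep(c("fluid_mL_per_step", "vasopressor_ug_kg_min"), each = 5),
  bin = rep(0:4, 2),
  lower_edge = c(0, min(cohort$action_fluid[cohort$action_fluid > 0]),
                 grid$fluid$edges,
                 0, min(cohort$action_vaso[cohort$action_vaso > 0]),
                 grid$vaso$edges),
  representative_dose = c(grid$fluid$representative,
                          grid$vaso$representative)
)
write.csv(bins, file.path(results_dir, "action_grid.csv"), row.names = FALSE)

seed_cluster <- sepsafe:::derive_seed(cfg$seed, 2L)
sm <- fit_state_clusters(cohort, k = cfg$k, seed = seed_cluster)
states <- assign_states(sm, cohort)
state_sizes <- as.data.frame(table(state = states))
write.csv(state_sizes, file.path(results_dir, "state_sizes.csv"),
          row.names = FALSE)

cat(sprintf("Action grid: %d fluid bins, %d vasopressor bins (25 composed actions)\n",
            grid$fluid$n_bins, grid$vaso$n_bins))
cat(sprintf("Fluid quartile edges (mL/step): %s\n",
            paste(round(grid$fluid$edges), collapse = ", ")))
cat(sprintf("State model: k = %d clusters over %d timesteps; occupancy %d-%d steps\n",
            cfg$k, nrow(cohort), min(state_sizes$Freq), max(state_sizes$Freq)))
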