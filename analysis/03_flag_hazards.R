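#!/usr/bin/env Rscript
# Audit the recorded (human) decisions against the four hazard scenarios and
# sweep the blood-pressure thresholds, since "low" and "high" blood pressure
# have no universally agreed cut-off.

source("analysis/00_config.R")

cohort <- read_cohort(file.path(results_dir, "cohort.csv"))
flags <- flag_cohort(cohort, step_hours = analysis_config$step_hours)
counts <- flag_counts(flags)
write.csv(counts, file.path(results_dir, "flag_counts_human.csv"),
          row.names = FALSE)

cat("Human unsafe-decision audit (per scenario and any-scenario union):\n")
print(counts[counts$agent == "human", ], row.names = FALSE)

scen <- default_scenarios()
for (s in names(scen)) {
  sw <- sweep_thresholds(cohort, scen[[s]], default_threshold_grid(s),
                         step_hours = analysis_config$step_hours)
  write.csv(sw, file.path(results_dir,
                          sprintf("threshold_sweep_%s_human.csv", s)),
            row.names = FALSE)
}
cat("\nThreshold sweeps written for scenarios",
    paste(names(scen), collapse = ", "),
    "(human counts; policy comparison in 04/07).\n")
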