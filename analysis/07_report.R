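#!/usr/bin/env Rscript
# Collate the full safety-assurance report: per-scenario proportions for the
# three agents, threshold-sweep significance, the any-scenario union with
# relative reductions, action-distribution histograms, and policy values.

source("analysis/00_config.R")

run <- get_run()
rep <- pipeline_report(run)
cohort <- run$cohort

lines <- c("# Safety-assurance report (synthetic cohort)", "")
lines <- c(lines, sprintf("Cohort: %d stays, %d timesteps, seed %d.",
                          run$config$n_stays, nrow(cohort),
                          run$config$seed), "")

lines <- c(lines, "## Unsafe-decision proportions", "")
tab <- rep$proportions[rep$proportions$scenario != "any", ]
lines <- c(lines, "scenario | agent | N at risk | unsafe | proportion",
           "---|---|---|---|---")
lines <- c(lines, sprintf("%s | %s | %d | %d | %s",
                          tab$scenario, tab$agent, tab$N, tab$x,
                          ifelse(is.na(tab$proportion), "not evaluable",
                                 sprintf("%.3f", tab$proportion))))
lines <- c(lines, "", "## Any-scenario union", "",
           "agent | unsafe steps | % of all steps | relative reduction vs human",
           "---|---|---|---",
           sprintf("%s | %d | %.2f%% | %.1f%%",
                   rep$union$agent, rep$union$unsafe, rep$union$pct_of_steps,
                   rep$union$relative_reduction_vs_human_pct))

lines <- c(lines, "", "## Policy values (WIS, stay-level bootstrap)", "",
           "agent | estimate | median | IQR",
           "---|---|---|---",
           sprintf("%s | %.1f | %.1f | %.1f to %.1f",
                   rep$ope$agent, rep$ope$estimate, rep$ope$median,
                   rep$ope$iqr_lo, rep$ope$iqr_hi))

lines <- c(lines, "", "## Recommended-action distributions (25 actions)", "")
for (nm in names(rep$action_histograms)) {
  h <- rep$action_histograms[[nm]]
  lines <- c(lines, sprintf("%s policy: %d states; actions used: %s",
                            nm, sum(h),
                            paste(which(h > 0) - 1L, collapse = ", ")))
}

if (!is.null(run$sweeps)) {
  lines <- c(lines, "", "## Threshold sweeps (human vs original policy)", "")
  for (s in names(run$sweeps)) {
    sw <- run$sweeps[[s]]
    sig <- sum(sw$p_value < 0.05, na.rm = TRUE)
    lines <- c(lines, sprintf(
      "Scenario %s: %d of %d thresholds show the policy significantly safer (one-sided p < 0.05).",
      s, sig, nrow(sw)))
    write.csv(sw, file.path(results_dir,
                            sprintf("threshold_sweep_%s_policy.csv", s)),
              row.names = FALSE)
  }
}

writeLines(lines, file.path(results_dir, "report.md"))
cat(paste(lines, collapse = "\n"), "\n")
cat("\nReport written to results/report.md\n")
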