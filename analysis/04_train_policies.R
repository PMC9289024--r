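#!/usr/bin/env Rscript
# Train the original policy (terminal survival reward only) and the
# safety-constrained policy (30-point intermediate penalty on unsafe
# state-action instances) by Q-learning on the estimated MDP, then audit all
# three agents on the shared at-risk sets.

source("analysis/00_config.R")

run <- get_run()
rep <- pipeline_report(run)

write.csv(rep$proportions, file.path(results_dir, "audit_proportions.csv"),
          row.names = FALSE)
write.csv(rep$tests, file.path(results_dir, "audit_ztests.csv"),
          row.names = FALSE)
pol <- data.frame(
  state = seq_len(run$mdp$nS),
  original_action = unclass(run$policies$original),
  safe_action = unclass(run$policies$safe))
write.csv(pol, file.path(results_dir, "policies.csv"), row.names = FALSE)

cat("Unsafe-decision proportions (shared at-risk denominators):\n")
print(rep$proportions[rep$proportions$scenario != "any", ],
      row.names = FALSE)
cat("\nHuman-vs-policy one-sided z-tests (AI safer):\n")
print(rep$tests, row.names = FALSE)
n_changed <- sum(pol$original_action != pol$safe_action, na.rm = TRUE)
cat(sprintf("\nSafety penalty changed the recommendation in %d of %d states.\n",
            n_changed, sum(!is.na(pol$original_action))))
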