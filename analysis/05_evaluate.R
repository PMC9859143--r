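#!/usr/bin/env Rscript
# Step 5 — repeated stratified cross-validation over classifiers and
# feature sets.
#
# Four feature sets (original risk factors, node embeddings, embeddings +
# topological features, and everything combined) are evaluated with seven
# classifiers under 5x5 stratified CV. Graph features are computed once on
# the full cohort (transductive protocol; the label never enters the graph).
# With all seven classifiers at the full cohort size this is a long-running
# batch job; pass a classifier subset to restrict it.

suppressMessages(library(lbwgraph))
args <- commandArgs(trailingOnly = TRUE)
classifiers <- if (length(args) >= 1) {
  strsplit(args[1], ",")[[1]]
} else {
  names(lbw_classifiers())
}
seed <- if (length(args) >= 2) as.integer(args[2]) else 1L

cohort <- read_cohort("results/cohort.csv")
cfg <- experiment_config(cohort, classifiers = classifiers, seed = seed)
report <- run_experiment(cfg)

utils::write.csv(as.data.frame(report), "results/evaluation_report.csv",
                 row.names = FALSE)
cat("wrote results/evaluation_report.csv\n")
print(as.data.frame(report)[, c("classifier", "feature_set", "precision",
                                "recall", "fscore", "auc", "pr_lbw",
                                "pr_overall")], digits = 3)
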