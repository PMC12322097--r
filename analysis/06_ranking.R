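#!/usr/bin/env Rscript
# Step 6 — ranking every possible test against the benchmark.
#
# Enumerates all 2048 attribute-level combinations, computes each profile's
# probability of being chosen over the benchmark multi-cancer test (PPV 76%,
# NPV 98%, 1-2 weeks, identifies the site, blood, early-stage, 25 cancers;
# off-grid accuracies interpolated between level coefficients) for each
# stakeholder group, and compares the single-cancer clinical tests (FIT,
# PSA, CA125; illustrative accuracy profiles) to the same benchmark.

library(mctchoice)

fit <- read_fit("results/pooled_fit.json")
schema <- mct_schema()
bm <- read_benchmarks()

for (g in c("gp", "public")) {
  rk <- rank_against_benchmark(schema, bm$benchmark, fit, g)
  print(rk)
  write.csv(rk$table, sprintf("results/ranking_%s.csv", g), row.names = FALSE)
  cat("Top 3 profiles vs benchmark:\n")
  print(head(rk$table[c(names(schema), "prob_vs_benchmark", "rank")], 3),
        row.names = FALSE)
}

cl <- compare_clinical_tests(bm$comparators, bm$benchmark, fit,
                             groups = c("gp", "public"))
cat("Clinical comparators vs benchmark (probability chosen over it):\n")
print(transform(cl, prob_vs_benchmark = round(prob_vs_benchmark, 3)),
      row.names = FALSE)
write.csv(cl, "results/clinical_comparison.csv", row.names = FALSE)
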