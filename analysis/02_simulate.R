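#!/usr/bin/env Rscript
# Step 2 — synthetic study population and stated choices.
#
# Draws 251 GPs (full 7-attribute design) and 1005 members of the public
# (randomised 50/50 to the PPV-only or NPV-only arm), each answering their
# block's 12 tasks, at the package's fixture truth: mean coefficients
# transcribed from published GP/public preference estimates, random PPV/NPV
# level coefficients, public-sample shifts inside the public scale, and
# group-balancing weights. Writes the long-format choice data and the truth
# used (for later recovery checks).

library(mctchoice)

seed <- 20260927L
dir.create("results", showWarnings = FALSE)

design <- read_design("results/design", mct_schema())

# the pooled model's data-generating process (demographic and latent shifts
# are exercised separately in steps 03b/04)
truth <- true_parameters(covariate = 0, tau = 0)
write_truth(truth, "results/truth_pooled.json")

resp <- generate_respondents(251, 1005, truth, seed = seed + 21L)
cat("Respondents:", nrow(resp), "- arms:",
    paste(names(table(resp$arm)), table(resp$arm), collapse = ", "), "\n")

choices <- simulate_choices(design, resp, truth, seed = seed + 22L)
cat("Choice rows:", nrow(choices), "(",
    nrow(choices) / 2, "respondent-tasks )\n")
share <- mean(choices$chosen[choices$alternative == 1])
cat(sprintf("Alternative-1 share: %.3f\n", share))
write_choice_data(choices, "results/choices_pooled.csv")

# public-only population with latent-variable effects for the ICLV analysis
truth_iclv <- true_parameters(sigma = 0, covariate = 0, lambda_pub = 1)
write_truth(truth_iclv, "results/truth_iclv.json")
resp_i <- generate_respondents(0, 1005, truth_iclv, seed = seed + 51L)
choices_i <- simulate_choices(design, resp_i, truth_iclv, seed = seed + 52L)
write_choice_data(choices_i, "results/choices_iclv.csv")
cat("ICLV sample:", nrow(resp_i), "public respondents;",
    "latent-score SD:", round(sd(resp_i$latent_score), 2), "\n")
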