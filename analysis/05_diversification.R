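#!/usr/bin/env Rscript
# Stage 5 -- lineages-through-time and diversification-rate-shift test.
#
# The real analysis pruned the ITS data to 37 species-level lineages, built
# an ultrametric tree, and asked whether the speciation rate changed over
# time by contrasting the best rate-constant against the best rate-variable
# model (AIC), with significance judged against 5000 constant-rate trees of
# the same size. Here the 37-tip ultrametric input is simulated under a
# density-dependent slowdown -- the regime the real data were found to be
# in -- so the expected outcome is a positive AIC difference and a small p.

suppressMessages(library(cophyr))

out <- "results/diversification"
dir.create(out, recursive = TRUE, showWarnings = FALSE)
seed <- 2024L

set.seed(stage_seed(seed, 500))
ages <- simulate_branching_ages(37, function(k) 1.0 * (1 - k / 40))

utils::write.table(ltt_series(ages), file.path(out, "ltt.tsv"), sep = "\t",
                   quote = FALSE, row.names = FALSE)

fits <- fit_models(ages)
print(fits[, c("model", "logL", "k", "AIC")])

shift <- rate_shift_test(ages, n_null = 5000, seed = stage_seed(seed, 501))
message(sprintf("delta AIC (best rate-constant - best rate-variable) = %.2f", shift$delta_aic))
message(sprintf("p = %.4g against %d constant-rate trees of %d tips",
                shift$p_value, shift$n_null, shift$n_tips))

jsonlite::write_json(list(
  fits = fits[, c("model", "logL", "k", "AIC")],
  delta_aic = shift$delta_aic,
  p_value = shift$p_value,
  n_null = shift$n_null,
  n_tips = shift$n_tips,
  lambda_null = shift$lambda),
  file.path(out, "summary.json"), auto_unbox = TRUE, digits = NA, pretty = TRUE)
message("wrote ", out)
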