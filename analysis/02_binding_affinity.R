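#!/usr/bin/env Rscript

# Quantify RNA-protein affinity from the simulated EMSA titrations: fit
# the single-site isotherm (maximal binding fixed at 100%) for a
# wild-type-like and a weakened-mutant-like dataset and attach bootstrap
# intervals. Expectation: the apparent Kd of the mutant roughly doubles.

suppressPackageStartupMessages(library(rnakin))
dir.create("results", showWarnings = FALSE)
seed <- 202
design <- builtin_design("emsa_titration")

rows <- lapply(list(c(label = "WT", kd = 1.39),
                    c(label = "Y82A-like", kd = 3.0)), function(x) {
  kd <- as.numeric(x[["kd"]])
  dat <- generate_binding_dataset(design, binding_params(kd), seed = seed)
  fit <- fit_binding_isotherm(dat)
  fit <- bootstrap_ci(fit, n_resamples = 1000, seed = seed + 1)
  write_fit_json(fit, sprintf("results/binding_fit_%s.json", x[["label"]]),
                 config = list(design = design$name, truth_kd = kd,
                               seed = seed))
  data.frame(variant = x[["label"]], truth_kd_uM = kd,
             kd_app_uM = fit$estimates[["kd_app"]],
             se_uM = fit$se[["kd_app"]],
             ci_lower = fit$boot$ci["lower", "kd_app"],
             ci_upper = fit$boot$ci["upper", "kd_app"])
})
tab <- do.call(rbind, rows)
utils::write.csv(tab, "results/binding_fits.csv", row.names = FALSE)

cat("EMSA binding isotherm fits (percent bound vs SHMT1, 0.3-9.6 uM):\n")
print(tab, digits = 3, row.names = FALSE)
cat("The weakened variant binds about",
    sprintf("%.1f-fold", tab$kd_app_uM[2] / tab$kd_app_uM[1]),
    "less tightly than wild type.\n")
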