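#!/usr/bin/env Rscript

# Generate the study's four experimental layouts as synthetic datasets:
# the THF x tRNA velocity matrix (hyperbolic competitive truth), the
# serine x tRNA matrix (mixed-inhibition truth), the EMSA protein
# titration (wild-type affinity) and the RNA inhibition curve (forward
# UTR2 potency). All constants reported by the kinetic characterisation
# are used as generating truths; 5% CV, triplicates, fixed seed.

suppressPackageStartupMessages(library(rnakin))
dir.create("results/data", recursive = TRUE, showWarnings = FALSE)
seed <- 101

truth_thf <- kinetic_params(vmax = 1, km = 50, ki_thf = 200,
                            ki = 0.031, alpha = 18.8)
tab <- generate_velocity_matrix(builtin_design("thf_trna_matrix"),
                                truth_thf, seed = seed)
write_velocity_table(tab, "results/data/velocity_thf_trna.csv")

truth_ser <- kinetic_params(vmax = 1, km = 1000, ki = 0.5, alpha = 1)
ser <- generate_velocity_matrix(builtin_design("serine_trna_matrix"),
                                truth_ser, model = "pure_mixed",
                                seed = seed)
write_velocity_table(ser, "results/data/velocity_serine_trna.csv")

emsa <- generate_binding_dataset(builtin_design("emsa_titration"),
                                 binding_params(kd_app = 1.39),
                                 seed = seed)
utils::write.csv(emsa, "results/data/emsa_titration.csv",
                 row.names = FALSE, quote = FALSE)

icc <- generate_inhibition_curve(builtin_design("ic50_curve"),
                                 inhibition_params(ic50 = 0.033),
                                 seed = seed)
utils::write.csv(icc, "results/data/inhibition_curve.csv",
                 row.names = FALSE, quote = FALSE)

cat("Simulated datasets (seed", seed, "):\n")
cat(sprintf("  velocity_thf_trna.csv    %4d rows (6 tRNA x 8 THF x 3 reps)\n",
            nrow(tab)))
cat(sprintf("  velocity_serine_trna.csv %4d rows (6 tRNA x 7 serine x 3 reps)\n",
            nrow(ser)))
cat(sprintf("  emsa_titration.csv       %4d rows\n", nrow(emsa)))
cat(sprintf("  inhibition_curve.csv     %4d rows\n", nrow(icc)))
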