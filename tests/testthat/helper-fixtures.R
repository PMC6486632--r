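# shared generating truths: the reported constants of the study system
# (inhibition constants for tRNA vs THF) plus plausible assay-scale values
# for the unreported Vmax/Km/KiTHF
truth_hyperbolic <- function() {
  kinetic_params(vmax = 1, km = 50, ki_thf = 200, ki = 0.031, alpha = 18.8)
}

truth_competitive <- function() {
  kinetic_params(vmax = 1, km = 50, ki_thf = 200, ki = 0.031)
}

truth_mixed_serine <- function() {
  kinetic_params(vmax = 1, km = 1000, ki = 0.5, alpha = 1)
}

noiseless <- function(name) builtin_design(name, cv = 0)

quiet <- function(expr) suppressMessages(suppressWarnings(expr))
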