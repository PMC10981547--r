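#!/usr/bin/env Rscript
# Which biometric covariates track the positional color difference?
# Pearson r for numeric items, correlation ratio (eta^2) for categorical
# ones, on the reported per-patient dE00 values.

suppressMessages(library(tonguecolor))
dir.create("results", showWarnings = FALSE)

assoc <- associate_covariates(tongue_cohort_lab()$dE00,
                              tongue_cohort_biometrics())
write.csv(assoc, "results/associations.csv", row.names = FALSE)
sig <- assoc[assoc$p_value < 0.05, ]
cat("Covariates with p < 0.05:\n")
print(sig[order(-abs(sig$value)), c("item", "statistic", "value", "p_value")],
      row.names = FALSE)
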