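#!/usr/bin/env Rscript
# Laboratory values above the prompt-consultation reference criteria,
# cross-tabulated against the acceptability of each patient's positional
# color difference.

suppressMessages(library(tonguecolor))
dir.create("results", showWarnings = FALSE)

tab <- compare_lab_table(tongue_cohort_lab())
flags <- flag_table(tongue_cohort_biometrics(), reference_criteria())
write.csv(flags, "results/reference_flags.csv", row.names = FALSE)
split <- count_flags_by_group(tab, flags)
write.csv(split, "results/flags_by_group.csv", row.names = FALSE)
print(split, row.names = FALSE)
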