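#!/usr/bin/env Rscript
# Stage 2: detect de novo events in the fixture written by 01_simulate.R
# and check the zero-noise calls against the planted truth.

suppressMessages(library(mutacc))

exp <- read_fixture("scratch/fixture")
filters <- filter_config()

nuc <- call_nuclear_mutations(exp, filters)
mito <- call_mito_mutations(exp, filters)
tracts <- detect_conversion_tracts(exp, max_gap = 10000, filters)

write.table(nuc, "results/nuclear_calls.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
write.table(mito, "results/mito_calls.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
write.table(tracts$tracts, "results/conversion_tracts.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(tracts$sites, "results/conversion_sites.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

cat(sprintf("nuclear calls: %d (planted %d)\n", nrow(nuc),
            nrow(exp$truth$nuclear)))
cat(sprintf("converted sites: %d in %d tracts (planted %d sites)\n",
            nrow(tracts$sites), nrow(tracts$tracts),
            nrow(exp$truth$tracts)))
cat(sprintf(
  "mito heteroplasmies >= %.2f frequency: %d of %d planted (the floor\n",
  filters$mito_min_frequency, nrow(mito), nrow(exp$truth$mito)))
cat("excludes low-frequency drift variants, as in real heteroplasmy calling)\n")
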