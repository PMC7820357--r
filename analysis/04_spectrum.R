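#!/usr/bin/env Rscript
# Stage 4: six-class and 32-context mutation spectra with conditional
# rates, Ts:Tv, the spectrum homogeneity test, the central-base contrast,
# and the CpG contrast across genotypes.

suppressMessages(library(mutacc))

exp <- read_fixture("scratch/fixture")
nuc <- call_nuclear_mutations(exp, filter_config())
ma_md <- exp$metadata[exp$metadata$role == "MA", ]
calls <- nuc[nuc$line_id %in% ma_md$line_id & !is.na(nuc$context), ]
denom <- count_callable_sites(exp$reference, "trinucleotide_context")
g_total <- sum(ma_md$generations)

sp <- context_conditional_rates(calls, denom, g_total)
write.table(data.frame(class = MUTATION_CLASSES,
                       count = as.numeric(sp$class_counts),
                       denominator = as.numeric(sp$class_denominators),
                       conditional_rate = as.numeric(sp$class_rates)),
            "results/spectrum_6class.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
write.table(data.frame(context = names(sp$context_counts),
                       count = as.numeric(sp$context_counts),
                       denominator = as.numeric(sp$context_denominators),
                       conditional_rate = as.numeric(sp$context_rates)),
            "results/spectrum_32context.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

cat(sprintf("nuclear mutations with context: %d\n", nrow(calls)))
cat(sprintf("most common class: %s\n",
            names(which.max(sp$class_counts))))
cat(sprintf("count-based Ts:Tv: %.2f (simulator plants 1.54)\n", ts_tv(sp)))
cat(sprintf("central-C / central-A conditional rate ratio: %.2f\n",
            sp$central_rates[["C"]] / sp$central_rates[["A"]]))

ht <- suppressWarnings(
  spectrum_homogeneity_test(sp$class_counts, sp$class_denominators))
cat(sprintf("spectrum homogeneity: chi-square = %.1f, df = %d, P = %.3g\n",
            ht$statistic, ht$df, ht$p.value))
cat("(at demo scale the per-class counts are small; the full-scale test is\n")
cat(" exercised in the package test suite)\n")

by_geno <- lapply(split(ma_md, ma_md$genotype_id), function(md) {
  context_conditional_rates(calls[calls$line_id %in% md$line_id, ], denom,
                            sum(md$generations))
})
cpg <- cpg_contrast(by_geno)
cat(sprintf("CpG vs non-CpG central-C contrast: t = %.2f, df = %d\n",
            cpg$statistic, cpg$df))
stats_tbl <- data.frame(
  statistic = c("ts_tv_count", "central_C_over_A", "homogeneity_chisq",
                "homogeneity_df", "cpg_t", "cpg_df"),
  value = c(ts_tv(sp), sp$central_rates[["C"]] / sp$central_rates[["A"]],
            ht$statistic, ht$df, cpg$statistic, cpg$df))
write.table(stats_tbl, "results/spectrum_stats.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
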