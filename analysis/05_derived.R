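#!/usr/bin/env Rscript
# Stage 5: derived evolutionary quantities from the detected rates:
# equilibrium GC content, mutation/conversion heterozygosity equilibrium,
# effective population size, heritability/evolvability of the rate as a
# trait, the population ANOVA, and the correlation with an external
# (synthetic) microsatellite rate table.

suppressMessages(library(mutacc))

exp <- read_fixture("scratch/fixture")
filters <- filter_config()
nuc <- call_nuclear_mutations(exp, filters)
mito <- call_mito_mutations(exp, filters)
tracts <- detect_conversion_tracts(exp, max_gap = 10000, filters)
line_tbl <- line_rate_table(exp, nuc, mito, tracts)
ma <- function(tbl) tbl[tbl$role == "MA", ]

bs <- ma(line_tbl[line_tbl$kind == "bs" & line_tbl$partition == "nuclear", ])
gc <- ma(line_tbl[line_tbl$kind == "gene_conversion", ])
mu_bs <- sum(bs$events) / sum(bs$exposure)
mu_gc <- sum(gc$events) / sum(gc$exposure)

ma_md <- exp$metadata[exp$metadata$role == "MA", ]
calls <- nuc[nuc$line_id %in% ma_md$line_id & !is.na(nuc$context), ]
denom <- count_callable_sites(exp$reference, "trinucleotide_context")
sp <- context_conditional_rates(calls, denom, sum(ma_md$generations))

gc_eq <- gc_equilibrium(sp$class_rates)
het_eq <- expected_heterozygosity(mu_bs, mu_gc)
# pi_s is an external input from population sequencing; this demo value is
# illustrative only (synthetic), not a published estimate
pi_s_demo <- 0.015
ne <- effective_population_size(pi_s_demo, mu_bs)

qg <- heritability_evolvability(bs$rate, bs$genotype_id)
geno <- aggregate_rates(bs, "genotype")
anova_out <- tryCatch(population_anova(geno$value, geno$population_id),
                      error = function(e) NULL)

# synthetic microsatellite rate table correlated with the line bs rates,
# standing in for an externally measured per-line microsatellite table
set.seed(2)
ms <- data.frame(line_id = bs$line_id,
                 mu_ms = abs(bs$rate * 50 + rnorm(nrow(bs), 0, 2e-7)))
write.table(ms, "results/microsat_rates_synthetic.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
cr <- correlate(bs$rate, ms$mu_ms)

derived <- data.frame(
  quantity = c("gc_equilibrium", "observed_gc", "expected_heterozygosity",
               "Ne_from_demo_pi", "H2", "evolvability_mean_sq",
               "evolvability_mean", "anova_F", "anova_df1", "anova_df2",
               "spearman_rho", "spearman_t", "spearman_df"),
  value = c(gc_eq,
            sum(Biostrings::letterFrequency(
              Biostrings::DNAString(exp$reference$seq[["nuc1"]]),
              c("G", "C"))) / nchar(exp$reference$seq[["nuc1"]]),
            het_eq, ne, qg$H2, qg$evolvability_mean_sq, qg$evolvability_mean,
            if (is.null(anova_out)) NA else anova_out$F,
            if (is.null(anova_out)) NA else anova_out$df1,
            if (is.null(anova_out)) NA else anova_out$df2,
            cr$rho, cr$t, cr$df))
write.table(derived, "results/derived_parameters.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

cat(sprintf("equilibrium GC from conditional rates: %.2f (observed %.2f)\n",
            gc_eq, derived$value[2]))
cat(sprintf("expected heterozygosity mu_bs/(mu_bs+mu_gc): %.3g\n", het_eq))
cat(sprintf("Ne from illustrative pi_s = %.3f: %.3g\n", pi_s_demo, ne))
cat(sprintf("H2 of the line bs rate: %.3f; evolvability (V_G/mean^2): %.3g\n",
            qg$H2, qg$evolvability_mean_sq))
if (!is.null(anova_out))
  cat(sprintf("population ANOVA on genotype rates: F(%d,%d) = %.2f\n",
              anova_out$df1, anova_out$df2, anova_out$F))
cat(sprintf("bs vs synthetic microsat rates: rho = %.2f, t(%d) = %.2f\n",
            cr$rho, cr$df, cr$t))
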