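# End-to-end orchestration: simulate (or read) -> detect -> rates ->
# spectrum -> derived quantities, with plain-text TSV/JSON outputs and a run
# log recording the seed. Deterministic given the seed.

#' Run the full MA analysis pipeline
#'
#' Either simulates an experiment from `config` or reads one from
#' `fixture_dir`, then calls nuclear/mito mutations and conversion tracts,
#' builds rate tables at all four aggregation levels under both aggregation
#' schemes (with bootstrap CIs), computes six-class and 32-context spectrum
#' tables, and derives equilibrium GC content, expected heterozygosity,
#' Ts:Tv, the spectrum homogeneity test and, where the design allows,
#' heritability/evolvability and the population ANOVA. All outputs are
#' plain-text TSV/JSON under `out_dir`.
#'
#' @param config An [sim_config()]; ignored when `fixture_dir` is given.
#' @param fixture_dir Optional fixture directory from [write_fixture()].
#' @param out_dir Output directory (created).
#' @param filters A [filter_config()].
#' @param max_gap Tract-clustering gap in bp.
#' @param B Bootstrap replicates for rate CIs (0 disables).
#' @param seed Seed for the bootstrap stage (simulation uses `config$seed`).
#' @return Invisibly, a list with the experiment, calls, tracts, rate and
#'   spectrum tables, and derived quantities.
#' @export
run_ma_pipeline <- function(config = NULL, fixture_dir = NULL, out_dir,
                            filters = filter_config(), max_gap = 10000,
                            B = 1000, seed = 1) {
  if (is.null(config) && is.null(fixture_dir))
    stop("supply a simulation config or a fixture directory", call. = FALSE)
  if (!is.null(fixture_dir) && !dir.exists(fixture_dir))
    stop("input path does not exist: ", fixture_dir, call. = FALSE)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE))
  }

  exp <- stage("input", {
    if (!is.null(fixture_dir)) read_fixture(fixture_dir)
    else simulate_ma_experiment(config)
  })

  nuc_calls <- stage("call_nuclear", call_nuclear_mutations(exp, filters))
  has_mito <- length(contigs_of(exp$reference, "mito")) > 0
  mito_calls <- if (has_mito)
    stage("call_mito", call_mito_mutations(exp, filters)) else NULL
  tracts <- stage("call_conversion",
                  detect_conversion_tracts(exp, max_gap, filters))

  line_tbl <- stage("rates", line_rate_table(exp, nuc_calls, mito_calls,
                                             tracts))
  set.seed(seed)
  kinds <- unique(line_tbl[, c("kind", "partition")])
  rate_tbl <- stage("rates", do.call(rbind, lapply(
    seq_len(nrow(kinds)), function(i) {
      sub <- line_tbl[line_tbl$kind == kinds$kind[i] &
                        line_tbl$partition == kinds$partition[i], ,
                      drop = FALSE]
      do.call(rbind, lapply(c("line", "genotype", "population", "species"),
        function(lv) {
          do.call(rbind, lapply(c("pooled", "mean_of_means"), function(sc) {
            r <- aggregate_rates(sub, level = lv, scheme = sc, B = B)
            miss <- setdiff(c("line_id", "genotype_id", "population_id"),
                            names(r))
            for (mcol in miss) r[[mcol]] <- NA_character_
            r[, c("level", "line_id", "genotype_id", "population_id",
                  "kind", "partition", "scheme", "event_count", "exposure",
                  "value", "n_lines",
                  if (B > 0) c("ci_low", "ci_high", "n_bootstrap",
                               "degenerate"))]
          }))
        }))
    })))

  spectrum <- stage("spectrum", {
    ctx_denom <- count_callable_sites(exp$reference,
                                      by = "trinucleotide_context")
    ma_lines <- exp$metadata[exp$metadata$role == "MA", ]
    g_total <- sum(ma_lines$generations)
    ma_calls <- nuc_calls[nuc_calls$line_id %in% ma_lines$line_id &
                            !is.na(nuc_calls$context), , drop = FALSE]
    overall <- context_conditional_rates(ma_calls, ctx_denom, g_total)
    by_geno <- lapply(split(ma_lines, ma_lines$genotype_id), function(md) {
      context_conditional_rates(
        ma_calls[ma_calls$line_id %in% md$line_id, , drop = FALSE],
        ctx_denom, sum(md$generations))
    })
    list(overall = overall, by_genotype = by_geno)
  })

  derived <- stage("derived", {
    sp <- spectrum$overall
    pooled_sp <- function(tbl, kind, part) {
      r <- tbl[tbl$level == "species" & tbl$kind == kind &
                 tbl$partition == part & tbl$scheme == "pooled", ]
      if (nrow(r)) r$value[1] else NA_real_
    }
    mu_bs <- pooled_sp(rate_tbl, "bs", "nuclear")
    mu_gc <- pooled_sp(rate_tbl, "gene_conversion", "nuclear")
    out <- list(
      ts_tv_count = ts_tv(sp, "count"),
      gc_equilibrium = tryCatch(gc_equilibrium(sp$class_rates),
                                error = function(e) NA_real_),
      expected_heterozygosity =
        if (!is.na(mu_bs) && !is.na(mu_gc) && mu_bs + mu_gc > 0)
          expected_heterozygosity(mu_bs, mu_gc) else NA_real_,
      homogeneity = tryCatch(
        spectrum_homogeneity_test(sp$class_counts, sp$class_denominators),
        error = function(e) list(statistic = NA_real_, df = NA_integer_,
                                 p.value = NA_real_))
    )
    geno_rates <- rate_tbl[rate_tbl$level == "genotype" &
                             rate_tbl$kind == "bs" &
                             rate_tbl$partition == "nuclear" &
                             rate_tbl$scheme == "pooled", ]
    line_bs <- line_tbl[line_tbl$kind == "bs" &
                          line_tbl$partition == "nuclear" &
                          line_tbl$role == "MA", ]
    out$quantgen <- tryCatch(
      heritability_evolvability(line_bs$rate, line_bs$genotype_id),
      error = function(e) NULL)
    out$population_anova <- tryCatch(
      population_anova(geno_rates$value, geno_rates$population_id),
      error = function(e) NULL)
    if (length(spectrum$by_genotype) >= 2)
      out$cpg <- tryCatch(cpg_contrast(spectrum$by_genotype),
                          error = function(e) NULL)
    out
  })

  stage("write", {
    wt <- function(d, f) utils::write.table(
      d, file.path(out_dir, f), sep = "\t", quote = FALSE, row.names = FALSE)
    wt(line_tbl, "line_rates.tsv")
    wt(rate_tbl, "rate_table.tsv")
    wt(nuc_calls, "nuclear_calls.tsv")
    if (!is.null(mito_calls)) wt(mito_calls, "mito_calls.tsv")
    wt(tracts$tracts, "conversion_tracts.tsv")
    wt(tracts$sites, "conversion_sites.tsv")
    sp <- spectrum$overall
    wt(data.frame(class = MUTATION_CLASSES,
                  count = as.numeric(sp$class_counts),
                  denominator = as.numeric(sp$class_denominators),
                  conditional_rate = as.numeric(sp$class_rates)),
       "spectrum_6class.tsv")
    wt(data.frame(context = all_contexts(),
                  count = as.numeric(sp$context_counts),
                  denominator = as.numeric(sp$context_denominators),
                  conditional_rate = as.numeric(sp$context_rates)),
       "spectrum_32context.tsv")
    jsonlite::write_json(
      list(n_tracts = nrow(tracts$tracts),
           n_converted_sites = nrow(tracts$sites),
           tracts = tracts$tracts),
      file.path(out_dir, "tract_report.json"), auto_unbox = TRUE,
      digits = I(15))
    dv <- derived
    jsonlite::write_json(
      list(ts_tv_count = dv$ts_tv_count,
           gc_equilibrium = dv$gc_equilibrium,
           expected_heterozygosity = dv$expected_heterozygosity,
           homogeneity_chisq = dv$homogeneity$statistic,
           homogeneity_df = dv$homogeneity$df,
           H2 = if (!is.null(dv$quantgen)) dv$quantgen$H2 else NULL,
           evolvability_mean_sq =
             if (!is.null(dv$quantgen)) dv$quantgen$evolvability_mean_sq
             else NULL,
           anova_F = if (!is.null(dv$population_anova))
             dv$population_anova$F else NULL,
           cpg_t = if (!is.null(dv$cpg)) dv$cpg$statistic else NULL),
      file.path(out_dir, "derived_parameters.json"), auto_unbox = TRUE,
      digits = I(15))
    writeLines(c(
      sprintf("mutacc version: %s",
              as.character(utils::packageVersion("mutacc"))),
      sprintf("R version: %s", R.version.string),
      sprintf("bootstrap seed: %s", seed),
      sprintf("simulation seed: %s",
              if (!is.null(exp$config)) exp$config$seed else "fixture"),
      sprintf("bootstrap replicates: %s", B),
      sprintf("tract max_gap: %s", max_gap)),
      file.path(out_dir, "run_log.txt"))
  })

  invisible(list(experiment = exp, nuclear_calls = nuc_calls,
                 mito_calls = mito_calls, tracts = tracts,
                 line_rates = line_tbl, rate_table = rate_tbl,
                 spectrum = spectrum, derived = derived))
}
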