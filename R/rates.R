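# Rate estimators, unit conversions, hierarchical aggregation, and
# line-resampling bootstrap confidence intervals.

#' Nuclear base-substitution rate per bp per generation
#'
#' `mu = x / (g * 2n)`: `x` accepted substitutions, `g` MA generations, `n`
#' haploid callable sites (`2n` diploid bases).
#'
#' @param x Event count (>= 0).
#' @param g Generations (>= 1).
#' @param n_callable_haploid Haploid callable sites (> 0).
#' @return Rate per bp per generation.
#' @export
nuclear_bs_rate <- function(x, g, n_callable_haploid) {
  assert_scalar_number(x, "x", min = 0)
  assert_scalar_number(g, "g", min = 1)
  if (!is.numeric(n_callable_haploid) || n_callable_haploid <= 0)
    stop("undefined rate: zero exposure", call. = FALSE)
  x / (g * 2 * n_callable_haploid)
}

#' Mitochondrial base-substitution rate per bp per generation
#'
#' `mu = sum(f_i) / (g * n)`: heteroplasmy frequencies are summed because,
#' under neutrality, a mutation at frequency `f` represents `f` of a fixed
#' mutation's expected contribution.
#'
#' @param frequencies Heteroplasmy frequencies, each in (0, 1]; may be empty.
#' @param g Generations (>= 1).
#' @param n_mito Mitochondrial callable sites (> 0).
#' @return Rate per bp per generation.
#' @export
mito_bs_rate <- function(frequencies, g, n_mito) {
  if (length(frequencies) &&
      any(frequencies <= 0 | frequencies > 1 | is.na(frequencies)))
    stop("heteroplasmy frequencies must lie in (0, 1]", call. = FALSE)
  assert_scalar_number(g, "g", min = 1)
  if (!is.numeric(n_mito) || n_mito <= 0)
    stop("undefined rate: zero exposure", call. = FALSE)
  sum(frequencies) / (g * n_mito)
}

#' Gene-conversion rate per ancestral heterozygous site per generation
#'
#' `mu = x_g / (g * n_het)` with `x_g` the number of converted sites and
#' `n_het` the ancestral heterozygous-site count.
#'
#' @param x_g Converted-site count (>= 0).
#' @param g Generations (>= 1).
#' @param n_het Ancestral heterozygous sites (> 0).
#' @return Rate per heterozygous site per generation.
#' @export
conversion_rate <- function(x_g, g, n_het) {
  assert_scalar_number(x_g, "x_g", min = 0)
  assert_scalar_number(g, "g", min = 1)
  if (!is.numeric(n_het) || n_het <= 0)
    stop("undefined rate: zero heterozygous-site exposure", call. = FALSE)
  x_g / (g * n_het)
}

#' Per-line event and exposure table
#'
#' One row per line and rate kind, the common input to aggregation,
#' bootstrap, and MA-vs-control comparisons. Exposures are `g * 2n` (nuclear
#' bs), `g * n_mito` (mito bs) and `g * n_het` (gene conversion, with the
#' genotype's ancestral het count).
#'
#' @param exp An `ma_experiment`.
#' @param nuclear_calls Output of [call_nuclear_mutations()].
#' @param mito_calls Output of [call_mito_mutations()] (or `NULL`).
#' @param tracts Output of [detect_conversion_tracts()] (or `NULL`).
#' @return data.frame with columns line_id, genotype_id, population_id,
#'   role, kind, partition, events, exposure, rate.
#' @export
line_rate_table <- function(exp, nuclear_calls, mito_calls = NULL,
                            tracts = NULL) {
  md <- exp$metadata
  nuc <- contigs_of(exp$reference, "nuclear")
  mito <- contigs_of(exp$reference, "mito")
  rows <- lapply(seq_len(nrow(md)), function(i) {
    lid <- md$line_id[i]
    g <- md$generations[i]
    n_nuc <- mask_width(mask_intersect(exp$reference$mask, exp$masks[[lid]]),
                        nuc)
    out <- data.frame(
      line_id = lid, genotype_id = md$genotype_id[i],
      population_id = md$population_id[i], role = md$role[i],
      kind = "bs", partition = "nuclear",
      events = sum(nuclear_calls$line_id == lid),
      exposure = g * 2 * n_nuc, stringsAsFactors = FALSE)
    if (!is.null(mito_calls) && length(mito)) {
      n_mt <- mask_width(mask_intersect(exp$reference$mask,
                                        exp$masks[[lid]]), mito)
      out <- rbind(out, data.frame(
        line_id = lid, genotype_id = md$genotype_id[i],
        population_id = md$population_id[i], role = md$role[i],
        kind = "bs", partition = "mito",
        events = sum(mito_calls$f[mito_calls$line_id == lid]),
        exposure = g * n_mt, stringsAsFactors = FALSE))
    }
    if (!is.null(tracts)) {
      n_het <- exp$ancestors[[md$genotype_id[i]]]$n_het
      out <- rbind(out, data.frame(
        line_id = lid, genotype_id = md$genotype_id[i],
        population_id = md$population_id[i], role = md$role[i],
        kind = "gene_conversion", partition = "nuclear",
        events = sum(tracts$sites$line_id == lid),
        exposure = g * n_het, stringsAsFactors = FALSE))
    }
    out
  })
  tbl <- do.call(rbind, rows)
  tbl$rate <- ifelse(tbl$exposure > 0, tbl$events / tbl$exposure, NA_real_)
  rownames(tbl) <- NULL
  tbl
}

level_groups <- function(level) {
  switch(level,
         line = c("line_id", "genotype_id", "population_id"),
         genotype = c("genotype_id", "population_id"),
         population = "population_id",
         species = character(0),
         stop("unknown aggregation level: ", level))
}

#' Aggregate line-level rates to genotype, population, or species level
#'
#' `pooled` divides summed events by summed exposures (exposure-weighted);
#' `mean_of_means` takes the unweighted mean of the next lower level's
#' values (line -> genotype -> population -> species). With `B > 0`, a
#' percentile bootstrap CI is attached by resampling lines with replacement
#' within each group (the line is the independent unit of an MA design).
#'
#' @param line_tbl One kind/partition subset of [line_rate_table()].
#' @param level `"line"`, `"genotype"`, `"population"` or `"species"`.
#' @param scheme `"pooled"` or `"mean_of_means"`.
#' @param B Bootstrap replicates (0 = no CI; >= 100 otherwise).
#' @param seed Optional seed for the bootstrap.
#' @param conf Confidence level for the percentile interval.
#' @param roles Line roles included (default MA lines only).
#' @return data.frame of class `ma_rates`: grouping columns plus value,
#'   event_count, exposure, n_lines, scheme and (with `B > 0`) ci_low,
#'   ci_high, n_bootstrap, degenerate.
#' @export
aggregate_rates <- function(line_tbl,
                            level = c("species", "population", "genotype",
                                      "line"),
                            scheme = c("pooled", "mean_of_means"),
                            B = 0, seed = NULL, conf = 0.95, roles = "MA") {
  level <- match.arg(level)
  scheme <- match.arg(scheme)
  stopifnot(all(c("line_id", "events", "exposure") %in% names(line_tbl)))
  if (length(unique(paste(line_tbl$kind, line_tbl$partition))) > 1)
    stop("aggregate one kind/partition at a time", call. = FALSE)
  tbl <- line_tbl[line_tbl$role %in% roles, , drop = FALSE]
  if (!nrow(tbl)) stop("no lines in the requested roles", call. = FALSE)
  if (B > 0) {
    if (B < 100) stop("B must be >= 100", call. = FALSE)
    if (!is.null(seed)) set.seed(seed)
  }
  gcols <- level_groups(level)
  key <- if (length(gcols)) interaction(tbl[gcols], drop = TRUE)
         else factor(rep("all", nrow(tbl)))
  groups <- split(tbl, key)
  res <- lapply(groups, function(d) {
    value <- if (scheme == "pooled") sum(d$events) / sum(d$exposure)
             else mean_of_means_value(d, level)
    row <- d[1, gcols, drop = FALSE]
    row$level <- level
    row$kind <- d$kind[1]
    row$partition <- d$partition[1]
    row$scheme <- scheme
    row$event_count <- sum(d$events)
    row$exposure <- sum(d$exposure)
    row$value <- value
    row$n_lines <- nrow(d)
    if (B > 0) {
      ci <- bootstrap_ci(d$events, d$exposure, B = B, conf = conf,
                         statistic = if (scheme == "pooled") "pooled"
                                     else "mean_of_rates")
      row$ci_low <- ci[["low"]]
      row$ci_high <- ci[["high"]]
      row$n_bootstrap <- B
      row$degenerate <- nrow(d) < 2
    }
    row
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  class(out) <- c("ma_rates", "data.frame")
  out
}

# Unweighted hierarchical mean: line rates -> genotype means -> population
# means -> species mean, stopping at the requested level.
mean_of_means_value <- function(d, level) {
  r <- d$events / d$exposure
  if (level %in% c("line")) return(mean(r))
  gmeans <- tapply(r, d$genotype_id, mean)
  if (level == "genotype") return(mean(gmeans))
  gpop <- tapply(d$population_id, d$genotype_id, function(x) x[1])
  pmeans <- tapply(gmeans, gpop[names(gmeans)], mean)
  if (level == "population") return(mean(pmeans))
  mean(pmeans)
}

#' Percentile bootstrap CI for a pooled rate
#'
#' Resamples lines (event, exposure) pairs with replacement and recomputes
#' the pooled rate per replicate. Deterministic given the RNG state; pass a
#' seed upstream for reproducibility.
#'
#' @param events,exposures Per-line event counts and exposures.
#' @param B Number of bootstrap replicates (>= 100).
#' @param conf Confidence level.
#' @param statistic `"pooled"` (sum/sum) or `"mean_of_rates"`.
#' @return Named vector `c(low = , high = )`.
#' @export
bootstrap_ci <- function(events, exposures, B = 1000, conf = 0.95,
                         statistic = c("pooled", "mean_of_rates")) {
  statistic <- match.arg(statistic)
  stopifnot(length(events) == length(exposures), length(events) >= 1)
  if (B < 100) stop("B must be >= 100", call. = FALSE)
  n <- length(events)
  idx <- matrix(sample.int(n, n * B, replace = TRUE), nrow = B)
  ev <- matrix(events[idx], nrow = B)
  ex <- matrix(exposures[idx], nrow = B)
  reps <- if (statistic == "pooled") rowSums(ev) / rowSums(ex)
          else rowMeans(ev / ex)
  alpha <- (1 - conf) / 2
  q <- stats::quantile(reps, c(alpha, 1 - alpha), names = FALSE)
  c(low = q[1], high = q[2])
}

#' Convert a per-bp per-generation rate to other units
#'
#' @param rate Rate per bp per generation (>= 0).
#' @param diploid_genome_size Diploid callable genome size in bp; yields the
#'   per-genome per-generation rate.
#' @param generation_time_days Days per generation; yields the per-bp
#'   per-day rate.
#' @return Named list with the requested conversions.
#' @export
convert_units <- function(rate, diploid_genome_size = NULL,
                          generation_time_days = NULL) {
  assert_scalar_number(rate, "rate", min = 0)
  if (is.null(diploid_genome_size) && is.null(generation_time_days))
    stop("supply diploid_genome_size and/or generation_time_days")
  out <- list()
  if (!is.null(diploid_genome_size)) {
    assert_scalar_number(diploid_genome_size, "diploid_genome_size",
                         min = 0, strict_min = TRUE)
    out$per_genome_per_generation <- rate * diploid_genome_size
  }
  if (!is.null(generation_time_days)) {
    assert_scalar_number(generation_time_days, "generation_time_days",
                         min = 0, strict_min = TRUE)
    out$per_bp_per_day <- rate / generation_time_days
  }
  out
}

#' Ratio of mitochondrial to nuclear rates by group
#'
#' @param nuclear,mito `ma_rates` tables at the same level (e.g. genotype).
#' @param by Grouping column shared by both tables.
#' @return data.frame with the two rates, their ratio (0 allowed), and an
#'   `infinite` flag where the nuclear rate is zero but the mito rate is not.
#' @export
rate_ratio_table <- function(nuclear, mito, by = "genotype_id") {
  stopifnot(by %in% names(nuclear), by %in% names(mito))
  m <- merge(nuclear[, c(by, "value")], mito[, c(by, "value")], by = by,
             suffixes = c("_nuclear", "_mito"))
  m$ratio <- ifelse(m$value_nuclear == 0,
                    ifelse(m$value_mito == 0, NA_real_, Inf),
                    m$value_mito / m$value_nuclear)
  m$infinite <- is.infinite(m$ratio)
  m
}
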