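#' Six collapsed base-substitution classes
#'
#' Strand-symmetric substitution classes with the mutated pair written
#' pyrimidine-on-top-strand first for the A:T pair and C first for the C:G
#' pair, e.g. a G->A change collapses to `"C:G>T:A"`.
#'
#' @format Character vector of length 6.
#' @export
MUTATION_CLASSES <- c("A:T>C:G", "A:T>G:C", "A:T>T:A",
                      "C:G>A:T", "C:G>G:C", "C:G>T:A")

#' Default six-class mutation spectrum
#'
#' Relative class weights used by the simulator when none are supplied.
#' C:G->T:A is the dominant class and the transition fraction is 0.6063,
#' giving a count-based Ts:Tv ratio of 1.54, the value observed for the
#' nuclear genome of *Daphnia magna*.
#'
#' @return Named numeric vector over [MUTATION_CLASSES] summing to 1.
#' @export
default_spectrum <- function() {
  c("A:T>C:G" = 0.0737, "A:T>G:C" = 0.2063, "A:T>T:A" = 0.12,
    "C:G>A:T" = 0.12,   "C:G>G:C" = 0.08,   "C:G>T:A" = 0.40)
}

#' Configuration of a simulated mutation-accumulation experiment
#'
#' Defaults reproduce the shape of the *D. magna* MA study: 9 ancestral
#' genotypes from 3 populations, 66 MA lines propagated by single-offspring
#' descent, and the species-wide point estimates as planted true rates.
#'
#' @param n_genotypes Number of ancestral genotypes.
#' @param lines_per_genotype MA lines per genotype; scalar or vector of
#'   length `n_genotypes`.
#' @param generations_per_line Number of MA generations `g` (>= 1).
#' @param nuclear_length Haploid nuclear genome length in bp.
#' @param mito_length Circular mitochondrial genome length in bp (0 omits
#'   the mitochondrial partition).
#' @param gc_content Reference GC fraction in `[0, 1]`.
#' @param ancestral_het_density Per-bp density of ancestrally heterozygous
#'   sites in `[0, 1)`.
#' @param true_mu_bs True nuclear base-substitution rate per bp per
#'   generation (per diploid site); scalar or per-genotype vector.
#' @param true_mu_gc True gene-conversion rate per ancestral heterozygous
#'   site per generation; scalar or per-genotype vector.
#' @param tract_length_mean Mean conversion tract length in bp (geometric).
#'   The default, together with the default het density, gives an expected
#'   `1 + (340 - 1) * 0.005 = 2.7` converted sites per tract, the
#'   sites-per-tract ratio observed in the *D. magna* MA study (35 converted
#'   sites over 13 tracts).
#' @param spectrum Named six-class relative weights summing to 1.
#' @param mito_mu Mitochondrial mutation rate per site per mtDNA copy per
#'   generation; scalar or per-genotype vector.
#' @param mito_copy_number Effective per-generation mtDNA copy number `N`
#'   (Wright-Fisher bottleneck size).
#' @param genotype_error_rate Probability that an emitted genotype record is
#'   flipped het<->hom (noise model for exercising filters).
#' @param generation_time_days Days per generation (per-line metadata used
#'   for per-day unit conversions).
#' @param seed Integer seed; the experiment consumes a single sequential RNG
#'   stream seeded once with this value.
#' @return An object of class `ma_sim_config`.
#' @export
sim_config <- function(n_genotypes = 9,
                       lines_per_genotype = c(7, 7, 8, 7, 7, 8, 7, 7, 8),
                       generations_per_line = 30,
                       nuclear_length = 1e7,
                       mito_length = 15000,
                       gc_content = 0.41,
                       ancestral_het_density = 0.005,
                       true_mu_bs = 8.96e-9,
                       true_mu_gc = 6.13e-7,
                       tract_length_mean = 340,
                       spectrum = default_spectrum(),
                       mito_mu = 8.7e-7,
                       mito_copy_number = 100,
                       genotype_error_rate = 0,
                       generation_time_days = 16.8,
                       seed = 1L) {
  assert_scalar_number(n_genotypes, "n_genotypes", min = 1)
  if (!length(lines_per_genotype) %in% c(1L, n_genotypes))
    stop("'lines_per_genotype' must be scalar or one value per genotype")
  lines_per_genotype <- rep_len(as.integer(lines_per_genotype), n_genotypes)
  if (any(lines_per_genotype < 1)) stop("lines_per_genotype must be >= 1")
  assert_scalar_number(generations_per_line, "generations_per_line", min = 1)
  assert_scalar_number(nuclear_length, "nuclear_length", min = 0, strict_min = TRUE)
  assert_scalar_number(mito_length, "mito_length", min = 0)
  assert_scalar_number(gc_content, "gc_content", min = 0, max = 1)
  assert_scalar_number(ancestral_het_density, "ancestral_het_density", min = 0)
  if (ancestral_het_density >= 1)
    stop("'ancestral_het_density' must be < 1")
  for (r in c(true_mu_bs, true_mu_gc, mito_mu))
    if (any(r < 0)) stop("mutation rates must be >= 0")
  assert_scalar_number(tract_length_mean, "tract_length_mean", min = 1)
  assert_scalar_number(mito_copy_number, "mito_copy_number", min = 1)
  assert_scalar_number(genotype_error_rate, "genotype_error_rate", min = 0, max = 1)
  assert_scalar_number(generation_time_days, "generation_time_days",
                       min = 0, strict_min = TRUE)
  if (is.null(names(spectrum))) names(spectrum) <- MUTATION_CLASSES
  if (!setequal(names(spectrum), MUTATION_CLASSES))
    stop("'spectrum' must be named by the six collapsed classes")
  spectrum <- spectrum[MUTATION_CLASSES]
  if (abs(sum(spectrum) - 1) > 1e-9)
    stop("'spectrum' weights must sum to 1 (tolerance 1e-9)")
  if (any(spectrum < 0)) stop("'spectrum' weights must be >= 0")

  structure(list(
    n_genotypes = as.integer(n_genotypes),
    lines_per_genotype = lines_per_genotype,
    generations_per_line = as.integer(generations_per_line),
    nuclear_length = as.integer(nuclear_length),
    mito_length = as.integer(mito_length),
    gc_content = gc_content,
    ancestral_het_density = ancestral_het_density,
    true_mu_bs = rep_len(true_mu_bs, n_genotypes),
    true_mu_gc = rep_len(true_mu_gc, n_genotypes),
    tract_length_mean = tract_length_mean,
    spectrum = spectrum,
    mito_mu = rep_len(mito_mu, n_genotypes),
    mito_copy_number = as.integer(mito_copy_number),
    genotype_error_rate = genotype_error_rate,
    generation_time_days = generation_time_days,
    seed = as.integer(seed)
  ), class = "ma_sim_config")
}

#' Detection filter configuration
#'
#' Thresholds applied when calling de novo events from ancestor/descendant
#' call sets. Defaults are documented stand-ins for the study's
#' (supplementary-only) validated cutoffs.
#'
#' @param min_depth Minimum read depth at a callable variant.
#' @param max_depth_factor Maximum depth as a multiple of the line's mean
#'   depth (repeat/CNV guard).
#' @param min_quality Minimum genotype quality.
#' @param require_unique_to_line If `TRUE`, a candidate variant observed in
#'   more than one MA line is rejected (shared variants cannot be de novo in
#'   independently propagated lines).
#' @param mito_min_frequency Heteroplasmy calling floor on the allele
#'   frequency `f`.
#' @param mito_min_alt_reads Minimum alternate-allele read support for a
#'   heteroplasmy.
#' @param lod_depth_ratio_min Loss-of-heterozygosity deletion guard: a
#'   candidate converted site with depth below this fraction of the line's
#'   mean depth is discarded as a likely hemizygous deletion.
#' @return An object of class `ma_filter_config`.
#' @export
filter_config <- function(min_depth = 10,
                          max_depth_factor = 2,
                          min_quality = 30,
                          require_unique_to_line = TRUE,
                          mito_min_frequency = 0.05,
                          mito_min_alt_reads = 2,
                          lod_depth_ratio_min = 0.5) {
  assert_scalar_number(min_depth, "min_depth", min = 0)
  assert_scalar_number(max_depth_factor, "max_depth_factor", min = 0)
  assert_scalar_number(min_quality, "min_quality", min = 0)
  assert_scalar_number(mito_min_frequency, "mito_min_frequency", min = 0, max = 1)
  assert_scalar_number(mito_min_alt_reads, "mito_min_alt_reads", min = 0)
  assert_scalar_number(lod_depth_ratio_min, "lod_depth_ratio_min", min = 0)
  structure(list(min_depth = min_depth,
                 max_depth_factor = max_depth_factor,
                 min_quality = min_quality,
                 require_unique_to_line = isTRUE(require_unique_to_line),
                 mito_min_frequency = mito_min_frequency,
                 mito_min_alt_reads = mito_min_alt_reads,
                 lod_depth_ratio_min = lod_depth_ratio_min),
            class = "ma_filter_config")
}
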