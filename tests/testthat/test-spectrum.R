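# Spectrum: class collapsing, context tables and conditional rates, Ts:Tv,
# CpG contrast, homogeneity test.

test_that("substitution collapsing is exhaustive and complement-symmetric", {
  expect_equal(collapse_substitution("G", "A"), "C:G>T:A")
  expect_equal(collapse_substitution("C", "T"), "C:G>T:A")
  expect_equal(collapse_substitution("A", "G"), "A:T>G:C")
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  pairs <- expand.grid(ref = names(comp), alt = names(comp),
                       stringsAsFactors = FALSE)
  pairs <- pairs[pairs$ref != pairs$alt, ]
  expect_equal(nrow(pairs), 12)
  cls <- collapse_substitution(pairs$ref, pairs$alt)
  cls_comp <- collapse_substitution(comp[pairs$ref], comp[pairs$alt])
  expect_equal(cls, cls_comp)
  expect_setequal(unique(cls), MUTATION_CLASSES)
  # each class is hit by exactly two ordered substitutions
  expect_true(all(table(cls) == 2))
  expect_error(collapse_substitution("A", "A"), "differ")
  expect_error(collapse_substitution("A", "N"), "A, C, G, T")
})

test_that("context collapsing is idempotent over all 64 contexts", {
  b <- c("A", "C", "G", "T")
  all64 <- as.vector(outer(as.vector(outer(b, b, paste0)), b, paste0))
  once <- collapse_context(all64)
  expect_true(all(substr(once, 2, 2) %in% c("A", "C")))
  expect_identical(collapse_context(once), once)
  expect_equal(length(unique(once)), 32)
})

fake_calls <- function(class, context) {
  data.frame(line_id = rep("L1", length(class)), class = class,
             context = context, stringsAsFactors = FALSE)
}

test_that("conditional rates divide counts by context exposure", {
  denom <- setNames(rep(100, 32), mutacc:::all_contexts())
  calls <- fake_calls(c("C:G>T:A", "C:G>T:A", "A:T>G:C"),
                      c("ACA", "ACA", "AAA"))
  sp <- context_conditional_rates(calls, denom, g_total = 10)
  expect_equal(sum(sp$class_counts), 3)
  expect_equal(unname(sp$context_rates[["ACA"]]), 2 / (10 * 2 * 100))
  expect_equal(unname(sp$class_rates[["C:G>T:A"]]), 2 / (10 * 2 * 1600))
  # class marginals of the joint class-by-context table are the class table
  expect_equal(as.numeric(rowSums(sp$joint)),
               as.numeric(sp$class_counts))
  expect_equal(as.numeric(colSums(sp$joint)),
               as.numeric(sp$context_counts))
  # zero calls give all-zero rates
  sp0 <- context_conditional_rates(fake_calls(character(0), character(0)),
                                   denom, g_total = 10)
  expect_true(all(sp0$context_rates == 0))
  expect_error(
    context_conditional_rates(calls, replace(denom, "ACA", 0), 10),
    "zero callable denominator")
})

test_that("a planted central-C excess is recovered as a rate ratio", {
  # weights sending 1.9x more rate to C:G sites than A:T sites at gc = 0.5
  w <- c("A:T>C:G" = 1, "A:T>G:C" = 1, "A:T>T:A" = 1,
         "C:G>A:T" = 1.9, "C:G>G:C" = 1.9, "C:G>T:A" = 1.9) / (3 * 2.9)
  cfg <- sim_config(n_genotypes = 1, lines_per_genotype = 40,
                    nuclear_length = 1e5, mito_length = 0, gc_content = 0.5,
                    ancestral_het_density = 0, true_mu_bs = 1e-5,
                    true_mu_gc = 0, mito_mu = 0, spectrum = w, seed = 73)
  exp <- simulate_ma_experiment(cfg)
  nc <- call_nuclear_mutations(exp,
                               no_filters(require_unique_to_line = FALSE))
  denom <- count_callable_sites(exp$reference, "trinucleotide_context")
  sp <- context_conditional_rates(nc[!is.na(nc$context), ], denom,
                                  g_total = sum(exp$metadata$generations))
  ratio <- unname(sp$central_rates[["C"]] / sp$central_rates[["A"]])
  expect_lt(abs(ratio - 1.9), 0.2)
})

test_that("Ts:Tv handles equal counts, planted ratios, and no transversions", {
  eq <- setNames(rep(10, 6), MUTATION_CLASSES)
  expect_equal(ts_tv(eq), 0.5)
  no_tv <- setNames(c(0, 10, 0, 0, 0, 10), MUTATION_CLASSES)
  expect_equal(ts_tv(no_tv), Inf)
  # the default simulator spectrum plants Ts:Tv = 1.54; recover it
  cfg <- sim_config(n_genotypes = 1, lines_per_genotype = 40,
                    nuclear_length = 1e5, mito_length = 0,
                    ancestral_het_density = 0, true_mu_bs = 1e-5,
                    true_mu_gc = 0, mito_mu = 0, seed = 79)
  exp <- simulate_ma_experiment(cfg)
  cls <- table(factor(exp$truth$nuclear$class, levels = MUTATION_CLASSES))
  got <- ts_tv(setNames(as.numeric(cls), MUTATION_CLASSES))
  n <- sum(cls)
  p <- 0.6063
  se <- sqrt(p * (1 - p) / n) / (1 - p)^2 # delta method on p/(1-p)
  expect_lt(abs(got - 1.54), 3 * se)
})

test_that("CpG contrast pairs genotypes and detects a planted deficit", {
  denom <- setNames(rep(1000, 32), mutacc:::all_contexts())
  cpg <- mutacc:::cpg_contexts()
  expect_setequal(cpg, c("ACG", "CCG", "GCG", "TCG"))
  mk <- function(n_cpg, n_non) {
    ctx <- c(rep("ACG", n_cpg), rep("ACA", n_non))
    context_conditional_rates(fake_calls(rep("C:G>T:A", length(ctx)), ctx),
                              denom, g_total = 100)
  }
  # identical rates in every genotype: difference 0, t = 0
  same <- lapply(1:8, function(i) mk(4, 12))
  out <- cpg_contrast(same)
  expect_equal(out$statistic, 0)
  expect_equal(out$df, 7) # 8 genotypes -> df 7
  expect_equal(out$mean_difference, 0)
  # planted CpG deficit: negative mean difference, negative t
  set.seed(83)
  deficit <- lapply(1:8, function(i) mk(rpois(1, 5), rpois(1, 120)))
  out2 <- cpg_contrast(deficit)
  expect_lt(out2$mean_difference, 0)
  expect_lt(out2$statistic, 0)
  expect_equal(out2$df, 7)
})

test_that("homogeneity test follows the chi-square closed form", {
  denoms <- setNames(c(295, 295, 295, 205, 205, 205) * 1000,
                     MUTATION_CLASSES)
  # counts exactly proportional to denominators -> chi-square 0
  prop <- setNames(denoms / 1000, MUTATION_CLASSES)
  h0 <- spectrum_homogeneity_test(prop, denoms)
  expect_equal(h0$statistic, 0)
  expect_equal(h0$df, 5)
  # hand-computed two-value check folded into six classes
  o <- setNames(c(30, 10, 10, 10, 10, 10), MUTATION_CLASSES)
  d <- setNames(rep(1, 6), MUTATION_CLASSES)
  e <- rep(sum(o) / 6, 6)
  expect_equal(spectrum_homogeneity_test(o, d)$statistic,
               sum((o - e)^2 / e))
  expect_error(spectrum_homogeneity_test(setNames(rep(0, 6),
                                                  MUTATION_CLASSES), d),
               "positive")
})

test_that("estimated class weights converge to planted weights", {
  cfg <- sim_config(n_genotypes = 1, lines_per_genotype = 60,
                    nuclear_length = 1e5, mito_length = 0,
                    ancestral_het_density = 0, true_mu_bs = 1e-5,
                    true_mu_gc = 0, mito_mu = 0, seed = 89)
  exp <- simulate_ma_experiment(cfg)
  tn <- exp$truth$nuclear
  obs <- table(factor(tn$class, levels = MUTATION_CLASSES)) / nrow(tn)
  w <- default_spectrum()
  se <- sqrt(w * (1 - w) / nrow(tn))
  expect_true(all(abs(as.numeric(obs) - w) < 4 * se))
})
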