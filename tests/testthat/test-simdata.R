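# Simulator: reference composition, ancestral heterozygosity, event counts,
# mitochondrial drift, and the fixture round trip.

test_that("simulated reference matches the requested GC content", {
  L <- 2e5
  for (gc in c(0.5, 0.41)) {
    ref <- simulate_reference(L, 0, gc_content = gc, seed = 1)
    obs <- sum(strsplit(ref$seq[["nuc1"]], "")[[1]] %in% c("G", "C"))
    expect_lt(abs(obs - gc * L), 3 * sqrt(L * gc * (1 - gc)))
  }
  at_only <- simulate_reference(100, 0, gc_content = 0, seed = 1)
  expect_true(grepl("^[AT]+$", at_only$seq[["nuc1"]]))
  expect_error(simulate_reference(0, 0), "out of range")
})

test_that("reference carries partitions, circular flags, all-callable masks", {
  ref <- simulate_reference(1000, 200, 0.5, seed = 2)
  expect_equal(unname(ref$partition[c("nuc1", "mt")]), c("nuclear", "mito"))
  expect_false(ref$circular[["nuc1"]])
  expect_true(ref$circular[["mt"]])
  expect_equal(mutacc:::mask_width(ref$mask), 1200)
})

test_that("ancestral heterozygosity is Bernoulli with alt != ref", {
  ref <- simulate_reference(1e5, 0, 0.5, seed = 3)
  none <- plant_ancestral_heterozygosity(ref, 0, seed = 1)
  expect_equal(none$n_het, 0)
  d <- 0.002
  anc <- plant_ancestral_heterozygosity(ref, d, seed = 1)
  expect_lt(abs(anc$n_het - d * 1e5), 3 * sqrt(1e5 * d * (1 - d)))
  expect_true(all(anc$het$alt != anc$het$ref))
  expect_true(all(anc$het$ref ==
                    substring(ref$seq[["nuc1"]], anc$het$pos, anc$het$pos)))
  expect_error(plant_ancestral_heterozygosity(ref, 1), "< 1")
})

test_that("zero rates give call sets identical to the ancestor", {
  cfg <- sim_config(n_genotypes = 2, lines_per_genotype = 2,
                    nuclear_length = 5e4, mito_length = 2000,
                    ancestral_het_density = 0.002, true_mu_bs = 0,
                    true_mu_gc = 0, mito_mu = 0, seed = 5)
  exp <- simulate_ma_experiment(cfg)
  expect_equal(nrow(exp$truth$nuclear), 0)
  expect_equal(nrow(exp$truth$tracts), 0)
  expect_equal(nrow(exp$truth$mito), 0)
  for (i in seq_len(nrow(exp$metadata))) {
    lid <- exp$metadata$line_id[i]
    anc <- exp$ancestors[[exp$metadata$genotype_id[i]]]$het
    calls <- exp$calls[[lid]]
    expect_equal(calls$pos, anc$pos)
    expect_true(all(calls$genotype == "het"))
  }
})

test_that("per-line nuclear mutation counts follow the Poisson law", {
  # variance of per-line planted counts ~ mean, within 3 SEs of s^2
  cfg <- sim_config(n_genotypes = 1, lines_per_genotype = 150,
                    generations_per_line = 10,
                    nuclear_length = 2e4, mito_length = 0,
                    ancestral_het_density = 0, true_mu_bs = 2e-5,
                    true_mu_gc = 0, mito_mu = 0, seed = 11)
  exp <- simulate_ma_experiment(cfg)
  counts <- table(factor(exp$truth$nuclear$line_id,
                         levels = exp$metadata$line_id))
  m <- mean(counts)
  v <- var(as.numeric(counts))
  n <- length(counts)
  se_var <- sqrt((2 * m^2 + m) / n) # Var(s^2) for Poisson, delta method
  expect_lt(abs(v - m), 3 * se_var)
  # planted total within 3 SD of the Poisson mean
  mu_total <- 2e-5 * 10 * 2 * 2e4 * 150
  expect_lt(abs(nrow(exp$truth$nuclear) - mu_total), 3 * sqrt(mu_total))
})

test_that("planted classes follow the configured spectrum", {
  spec <- c("A:T>C:G" = 0.05, "A:T>G:C" = 0.45, "A:T>T:A" = 0.05,
            "C:G>A:T" = 0.05, "C:G>G:C" = 0.05, "C:G>T:A" = 0.35)
  cfg <- sim_config(n_genotypes = 1, lines_per_genotype = 30,
                    nuclear_length = 5e4, mito_length = 0,
                    ancestral_het_density = 0, true_mu_bs = 2e-5,
                    true_mu_gc = 0, mito_mu = 0, spectrum = spec, seed = 13)
  exp <- simulate_ma_experiment(cfg)
  tn <- exp$truth$nuclear
  expect_gt(nrow(tn), 500)
  # alt alleles consistent with the planted class at every site
  expect_equal(collapse_substitution(tn$ref, tn$alt), tn$class)
  obs <- table(factor(tn$class, levels = names(spec))) / nrow(tn)
  expect_lt(max(abs(obs - spec)), 3 * sqrt(max(spec) / nrow(tn)) + 0.02)
})

test_that("mito heteroplasmy drift: boundaries and unbiased frequency sum", {
  expect_equal(nrow(simulate_mito_heteroplasmy(0, 1000, 10, 100, seed = 1)), 0)
  set.seed(21)
  out <- simulate_mito_heteroplasmy(1e-4, 2000, 20, 50)
  expect_true(all(out$f > 0 & out$f <= 1))
  expect_true(all(out$pos >= 1 & out$pos <= 2000))
  expect_false(any(duplicated(out$pos)))
  # E[sum f] = mu * g * n_sites under neutral drift
  set.seed(22)
  sums <- replicate(200, sum(simulate_mito_heteroplasmy(5e-6, 2000, 20, 50)$f))
  expected <- 5e-6 * 20 * 2000
  se <- sd(sums) / sqrt(length(sums))
  expect_lt(abs(mean(sums) - expected), 3 * se)
  expect_lt(abs(mean(sums) / expected - 1), 0.1)
})

test_that("fixture write/read round-trips the experiment exactly", {
  exp <- small_experiment(seed = 31)
  d <- withr::local_tempdir()
  write_fixture(exp, d)
  exp2 <- read_fixture(d)
  expect_identical(exp2$calls, exp$calls)
  expect_identical(exp2$reference$seq, exp$reference$seq)
  expect_identical(exp2$reference$partition, exp$reference$partition)
  expect_identical(exp2$reference$circular, exp$reference$circular)
  expect_equal(exp2$masks, exp$masks, ignore_attr = TRUE)
  expect_equal(exp2$metadata, exp$metadata)
  expect_identical(lapply(exp2$ancestors, `[[`, "het"),
                   lapply(exp$ancestors, `[[`, "het"))
  expect_equal(exp2$truth$nuclear, exp$truth$nuclear)
  expect_equal(exp2$truth$tracts, exp$truth$tracts)
  expect_equal(exp2$truth$mito, exp$truth$mito)
})

test_that("written VCFs are 1-based, sorted, and valid with zero records", {
  exp <- small_experiment(seed = 33)
  d <- withr::local_tempdir()
  write_fixture(exp, d)
  lid <- exp$metadata$line_id[1]
  lines <- readLines(file.path(d, "lines", paste0(lid, ".vcf")))
  body <- lines[!startsWith(lines, "#")]
  flds <- do.call(rbind, strsplit(body, "\t"))
  pos <- as.integer(flds[, 2])
  expect_true(all(pos >= 1))
  for (cg in unique(flds[, 1]))
    expect_false(is.unsorted(pos[flds[, 1] == cg]))
  # header-only VCF round-trips to an empty call table
  empty <- exp$calls[[lid]][0, ]
  p <- file.path(d, "empty.vcf")
  mutacc:::write_vcf(empty, p, exp$reference, "none")
  expect_equal(nrow(mutacc:::read_vcf_calls(p)), 0)
})

test_that("infeasible mutation rates raise a simulation error", {
  cfg <- sim_config(n_genotypes = 1, lines_per_genotype = 1,
                    nuclear_length = 100, mito_length = 0,
                    ancestral_het_density = 0, true_mu_bs = 0.5,
                    true_mu_gc = 0, mito_mu = 0, seed = 1)
  expect_error(simulate_ma_experiment(cfg), "enlarge the genome")
})
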