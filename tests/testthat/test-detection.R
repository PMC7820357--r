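# Detection: nuclear filters against a hand oracle, mito frequency filters,
# tract clustering vs a brute-force single-linkage oracle, round trips on
# zero-noise simulator output, and filter monotonicity.

test_that("a unique planted het among 5 lines is the only nuclear call", {
  # 5 lines x 6 sites; hand oracle: only the line-3 singleton at pos 200
  # passes; the variant at pos 400 shared by two lines fails uniqueness;
  # low depth (pos 500), low qual (pos 600) and ancestral het (pos 100) fail.
  het <- data.frame(contig = "nuc1", pos = 100L, ref = "A", alt = "G",
                    stringsAsFactors = FALSE)
  base <- rec(100, "A", "G") # the ancestral het, present in every line
  lines <- list(
    L1 = recs(base, rec(400, "C", "T")),
    L2 = recs(base, rec(400, "C", "T")),
    L3 = recs(base, rec(200, "G", "A"), rec(500, "A", "C", depth = 3),
              rec(600, "T", "G", qual = 5)),
    L4 = base,
    L5 = base
  )
  set.seed(1)
  sq <- paste(sample(c("A", "C", "G", "T"), 1000, TRUE), collapse = "")
  substr(sq, 100, 100) <- "A"; substr(sq, 200, 200) <- "G"
  substr(sq, 400, 400) <- "C"; substr(sq, 500, 500) <- "A"
  substr(sq, 600, 600) <- "T"
  exp <- toy_experiment(lines, het = het, seq_nuc = sq)
  calls <- call_nuclear_mutations(exp, filter_config())
  expect_equal(nrow(calls), 1)
  expect_equal(calls$pos, 200L)
  expect_equal(calls$line_id, "L3")
  expect_equal(calls$class, "C:G>T:A") # G>A collapses
  # without the uniqueness filter the shared variant is admitted
  calls2 <- call_nuclear_mutations(
    exp, filter_config(require_unique_to_line = FALSE))
  expect_setequal(calls2$pos, c(200L, 400L, 400L))
})

test_that("tightening any filter never increases the number of calls", {
  exp <- small_experiment(seed = 47, error_rate = 0.02)
  base <- filter_config(min_depth = 0, min_quality = 0)
  n_base <- nrow(call_nuclear_mutations(exp, base))
  for (f in list(filter_config(min_depth = 31),
                 filter_config(min_quality = 100),
                 filter_config(max_depth_factor = 0.5))) {
    expect_lte(nrow(call_nuclear_mutations(exp, f)), n_base)
  }
  # detection is a pure function: identical inputs, identical output
  expect_identical(call_nuclear_mutations(exp, base),
                   call_nuclear_mutations(exp, base))
})

test_that("mito heteroplasmy filters apply the frequency floor", {
  mito_seq <- paste(rep("ACGT", 25), collapse = "")
  lines <- list(
    L1 = recs(rec(10, "C", "T", af = 0.04, contig = "mt"),
              rec(20, "A", "G", af = 0.05, contig = "mt"),
              rec(30, "G", "A", genotype = "hom_alt", af = 1.0,
                  contig = "mt"),
              rec(40, "T", "C", af = 0.12, contig = "mt"),
              rec(50, "C", "A", af = 0.55, contig = "mt"))
  )
  exp <- toy_experiment(lines, mito_seq = mito_seq)
  calls <- call_mito_mutations(exp, filter_config(mito_min_frequency = 0.05,
                                                  mito_min_alt_reads = 1))
  expect_setequal(calls$pos, c(20L, 30L, 40L, 50L))
  expect_equal(calls$f[calls$pos == 30], 1)
  expect_equal(sum(calls$f[calls$pos %in% c(40, 50)]), 0.67)
  bad <- lines
  bad$L1$af[1] <- 1.5
  exp_bad <- toy_experiment(bad, mito_seq = mito_seq)
  expect_error(call_mito_mutations(exp_bad), "frequencies outside")
})

test_that("tract clustering matches the spec example and handles no-LOH", {
  het <- data.frame(contig = "nuc1",
                    pos = c(100L, 150L, 2000L, 3500L),
                    ref = c("A", "C", "G", "T"),
                    alt = c("G", "T", "A", "C"), stringsAsFactors = FALSE)
  anc_recs <- function(gt) {
    do.call(rbind, lapply(seq_len(nrow(het)), function(i)
      rec(het$pos[i], het$ref[i], het$alt[i], genotype = gt[i])))
  }
  lines <- list(L1 = anc_recs(c("hom_ref", "hom_alt", "hom_ref", "het")),
                L2 = anc_recs(rep("het", 4)))
  exp <- toy_experiment(lines, het = het, L = 5000)
  tr <- detect_conversion_tracts(exp, max_gap = 1000)
  expect_equal(nrow(tr$sites), 3) # x_g = 3
  t1 <- tr$tracts[tr$tracts$line_id == "L1", ]
  expect_equal(nrow(t1), 2)
  expect_equal(t1$n_sites, c(2L, 1L))
  expect_equal(t1$start, c(100L, 2000L))
  expect_equal(t1$span, c(51L, 1L))
  expect_equal(tr$sites$direction[tr$sites$pos == 150], "to_alt")
  expect_equal(sum(tr$tracts$line_id == "L2"), 0)
})

test_that("tract clustering equals a brute-force single-linkage oracle", {
  # oracle: merge any two sites anywhere in the same cluster when some pair
  # is within max_gap (single linkage), by repeated scanning
  brute_force <- function(pos, max_gap) {
    pos <- sort(pos)
    groups <- as.list(pos)
    repeat {
      merged <- FALSE
      for (i in seq_along(groups)) {
        for (j in seq_along(groups)) {
          if (i >= j) next
          if (min(abs(outer(groups[[i]], groups[[j]], "-"))) <= max_gap) {
            groups[[i]] <- sort(c(groups[[i]], groups[[j]]))
            groups[[j]] <- NULL
            merged <- TRUE
            break
          }
        }
        if (merged) break
      }
      if (!merged) break
    }
    groups[order(vapply(groups, min, numeric(1)))]
  }
  set.seed(17)
  for (rep in 1:20) {
    n <- sample(2:60, 1)
    pos <- sort(sample.int(50000, n))
    max_gap <- sample(c(50, 500, 5000), 1)
    het <- data.frame(contig = "nuc1", pos = pos, ref = "A", alt = "G",
                      stringsAsFactors = FALSE)
    gt <- rep("hom_ref", n)
    lines <- list(L1 = do.call(rbind, lapply(pos, function(p)
      rec(p, "A", "G", genotype = "hom_ref"))))
    exp <- toy_experiment(lines, het = het, L = 60000)
    got <- detect_conversion_tracts(exp, max_gap = max_gap)
    got_groups <- split(got$sites$pos, got$sites$tract_id)
    want <- brute_force(pos, max_gap)
    expect_equal(unname(lapply(got_groups, as.numeric)),
                 lapply(want, as.numeric))
  }
})

test_that("deletion guard excludes low-depth LOH candidates", {
  het <- data.frame(contig = "nuc1", pos = c(100L, 200L), ref = "A",
                    alt = "G", stringsAsFactors = FALSE)
  # line mean depth (30 + 5)/2 = 17.5; pos 200 at depth 5 < 0.5 * 17.5
  # fails the hemizygous-deletion guard
  lines <- list(L1 = recs(rec(100, "A", "G", genotype = "hom_ref"),
                          rec(200, "A", "G", genotype = "hom_ref",
                              depth = 5)))
  exp <- toy_experiment(lines, het = het)
  tr <- detect_conversion_tracts(exp, filters = filter_config(min_depth = 0))
  expect_equal(tr$sites$pos, 100L)
  tr2 <- detect_conversion_tracts(
    exp, filters = filter_config(min_depth = 0, lod_depth_ratio_min = 0))
  expect_setequal(tr2$sites$pos, c(100L, 200L))
})

test_that("zero-noise detection recovers exactly the truth ledger", {
  exp <- small_experiment(seed = 53)
  # uniqueness off so chance same-site plantings in two lines stay comparable
  # to the truth ledger
  nc <- call_nuclear_mutations(exp,
                               no_filters(require_unique_to_line = FALSE))
  key <- function(d) sort(paste(d$line_id, d$contig, d$pos, d$alt))
  expect_identical(key(nc), key(exp$truth$nuclear))
  expect_equal(nc$class[order(paste(nc$line_id, nc$pos))],
               exp$truth$nuclear$class[
                 order(paste(exp$truth$nuclear$line_id,
                             exp$truth$nuclear$pos))])
  mc <- call_mito_mutations(exp, no_filters())
  expect_identical(key(mc), key(exp$truth$mito))
  expect_equal(sort(mc$f), sort(exp$truth$mito$f))
  tr <- detect_conversion_tracts(exp, filters = no_filters())
  skey <- function(d) sort(paste(d$line_id, d$pos, d$direction))
  expect_identical(skey(tr$sites), skey(exp$truth$tracts))
})

test_that("MA lines show ~10x the control conversion rate", {
  cfg <- sim_config(n_genotypes = 3, lines_per_genotype = 25,
                    nuclear_length = 1e5, mito_length = 0,
                    ancestral_het_density = 0.01, true_mu_bs = 0,
                    true_mu_gc = 3e-4, mito_mu = 0, seed = 59)
  exp <- simulate_ma_experiment(cfg, control_lines_per_genotype = 25,
                                control_mu_factor = 0.1)
  tr <- detect_conversion_tracts(exp, filters = no_filters())
  lt <- line_rate_table(exp, call_nuclear_mutations(exp, no_filters()),
                        NULL, tr)
  gc_tbl <- lt[lt$kind == "gene_conversion", ]
  cmp <- compare_ma_vs_controls(gc_tbl)
  expect_false(cmp$undefined)
  expect_gt(cmp$ratio, 5)
  expect_lt(cmp$ratio, 20)
  # arithmetic contract
  toy <- data.frame(role = c("MA", "extant_control"),
                    events = c(6, 3), exposure = c(1e7, 5e7))
  expect_equal(compare_ma_vs_controls(toy)$ratio, 10)
  toy$events[2] <- 0
  expect_true(compare_ma_vs_controls(toy)$undefined)
  expect_error(compare_ma_vs_controls(toy[1, ]), "both MA and control")
})
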