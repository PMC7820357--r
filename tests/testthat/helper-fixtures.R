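# Small in-code fixtures shared across test files.

# A fast, small experiment with all three mutation processes active.
small_experiment <- function(seed = 7, error_rate = 0, ...) {
  cfg <- sim_config(n_genotypes = 3, lines_per_genotype = 4,
                    generations_per_line = 30,
                    nuclear_length = 2e5, mito_length = 5000,
                    ancestral_het_density = 0.002,
                    true_mu_bs = 2e-6, true_mu_gc = 2e-4, mito_mu = 5e-6,
                    genotype_error_rate = error_rate, seed = seed, ...)
  simulate_ma_experiment(cfg)
}

# Hand-built experiment: one reference, one genotype, explicit call sets.
# Used to enumerate filter outcomes against a hand oracle.
toy_experiment <- function(lines, het = NULL, seq_nuc = NULL, L = 1000,
                           mito_seq = NULL) {
  if (is.null(seq_nuc)) {
    set.seed(42)
    seq_nuc <- paste(sample(c("A", "C", "G", "T"), L, TRUE), collapse = "")
  }
  seqs <- c(nuc1 = seq_nuc)
  partition <- c(nuc1 = "nuclear")
  circular <- c(nuc1 = FALSE)
  if (!is.null(mito_seq)) {
    seqs <- c(seqs, mt = mito_seq)
    partition <- c(partition, mt = "mito")
    circular <- c(circular, mt = TRUE)
  }
  ref <- mutacc:::new_reference(seqs, partition, circular)
  if (is.null(het))
    het <- data.frame(contig = character(), pos = integer(),
                      ref = character(), alt = character(),
                      stringsAsFactors = FALSE)
  anc <- structure(list(het = het, n_het = nrow(het)), class = "ma_ancestry")
  md <- data.frame(line_id = names(lines), genotype_id = "G01",
                   population_id = "P1", generations = 10L,
                   generation_time_days = 16.8, role = "MA",
                   stringsAsFactors = FALSE)
  masks <- stats::setNames(rep(list(ref$mask), length(lines)), names(lines))
  structure(list(reference = ref, ancestors = list(G01 = anc),
                 metadata = md, calls = lines, masks = masks,
                 truth = NULL, config = NULL),
            class = "ma_experiment")
}

# One variant-call record in the internal representation.
rec <- function(pos, ref, alt, genotype = "het", contig = "nuc1",
                af = NA_real_, depth = 30L, qual = 99) {
  data.frame(contig = contig, pos = as.integer(pos), ref = ref, alt = alt,
             genotype = genotype, af = af, depth = as.integer(depth),
             qual = qual, stringsAsFactors = FALSE)
}

recs <- function(...) do.call(rbind, list(...))

no_filters <- function(...) {
  filter_config(min_depth = 0, max_depth_factor = Inf, min_quality = 0,
                mito_min_frequency = 0, mito_min_alt_reads = 0,
                lod_depth_ratio_min = 0, ...)
}
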