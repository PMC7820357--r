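# Forward simulator of a mutation-accumulation experiment. Produces per-line
# call sets with the statistical structure the downstream analysis assumes
# (Poisson nuclear substitutions drawn from a six-class spectrum, geometric
# gene-conversion tracts at ancestral heterozygous sites, Wright-Fisher
# mitochondrial heteroplasmy drift), plus a complete ground-truth ledger.

#' Simulate a reference genome
#'
#' One linear nuclear contig plus one circular mitochondrial contig with
#' i.i.d. bases at the requested GC content and an all-callable mask.
#'
#' @param nuclear_length,mito_length Contig lengths in bp (> 0; `mito_length`
#'   may be 0 to omit the mitochondrial partition).
#' @param gc_content P(G) + P(C) for each simulated base.
#' @param seed Optional integer seed; `NULL` uses the current RNG stream.
#' @return An object of class `ma_reference`: list with `seq` (named contig
#'   strings), `partition` ("nuclear"/"mito" per contig), `circular` (logical
#'   per contig) and `mask` (callable intervals, 1-based closed).
#' @export
simulate_reference <- function(nuclear_length, mito_length = 0,
                               gc_content = 0.5, seed = NULL) {
  assert_scalar_number(nuclear_length, "nuclear_length", min = 0, strict_min = TRUE)
  assert_scalar_number(mito_length, "mito_length", min = 0)
  assert_scalar_number(gc_content, "gc_content", min = 0, max = 1)
  if (!is.null(seed)) set.seed(seed)
  p <- c((1 - gc_content) / 2, gc_content / 2, gc_content / 2,
         (1 - gc_content) / 2)
  draw <- function(n) paste(sample(BASES, n, replace = TRUE, prob = p),
                            collapse = "")
  seqs <- c(nuc1 = draw(nuclear_length))
  partition <- c(nuc1 = "nuclear")
  circular <- c(nuc1 = FALSE)
  if (mito_length > 0) {
    seqs <- c(seqs, mt = draw(mito_length))
    partition <- c(partition, mt = "mito")
    circular <- c(circular, mt = TRUE)
  }
  new_reference(seqs, partition, circular)
}

new_reference <- function(seqs, partition, circular, mask = NULL) {
  stopifnot(is.character(seqs), !is.null(names(seqs)),
            setequal(names(partition), names(seqs)),
            setequal(names(circular), names(seqs)))
  if (sum(partition == "mito") > 1)
    stop("at most one mitochondrial contig per genome")
  lens <- vapply(seqs, nchar, integer(1))
  if (is.null(mask)) mask <- full_mask(lens)
  bad <- mask$end > lens[mask$contig]
  if (any(bad)) stop("callable mask extends beyond contig end")
  structure(list(seq = seqs, partition = partition[names(seqs)],
                 circular = circular[names(seqs)], mask = mask,
                 lengths = lens),
            class = "ma_reference")
}

contigs_of <- function(ref, partition) {
  names(ref$partition)[ref$partition == partition]
}

#' Plant ancestral heterozygosity on the nuclear partition
#'
#' Each callable nuclear site is heterozygous with probability `het_density`,
#' with an alternate allele drawn uniformly from the three non-reference
#' bases. These sites form the denominator of the gene-conversion rate and
#' the substrate for conversion tracts.
#'
#' @param ref An `ma_reference`.
#' @param het_density Per-site heterozygosity probability in `[0, 1)`.
#' @param seed Optional integer seed; `NULL` uses the current RNG stream.
#' @return An object of class `ma_ancestry`: list with `het` (data.frame
#'   contig/pos/ref/alt) and `n_het`.
#' @export
plant_ancestral_heterozygosity <- function(ref, het_density, seed = NULL) {
  assert_scalar_number(het_density, "het_density", min = 0)
  if (het_density >= 1) stop("'het_density' must be < 1")
  if (!is.null(seed)) set.seed(seed)
  out <- list()
  for (cg in contigs_of(ref, "nuclear")) {
    m <- ref$mask[ref$mask$contig == cg, , drop = FALSE]
    n_callable <- mask_width(m)
    n_het <- rbinom(1, n_callable, het_density)
    if (n_het == 0) next
    # uniform callable positions: index into the concatenated mask intervals
    offs <- sort(sample.int(n_callable, n_het))
    pos <- callable_index_to_pos(m, offs)
    refb <- substring(ref$seq[[cg]], pos, pos)
    alt <- vapply(refb, function(b) sample(setdiff(BASES, b), 1), character(1),
                  USE.NAMES = FALSE)
    keep <- refb %in% BASES
    out[[cg]] <- data.frame(contig = cg, pos = pos, ref = refb, alt = alt,
                            stringsAsFactors = FALSE)[keep, , drop = FALSE]
  }
  het <- if (length(out)) do.call(rbind, out) else
    data.frame(contig = character(), pos = integer(),
               ref = character(), alt = character(), stringsAsFactors = FALSE)
  rownames(het) <- NULL
  structure(list(het = het, n_het = nrow(het)), class = "ma_ancestry")
}

# Map 1..n_callable offsets into genomic positions of a (sorted) mask.
callable_index_to_pos <- function(mask, offsets) {
  w <- mask$end - mask$start + 1L
  cum <- cumsum(w)
  iv <- findInterval(offsets - 1L, c(0L, cum), rightmost.closed = FALSE)
  mask$start[iv] + (offsets - c(0L, cum)[iv] - 1L)
}

#' Simulate mitochondrial heteroplasmy frequencies under neutral drift
#'
#' Each generation, new per-copy mutations arise as
#' Poisson(`mito_mu * n_sites * N`) at initial frequency `1/N`, then every
#' segregating variant drifts by binomial resampling of the `N` mtDNA copies
#' (a Wright-Fisher bottleneck). Under neutrality the expected total derived
#' frequency satisfies `E[sum(f)] = mito_mu * g * n_sites`, which is what
#' makes the `sum(f)/(g*n)` rate estimator unbiased.
#'
#' @param mito_mu Mutation rate per site per mtDNA copy per generation.
#' @param n_sites Mitochondrial genome length in bp.
#' @param g Number of generations.
#' @param N Effective mtDNA copy number per generation.
#' @param seed Optional integer seed; `NULL` uses the current RNG stream.
#' @return data.frame with columns `pos` and `f` (frequencies in (0, 1]) for
#'   all variants segregating or fixed at generation `g`.
#' @export
simulate_mito_heteroplasmy <- function(mito_mu, n_sites, g, N, seed = NULL) {
  assert_scalar_number(mito_mu, "mito_mu", min = 0)
  assert_scalar_number(n_sites, "n_sites", min = 1)
  assert_scalar_number(g, "g", min = 1)
  assert_scalar_number(N, "N", min = 1)
  if (!is.null(seed)) set.seed(seed)
  pos <- integer(0)
  f <- numeric(0)
  for (gen in seq_len(g)) {
    n_new <- rpois(1, mito_mu * n_sites * N)
    if (n_new > 0) {
      avail <- setdiff(seq_len(n_sites), pos)
      n_new <- min(n_new, length(avail))
      newpos <- avail[sample.int(length(avail), n_new)]
      pos <- c(pos, newpos)
      f <- c(f, rep(1 / N, n_new))
    }
    if (length(f)) {
      f <- rbinom(length(f), N, f) / N
      keep <- f > 0
      pos <- pos[keep]
      f <- f[keep]
    }
  }
  data.frame(pos = as.integer(pos), f = f)[order(pos), , drop = FALSE]
}

# Draw de novo substitution positions for one line by rejection sampling:
# uniform over callable, ancestrally homozygous sites whose reference base
# matches the class's mutated pair.
sample_mutation_sites <- function(ref, contig, classes, het_pos) {
  L <- ref$lengths[[contig]]
  seq <- ref$seq[[contig]]
  need_pair <- substr(classes, 1, 1) # "A" (A:T pair) or "C" (C:G pair)
  pos <- integer(length(classes))
  refb <- character(length(classes))
  taken <- integer(0)
  for (pair in unique(need_pair)) {
    idx <- which(need_pair == pair)
    want <- if (pair == "A") c("A", "T") else c("C", "G")
    got <- 0L
    guard <- 0L
    while (got < length(idx)) {
      guard <- guard + 1L
      if (guard > 10000L)
        stop("expected mutation count exceeds available sites; ",
             "enlarge the genome or lower the rate")
      cand <- sample.int(L, max(64L, 2L * (length(idx) - got)), replace = TRUE)
      b <- substring(seq, cand, cand)
      ok <- b %in% want &
        mask_covers(ref$mask, rep(contig, length(cand)), cand) &
        !(cand %in% het_pos) & !(cand %in% taken) & !duplicated(cand)
      cand <- cand[ok]
      b <- b[ok]
      if (!length(cand)) next
      take <- seq_len(min(length(cand), length(idx) - got))
      sel <- idx[got + take]
      pos[sel] <- cand[take]
      refb[sel] <- b[take]
      taken <- c(taken, cand[take])
      got <- got + length(take)
    }
  }
  data.frame(pos = pos, ref = refb, stringsAsFactors = FALSE)
}

# Alternate allele implied by a collapsed class and the strand of `ref`:
# class "X:X'>Y:Y'" sends X -> Y and X' -> Y'.
alt_for_class <- function(ref, class) {
  from1 <- substr(class, 1, 1)
  to1 <- substr(class, 5, 5)
  ifelse(ref == from1, to1,
         ifelse(ref == comp_base(from1), comp_base(to1), NA_character_))
}

#' Simulate a full mutation-accumulation experiment
#'
#' Simulates the reference, per-genotype ancestral heterozygosity, and one
#' call set per MA line: Poisson de novo nuclear substitutions (class drawn
#' from the configured spectrum), gene-conversion tracts initiated at
#' ancestral het sites with geometric extent and a fair-coin direction, and
#' mitochondrial heteroplasmies from [simulate_mito_heteroplasmy()]. Every
#' planted event is recorded in a truth ledger so detection can be validated
#' exactly at zero noise.
#'
#' @param config An [sim_config()] object.
#' @param control_lines_per_genotype Optional number of large-population
#'   control lines per genotype (role `"extant_control"`).
#' @param control_mu_factor Multiplier applied to all planted rates in
#'   control lines (selection suppresses accumulation in large populations).
#' @return An object of class `ma_experiment`: reference, `ancestors`
#'   (named list of `ma_ancestry` by genotype), `metadata` (one row per
#'   line), `calls` (named list of per-line call tables), `masks` (per-line
#'   callable masks), `truth` (ledgers `nuclear`, `tracts`, `mito`) and
#'   `config`.
#' @export
simulate_ma_experiment <- function(config,
                                   control_lines_per_genotype = 0,
                                   control_mu_factor = 0.1) {
  stopifnot(inherits(config, "ma_sim_config"))
  set.seed(config$seed)
  ref <- simulate_reference(config$nuclear_length, config$mito_length,
                            config$gc_content, seed = NULL)
  nuc <- contigs_of(ref, "nuclear")[1]
  mito <- contigs_of(ref, "mito")
  mito <- if (length(mito)) mito[1] else NULL
  g <- config$generations_per_line
  n_pop <- min(3L, config$n_genotypes)
  n_callable_nuc <- mask_width(ref$mask, nuc)
  n_callable_mt <- if (is.null(mito)) 0L else mask_width(ref$mask, mito)

  # feasibility guard: expected events must fit the genome
  max_mu <- max(config$true_mu_bs)
  if (max_mu * g * 2 * n_callable_nuc > 0.2 * n_callable_nuc)
    stop("expected mutation count exceeds available sites; ",
         "enlarge the genome or lower the rate")

  ancestors <- list()
  metadata <- list()
  calls <- list()
  truth_nuc <- list()
  truth_tracts <- list()
  truth_mito <- list()

  for (i in seq_len(config$n_genotypes)) {
    gid <- sprintf("G%02d", i)
    pid <- sprintf("P%d", ((i - 1L) %% n_pop) + 1L)
    anc <- plant_ancestral_heterozygosity(ref, config$ancestral_het_density,
                                          seed = NULL)
    ancestors[[gid]] <- anc
    het <- anc$het[anc$het$contig == nuc, , drop = FALSE]
    het_pos <- het$pos

    n_roles <- c(MA = config$lines_per_genotype[i],
                 extant_control = as.integer(control_lines_per_genotype))
    line_no <- 0L
    for (role in names(n_roles)) {
      fac <- if (role == "MA") 1 else control_mu_factor
      mu_bs <- config$true_mu_bs[i] * fac
      mu_gc <- config$true_mu_gc[i] * fac
      mu_mt <- config$mito_mu[i] * fac
      for (j in seq_len(n_roles[[role]])) {
        line_no <- line_no + 1L
        lid <- sprintf("%s_L%02d", gid, line_no)

        ## --- de novo nuclear substitutions -------------------------------
        x <- rpois(1, mu_bs * g * 2 * n_callable_nuc)
        if (x > 0) {
          cls <- sample(MUTATION_CLASSES, x, replace = TRUE,
                        prob = config$spectrum)
          sites <- sample_mutation_sites(ref, nuc, cls, het_pos)
          dn <- data.frame(line_id = lid, contig = nuc, pos = sites$pos,
                           ref = sites$ref,
                           alt = alt_for_class(sites$ref, cls),
                           class = cls, stringsAsFactors = FALSE)
          dn <- dn[order(dn$pos), , drop = FALSE]
        } else {
          dn <- NULL
        }

        ## --- gene-conversion tracts --------------------------------------
        tr <- NULL
        if (mu_gc > 0 && length(het_pos) > 0) {
          m_sites <- 1 + (config$tract_length_mean - 1) *
            config$ancestral_het_density
          n_init <- rpois(1, mu_gc / m_sites * g * length(het_pos))
          if (n_init > 0) {
            starts <- het_pos[sample.int(length(het_pos), n_init,
                                         replace = TRUE)]
            lens <- rgeom(n_init, 1 / config$tract_length_mean) + 1L
            dirs <- sample(c("to_ref", "to_alt"), n_init, replace = TRUE)
            pieces <- lapply(seq_len(n_init), function(k) {
              memb <- het_pos[het_pos >= starts[k] &
                                het_pos <= starts[k] + lens[k] - 1L]
              data.frame(tract_id = k, pos = memb, direction = dirs[k],
                         stringsAsFactors = FALSE)
            })
            tr <- do.call(rbind, pieces)
            tr <- tr[!duplicated(tr$pos), , drop = FALSE]
            tr$tract_id <- match(tr$tract_id, unique(tr$tract_id))
            tr <- data.frame(line_id = lid, contig = nuc,
                             tract_id = tr$tract_id, pos = tr$pos,
                             direction = tr$direction,
                             stringsAsFactors = FALSE)
            tr <- tr[order(tr$pos), , drop = FALSE]
          }
        }

        ## --- mitochondrial heteroplasmies --------------------------------
        mt_ev <- NULL
        if (!is.null(mito) && mu_mt > 0) {
          hp <- simulate_mito_heteroplasmy(mu_mt, config$mito_length, g,
                                           config$mito_copy_number,
                                           seed = NULL)
          if (nrow(hp)) {
            refb <- substring(ref$seq[[mito]], hp$pos, hp$pos)
            altb <- vapply(refb, function(b) sample(setdiff(BASES, b), 1),
                           character(1), USE.NAMES = FALSE)
            mt_ev <- data.frame(line_id = lid, contig = mito, pos = hp$pos,
                                ref = refb, alt = altb, f = hp$f,
                                stringsAsFactors = FALSE)
          }
        }

        calls[[lid]] <- assemble_line_calls(het, dn, tr, mt_ev,
                                            config$genotype_error_rate)
        metadata[[lid]] <- data.frame(
          line_id = lid, genotype_id = gid, population_id = pid,
          generations = g,
          generation_time_days = config$generation_time_days,
          role = role, stringsAsFactors = FALSE)
        if (!is.null(dn)) truth_nuc[[lid]] <- dn
        if (!is.null(tr)) truth_tracts[[lid]] <- tr
        if (!is.null(mt_ev)) truth_mito[[lid]] <- mt_ev
      }
    }
  }

  bind <- function(lst, proto) {
    if (length(lst)) {
      out <- do.call(rbind, lst)
      rownames(out) <- NULL
      out
    } else proto
  }
  truth <- list(
    nuclear = bind(truth_nuc, data.frame(
      line_id = character(), contig = character(), pos = integer(),
      ref = character(), alt = character(), class = character(),
      stringsAsFactors = FALSE)),
    tracts = bind(truth_tracts, data.frame(
      line_id = character(), contig = character(), tract_id = integer(),
      pos = integer(), direction = character(), stringsAsFactors = FALSE)),
    mito = bind(truth_mito, data.frame(
      line_id = character(), contig = character(), pos = integer(),
      ref = character(), alt = character(), f = numeric(),
      stringsAsFactors = FALSE))
  )
  metadata <- bind(metadata, NULL)
  masks <- stats::setNames(rep(list(ref$mask), nrow(metadata)),
                           metadata$line_id)

  structure(list(reference = ref, ancestors = ancestors,
                 metadata = metadata, calls = calls, masks = masks,
                 truth = truth, config = config),
            class = "ma_experiment")
}

# One line's variant-call table relative to the reference: ancestral het
# sites (possibly converted), de novo substitutions, and mito records.
# Constant DP/GQ; genotype noise flips het<->hom on emitted records.
assemble_line_calls <- function(het, dn, tracts, mito_ev, error_rate,
                                depth = 30L, qual = 99) {
  gt <- rep("het", nrow(het))
  if (!is.null(tracts) && nrow(tracts)) {
    idx <- match(tracts$pos, het$pos)
    gt[idx] <- ifelse(tracts$direction == "to_alt", "hom_alt", "hom_ref")
  }
  parts <- list(
    data.frame(contig = het$contig, pos = het$pos, ref = het$ref,
               alt = het$alt, genotype = gt,
               af = rep(NA_real_, nrow(het)), stringsAsFactors = FALSE)
  )
  if (!is.null(dn) && nrow(dn))
    parts <- c(parts, list(data.frame(
      contig = dn$contig, pos = dn$pos, ref = dn$ref, alt = dn$alt,
      genotype = "het", af = NA_real_, stringsAsFactors = FALSE)))
  if (!is.null(mito_ev) && nrow(mito_ev))
    parts <- c(parts, list(data.frame(
      contig = mito_ev$contig, pos = mito_ev$pos, ref = mito_ev$ref,
      alt = mito_ev$alt,
      genotype = ifelse(mito_ev$f == 1, "hom_alt", "het"),
      af = mito_ev$f, stringsAsFactors = FALSE)))
  out <- do.call(rbind, parts)
  out <- out[order(out$contig, out$pos), , drop = FALSE]
  rownames(out) <- NULL
  out$depth <- rep(depth, nrow(out))
  out$qual <- rep(qual, nrow(out))
  if (error_rate > 0 && nrow(out)) {
    flip <- runif(nrow(out)) < error_rate & is.na(out$af)
    out$genotype[flip] <- ifelse(out$genotype[flip] == "het",
                                 sample(c("hom_ref", "hom_alt"), sum(flip),
                                        replace = TRUE),
                                 "het")
  }
  out
}
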