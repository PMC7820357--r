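# Detection of de novo events from ancestor vs. MA-line call sets under
# explicit, configurable filters. Detection is a pure function of the call
# sets and the filter configuration.

#' Call de novo nuclear base substitutions
#'
#' A site is called in a focal line iff it is ancestrally homozygous (not in
#' the genotype's ancestral het index), callable in both the ancestor
#' (reference mask) and the focal line, carries a new allele, and passes the
#' depth/quality filters. With `require_unique_to_line`, a variant observed
#' in more than one line is rejected as ancestral polymorphism or a
#' systematic artifact.
#'
#' @param exp An `ma_experiment` (from [simulate_ma_experiment()],
#'   [read_callsets()] or [read_fixture()]).
#' @param filters A [filter_config()].
#' @return data.frame of accepted calls with collapsed class and (strand
#'   collapsed) trinucleotide context, one row per line x site.
#' @export
call_nuclear_mutations <- function(exp, filters = filter_config()) {
  stopifnot(inherits(exp, "ma_experiment"),
            inherits(filters, "ma_filter_config"))
  nuc <- contigs_of(exp$reference, "nuclear")
  out <- list()
  for (i in seq_len(nrow(exp$metadata))) {
    lid <- exp$metadata$line_id[i]
    gid <- exp$metadata$genotype_id[i]
    if (!gid %in% names(exp$ancestors))
      stop("line ", lid, " references unknown genotype ", gid, call. = FALSE)
    recs <- exp$calls[[lid]]
    if (is.null(recs))
      stop("line ", lid, " absent from call sets", call. = FALSE)
    recs <- recs[recs$contig %in% nuc, , drop = FALSE]
    if (!nrow(recs)) next
    anc <- exp$ancestors[[gid]]$het
    anc_key <- paste(anc$contig, anc$pos)
    is_anc <- paste(recs$contig, recs$pos) %in% anc_key
    mean_dp <- mean(recs$depth, na.rm = TRUE)
    keep <- !is_anc &
      recs$genotype %in% c("het", "hom_alt") &
      mask_covers(exp$reference$mask, recs$contig, recs$pos) &
      mask_covers(exp$masks[[lid]], recs$contig, recs$pos) &
      recs$depth >= filters$min_depth &
      recs$depth <= filters$max_depth_factor * mean_dp &
      recs$qual >= filters$min_quality
    if (!any(keep)) next
    hit <- recs[keep, , drop = FALSE]
    hit$line_id <- lid
    out[[lid]] <- hit
  }
  calls <- if (length(out)) do.call(rbind, out) else NULL
  if (is.null(calls))
    return(empty_nuclear_calls())
  if (filters$require_unique_to_line) {
    key <- paste(calls$contig, calls$pos, calls$alt)
    calls <- calls[key %in% names(which(table(key) == 1)), , drop = FALSE]
  }
  if (!nrow(calls)) return(empty_nuclear_calls())
  calls$class <- collapse_substitution(calls$ref, calls$alt)
  calls$context <- site_context(exp$reference, calls$contig, calls$pos)
  calls$partition <- "nuclear"
  rownames(calls) <- NULL
  calls[, c("line_id", "contig", "pos", "ref", "alt", "genotype", "depth",
            "qual", "class", "context", "partition")]
}

empty_nuclear_calls <- function() {
  data.frame(line_id = character(), contig = character(), pos = integer(),
             ref = character(), alt = character(), genotype = character(),
             depth = integer(), qual = numeric(), class = character(),
             context = character(), partition = character(),
             stringsAsFactors = FALSE)
}

# Strand-collapsed 3-bp context of reference positions; NA when the window
# leaves a linear contig or touches a non-ACGT base. Windows wrap on
# circular contigs.
site_context <- function(ref, contig, pos) {
  out <- rep(NA_character_, length(pos))
  for (cg in unique(contig)) {
    sel <- which(contig == cg)
    L <- ref$lengths[[cg]]
    sq <- ref$seq[[cg]]
    p <- pos[sel]
    if (ref$circular[[cg]]) {
      lft <- (p - 2L) %% L + 1L
      rgt <- p %% L + 1L
      ctx <- paste0(substring(sq, lft, lft), substring(sq, p, p),
                    substring(sq, rgt, rgt))
      ok <- !grepl("[^ACGT]", ctx)
    } else {
      ok <- p >= 2L & p <= L - 1L
      ctx <- rep(NA_character_, length(p))
      ctx[ok] <- substring(sq, p[ok] - 1L, p[ok] + 1L)
      ok[ok] <- !grepl("[^ACGT]", ctx[ok])
    }
    out[sel[ok]] <- collapse_context(ctx[ok])
  }
  out
}

#' Call mitochondrial heteroplasmies
#'
#' A mitochondrial variant is accepted iff it is absent from the genotype's
#' ancestor, its allele frequency `f` is at least `mito_min_frequency`, its
#' implied alternate-read support (`round(f * depth)`) is at least
#' `mito_min_alt_reads`, and quality passes. Frequencies are retained for
#' the frequency-sum rate estimator.
#'
#' @inheritParams call_nuclear_mutations
#' @return data.frame of accepted calls with column `f` in (0, 1].
#' @export
call_mito_mutations <- function(exp, filters = filter_config()) {
  stopifnot(inherits(exp, "ma_experiment"))
  mito <- contigs_of(exp$reference, "mito")
  if (!length(mito)) stop("no mitochondrial contig in reference")
  out <- list()
  for (i in seq_len(nrow(exp$metadata))) {
    lid <- exp$metadata$line_id[i]
    gid <- exp$metadata$genotype_id[i]
    recs <- exp$calls[[lid]]
    recs <- recs[recs$contig %in% mito & !is.na(recs$af), , drop = FALSE]
    if (!nrow(recs)) next
    if (any(recs$af < 0 | recs$af > 1))
      stop("allele frequencies outside [0, 1] in line ", lid, call. = FALSE)
    anc <- exp$ancestors[[gid]]$het
    anc_key <- paste(anc$contig, anc$pos)
    keep <- !(paste(recs$contig, recs$pos) %in% anc_key) &
      recs$af >= filters$mito_min_frequency &
      round(recs$af * recs$depth) >= filters$mito_min_alt_reads &
      recs$qual >= filters$min_quality &
      mask_covers(exp$masks[[lid]], recs$contig, recs$pos)
    if (!any(keep)) next
    hit <- recs[keep, , drop = FALSE]
    out[[lid]] <- data.frame(line_id = lid, contig = hit$contig,
                             pos = hit$pos, ref = hit$ref, alt = hit$alt,
                             f = hit$af,
                             class = collapse_substitution(hit$ref, hit$alt),
                             partition = "mito", stringsAsFactors = FALSE)
  }
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(line_id = character(), contig = character(), pos = integer(),
               ref = character(), alt = character(), f = numeric(),
               class = character(), partition = character(),
               stringsAsFactors = FALSE)
  rownames(res) <- NULL
  res
}

#' Detect gene-conversion (loss-of-heterozygosity) tracts
#'
#' Candidate sites are ancestral heterozygous sites rendered homozygous in
#' the focal line and callable in both ancestor and line. Sites whose depth
#' falls below `lod_depth_ratio_min` times the line's mean depth are
#' excluded as likely hemizygous deletions. Candidates are clustered into
#' tracts by single linkage with inter-site gap at most `max_gap`.
#'
#' @inheritParams call_nuclear_mutations
#' @param max_gap Maximum bp gap between consecutive sites of one tract.
#' @return list of class `ma_tracts` with elements `tracts` (one row per
#'   tract: line_id, contig, tract_id, start, end, n_sites, span) and
#'   `sites` (one row per converted site with its direction).
#' @export
detect_conversion_tracts <- function(exp, max_gap = 10000,
                                     filters = filter_config()) {
  stopifnot(inherits(exp, "ma_experiment"))
  nuc <- contigs_of(exp$reference, "nuclear")
  tracts <- list()
  sites <- list()
  for (i in seq_len(nrow(exp$metadata))) {
    lid <- exp$metadata$line_id[i]
    gid <- exp$metadata$genotype_id[i]
    anc <- exp$ancestors[[gid]]$het
    anc <- anc[anc$contig %in% nuc, , drop = FALSE]
    if (!nrow(anc)) next
    recs <- exp$calls[[lid]]
    recs <- recs[recs$contig %in% nuc, , drop = FALSE]
    mean_dp <- mean(recs$depth, na.rm = TRUE)
    idx <- match(paste(anc$contig, anc$pos), paste(recs$contig, recs$pos))
    seen <- !is.na(idx)
    gt <- recs$genotype[idx[seen]]
    dp <- recs$depth[idx[seen]]
    ql <- recs$qual[idx[seen]]
    same_alt <- recs$alt[idx[seen]] == anc$alt[seen]
    cand <- (gt == "hom_ref" | (gt == "hom_alt" & same_alt)) &
      dp >= filters$lod_depth_ratio_min * mean_dp &
      dp >= filters$min_depth &
      ql >= filters$min_quality &
      mask_covers(exp$reference$mask, anc$contig[seen], anc$pos[seen]) &
      mask_covers(exp$masks[[lid]], anc$contig[seen], anc$pos[seen])
    hit <- anc[seen, , drop = FALSE][cand, , drop = FALSE]
    if (!nrow(hit)) next
    hit$direction <- ifelse(gt[cand] == "hom_ref", "to_ref", "to_alt")
    tid0 <- 0L
    for (cg in unique(hit$contig)) {
      h <- hit[hit$contig == cg, , drop = FALSE]
      h <- h[order(h$pos), , drop = FALSE]
      grp <- cumsum(c(1L, as.integer(diff(h$pos) > max_gap))) + tid0
      tid0 <- max(grp)
      sites[[paste(lid, cg)]] <- data.frame(
        line_id = lid, contig = cg, tract_id = grp, pos = h$pos,
        direction = h$direction, stringsAsFactors = FALSE)
      agg_start <- tapply(h$pos, grp, min)
      agg_end <- tapply(h$pos, grp, max)
      agg_n <- tapply(h$pos, grp, length)
      tracts[[paste(lid, cg)]] <- data.frame(
        line_id = lid, contig = cg, tract_id = as.integer(names(agg_start)),
        start = as.integer(agg_start), end = as.integer(agg_end),
        n_sites = as.integer(agg_n),
        span = as.integer(agg_end - agg_start + 1L),
        stringsAsFactors = FALSE)
    }
  }
  bindr <- function(lst, proto) {
    if (length(lst)) {
      out <- do.call(rbind, lst)
      rownames(out) <- NULL
      out
    } else proto
  }
  structure(list(
    tracts = bindr(tracts, data.frame(
      line_id = character(), contig = character(), tract_id = integer(),
      start = integer(), end = integer(), n_sites = integer(),
      span = integer(), stringsAsFactors = FALSE)),
    sites = bindr(sites, data.frame(
      line_id = character(), contig = character(), tract_id = integer(),
      pos = integer(), direction = character(), stringsAsFactors = FALSE))
  ), class = "ma_tracts")
}

#' Compare pooled MA rates with large-population control rates
#'
#' @param rate_table data.frame with columns `role`, `events`, `exposure`
#'   (one row per line), e.g. from [line_rate_table()] filtered to one kind.
#' @return list with `ma_rate`, `control_rate`, `ratio` (NA and
#'   `undefined = TRUE` when the control rate is zero).
#' @export
compare_ma_vs_controls <- function(rate_table) {
  stopifnot(all(c("role", "events", "exposure") %in% names(rate_table)))
  ma <- rate_table[rate_table$role == "MA", , drop = FALSE]
  ctl <- rate_table[rate_table$role %in%
                      c("extant_control", "starting_control"), , drop = FALSE]
  if (!nrow(ma) || !nrow(ctl))
    stop("rate table must contain both MA and control lines", call. = FALSE)
  ma_rate <- sum(ma$events) / sum(ma$exposure)
  control_rate <- sum(ctl$events) / sum(ctl$exposure)
  undefined <- control_rate == 0
  list(ma_rate = ma_rate, control_rate = control_rate,
       ratio = if (undefined) NA_real_ else ma_rate / control_rate,
       undefined = undefined)
}
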