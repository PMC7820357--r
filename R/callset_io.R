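# Readers/writers and the harmonized data model: FASTA via Biostrings, BED
# via rtracklayer (0-based half-open on disk, 1-based closed internally),
# VCF v4.2 read via vcfR, line metadata as TSV, truth ledger as JSON.

GT_CODES <- c(hom_ref = "0/0", het = "0/1", hom_alt = "1/1")

#' Write a simulated experiment to disk as a plain-text fixture
#'
#' Emits `reference.fa`, one VCF v4.2 per line under `lines/`, one callable
#' BED per line under `masks/`, per-genotype ancestor VCFs under
#' `ancestors/`, `metadata.tsv`, and `truth.json`. Re-reading with
#' [read_fixture()] reproduces the in-memory objects.
#'
#' @param exp An `ma_experiment`.
#' @param out_dir Output directory (created if absent).
#' @return `out_dir`, invisibly.
#' @export
write_fixture <- function(exp, out_dir) {
  stopifnot(inherits(exp, "ma_experiment"))
  for (d in file.path(out_dir, c("", "lines", "masks", "ancestors")))
    dir.create(d, recursive = TRUE, showWarnings = FALSE)
  write_reference_fasta(exp$reference, file.path(out_dir, "reference.fa"))
  for (lid in names(exp$calls)) {
    write_vcf(exp$calls[[lid]], file.path(out_dir, "lines", paste0(lid, ".vcf")),
              exp$reference, sample_id = lid)
    write_bed(exp$masks[[lid]], file.path(out_dir, "masks", paste0(lid, ".bed")))
  }
  for (gid in names(exp$ancestors)) {
    anc <- exp$ancestors[[gid]]
    anc_calls <- data.frame(contig = anc$het$contig, pos = anc$het$pos,
                            ref = anc$het$ref, alt = anc$het$alt,
                            genotype = "het", af = NA_real_,
                            depth = 30L, qual = 99,
                            stringsAsFactors = FALSE)
    write_vcf(anc_calls, file.path(out_dir, "ancestors", paste0(gid, ".vcf")),
              exp$reference, sample_id = gid)
  }
  utils::write.table(exp$metadata, file.path(out_dir, "metadata.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(exp$truth, file.path(out_dir, "truth.json"),
                       dataframe = "columns", digits = I(17))
  invisible(out_dir)
}

write_reference_fasta <- function(ref, path) {
  ss <- Biostrings::DNAStringSet(ref$seq)
  names(ss) <- sprintf("%s partition=%s circular=%d", names(ref$seq),
                       ref$partition, as.integer(ref$circular))
  Biostrings::writeXStringSet(ss, path)
}

read_reference_fasta <- function(path, mask = NULL) {
  ss <- Biostrings::readDNAStringSet(path)
  hdr <- names(ss)
  nm <- sub(" .*", "", hdr)
  grab <- function(key, default) {
    m <- regmatches(hdr, regexpr(sprintf("%s=[^ ]+", key), hdr))
    out <- rep(default, length(hdr))
    hit <- grepl(sprintf("%s=", key), hdr)
    out[hit] <- sub(sprintf("%s=", key), "", m)
    out
  }
  partition <- stats::setNames(grab("partition", "nuclear"), nm)
  circular <- stats::setNames(grab("circular", "0") == "1", nm)
  seqs <- stats::setNames(as.character(ss), nm)
  new_reference(seqs, partition, circular, mask = mask)
}

write_bed <- function(mask, path) {
  gr <- GenomicRanges::GRanges(mask$contig,
                               IRanges::IRanges(mask$start, mask$end))
  rtracklayer::export(gr, path, format = "BED")
  invisible(path)
}

read_bed <- function(path) {
  gr <- rtracklayer::import(path, format = "BED")
  new_mask(as.character(GenomicRanges::seqnames(gr)),
           GenomicRanges::start(gr), GenomicRanges::end(gr))
}

# Minimal VCF v4.2 emitter for one sample. GT/DP/GQ in FORMAT; heteroplasmy
# records carry AF in INFO. Positions are written sorted per contig.
write_vcf <- function(calls, path, ref, sample_id) {
  hdr <- c(
    "##fileformat=VCFv4.2",
    "##source=mutacc",
    sprintf("##contig=<ID=%s,length=%d>", names(ref$seq), ref$lengths),
    "##INFO=<ID=AF,Number=1,Type=Float,Description=\"Alternate allele frequency\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
    "##FORMAT=<ID=GQ,Number=1,Type=Integer,Description=\"Genotype quality\">",
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", sample_id, sep = "\t")
  )
  calls <- calls[order(calls$contig, calls$pos), , drop = FALSE]
  body <- if (nrow(calls)) {
    info <- ifelse(is.na(calls$af), ".", sprintf("AF=%.17g", calls$af))
    paste(calls$contig, calls$pos, ".", calls$ref, calls$alt,
          format(calls$qual, trim = TRUE), "PASS", info, "GT:DP:GQ",
          sprintf("%s:%d:%d", GT_CODES[calls$genotype],
                  as.integer(calls$depth), as.integer(round(calls$qual))),
          sep = "\t")
  } else character(0)
  writeLines(c(hdr, body), path)
  invisible(path)
}

read_vcf_calls <- function(path) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  empty <- data.frame(contig = character(), pos = integer(),
                      ref = character(), alt = character(),
                      genotype = character(), af = numeric(),
                      depth = integer(), qual = numeric(),
                      stringsAsFactors = FALSE)
  if (nrow(vcf@fix) == 0) return(empty)
  fix <- as.data.frame(vcf@fix, stringsAsFactors = FALSE)
  gt <- vcfR::extract.gt(vcf, element = "GT")
  dp <- vcfR::extract.gt(vcf, element = "DP", as.numeric = TRUE)
  af <- suppressWarnings(vcfR::extract.info(vcf, element = "AF",
                                            as.numeric = TRUE))
  if (is.null(af)) af <- rep(NA_real_, nrow(fix))
  geno <- names(GT_CODES)[match(gt[, 1], GT_CODES)]
  data.frame(contig = fix$CHROM, pos = as.integer(fix$POS),
             ref = fix$REF, alt = fix$ALT, genotype = geno,
             af = as.numeric(af), depth = as.integer(dp[, 1]),
             qual = as.numeric(fix$QUAL), stringsAsFactors = FALSE)
}

#' Read a call-set bundle into the harmonized experiment model
#'
#' @param vcf_paths Named character vector of per-line VCF paths (names =
#'   line ids matching the metadata).
#' @param fasta_path Reference FASTA; contig descriptions may carry
#'   `partition=` and `circular=` tags.
#' @param bed_paths Named character vector of per-line callable-mask BED
#'   paths (0-based half-open on disk).
#' @param metadata_path TSV with columns line_id, genotype_id, population_id,
#'   generations, generation_time_days, role.
#' @param ancestor_vcf_paths Named character vector of per-genotype ancestor
#'   VCFs (heterozygous-site call sets).
#' @return An `ma_experiment` (without a truth ledger).
#' @export
read_callsets <- function(vcf_paths, fasta_path, bed_paths, metadata_path,
                          ancestor_vcf_paths) {
  for (p in c(vcf_paths, fasta_path, bed_paths, metadata_path,
              ancestor_vcf_paths))
    if (!file.exists(p)) stop("input file not found: ", p, call. = FALSE)
  metadata <- utils::read.delim(metadata_path, stringsAsFactors = FALSE)
  required <- c("line_id", "genotype_id", "population_id", "generations",
                "generation_time_days", "role")
  missing_cols <- setdiff(required, names(metadata))
  if (length(missing_cols))
    stop("metadata is missing required columns: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  if (!all(metadata$role %in% c("MA", "starting_control", "extant_control")))
    stop("metadata 'role' must be MA, starting_control or extant_control")
  if (!all(metadata$line_id %in% names(vcf_paths)))
    stop("VCF missing for lines: ",
         paste(setdiff(metadata$line_id, names(vcf_paths)), collapse = ", "))

  ref <- read_reference_fasta(fasta_path)
  masks <- lapply(bed_paths, read_bed)
  calls <- lapply(vcf_paths, read_vcf_calls)
  for (lid in names(calls)) {
    bad <- setdiff(unique(calls[[lid]]$contig), names(ref$seq))
    if (length(bad))
      stop("contig(s) in ", lid, " VCF absent from reference: ",
           paste(bad, collapse = ", "), call. = FALSE)
  }
  ancestors <- lapply(ancestor_vcf_paths, function(p) {
    v <- read_vcf_calls(p)
    het <- v[v$genotype == "het" & is.na(v$af),
             c("contig", "pos", "ref", "alt")]
    rownames(het) <- NULL
    structure(list(het = het, n_het = nrow(het)), class = "ma_ancestry")
  })
  structure(list(reference = ref, ancestors = ancestors,
                 metadata = metadata, calls = calls, masks = masks,
                 truth = NULL, config = NULL),
            class = "ma_experiment")
}

#' Read a fixture directory written by [write_fixture()]
#'
#' @param dir Fixture directory.
#' @return An `ma_experiment`, with the truth ledger attached when
#'   `truth.json` is present.
#' @export
read_fixture <- function(dir) {
  if (!dir.exists(dir)) stop("fixture directory not found: ", dir,
                             call. = FALSE)
  metadata <- utils::read.delim(file.path(dir, "metadata.tsv"),
                                stringsAsFactors = FALSE)
  lids <- metadata$line_id
  vcfs <- stats::setNames(file.path(dir, "lines", paste0(lids, ".vcf")), lids)
  beds <- stats::setNames(file.path(dir, "masks", paste0(lids, ".bed")), lids)
  anc_files <- list.files(file.path(dir, "ancestors"), "\\.vcf$",
                          full.names = TRUE)
  ancs <- stats::setNames(anc_files, sub("\\.vcf$", "", basename(anc_files)))
  exp <- read_callsets(vcfs, file.path(dir, "reference.fa"), beds,
                       file.path(dir, "metadata.tsv"), ancs)
  truth_path <- file.path(dir, "truth.json")
  if (file.exists(truth_path)) {
    tr <- jsonlite::read_json(truth_path, simplifyVector = TRUE)
    exp$truth <- lapply(tr, function(d) {
      d <- as.data.frame(d, stringsAsFactors = FALSE)
      if ("pos" %in% names(d)) d$pos <- as.integer(d$pos)
      if ("tract_id" %in% names(d)) d$tract_id <- as.integer(d$tract_id)
      d
    })
  }
  exp
}

#' Count callable sites, optionally by central base or trinucleotide context
#'
#' Context counting uses the strand-collapsed convention (central base A or
#' C after reverse complementation). A site is context-countable only if its
#' 3-bp window stays on the contig (windows wrap on circular contigs) and
#' contains no N; the sum over the 32 collapsed contexts therefore equals
#' the number of context-countable callable sites.
#'
#' @param ref An `ma_reference`.
#' @param by One of `"total"`, `"central_base_class"`,
#'   `"trinucleotide_context"`.
#' @param mask Callable mask (defaults to the reference mask).
#' @param partition Which partition to count (default nuclear).
#' @return Named numeric vector of counts.
#' @export
count_callable_sites <- function(ref, by = c("total", "central_base_class",
                                             "trinucleotide_context"),
                                 mask = ref$mask, partition = "nuclear") {
  by <- match.arg(by)
  cgs <- contigs_of(ref, partition)
  mask <- mask[mask$contig %in% cgs, , drop = FALSE]
  if (by == "total") return(c(total = mask_width(mask)))
  counts <- stats::setNames(numeric(length(all_contexts())), all_contexts())
  for (cg in cgs) {
    m <- mask[mask$contig == cg, , drop = FALSE]
    if (!nrow(m)) next
    L <- ref$lengths[[cg]]
    circ <- ref$circular[[cg]]
    sq <- ref$seq[[cg]]
    for (k in seq_len(nrow(m))) {
      s <- m$start[k]; e <- m$end[k]
      if (!circ) {
        s <- max(s, 2L); e <- min(e, L - 1L)
        if (s > e) next
        sub <- substring(sq, s - 1L, e + 1L)
      } else {
        idx <- ((s - 2L):(e)) %% L + 1L # window start positions, wrapped
        sub <- paste(substring(sq, idx, idx), collapse = "")
      }
      tri <- Biostrings::oligonucleotideFrequency(Biostrings::DNAString(sub), 3)
      tri <- tri[tri > 0]
      if (!length(tri)) next
      coll <- collapse_context(names(tri))
      agg <- tapply(as.numeric(tri), coll, sum)
      counts[names(agg)] <- counts[names(agg)] + agg
    }
  }
  if (by == "trinucleotide_context") return(counts)
  central <- substr(names(counts), 2, 2)
  c(A = sum(counts[central == "A"]), C = sum(counts[central == "C"]))
}

all_contexts <- function() {
  out <- as.vector(outer(BASES, c("A", "C"), function(l, c) paste0(l, c)))
  out <- as.vector(outer(out, BASES, paste0))
  sort(out)
}
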