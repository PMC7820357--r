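# Shared helpers: base complementation, interval (mask) arithmetic, and
# small validators used across modules.

BASES <- c("A", "C", "G", "T")

comp_base <- function(x) chartr("ACGT", "TGCA", x)

revcomp <- function(x) {
  vapply(x, function(s) {
    comp_base(paste(rev(strsplit(s, "")[[1]]), collapse = ""))
  }, character(1), USE.NAMES = FALSE)
}

#' @importFrom IRanges IRanges reduce width
NULL

# Masks are data.frames with columns contig, start, end (1-based, closed).
new_mask <- function(contig, start, end) {
  stopifnot(length(contig) == length(start), length(start) == length(end))
  m <- data.frame(contig = as.character(contig),
                  start = as.integer(start), end = as.integer(end),
                  stringsAsFactors = FALSE)
  if (nrow(m) && any(m$end < m$start)) stop("mask intervals must have end >= start")
  m[order(m$contig, m$start), , drop = FALSE]
}

full_mask <- function(contig_lengths) {
  new_mask(names(contig_lengths), rep(1L, length(contig_lengths)),
           as.integer(contig_lengths))
}

mask_width <- function(mask, contigs = unique(mask$contig)) {
  m <- mask[mask$contig %in% contigs, , drop = FALSE]
  if (!nrow(m)) return(0L)
  sum(vapply(split(m, m$contig), function(d) {
    sum(IRanges::width(IRanges::reduce(IRanges::IRanges(d$start, d$end))))
  }, numeric(1)))
}

mask_intersect <- function(a, b) {
  contigs <- intersect(unique(a$contig), unique(b$contig))
  out <- lapply(contigs, function(cg) {
    ir <- IRanges::intersect(
      IRanges::reduce(IRanges::IRanges(a$start[a$contig == cg], a$end[a$contig == cg])),
      IRanges::reduce(IRanges::IRanges(b$start[b$contig == cg], b$end[b$contig == cg]))
    )
    if (!length(ir)) return(NULL)
    new_mask(rep(cg, length(ir)), IRanges::start(ir), IRanges::end(ir))
  })
  out <- do.call(rbind, out)
  if (is.null(out)) new_mask(character(), integer(), integer()) else out
}

# TRUE for each (contig, pos) covered by the mask.
mask_covers <- function(mask, contig, pos) {
  out <- logical(length(pos))
  for (cg in unique(contig)) {
    sel <- contig == cg
    m <- mask[mask$contig == cg, , drop = FALSE]
    if (!nrow(m)) next
    m <- m[order(m$start), , drop = FALSE]
    idx <- findInterval(pos[sel], m$start)
    ok <- idx >= 1L
    ok[ok] <- pos[sel][ok] <= m$end[idx[ok]]
    out[sel] <- ok
  }
  out
}

assert_scalar_number <- function(x, name, min = -Inf, max = Inf,
                                 strict_min = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x))
    stop(sprintf("'%s' must be a single number", name), call. = FALSE)
  if (x < min || (strict_min && x <= min) || x > max)
    stop(sprintf("'%s' = %s is out of range", name, format(x)), call. = FALSE)
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
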