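# Mutation spectrum: six strand-collapsed substitution classes, 32
# trinucleotide contexts, conditional rates, Ts:Tv, CpG contrasts, and a
# goodness-of-fit test of spectrum homogeneity.

#' Collapse a substitution into one of six strand-symmetric classes
#'
#' Complementary changes are identified (`G>A` and `C>T` both collapse to
#' `"C:G>T:A"`), so the class depends only on the mutated base pair.
#'
#' @param ref,alt Reference and alternate bases (vectors of single
#'   characters in A/C/G/T, `ref != alt`).
#' @return Character vector over [MUTATION_CLASSES].
#' @export
collapse_substitution <- function(ref, alt) {
  if (length(ref) != length(alt)) stop("ref and alt must match in length")
  if (!length(ref)) return(character(0))
  if (!all(ref %in% BASES) || !all(alt %in% BASES))
    stop("bases must be one of A, C, G, T", call. = FALSE)
  if (any(ref == alt)) stop("ref and alt must differ", call. = FALSE)
  flip <- ref %in% c("G", "T")
  from <- ifelse(flip, comp_base(ref), ref)
  to <- ifelse(flip, comp_base(alt), alt)
  paste0(from, ":", comp_base(from), ">", to, ":", comp_base(to))
}

#' Collapse a 3-bp context so its central base is A or C
#'
#' Contexts with a central G or T are reverse complemented.
#'
#' @param context Character vector of 3-bp contexts (A/C/G/T only).
#' @return Collapsed contexts (32 possible values).
#' @export
collapse_context <- function(context) {
  if (!length(context)) return(character(0))
  stopifnot(all(nchar(context) == 3))
  flip <- substr(context, 2, 2) %in% c("G", "T")
  context[flip] <- revcomp(context[flip])
  context
}

transition_classes <- function() c("A:T>G:C", "C:G>T:A")

#' Build a spectrum table with conditional rates
#'
#' Conditional rates divide each count by `g_total * 2 * denominator`, where
#' the denominator is the callable-site count of the matching context (or of
#' the matching central-base class for the six-class rates), removing
#' base-composition bias. `g_total` is the summed line-generations of the
#' lines contributing the calls.
#'
#' @param calls Nuclear calls from [call_nuclear_mutations()] (columns
#'   `class` and `context`; rows with `NA` context are counted in the class
#'   table only).
#' @param context_denominators Named counts over the 32 collapsed contexts,
#'   from [count_callable_sites()].
#' @param g_total Summed generations across contributing lines.
#' @return Object of class `ma_spectrum`: class/context counts, their
#'   denominators, conditional rates, the class-by-context joint table, and
#'   central-base aggregate rates.
#' @export
context_conditional_rates <- function(calls, context_denominators, g_total) {
  assert_scalar_number(g_total, "g_total", min = 1)
  ctxs <- all_contexts()
  if (!all(ctxs %in% names(context_denominators)))
    stop("context_denominators must cover all 32 collapsed contexts")
  context_denominators <- context_denominators[ctxs]
  cls <- factor(calls$class, levels = MUTATION_CLASSES)
  ctx <- factor(calls$context, levels = ctxs)
  class_counts <- table(cls)
  context_counts <- table(ctx)
  if (any(context_counts > 0 & context_denominators == 0))
    stop("mutation observed at a context with zero callable denominator")
  joint <- table(cls, ctx)
  central <- substr(ctxs, 2, 2)
  denom_central <- c(A = sum(context_denominators[central == "A"]),
                     C = sum(context_denominators[central == "C"]))
  class_pair <- substr(MUTATION_CLASSES, 1, 1) # "A" or "C"
  class_denom <- stats::setNames(denom_central[class_pair], MUTATION_CLASSES)
  class_rates <- as.numeric(class_counts) / (g_total * 2 * class_denom)
  context_rates <- ifelse(context_denominators > 0,
                          as.numeric(context_counts) /
                            (g_total * 2 * context_denominators), NA_real_)
  central_counts <- c(A = sum(context_counts[central == "A"]),
                      C = sum(context_counts[central == "C"]))
  structure(list(
    class_counts = stats::setNames(as.numeric(class_counts), MUTATION_CLASSES),
    context_counts = stats::setNames(as.numeric(context_counts), ctxs),
    joint = joint,
    class_denominators = class_denom,
    context_denominators = context_denominators,
    g_total = g_total,
    class_rates = stats::setNames(as.numeric(class_rates), MUTATION_CLASSES),
    context_rates = stats::setNames(as.numeric(context_rates), ctxs),
    central_rates = central_counts / (g_total * 2 * denom_central)
  ), class = "ma_spectrum")
}

#' Transition:transversion ratio
#'
#' @param spectrum An `ma_spectrum` or a named six-class count vector.
#' @param weighting `"count"` (raw counts) or `"conditional"` (sums of
#'   conditional class rates).
#' @return The Ts:Tv ratio; `Inf` when no transversions were observed.
#' @export
ts_tv <- function(spectrum, weighting = c("count", "conditional")) {
  weighting <- match.arg(weighting)
  v <- if (inherits(spectrum, "ma_spectrum")) {
    if (weighting == "count") spectrum$class_counts else spectrum$class_rates
  } else {
    stopifnot(setequal(names(spectrum), MUTATION_CLASSES))
    spectrum[MUTATION_CLASSES]
  }
  ts <- sum(v[transition_classes()])
  tv <- sum(v[setdiff(MUTATION_CLASSES, transition_classes())])
  if (tv == 0) return(Inf)
  unname(ts / tv)
}

cpg_contexts <- function() {
  ctx <- all_contexts()
  ctx[substr(ctx, 2, 2) == "C" & substr(ctx, 3, 3) == "G"]
}

#' CpG vs non-CpG conditional-rate contrast
#'
#' Under the strand-collapsed convention a site is CpG iff its central base
#' is C and the 3' neighbour is G (equivalently, C followed by G on either
#' strand). The contrast pools CpG-context counts against the remaining
#' central-C contexts per group (typically genotypes) and applies a paired
#' t-test to the per-group differences (df = groups - 1).
#'
#' @param group_spectra Named list of `ma_spectrum`, one per group.
#' @return list with per-group rates, `mean_difference` (CpG minus
#'   non-CpG), `statistic`, `df`, `p.value`.
#' @export
cpg_contrast <- function(group_spectra) {
  stopifnot(length(group_spectra) >= 2)
  cpg <- cpg_contexts()
  ctx <- all_contexts()
  noncpg <- setdiff(ctx[substr(ctx, 2, 2) == "C"], cpg)
  one <- function(sp, which_ctx) {
    sum(sp$context_counts[which_ctx]) /
      (sp$g_total * 2 * sum(sp$context_denominators[which_ctx]))
  }
  cpg_rates <- vapply(group_spectra, one, numeric(1), which_ctx = cpg)
  non_rates <- vapply(group_spectra, one, numeric(1), which_ctx = noncpg)
  d <- cpg_rates - non_rates
  n <- length(d)
  if (stats::sd(d) == 0) {
    stat <- if (mean(d) == 0) 0 else Inf * sign(mean(d))
    p <- if (mean(d) == 0) 1 else 0
  } else {
    tt <- stats::t.test(cpg_rates, non_rates, paired = TRUE)
    stat <- unname(tt$statistic)
    p <- tt$p.value
  }
  list(cpg_rates = cpg_rates, noncpg_rates = non_rates,
       mean_difference = mean(d), statistic = stat, df = n - 1L,
       p.value = p)
}

#' Goodness-of-fit test of spectrum homogeneity across the six classes
#'
#' Tests the observed class counts against the expectation proportional to
#' each class's callable site exposure (a uniform per-site mutation rate
#' across classes); df = 5.
#'
#' @param class_counts Named six-class counts.
#' @param class_denominators Named six-class callable-site denominators.
#' @return list with `statistic`, `df`, `p.value`.
#' @export
spectrum_homogeneity_test <- function(class_counts, class_denominators) {
  stopifnot(setequal(names(class_counts), MUTATION_CLASSES),
            setequal(names(class_denominators), MUTATION_CLASSES))
  o <- as.numeric(class_counts[MUTATION_CLASSES])
  d <- as.numeric(class_denominators[MUTATION_CLASSES])
  if (sum(o) <= 0) stop("total mutation count must be positive")
  if (any(d <= 0)) stop("class denominators must be positive")
  ht <- suppressWarnings(stats::chisq.test(o, p = d / sum(d)))
  list(statistic = unname(ht$statistic), df = unname(ht$parameter),
       p.value = ht$p.value)
}
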