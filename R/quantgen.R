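# Derived evolutionary quantities: mutational-equilibrium GC content,
# mutation/conversion heterozygosity equilibrium, effective population size,
# heritability and evolvability of the mutation rate as a trait, and the
# correlation/ANOVA comparisons used across genotypes and populations.

#' Equilibrium GC content implied by the conditional class rates
#'
#' With `alpha` the total AT->GC conditional rate per A:T site and `beta`
#' the total GC->AT conditional rate per C:G site, the expected GC fraction
#' at mutational equilibrium is `alpha / (alpha + beta)`. Invariant to
#' rescaling all rates by a constant.
#'
#' @param class_rates Named conditional rates including `"A:T>G:C"`,
#'   `"A:T>C:G"`, `"C:G>A:T"`, `"C:G>T:A"` (e.g. `$class_rates` of an
#'   `ma_spectrum`).
#' @return Expected equilibrium GC fraction in `[0, 1]`.
#' @export
gc_equilibrium <- function(class_rates) {
  need <- c("A:T>G:C", "A:T>C:G", "C:G>A:T", "C:G>T:A")
  if (!all(need %in% names(class_rates)))
    stop("class_rates must include the four GC-changing classes")
  alpha <- sum(class_rates[c("A:T>G:C", "A:T>C:G")])
  beta <- sum(class_rates[c("C:G>A:T", "C:G>T:A")])
  if (alpha == 0 && beta == 0)
    stop("undefined equilibrium: all GC-changing rates are zero",
         call. = FALSE)
  unname(alpha / (alpha + beta))
}

#' Expected heterozygosity at mutation-conversion equilibrium
#'
#' Gene conversion erodes the heterozygosity that mutation introduces; at
#' equilibrium the expected heterozygous fraction of new variation is
#' `mu_bs / (mu_bs + mu_gc)`.
#'
#' @param mu_bs Base-substitution rate (>= 0).
#' @param mu_gc Gene-conversion rate (>= 0); `mu_bs + mu_gc > 0`.
#' @return Value in (0, 1].
#' @export
expected_heterozygosity <- function(mu_bs, mu_gc) {
  assert_scalar_number(mu_bs, "mu_bs", min = 0)
  assert_scalar_number(mu_gc, "mu_gc", min = 0)
  if (mu_bs + mu_gc <= 0) stop("mu_bs + mu_gc must be positive")
  mu_bs / (mu_bs + mu_gc)
}

#' Effective population size from neutral diversity
#'
#' Solves `pi = 4 Ne mu` for `Ne` given synonymous-site diversity and the
#' per-generation mutation rate.
#'
#' @param pi_s Synonymous-site nucleotide diversity (>= 0).
#' @param mu Mutation rate per bp per generation (> 0).
#' @return Effective population size estimate.
#' @export
effective_population_size <- function(pi_s, mu) {
  assert_scalar_number(pi_s, "pi_s", min = 0)
  assert_scalar_number(mu, "mu", min = 0, strict_min = TRUE)
  pi_s / (4 * mu)
}

#' Heritability and evolvability of a line-level trait
#'
#' One-way random-effects decomposition by expected mean squares of line
#' values grouped by genotype: `V_E = MS_within`,
#' `V_G = (MS_between - MS_within) / n0` with
#' `n0 = (N - sum(n_i^2)/N) / (k - 1)` the effective lines per genotype for
#' unbalanced designs. Broad-sense heritability is `H2 = V_G / (V_G + V_E)`.
#' Because "evolvability" admits two mean-scalings, both are returned with
#' explicit labels: `evolvability_mean_sq = V_G / mean^2` (the conventional
#' mean-standardized genetic variance) and `evolvability_mean = V_G / mean`.
#'
#' @param values Line-level trait values (e.g. per-line mutation rates).
#' @param genotype Grouping factor (>= 2 groups, >= 2 lines in some group).
#' @return Object of class `ma_quantgen`: `V_G`, `V_E`, `H2`, both
#'   evolvability variants, `truncated` (TRUE when a negative
#'   method-of-moments `V_G` was set to 0), `undefined` (TRUE when total
#'   variance is 0), and the scheme label.
#' @export
heritability_evolvability <- function(values, genotype) {
  genotype <- as.factor(genotype)
  stopifnot(length(values) == length(genotype))
  if (nlevels(droplevels(genotype)) < 2)
    stop("need at least 2 genotypes", call. = FALSE)
  genotype <- droplevels(genotype)
  N <- length(values)
  k <- nlevels(genotype)
  ni <- as.numeric(table(genotype))
  if (all(ni < 2)) stop("need replicate lines within genotypes", call. = FALSE)
  gm <- tapply(values, genotype, mean)
  ss_between <- sum(ni * (gm - mean(values))^2)
  ss_within <- sum((values - gm[genotype])^2)
  ms_between <- ss_between / (k - 1)
  ms_within <- ss_within / (N - k)
  n0 <- (N - sum(ni^2) / N) / (k - 1)
  v_e <- ms_within
  v_g <- (ms_between - ms_within) / n0
  truncated <- v_g < 0
  if (truncated) v_g <- 0
  undefined <- (v_g + v_e) == 0
  h2 <- if (undefined) NA_real_ else v_g / (v_g + v_e)
  xbar <- mean(values)
  structure(list(V_G = v_g, V_E = v_e, H2 = h2,
                 evolvability_mean_sq = if (xbar != 0) v_g / xbar^2 else NA_real_,
                 evolvability_mean = if (xbar != 0) v_g / xbar else NA_real_,
                 truncated = truncated, undefined = undefined,
                 scheme = "one-way random effects (expected mean squares)"),
            class = "ma_quantgen")
}

#' Spearman rank correlation with the t approximation
#'
#' `rho` on ranks with `t = rho * sqrt((n - 2) / (1 - rho^2))` on `n - 2`
#' degrees of freedom; `t` is flagged infinite for perfectly monotone pairs.
#'
#' @param x,y Paired numeric vectors (n >= 3).
#' @return list with `rho`, `t`, `df`, `p.value`.
#' @export
correlate <- function(x, y) {
  stopifnot(length(x) == length(y))
  n <- length(x)
  if (n < 3) stop("need at least 3 pairs", call. = FALSE)
  rho <- stats::cor(x, y, method = "spearman")
  df <- n - 2L
  if (abs(rho) >= 1 - 1e-12) {
    t <- sign(rho) * Inf
    p <- 0
  } else {
    t <- rho * sqrt(df / (1 - rho^2))
    p <- 2 * stats::pt(-abs(t), df)
  }
  list(rho = rho, t = t, df = df, p.value = p)
}

#' One-way ANOVA of rates across groups with Tukey HSD
#'
#' @param values Numeric response (e.g. genotype-level rates).
#' @param group Grouping factor (>= 2 groups, e.g. population).
#' @param transform `"none"` or `"log10"` (requires positive values).
#' @return list with `F`, `df1`, `df2`, `p.value` and `tukey` (pairwise
#'   comparison table).
#' @export
population_anova <- function(values, group, transform = c("none", "log10")) {
  transform <- match.arg(transform)
  group <- droplevels(as.factor(group))
  if (nlevels(group) < 2) stop("need at least 2 groups", call. = FALSE)
  if (length(values) - nlevels(group) < 1)
    stop("need replication within groups (residual df >= 1)", call. = FALSE)
  if (transform == "log10") {
    if (any(values <= 0))
      stop("log10 transform requires positive values", call. = FALSE)
    values <- log10(values)
  }
  fit <- stats::aov(values ~ group)
  s <- summary(fit)[[1]]
  tk <- stats::TukeyHSD(fit)$group
  list(F = s[["F value"]][1], df1 = s[["Df"]][1], df2 = s[["Df"]][2],
       p.value = s[["Pr(>F)"]][1],
       tukey = data.frame(pair = rownames(tk), tk, row.names = NULL))
}
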