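#' Hardy-Weinberg equilibrium goodness-of-fit test
#'
#' One-degree-of-freedom chi-square goodness-of-fit of the observed genotype
#' counts against the Hardy-Weinberg expectations \eqn{p^2, 2pq, q^2} computed
#' from the observed allele frequencies, where \eqn{q} is the 5-repeat allele
#' frequency \eqn{(2 n_{55} + n_{45}) / (2 n)}.
#'
#' @param counts A [genotypeCounts()] object (total > 0).
#' @return Object of class `hwe_result`: list with `chi2`, `df` (always 1),
#'   `p_value` (upper chi-square tail) and `allele5_freq`. A monomorphic
#'   sample (an expected class of zero) yields `p_value = 1` with a warning.
#' @examples
#' hweTest(genotypeCounts(268, 248, 51))  # p about 0.55
#' @export
hweTest <- function(counts) {
  stopifnot(inherits(counts, "genotype_counts"))
  n <- attr(counts, "total")
  if (n <= 0) stop("cannot test HWE on an empty count table")
  q <- (2 * counts[["n55"]] + counts[["n45"]]) / (2 * n)
  p <- 1 - q
  expected <- n * c(p^2, 2 * p * q, q^2)
  observed <- unclass(counts)
  if (any(expected == 0)) {
    warning("monomorphic sample: an expected genotype class is zero; p set to 1")
    res <- list(chi2 = 0, df = 1L, p_value = 1, allele5_freq = q)
    class(res) <- "hwe_result"
    return(res)
  }
  chi2 <- sum((observed - expected)^2 / expected)
  res <- list(chi2 = chi2, df = 1L,
              p_value = pchisq(chi2, df = 1, lower.tail = FALSE),
              allele5_freq = unname(q))
  class(res) <- "hwe_result"
  res
}

#' @export
print.hwe_result <- function(x, ...) {
  cat(sprintf("HWE goodness-of-fit: chi2 = %.4f (df = 1), p = %.4g; 5-allele freq = %.4f\n",
              x$chi2, x$p_value, x$allele5_freq))
  invisible(x)
}

#' Genotype frequencies
#'
#' @param counts A [genotypeCounts()] object with total > 0.
#' @return Named numeric vector of the three genotype proportions (sums to 1).
#' @export
genotypeFrequencies <- function(counts) {
  stopifnot(inherits(counts, "genotype_counts"))
  n <- attr(counts, "total")
  if (n <= 0) stop("cannot compute frequencies of an empty count table")
  setNames(as.vector(counts, mode = "numeric") / n, genotypeLevels())
}

#' Genotype contrasts
#'
#' The three case-control contrasts supported by [contrastOR()], named by
#' genotype composition: `HOM` (5/5 vs 4/4), `HET` (4/5 vs 4/4) and
#' `COMBINED` (4/5 plus 5/5 vs 4/4).
#'
#' @return Character vector of the contrast names.
#' @export
contrastLevels <- function() c("HOM", "HET", "COMBINED")

# 2x2 table (a = exposed cases, b = exposed controls, c = reference cases,
# d = reference controls) for one genotype contrast; NA if any needed cell
# is missing.
.contrastTable <- function(cases, controls, contrast) {
  contrast <- match.arg(contrast, contrastLevels())
  pick <- switch(contrast,
                 HOM = function(x) x[["n55"]],
                 HET = function(x) x[["n45"]],
                 COMBINED = function(x) x[["n45"]] + x[["n55"]])
  c(a = pick(cases), b = pick(controls),
    c = cases[["n44"]], d = controls[["n44"]])
}

# Woolf log-OR machinery shared by contrastOR() and tumorEnrichmentOR().
.woolfOR <- function(cells, contrast, ci_level) {
  if (all(cells == 0)) stop("all-zero 2x2 table")
  if (any(cells == 0)) {
    warning("zero cell in 2x2 table; adding 0.5 continuity correction to all cells")
    cells <- cells + 0.5
  }
  log_or <- log(cells[["a"]]) + log(cells[["d"]]) -
    log(cells[["b"]]) - log(cells[["c"]])
  se <- sqrt(sum(1 / cells))
  z <- qnorm(1 - (1 - ci_level) / 2)
  res <- list(contrast = contrast,
              odds_ratio = exp(log_or),
              log_or = log_or,
              se_log_or = se,
              ci_low = exp(log_or - z * se),
              ci_high = exp(log_or + z * se),
              ci_level = ci_level,
              table = cells)
  class(res) <- "or_result"
  res
}

#' Unadjusted genotype odds ratio with Woolf confidence interval
#'
#' Computes the odds ratio OR = (a d)/(b c) for one genotype contrast, with
#' the Woolf (log-normal) confidence interval
#' \eqn{\exp(\log OR \pm z_{1-\alpha/2} \sqrt{1/a + 1/b + 1/c + 1/d})}.
#' No continuity correction is applied when all four cells are positive; a
#' zero cell triggers the 0.5 correction on all cells with a warning.
#'
#' @param cases,controls [genotypeCounts()] objects for the two groups.
#' @param contrast One of [contrastLevels()]: `"HOM"` (5/5 vs 4/4), `"HET"`
#'   (4/5 vs 4/4) or `"COMBINED"` (4/5 and 5/5 vs 4/4).
#' @param ci_level Confidence level (default 0.95).
#' @return Object of class `or_result` with `odds_ratio`, `log_or`,
#'   `se_log_or`, `ci_low`, `ci_high`, `ci_level` and the underlying 2x2
#'   `table`.
#' @examples
#' # Oslo cohort, 5/5 vs 4/4: OR 1.09 (0.85-1.40)
#' contrastOR(genotypeCounts(761, 666, 148), genotypeCounts(816, 679, 145), "HOM")
#' @export
contrastOR <- function(cases, controls, contrast = c("HOM", "HET", "COMBINED"),
                       ci_level = 0.95) {
  stopifnot(inherits(cases, "genotype_counts"),
            inherits(controls, "genotype_counts"))
  contrast <- match.arg(contrast)
  .woolfOR(.contrastTable(cases, controls, contrast), contrast, ci_level)
}

#' @export
print.or_result <- function(x, ...) {
  cat(sprintf("%s contrast: OR = %.2f (%d%% CI %.2f-%.2f)\n",
              x$contrast, x$odds_ratio, round(100 * x$ci_level),
              x$ci_low, x$ci_high))
  invisible(x)
}

#' Chi-square homogeneity test of genotype distributions across groups
#'
#' Standard contingency chi-square of the 3-column genotype distribution
#' across k groups, with df = 2(k - 1). Cells whose expected count is zero
#' (a genotype absent from every group) contribute nothing to the statistic;
#' an expected count below 1 triggers a warning but not an abort.
#'
#' @param tables List of two or more [genotypeCounts()] objects, each with a
#'   positive total.
#' @return List with `chi2`, `df` and `p`.
#' @export
homogeneityChi2 <- function(tables) {
  stopifnot(is.list(tables), length(tables) >= 2)
  mat <- do.call(rbind, lapply(tables, function(t) {
    stopifnot(inherits(t, "genotype_counts"))
    if (attr(t, "total") <= 0) stop("every group must have a positive total")
    unclass(t)
  }))
  expected <- outer(rowSums(mat), colSums(mat)) / sum(mat)
  if (any(expected > 0 & expected < 1)) {
    warning("expected cell count below 1; chi-square approximation may be poor")
  }
  pos <- expected > 0
  chi2 <- sum((mat[pos] - expected[pos])^2 / expected[pos])
  df <- 2L * (nrow(mat) - 1L)
  list(chi2 = chi2, df = df, p = pchisq(chi2, df = df, lower.tail = FALSE))
}
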