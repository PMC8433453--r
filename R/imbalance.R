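#' Classify blood-to-tumor genotype transitions
#'
#' Scans matched blood/tumor genotype pairs for loss-of-heterozygosity (LOH)
#' events. A blood heterozygote whose tumor is `4/4` counts as an LOH event
#' retaining the 4-repeat allele; one whose tumor is `5/5` retains the
#' 5-repeat allele. A blood homozygote whose tumor carries an allele absent
#' from the blood cannot arise by allele loss and is counted as inconsistent
#' (and kept, not dropped).
#'
#' @param pairs Data frame with columns `patient_id`, `blood`, `tumor`
#'   (genotype factors or strings; see [readMatchedPairs()]).
#' @return Object of class `transition_summary`: list with `n_pairs`,
#'   `n_blood_het`, `n_het_changed`, `n_loh_retain4`, `n_loh_retain5`,
#'   `n_inconsistent`.
#' @export
classifyTransitions <- function(pairs) {
  if (anyDuplicated(pairs$patient_id)) {
    stop("duplicate patient_id: ",
         paste(unique(pairs$patient_id[duplicated(pairs$patient_id)]),
               collapse = ", "))
  }
  blood <- parseGenotype(pairs$blood)
  tumor <- parseGenotype(pairs$tumor)
  het <- blood == "4/5"
  retain4 <- het & tumor == "4/4"
  retain5 <- het & tumor == "5/5"
  # a homozygote's tumor showing the other allele implies allele gain
  inconsistent <- (blood == "4/4" & tumor != "4/4") |
    (blood == "5/5" & tumor != "5/5")
  res <- list(n_pairs = length(blood),
              n_blood_het = sum(het),
              n_het_changed = sum(retain4) + sum(retain5),
              n_loh_retain4 = sum(retain4),
              n_loh_retain5 = sum(retain5),
              n_inconsistent = sum(inconsistent))
  class(res) <- "transition_summary"
  res
}

#' @export
print.transition_summary <- function(x, ...) {
  cat(sprintf("Matched pairs: %d (%d blood heterozygotes)\n",
              x$n_pairs, x$n_blood_het))
  cat(sprintf("  LOH events: %d (%d retain 4-allele, %d retain 5-allele)\n",
              x$n_het_changed, x$n_loh_retain4, x$n_loh_retain5))
  if (x$n_inconsistent > 0) {
    cat(sprintf("  inconsistent (allele-gain) pairs: %d\n", x$n_inconsistent))
  }
  invisible(x)
}

#' Exact binomial test of allele-retention direction
#'
#' Under no retention bias, each LOH event retains either allele with
#' probability 1/2. Both one-sided "greater" tails of the exact binomial are
#' reported: `p_toward5` = P(X >= n_retain5) and `p_toward4` =
#' P(X >= n_retain4), with n = n_retain4 + n_retain5 trials.
#'
#' @param n_retain4,n_retain5 Counts of LOH events retaining each allele
#'   (at least one must be positive).
#' @return Object of class `retention_test`: list with `p_toward5`,
#'   `p_toward4`, `retention5_fraction` and `n`.
#' @examples
#' retentionBiasTest(12, 24)  # p_toward5 about 0.033
#' @export
retentionBiasTest <- function(n_retain4, n_retain5) {
  stopifnot(n_retain4 >= 0, n_retain5 >= 0)
  n <- n_retain4 + n_retain5
  if (n < 1) stop("no LOH events to test")
  res <- list(p_toward5 = pbinom(n_retain5 - 1, n, 0.5, lower.tail = FALSE),
              p_toward4 = pbinom(n_retain4 - 1, n, 0.5, lower.tail = FALSE),
              retention5_fraction = n_retain5 / n,
              n = n)
  class(res) <- "retention_test"
  res
}

#' @export
print.retention_test <- function(x, ...) {
  cat(sprintf("Retention-direction binomial test on %d LOH events\n", x$n))
  cat(sprintf("  retain-5 fraction = %.3f; P(toward 5) = %.4g; P(toward 4) = %.4g\n",
              x$retention5_fraction, x$p_toward5, x$p_toward4))
  invisible(x)
}

#' Wilson score interval for the 5-allele retention fraction
#'
#' @param n_retain4,n_retain5 LOH event counts as in [retentionBiasTest()].
#' @param ci_level Confidence level (default 0.95).
#' @return Numeric vector `c(low, high)`.
#' @export
retentionWilsonCI <- function(n_retain4, n_retain5, ci_level = 0.95) {
  n <- n_retain4 + n_retain5
  if (n < 1) stop("no LOH events")
  phat <- n_retain5 / n
  z <- qnorm(1 - (1 - ci_level) / 2)
  denom <- 1 + z^2 / n
  center <- (phat + z^2 / (2 * n)) / denom
  half <- z * sqrt(phat * (1 - phat) / n + z^2 / (4 * n^2)) / denom
  c(low = max(0, center - half), high = min(1, center + half))
}

#' Fisher's exact test on a 2x2 table
#'
#' Thin wrapper around [stats::fisher.test()] returning the two-sided
#' hypergeometric exact p-value (sum of tables with probability at most that
#' of the observed table) and the conditional odds-ratio estimate.
#'
#' @param table 2x2 matrix of non-negative counts with at least one positive
#'   margin.
#' @return List with `odds_ratio` and `p_two_sided`.
#' @export
fisherExact2x2 <- function(table) {
  table <- as.matrix(table)
  stopifnot(all(dim(table) == 2L))
  if (any(table < 0)) stop("counts must be non-negative")
  if (sum(table) == 0) stop("empty table")
  ft <- fisher.test(table)
  list(odds_ratio = unname(ft$estimate), p_two_sided = ft$p.value)
}

#' Tumor-versus-blood 5/5 genotype enrichment
#'
#' Odds ratio for carrying the `5/5` genotype (vs not) in tumor samples
#' relative to blood samples, with the Woolf confidence interval used
#' throughout the package. A zero cell triggers the 0.5 continuity
#' correction with a warning.
#'
#' @param blood,tumor [genotypeCounts()] objects with positive totals.
#' @param ci_level Confidence level (default 0.95).
#' @return An `or_result` (see [contrastOR()]) with contrast `"HOM55_VS_REST"`.
#' @export
tumorEnrichmentOR <- function(blood, tumor, ci_level = 0.95) {
  stopifnot(inherits(blood, "genotype_counts"),
            inherits(tumor, "genotype_counts"),
            attr(blood, "total") > 0, attr(tumor, "total") > 0)
  cells <- c(a = tumor[["n55"]],
             b = blood[["n55"]],
             c = attr(tumor, "total") - tumor[["n55"]],
             d = attr(blood, "total") - blood[["n55"]])
  .woolfOR(cells, "HOM55_VS_REST", ci_level)
}
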