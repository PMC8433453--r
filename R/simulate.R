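#' Simulate a case-control genotype cohort
#'
#' Controls are drawn from Hardy-Weinberg genotype probabilities
#' \eqn{(p^2, 2pq, q^2)} at the given 5-repeat allele frequency q. Case
#' genotype probabilities are the control probabilities reweighted by the
#' per-genotype disease odds ratios \eqn{(1, OR_{het}, OR_{hom})} and
#' renormalized (the rare-disease genotype-OR model), so the planted ORs are
#' directly recoverable by [contrastOR()] on large cohorts.
#'
#' @param n_cases,n_controls Cohort sizes.
#' @param allele5_freq 5-repeat allele frequency in controls (strictly
#'   inside (0, 1)).
#' @param or_het,or_hom Disease odds ratios of the `4/5` and `5/5`
#'   genotypes relative to `4/4` (default 1: no association).
#' @param seed Integer seed; the generator is a pure function of its
#'   arguments and never touches global RNG state.
#' @return Data frame of cohort records (`sample_id`, `group` =
#'   `case`/`control`, `genotype`).
#' @export
simulateCohort <- function(n_cases, n_controls, allele5_freq,
                           or_het = 1, or_hom = 1, seed = NULL) {
  stopifnot(n_cases >= 0, n_controls >= 0,
            allele5_freq > 0, allele5_freq < 1,
            or_het > 0, or_hom > 0)
  q <- allele5_freq
  p_control <- c((1 - q)^2, 2 * (1 - q) * q, q^2)
  p_case <- p_control * c(1, or_het, or_hom)
  p_case <- p_case / sum(p_case)
  withSeed(seed, {
    g_case <- sample(genotypeLevels(), n_cases, replace = TRUE, prob = p_case)
    g_ctrl <- sample(genotypeLevels(), n_controls, replace = TRUE,
                     prob = p_control)
    data.frame(
      sample_id = c(sprintf("case_%05d", seq_len(n_cases)),
                    sprintf("ctrl_%05d", seq_len(n_controls))),
      group = rep(c("case", "control"), c(n_cases, n_controls)),
      genotype = parseGenotype(c(g_case, g_ctrl)),
      stringsAsFactors = FALSE)
  })
}

#' Simulate matched tumor genotypes under an LOH process
#'
#' Each blood heterozygote undergoes loss of heterozygosity with probability
#' `loh_rate`; given an LOH event the tumor becomes `5/5` with probability
#' `retention5_bias` (retaining the 5-repeat allele) and `4/4` otherwise.
#' Blood homozygotes are carried over unchanged.
#'
#' @param blood Data frame of cohort records (`sample_id`, `genotype`), e.g.
#'   from [simulateCohort()].
#' @param loh_rate Probability in \[0, 1\] that a heterozygote loses an
#'   allele in the tumor.
#' @param retention5_bias Probability in \[0, 1\] that an LOH event retains
#'   the 5-repeat allele.
#' @param seed Integer seed (see [simulateCohort()]).
#' @return Data frame of matched pairs (`patient_id`, `blood`, `tumor`).
#' @export
simulateMatchedTumors <- function(blood, loh_rate, retention5_bias,
                                  seed = NULL) {
  stopifnot(loh_rate >= 0, loh_rate <= 1,
            retention5_bias >= 0, retention5_bias <= 1)
  g <- parseGenotype(blood$genotype)
  withSeed(seed, {
    tumor <- as.character(g)
    het <- which(g == "4/5")
    if (length(het)) {
      loh <- het[stats::runif(length(het)) < loh_rate]
      if (length(loh)) {
        retain5 <- stats::runif(length(loh)) < retention5_bias
        tumor[loh] <- ifelse(retain5, "5/5", "4/4")
      }
    }
    data.frame(patient_id = blood$sample_id,
               blood = g,
               tumor = parseGenotype(tumor),
               stringsAsFactors = FALSE)
  })
}

# Invert the bivariate-normal Spearman/Pearson identity
# rho_s = (6/pi) asin(a/2): the Pearson loading that yields the target
# Spearman correlation under Gaussianity.
.pearsonFromSpearman <- function(rho_s) 2 * sin(pi * rho_s / 6)

#' Simulate a grouped expression matrix with planted anchor correlations
#'
#' Latent-factor construction per sample group: the anchor gene is a
#' standard-normal latent factor L and every other gene i is
#' \eqn{a_i L + \sqrt{1 - a_i^2}\, \epsilon_i} with independent Gaussian
#' noise, so its population Pearson correlation with the anchor is exactly
#' \eqn{a_i}. The loading is chosen by inverting the bivariate-normal
#' identity \eqn{\rho_s = (6/\pi) \arcsin(a/2)} so that the population
#' Spearman correlation hits the requested target (exact under Gaussianity).
#'
#' @param anchor_corr Named list: one numeric vector of target Spearman
#'   correlations per group (all |target| < 1, strictly attainable). All
#'   vectors must have the same length (the number of non-anchor genes) and
#'   gene order.
#' @param n_samples Named integer vector of samples per group (names must
#'   match `anchor_corr`).
#' @param anchor Name to give the anchor gene row (default `"ANCHOR"`).
#' @param gene_names Optional symbols for the non-anchor genes (default
#'   `G0001`, `G0002`, ...).
#' @param seed Integer seed (see [simulateCohort()]).
#' @return A `SummarizedExperiment` with assay `exprs` (anchor first row)
#'   and a `group` column in `colData`.
#' @export
simulateExpression <- function(anchor_corr, n_samples, anchor = "ANCHOR",
                               gene_names = NULL, seed = NULL) {
  stopifnot(is.list(anchor_corr), length(anchor_corr) >= 1,
            all(names(anchor_corr) %in% names(n_samples)))
  n_genes <- unique(vapply(anchor_corr, length, integer(1)))
  if (length(n_genes) != 1) {
    stop("all groups must target the same number of genes")
  }
  if (any(vapply(anchor_corr, function(r) any(abs(r) >= 1), logical(1)))) {
    stop("target Spearman correlations must satisfy |rho| < 1")
  }
  if (is.null(gene_names)) gene_names <- sprintf("G%04d", seq_len(n_genes))
  stopifnot(length(gene_names) == n_genes)
  withSeed(seed, {
    blocks <- lapply(names(anchor_corr), function(grp) {
      n <- n_samples[[grp]]
      a <- .pearsonFromSpearman(anchor_corr[[grp]])
      L <- rnorm(n)
      noise <- matrix(rnorm(n_genes * n), nrow = n_genes)
      genes <- a * matrix(L, nrow = n_genes, ncol = n, byrow = TRUE) +
        sqrt(1 - a^2) * noise
      rbind(L, genes)
    })
    mat <- do.call(cbind, blocks)
    rownames(mat) <- c(anchor, gene_names)
    sizes <- vapply(names(anchor_corr), function(g) as.integer(n_samples[[g]]),
                    integer(1))
    groups <- rep(names(anchor_corr), sizes)
    colnames(mat) <- sprintf("%s_s%04d", groups,
                             unlist(lapply(sizes, seq_len)))
    SummarizedExperiment::SummarizedExperiment(
      assays = list(exprs = mat),
      colData = S4Vectors::DataFrame(group = groups,
                                     row.names = colnames(mat)))
  })
}

#' Simulate survival outcomes tied to an expression score
#'
#' Event times are exponential with per-sample rate
#' \eqn{\lambda_i = \lambda_0 \exp(\beta \, score_i)} (a proportional-hazards
#' model with true log hazard ratio \eqn{\beta} per unit of score);
#' independent exponential censoring at rate `censor_rate` (0 disables
#' censoring).
#'
#' @param scores Named numeric vector: one score per sample (finite).
#' @param true_log_hr_per_unit True log hazard ratio per unit score.
#' @param baseline_rate Baseline hazard rate (> 0), in 1/months.
#' @param censor_rate Censoring hazard rate (>= 0), in 1/months.
#' @param seed Integer seed (see [simulateCohort()]).
#' @return Data frame of survival records (`sample_id`, `time`, `event`,
#'   `score`).
#' @export
simulateSurvival <- function(scores, true_log_hr_per_unit, baseline_rate,
                             censor_rate = 0, seed = NULL) {
  stopifnot(all(is.finite(scores)), baseline_rate > 0, censor_rate >= 0)
  n <- length(scores)
  ids <- if (is.null(names(scores))) sprintf("s%05d", seq_len(n))
         else names(scores)
  withSeed(seed, {
    t_event <- rexp(n, rate = baseline_rate *
                      exp(true_log_hr_per_unit * scores))
    t_cens <- if (censor_rate > 0) rexp(n, rate = censor_rate) else
      rep(Inf, n)
    data.frame(sample_id = ids,
               time = pmin(t_event, t_cens),
               event = as.integer(t_event <= t_cens),
               score = unname(scores),
               stringsAsFactors = FALSE)
  })
}
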