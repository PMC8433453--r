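#' Fisher z-transform of a correlation coefficient
#'
#' \eqn{Z = 0.5 \log((1 + r)/(1 - r))} (natural logarithm), the variance
#' stabilizing transform that makes correlation differences approximately
#' normal.
#'
#' @param r Correlation(s) strictly inside (-1, 1).
#' @return Numeric vector of transformed values.
#' @export
fisherZ <- function(r) {
  if (any(!is.finite(r)) || any(abs(r) >= 1)) {
    stop("fisherZ requires -1 < r < 1 (the transform diverges at |r| = 1)")
  }
  0.5 * log((1 + r) / (1 - r))
}

#' Two-group differential correlation test
#'
#' Tests whether the anchor correlation of one gene differs between two
#' groups. Both correlations are Fisher z-transformed, their difference
#' \eqn{Z_{Diff} = Z_1 - Z_2} is standardized by
#' \eqn{Z_{DiffSD} = \sqrt{1/(N_1 - 3) + 1/(N_2 - 3)}}, and the ratio is
#' referred to the standard normal (two-sided).
#'
#' The \eqn{1/(N-3)} variance is the classical Pearson-based form; when the
#' input correlations are Spearman's, the asymptotic variance is inflated by
#' about 1.06, available via `spearman_var = TRUE` (default off).
#'
#' @param r1,r2 Correlations in the two groups (strictly inside (-1, 1)).
#' @param n1,n2 Sample counts used for each correlation (both > 3).
#' @param spearman_var Use the 1.06/(N-3) Spearman variance instead of
#'   1/(N-3).
#' @return List with `r1`, `r2`, `Z1`, `Z2`, `Z_Diff`, `Z_DiffSD`, `z_stat`
#'   and the two-sided `p`.
#' @examples
#' diffTest(0.5, 103, 0, 103)  # z about 3.88, p about 1e-4
#' @export
diffTest <- function(r1, n1, r2, n2, spearman_var = FALSE) {
  if (n1 <= 3 || n2 <= 3) stop("both groups need more than 3 samples")
  Z1 <- fisherZ(r1)
  Z2 <- fisherZ(r2)
  k <- if (spearman_var) 1.06 else 1
  Z_Diff <- Z1 - Z2
  Z_DiffSD <- sqrt(k / (n1 - 3) + k / (n2 - 3))
  z_stat <- Z_Diff / Z_DiffSD
  list(r1 = r1, r2 = r2, Z1 = Z1, Z2 = Z2,
       Z_Diff = Z_Diff, Z_DiffSD = Z_DiffSD, z_stat = z_stat,
       p = 2 * pnorm(abs(z_stat), lower.tail = FALSE))
}

#' Transcriptome-wide differential co-expression against an anchor gene
#'
#' Computes the anchor's Spearman correlation profile in each of two sample
#' groups ([anchorProfile()]), applies [diffTest()] gene by gene, and
#' controls the false discovery rate across all tested genes with
#' Benjamini-Hochberg. Genes constant in either group (undefined
#' correlation) are skipped, with the number skipped reported via a message.
#'
#' @inheritParams anchorProfile
#' @param group1,group2 Labels of the two sample groups to contrast (each
#'   needs more than 4 samples).
#' @param alpha FDR threshold for the `significant` flag (default 0.05).
#' @param spearman_var Passed to [diffTest()].
#' @return Data frame with one row per tested gene: `gene`, `r1`, `r2`,
#'   `Z1`, `Z2`, `Z_Diff`, `Z_DiffSD`, `z_stat`, `p`, `q`, `significant`
#'   and `direction` (`"group1"`/`"group2"`: which group has the higher
#'   correlation), sorted by `p`. The anchor itself is not tested.
#' @export
transcriptomeDiff <- function(x, anchor, group1, group2, alpha = 0.05,
                              sample_groups = NULL, spearman_var = FALSE) {
  p1 <- anchorProfile(x, anchor, group1, sample_groups)
  p2 <- anchorProfile(x, anchor, group2, sample_groups)
  if (p1$n <= 4 || p2$n <= 4) stop("both groups need more than 4 samples")
  genes <- setdiff(intersect(names(p1$rho), names(p2$rho)), anchor)
  r1 <- p1$rho[genes]
  r2 <- p2$rho[genes]
  usable <- !is.na(r1) & !is.na(r2) & abs(r1) < 1 & abs(r2) < 1
  if (any(!usable)) {
    message(sum(!usable), " gene(s) skipped (constant or degenerate ",
            "correlation in at least one group)")
  }
  genes <- genes[usable]
  r1 <- r1[usable]
  r2 <- r2[usable]
  k <- if (spearman_var) 1.06 else 1
  Z1 <- fisherZ(r1)
  Z2 <- fisherZ(r2)
  Z_DiffSD <- sqrt(k / (p1$n - 3) + k / (p2$n - 3))
  z_stat <- (Z1 - Z2) / Z_DiffSD
  p <- 2 * pnorm(abs(z_stat), lower.tail = FALSE)
  q <- p.adjust(p, method = "BH")
  out <- data.frame(gene = genes, r1 = unname(r1), r2 = unname(r2),
                    Z1 = unname(Z1), Z2 = unname(Z2),
                    Z_Diff = unname(Z1 - Z2), Z_DiffSD = Z_DiffSD,
                    z_stat = unname(z_stat), p = unname(p), q = unname(q),
                    significant = unname(q < alpha),
                    direction = ifelse(Z1 >= Z2, "group1", "group2"),
                    stringsAsFactors = FALSE)
  out[order(out$p, out$gene), , drop = FALSE]
}

#' Write the significant genes of a differential co-expression table
#'
#' Plain one-symbol-per-line list, the input format of external
#' over-representation tools.
#'
#' @param records Data frame from [transcriptomeDiff()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
writeSignificantGenes <- function(records, path) {
  writeLines(records$gene[records$significant], path)
  invisible(path)
}
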