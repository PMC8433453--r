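#' Per-study effect for one genotype contrast
#'
#' Builds the study-level summary used by the inverse-variance pooling
#' functions: the log odds ratio and its large-sample variance
#' \eqn{1/a + 1/b + 1/c + 1/d} on the contrast's 2x2 table.
#'
#' @inheritParams contrastOR
#' @param study_id Label carried through to the meta-analysis output.
#' @return Object of class `study_effect`: list with `study_id`, `log_or`,
#'   `variance`.
#' @seealso [studyEffects()] to build a whole table of studies at once.
#' @export
effectFromCounts <- function(cases, controls,
                             contrast = c("HOM", "HET", "COMBINED"),
                             study_id = "study") {
  contrast <- match.arg(contrast)
  or <- contrastOR(cases, controls, contrast)
  res <- list(study_id = study_id, log_or = or$log_or,
              variance = or$se_log_or^2)
  class(res) <- "study_effect"
  res
}

#' Study effects from a per-study genotype count table
#'
#' Converts a wide per-study count table (the schema of [studyCounts()]) into
#' a list of [effectFromCounts()] study effects for one contrast. Studies
#' missing the counts the contrast needs (e.g. a study reporting only the
#' combined carrier row, with `NA` heterozygote and homozygote cells) are
#' excluded from that contrast with a message.
#'
#' @param counts Data frame with columns `study`, `case_n44`, `case_n45`,
#'   `case_n55`, `case_n4555`, `control_n44`, `control_n45`, `control_n55`,
#'   `control_n4555`. The `*_n4555` columns allow a combined row to be used
#'   when the split is unavailable; when `NA` they are derived as n45 + n55.
#' @param contrast One of [contrastLevels()].
#' @return List of `study_effect` objects.
#' @export
studyEffects <- function(counts, contrast = c("HOM", "HET", "COMBINED")) {
  contrast <- match.arg(contrast)
  effects <- list()
  for (i in seq_len(nrow(counts))) {
    row <- counts[i, ]
    cells <- switch(contrast,
      HOM = c(row$case_n55, row$control_n55, row$case_n44, row$control_n44),
      HET = c(row$case_n45, row$control_n45, row$case_n44, row$control_n44),
      COMBINED = {
        ca <- if (!is.na(row$case_n4555)) row$case_n4555 else
          row$case_n45 + row$case_n55
        co <- if (!is.na(row$control_n4555)) row$control_n4555 else
          row$control_n45 + row$control_n55
        c(ca, co, row$case_n44, row$control_n44)
      })
    if (any(is.na(cells))) {
      message("study '", row$study, "' lacks the counts for the ", contrast,
              " contrast; excluded")
      next
    }
    log_or <- log(cells[1]) + log(cells[4]) - log(cells[2]) - log(cells[3])
    effects[[length(effects) + 1L]] <- structure(
      list(study_id = row$study, log_or = log_or,
           variance = sum(1 / cells)),
      class = "study_effect")
  }
  effects
}

# Shared pooling core. tau2 = 0 gives the fixed-effect model; Q/df/I2 are
# always computed from the fixed-effect (tau2-free) weights, as in standard
# inverse-variance meta-analysis.
.pool <- function(effects, ci_level, model, tau2) {
  y <- vapply(effects, function(e) e$log_or, numeric(1))
  v <- vapply(effects, function(e) e$variance, numeric(1))
  w_fixed <- 1 / v
  mu_fixed <- sum(w_fixed * y) / sum(w_fixed)
  Q <- sum(w_fixed * (y - mu_fixed)^2)
  df <- length(y) - 1L
  p_het <- if (df > 0) pchisq(Q, df = df, lower.tail = FALSE) else NA_real_
  I2 <- if (Q > 0) max(0, (Q - df) / Q) * 100 else 0
  w <- 1 / (v + tau2)
  mu <- sum(w * y) / sum(w)
  se <- 1 / sqrt(sum(w))
  z <- qnorm(1 - (1 - ci_level) / 2)
  res <- list(model = model,
              pooled_or = exp(mu),
              pooled_log_or = mu,
              se = se,
              ci_low = exp(mu - z * se),
              ci_high = exp(mu + z * se),
              ci_level = ci_level,
              k = length(y),
              Q = Q, df = df, p_het = p_het, I2 = I2, tau2 = tau2,
              weights = w / sum(w))
  class(res) <- "meta_result"
  res
}

#' Fixed-effect inverse-variance meta-analysis
#'
#' Pools study log odds ratios with weights \eqn{w_i = 1/v_i}; the pooled
#' log OR is \eqn{\sum w_i y_i / \sum w_i} with standard error
#' \eqn{(\sum w_i)^{-1/2}}. Heterogeneity is summarized by Cochran's
#' \eqn{Q = \sum w_i (y_i - \bar y)^2} on k - 1 df and
#' \eqn{I^2 = \max(0, (Q - df)/Q) \times 100}.
#'
#' @param effects Non-empty list of `study_effect` objects (see
#'   [effectFromCounts()], [studyEffects()]).
#' @param ci_level Confidence level (default 0.95).
#' @return Object of class `meta_result` with `pooled_or`, `ci_low`,
#'   `ci_high`, `Q`, `df`, `p_het`, `I2`, `tau2` (0 for the fixed model) and
#'   normalized `weights`.
#' @examples
#' eff <- studyEffects(studyCounts(), "HOM")
#' poolFixed(eff)  # pooled OR 1.17 (0.97-1.42)
#' @export
poolFixed <- function(effects, ci_level = 0.95) {
  if (length(effects) < 1) stop("need at least one study effect")
  .pool(effects, ci_level, model = "fixed", tau2 = 0)
}

#' Random-effects (DerSimonian-Laird) meta-analysis
#'
#' Method-of-moments between-study variance
#' \eqn{\hat\tau^2 = \max(0, (Q - df) / (\sum w_i - \sum w_i^2 / \sum w_i))}
#' with fixed-effect weights \eqn{w_i = 1/v_i}; pooling then proceeds as in
#' [poolFixed()] with weights \eqn{1/(v_i + \hat\tau^2)}. When Q <= df the
#' estimate collapses to zero and the result equals the fixed-effect one.
#'
#' @inheritParams poolFixed
#' @return A `meta_result` (see [poolFixed()]) with `model = "random"`.
#' @export
poolRandom <- function(effects, ci_level = 0.95) {
  if (length(effects) < 2) {
    stop("random-effects pooling needs at least two studies; use poolFixed()")
  }
  v <- vapply(effects, function(e) e$variance, numeric(1))
  y <- vapply(effects, function(e) e$log_or, numeric(1))
  w <- 1 / v
  mu <- sum(w * y) / sum(w)
  Q <- sum(w * (y - mu)^2)
  df <- length(y) - 1L
  tau2 <- max(0, (Q - df) / (sum(w) - sum(w^2) / sum(w)))
  .pool(effects, ci_level, model = "random", tau2 = tau2)
}

#' @export
print.meta_result <- function(x, ...) {
  cat(sprintf("%s-effects inverse-variance meta-analysis of %d studies\n",
              x$model, x$k))
  cat(sprintf("  pooled OR = %.2f (%d%% CI %.2f-%.2f)\n",
              x$pooled_or, round(100 * x$ci_level), x$ci_low, x$ci_high))
  cat(sprintf("  Q = %.2f (df = %d, p = %.2f), I2 = %.1f%%, tau2 = %.4f\n",
              x$Q, x$df, x$p_het, x$I2, x$tau2))
  invisible(x)
}

#' Forest-plot data for a set of study effects
#'
#' @param effects List of `study_effect` objects.
#' @param ci_level Confidence level for the per-study intervals.
#' @return Data frame with one row per study: `study`, `or`, `ci_low`,
#'   `ci_high`, `weight_pct` (fixed-effect inverse-variance weight, percent).
#' @export
forestData <- function(effects, ci_level = 0.95) {
  y <- vapply(effects, function(e) e$log_or, numeric(1))
  v <- vapply(effects, function(e) e$variance, numeric(1))
  w <- 1 / v
  z <- qnorm(1 - (1 - ci_level) / 2)
  data.frame(study = vapply(effects, function(e) e$study_id, character(1)),
             or = exp(y),
             ci_low = exp(y - z * sqrt(v)),
             ci_high = exp(y + z * sqrt(v)),
             weight_pct = 100 * w / sum(w),
             stringsAsFactors = FALSE)
}
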