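#' Tertile trichotomization of an expression score
#'
#' Ranks survival records by their expression score and keeps the top third
#' (`high`) and bottom third (`low`), discarding the middle; the two retained
#' groups have floor(n/3) members each, so they are always equal-sized, with
#' the remainder assigned to the excluded middle. Ties are broken by stable
#' `sample_id` order; a tie straddling a tertile boundary triggers a warning.
#'
#' @param records Data frame with columns `sample_id`, `time`, `event`,
#'   `score` (at least 6 rows, scores not all equal).
#' @return List with data frames `high` and `low`.
#' @export
tertileSplit <- function(records) {
  n <- nrow(records)
  if (n < 6) stop("need at least 6 records to form tertiles")
  if (length(unique(records$score)) == 1L) {
    stop("all scores identical; tertiles are undefined")
  }
  ord <- order(records$score, records$sample_id, method = "radix")
  sorted <- records[ord, , drop = FALSE]
  size <- n %/% 3L
  s <- sorted$score
  if (s[size] == s[size + 1L] || s[n - size] == s[n - size + 1L]) {
    warning("tied scores straddle a tertile boundary; ",
            "ties broken by sample_id order")
  }
  list(high = sorted[(n - size + 1L):n, , drop = FALSE],
       low = sorted[seq_len(size), , drop = FALSE])
}

#' Two-group logrank test with O/E hazard ratio
#'
#' Standard 1-df logrank comparison of the high- versus low-score groups
#' (via [survival::survdiff()]), reporting the observed/expected hazard
#' ratio HR = (O_high/E_high) / (O_low/E_low) with confidence interval
#' \eqn{\exp(\log HR \pm z \sqrt{1/E_{high} + 1/E_{low}})}. By this
#' convention HR < 1 means the high-expression group relapses less (high
#' expression is protective). If one group has no events the HR is undefined
#' (`NA`, with a warning) but the test p-value is still reported.
#'
#' @param high,low Data frames with columns `time` and `event`.
#' @param ci_level Confidence level (default 0.95).
#' @return Object of class `logrank_result`: list with `chi2`, `p`,
#'   `hazard_ratio`, `ci_low`, `ci_high`, `n_high`, `n_low`, `obs`, `exp`.
#' @export
logrankTest <- function(high, low, ci_level = 0.95) {
  time <- c(high$time, low$time)
  event <- c(high$event, low$event)
  grp <- factor(rep(c("high", "low"), c(nrow(high), nrow(low))),
                levels = c("high", "low"))
  if (sum(event) == 0) stop("no events in either group")
  sd <- survival::survdiff(survival::Surv(time, event) ~ grp)
  # survdiff orders groups by factor level: 1 = high, 2 = low
  O <- sd$obs
  E <- sd$exp
  chi2 <- sd$chisq
  p <- pchisq(chi2, df = 1, lower.tail = FALSE)
  if (any(O == 0)) {
    warning("a group has zero events; hazard ratio undefined")
    hr <- ci_lo <- ci_hi <- NA_real_
  } else {
    log_hr <- log(O[1] / E[1]) - log(O[2] / E[2])
    se <- sqrt(1 / E[1] + 1 / E[2])
    z <- qnorm(1 - (1 - ci_level) / 2)
    hr <- exp(log_hr)
    ci_lo <- exp(log_hr - z * se)
    ci_hi <- exp(log_hr + z * se)
  }
  res <- list(chi2 = chi2, p = p, hazard_ratio = unname(hr),
              ci_low = unname(ci_lo), ci_high = unname(ci_hi),
              n_high = nrow(high), n_low = nrow(low),
              obs = unname(O), exp = unname(E), ci_level = ci_level)
  class(res) <- "logrank_result"
  res
}

#' @export
print.logrank_result <- function(x, ...) {
  cat(sprintf("Logrank test (high n = %d vs low n = %d): chi2 = %.3f, p = %.3g\n",
              x$n_high, x$n_low, x$chi2, x$p))
  if (is.na(x$hazard_ratio)) {
    cat("  hazard ratio undefined (a group has zero events)\n")
  } else {
    cat(sprintf("  HR (high vs low) = %.2f (%d%% CI %.2f-%.2f)\n",
                x$hazard_ratio, round(100 * x$ci_level), x$ci_low, x$ci_high))
  }
  invisible(x)
}

#' Average expression signature
#'
#' Per-sample unweighted mean of the listed genes' expression values, the
#' score used to summarize a set of survival-associated co-expression
#' partners. Listed genes absent from the matrix are skipped with a message.
#'
#' @inheritParams anchorProfile
#' @param genes Character vector of gene symbols (at least one present).
#' @return Named numeric vector: one score per sample.
#' @export
averageSignature <- function(x, genes, sample_groups = NULL) {
  mat <- .expressionParts(x, sample_groups)$mat
  present <- intersect(genes, rownames(mat))
  if (length(present) == 0) {
    stop("none of the listed genes are present in the expression matrix")
  }
  missing <- setdiff(genes, present)
  if (length(missing)) {
    message(length(missing), " listed gene(s) absent from the matrix, skipped: ",
            paste(utils::head(missing, 5), collapse = ", "),
            if (length(missing) > 5) ", ..." else "")
  }
  colMeans(mat[present, , drop = FALSE])
}

#' Per-gene tertile relapse-free-survival screen
#'
#' For each gene, joins its expression values to the survival table,
#' trichotomizes ([tertileSplit()]) and runs the top-versus-bottom-tertile
#' logrank test ([logrankTest()]). Genes significant at `alpha` are the
#' usual input to [averageSignature()].
#'
#' @inheritParams anchorProfile
#' @param survival_table Data frame with columns `sample_id`, `time`,
#'   `event` (see [readSurvivalTable()]).
#' @param genes Gene symbols to screen; defaults to every row of `x`.
#' @param alpha Significance level for the `significant` flag (default 0.05).
#' @param ci_level Confidence level for the HR intervals.
#' @return Data frame with one row per screened gene: `gene`, `n_high`,
#'   `n_low`, `hazard_ratio`, `ci_low`, `ci_high`, `chi2`, `p`,
#'   `significant`.
#' @export
rfsScreen <- function(x, survival_table, genes = NULL, alpha = 0.05,
                      ci_level = 0.95, sample_groups = NULL) {
  mat <- .expressionParts(x, sample_groups)$mat
  if (is.null(genes)) genes <- rownames(mat)
  genes <- intersect(genes, rownames(mat))
  if (length(genes) == 0) stop("no screened gene is present in the matrix")
  ids <- intersect(colnames(mat), survival_table$sample_id)
  if (length(ids) < 6) {
    stop("fewer than 6 samples shared between expression matrix and survival table")
  }
  surv <- survival_table[match(ids, survival_table$sample_id), , drop = FALSE]
  rows <- lapply(genes, function(g) {
    rec <- data.frame(sample_id = ids, time = surv$time, event = surv$event,
                      score = mat[g, ids], stringsAsFactors = FALSE)
    lr <- tryCatch({
      split <- tertileSplit(rec)
      logrankTest(split$high, split$low, ci_level)
    }, error = function(e) NULL)
    if (is.null(lr)) {
      return(data.frame(gene = g, n_high = NA_integer_, n_low = NA_integer_,
                        hazard_ratio = NA_real_, ci_low = NA_real_,
                        ci_high = NA_real_, chi2 = NA_real_, p = NA_real_,
                        significant = NA, stringsAsFactors = FALSE))
    }
    data.frame(gene = g, n_high = lr$n_high, n_low = lr$n_low,
               hazard_ratio = lr$hazard_ratio, ci_low = lr$ci_low,
               ci_high = lr$ci_high, chi2 = lr$chi2, p = lr$p,
               significant = lr$p < alpha, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Kaplan-Meier step-function coordinates for the two tertile groups
#'
#' @param high,low Data frames with columns `time` and `event`.
#' @return Data frame with columns `group`, `time`, `surv`, `n_risk`,
#'   `n_event`, suitable for step plotting.
#' @export
kmCurves <- function(high, low) {
  one <- function(df, label) {
    fit <- survival::survfit(survival::Surv(df$time, df$event) ~ 1)
    data.frame(group = label, time = fit$time, surv = fit$surv,
               n_risk = fit$n.risk, n_event = fit$n.event,
               stringsAsFactors = FALSE)
  }
  rbind(one(high, "high"), one(low, "low"))
}
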