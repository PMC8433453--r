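#' Anchor-gene Spearman correlation profile
#'
#' Computes the Spearman rank correlation (average ranks for ties) between
#' one anchor gene and every other gene of an expression matrix, over the
#' samples of one group. Samples with a missing value in either gene of a
#' pair are dropped pairwise; genes constant across the used samples have an
#' undefined correlation and are recorded as `NA` with a warning.
#'
#' @param x A `SummarizedExperiment` (assay 1, `group` column in `colData`)
#'   or a numeric genes-by-samples matrix.
#' @param anchor Anchor gene symbol; must be a row of `x`.
#' @param group Optional group label restricting the samples used; `NULL`
#'   uses all samples.
#' @param sample_groups Optional named vector mapping sample id to group, for
#'   plain-matrix input.
#' @return Object of class `correlation_profile`: list with `anchor`, `rho`
#'   (named vector over all genes, `rho[anchor] == 1`) and `n` (samples
#'   used).
#' @export
anchorProfile <- function(x, anchor, group = NULL, sample_groups = NULL) {
  parts <- .expressionParts(x, sample_groups)
  mat <- parts$mat
  if (!anchor %in% rownames(mat)) {
    stop("anchor gene '", anchor, "' not present in the expression matrix")
  }
  if (!is.null(group)) {
    sel <- !is.na(parts$groups) & parts$groups == group
    if (!any(sel)) stop("no samples in group '", group, "'")
    mat <- mat[, sel, drop = FALSE]
  }
  if (ncol(mat) < 4) stop("need at least 4 samples to compute correlations")
  rho <- suppressWarnings(
    cor(t(mat), mat[anchor, ], method = "spearman",
        use = "pairwise.complete.obs")[, 1L])
  nconst <- sum(is.na(rho))
  if (nconst > 0) {
    warning(nconst, " gene(s) constant (or all-missing) in the selected ",
            "samples; correlation recorded as NA")
  }
  res <- list(anchor = anchor, rho = rho, n = ncol(mat))
  class(res) <- "correlation_profile"
  res
}

#' @export
print.correlation_profile <- function(x, ...) {
  cat(sprintf("Spearman correlation profile of anchor '%s' over %d genes (n = %d samples)\n",
              x$anchor, length(x$rho), x$n))
  invisible(x)
}

#' Cross-dataset robust co-expression partners
#'
#' Genes whose absolute correlation with the anchor exceeds `threshold`
#' (strictly) in both profiles. Symbols are matched case-insensitively by
#' default, a pragmatic stand-in for orthology mapping when the two datasets
#' come from different species; a two-column ortholog table overrides it.
#' The anchor itself is never reported.
#'
#' @param profile_a,profile_b `correlation_profile` objects (see
#'   [anchorProfile()]); order is immaterial.
#' @param threshold Absolute-correlation cutoff (default 0.4).
#' @param orthologs Optional data frame whose first column holds symbols of
#'   dataset A and second column the matching symbols of dataset B.
#' @return Character vector of partner symbols (uppercased symbols of
#'   dataset A's namespace), sorted.
#' @export
robustPartners <- function(profile_a, profile_b, threshold = 0.4,
                           orthologs = NULL) {
  stopifnot(inherits(profile_a, "correlation_profile"),
            inherits(profile_b, "correlation_profile"))
  ra <- profile_a$rho
  rb <- profile_b$rho
  names(ra) <- toupper(names(ra))
  names(rb) <- toupper(names(rb))
  if (!is.null(orthologs)) {
    map <- setNames(toupper(as.character(orthologs[[2L]])),
                    toupper(as.character(orthologs[[1L]])))
    hit <- names(ra) %in% names(map)
    names(ra)[hit] <- map[names(ra)[hit]]
  }
  common <- intersect(names(ra), names(rb))
  if (length(common) == 0) stop("no gene symbols shared between the profiles")
  common <- setdiff(common, toupper(c(profile_a$anchor, profile_b$anchor)))
  keep <- !is.na(ra[common]) & !is.na(rb[common]) &
    abs(ra[common]) > threshold & abs(rb[common]) > threshold
  sort(common[keep])
}

#' Hypergeometric gene-set over-representation test
#'
#' Upper-tail hypergeometric probability of observing at least the overlap
#' between a hit list and an annotation set, drawn from a finite gene
#' universe: P(X >= k) with |hits| draws from a universe containing
#' |annotation in universe| successes.
#'
#' @param hits Character vector of hit genes (must lie within `universe`).
#' @param annotation Character vector of annotated genes.
#' @param universe Character vector of all testable genes (non-empty).
#' @return List with `overlap` and `p`.
#' @export
hypergeometricEnrichment <- function(hits, annotation, universe) {
  universe <- unique(universe)
  if (length(universe) == 0) stop("empty gene universe")
  hits <- unique(hits)
  if (!all(hits %in% universe)) stop("hits must be a subset of the universe")
  ann <- intersect(unique(annotation), universe)
  if (length(ann) == 0) stop("annotation set does not intersect the universe")
  k <- length(intersect(hits, ann))
  p <- phyper(k - 1, m = length(ann), n = length(universe) - length(ann),
              k = length(hits), lower.tail = FALSE)
  list(overlap = k, p = p)
}

#' Export a ranked gene list for external enrichment tools
#'
#' Writes the two-column `.rnk` format (gene, score) consumed by preranked
#' gene-set enrichment tools, sorted by correlation descending with ties
#' broken alphabetically by gene symbol. Genes with `NA` correlation are
#' omitted.
#'
#' @param profile A `correlation_profile` (see [anchorProfile()]).
#' @param path Output path.
#' @param include_anchor Keep the anchor's self-correlation row (default
#'   `FALSE`).
#' @return `path`, invisibly.
#' @export
exportRankedList <- function(profile, path, include_anchor = FALSE) {
  stopifnot(inherits(profile, "correlation_profile"))
  rho <- profile$rho[!is.na(profile$rho)]
  if (!include_anchor) rho <- rho[names(rho) != profile$anchor]
  if (length(rho) == 0) stop("empty correlation profile")
  ord <- order(-rho, names(rho), method = "radix")
  out <- data.frame(gene = names(rho)[ord], score = unname(rho[ord]))
  write.table(out, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a two-column ranked gene list
#'
#' @param path A `.rnk` file as written by [exportRankedList()].
#' @return Data frame with columns `gene` and `score`, in file order.
#' @export
readRankedList <- function(path) {
  df <- read.table(path, header = FALSE, sep = "\t",
                   stringsAsFactors = FALSE,
                   col.names = c("gene", "score"))
  df
}
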