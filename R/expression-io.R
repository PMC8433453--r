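#' Read a gene-by-sample expression matrix
#'
#' Reads a delimited matrix of (log-scale) expression values whose first
#' column holds gene symbols and whose header holds sample ids, together with
#' an optional sample-group annotation, into a
#' [SummarizedExperiment::SummarizedExperiment] with assay `exprs` and a
#' `group` column in `colData`. Duplicate gene symbols are an error: probes
#' must be collapsed to one row per gene upstream.
#'
#' @param path Delimited expression file (tab or comma; sniffed).
#' @param groups Either `NULL`, a named character vector mapping sample id to
#'   group label, or the path to a two-column delimited file with header
#'   columns `sample_id` and `group`.
#' @return A `SummarizedExperiment`.
#' @export
readExpressionMatrix <- function(path, groups = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  sep <- .sniffSep(path)
  df <- read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                   stringsAsFactors = FALSE, quote = "\"", comment.char = "")
  genes <- as.character(df[[1L]])
  if (anyDuplicated(genes)) {
    stop("duplicate gene symbols in ", path,
         "; collapse probes to one row per gene before import")
  }
  mat <- as.matrix(df[, -1L, drop = FALSE])
  storage.mode(mat) <- "double"
  rownames(mat) <- genes
  if (is.character(groups) && length(groups) == 1L && file.exists(groups)) {
    gdf <- .readDelim(groups, c("sample_id", "group"))
    groups <- setNames(as.character(gdf$group), as.character(gdf$sample_id))
  }
  grp <- if (is.null(groups)) rep(NA_character_, ncol(mat)) else {
    missing <- setdiff(colnames(mat), names(groups))
    if (length(missing)) {
      stop("samples without a group label: ", paste(missing, collapse = ", "))
    }
    unname(groups[colnames(mat)])
  }
  SummarizedExperiment::SummarizedExperiment(
    assays = list(exprs = mat),
    colData = S4Vectors::DataFrame(group = grp, row.names = colnames(mat)))
}

#' Write an expression matrix with its group annotation
#'
#' @param se A `SummarizedExperiment` (or plain matrix).
#' @param path Output path for the tab-separated matrix (first column `gene`).
#' @param groups_path Optional path for a `sample_id`/`group` annotation table.
#' @return `path`, invisibly.
#' @export
writeExpressionMatrix <- function(se, path, groups_path = NULL) {
  parts <- .expressionParts(se)
  out <- data.frame(gene = rownames(parts$mat), parts$mat,
                    check.names = FALSE, stringsAsFactors = FALSE)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(groups_path)) {
    write.table(data.frame(sample_id = colnames(parts$mat),
                           group = parts$groups),
                groups_path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

# Accept a SummarizedExperiment (assay 1 + colData$group) or a plain numeric
# matrix (optionally with a sample_groups argument handled by callers).
.expressionParts <- function(x, sample_groups = NULL) {
  if (methods::is(x, "SummarizedExperiment")) {
    mat <- SummarizedExperiment::assay(x, 1L)
    cd <- SummarizedExperiment::colData(x)
    groups <- if ("group" %in% colnames(cd)) as.character(cd$group)
              else rep(NA_character_, ncol(mat))
  } else if (is.matrix(x)) {
    mat <- x
    groups <- if (is.null(sample_groups)) rep(NA_character_, ncol(mat))
              else unname(sample_groups[colnames(mat)])
  } else {
    stop("expected a SummarizedExperiment or a numeric matrix")
  }
  list(mat = mat, groups = groups)
}

#' Read gene sets from a GMT file
#'
#' Standard tab-separated GMT: one set per line, fields name, description,
#' then member genes.
#'
#' @param path GMT file path.
#' @return Named list of character vectors of gene symbols.
#' @export
readGmt <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  sets <- lapply(strsplit(lines, "\t", fixed = TRUE), function(f) {
    if (length(f) < 3L) stop("malformed GMT line: ", f[1L])
    unique(f[-(1:2)])
  })
  names(sets) <- vapply(strsplit(lines, "\t", fixed = TRUE), `[[`, "", 1L)
  sets
}
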