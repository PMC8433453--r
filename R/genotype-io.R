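#' Genotype levels of the biallelic VNTR locus
#'
#' The three genotypes formed by the 4- and 5-repeat alleles, in the canonical
#' order used by all count tables in the package.
#'
#' @return Character vector `c("4/4", "4/5", "5/5")`.
#' @export
genotypeLevels <- function() c("4/4", "4/5", "5/5")

#' Parse genotype strings
#'
#' Normalizes raw genotype strings to the three canonical levels. The
#' heterozygote may be written either way round (`"4/5"` or `"5/4"`);
#' surrounding whitespace is ignored. Any other value is an error.
#'
#' @param x Character vector of raw genotype strings.
#' @return Factor with levels [genotypeLevels()].
#' @examples
#' parseGenotype(c("4/4", "5/4", "5/5"))
#' @export
parseGenotype <- function(x) {
  x <- trimws(as.character(x))
  x[x == "5/4"] <- "4/5"
  bad <- !(x %in% genotypeLevels())
  if (any(bad)) {
    stop("unknown genotype value(s): ",
         paste(unique(x[bad]), collapse = ", "),
         " (expected 4/4, 4/5 or 5/5)")
  }
  factor(x, levels = genotypeLevels())
}

# Sniff the field separator of a delimited text file: tab wins if present on
# the first line, otherwise comma.
.sniffSep <- function(path) {
  first <- readLines(path, n = 1L)
  if (grepl("\t", first, fixed = TRUE)) "\t" else ","
}

.readDelim <- function(path, required) {
  if (!file.exists(path)) stop("file not found: ", path)
  sep <- .sniffSep(path)
  df <- read.table(path, header = TRUE, sep = sep, stringsAsFactors = FALSE,
                   check.names = FALSE, quote = "\"", comment.char = "")
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    stop("file ", path, " is missing required column(s): ",
         paste(missing, collapse = ", "))
  }
  df
}

#' Read a per-individual genotype table
#'
#' Reads a tab- or comma-separated table with a mandatory header declaring at
#' least the columns `sample_id`, `group` and `genotype`. Genotypes are
#' normalized via [parseGenotype()]; a malformed genotype is reported with the
#' offending line number.
#'
#' @param path Path to the delimited file.
#' @return A `data.frame` with columns `sample_id` (character), `group`
#'   (character: typically `case`, `control`, `tumor` or `cellline`) and
#'   `genotype` (factor with levels [genotypeLevels()]).
#' @seealso [writeGenotypeTable()], [countsFromRecords()]
#' @export
readGenotypeTable <- function(path) {
  df <- .readDelim(path, c("sample_id", "group", "genotype"))
  geno <- tryCatch(parseGenotype(df$genotype), error = function(e) e)
  if (inherits(geno, "error")) {
    raw <- trimws(as.character(df$genotype))
    raw[raw == "5/4"] <- "4/5"
    bad <- which(!(raw %in% genotypeLevels()))[1L]
    # +1 for the header line
    stop("line ", bad + 1L, " of ", path, ": ", conditionMessage(geno))
  }
  ids <- as.character(df$sample_id)
  if (anyDuplicated(ids)) {
    stop("duplicate sample_id in ", path, ": ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  data.frame(sample_id = ids, group = as.character(df$group),
             genotype = geno, stringsAsFactors = FALSE)
}

#' Write a per-individual genotype table
#'
#' Inverse of [readGenotypeTable()]; always writes tab-separated with a header.
#'
#' @param records Data frame with columns `sample_id`, `group`, `genotype`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
writeGenotypeTable <- function(records, path) {
  out <- data.frame(sample_id = records$sample_id,
                    group = records$group,
                    genotype = as.character(records$genotype))
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a matched blood-tumor genotype pair table
#'
#' @param path Delimited file with header columns `patient_id`, `blood`,
#'   `tumor`; genotype columns are normalized via [parseGenotype()].
#' @return Data frame with `patient_id` (character) and `blood`, `tumor`
#'   (genotype factors).
#' @seealso [classifyTransitions()]
#' @export
readMatchedPairs <- function(path) {
  df <- .readDelim(path, c("patient_id", "blood", "tumor"))
  ids <- as.character(df$patient_id)
  if (anyDuplicated(ids)) {
    stop("duplicate patient_id in ", path, ": ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  data.frame(patient_id = ids,
             blood = parseGenotype(df$blood),
             tumor = parseGenotype(df$tumor),
             stringsAsFactors = FALSE)
}

#' Read a survival table
#'
#' @param path Delimited file with header columns `sample_id`, `time`
#'   (non-negative, months), `event` (1 = relapse, 0 = censored) and
#'   optionally `score` (expression value or signature average).
#' @return Data frame with those columns.
#' @export
readSurvivalTable <- function(path) {
  df <- .readDelim(path, c("sample_id", "time", "event"))
  time <- as.numeric(df$time)
  event <- as.integer(df$event)
  if (any(is.na(time)) || any(time < 0)) stop("time must be non-negative")
  if (!all(event %in% c(0L, 1L))) stop("event must be 0 or 1")
  out <- data.frame(sample_id = as.character(df$sample_id),
                    time = time, event = event, stringsAsFactors = FALSE)
  if ("score" %in% names(df)) out$score <- as.numeric(df$score)
  out
}

#' Genotype count table
#'
#' Constructs the count table of the three genotypes for one group of
#' individuals, the elementary unit of the association and meta-analysis
#' functions.
#'
#' @param n44,n45,n55 Non-negative integer counts of the `4/4`, `4/5` and
#'   `5/5` genotypes.
#' @return An object of class `genotype_counts`: a named numeric vector with
#'   elements `n44`, `n45`, `n55` and attribute `total`.
#' @examples
#' genotypeCounts(761, 666, 148)   # Oslo cohort cases
#' @export
genotypeCounts <- function(n44, n45, n55) {
  n <- c(n44 = as.numeric(n44), n45 = as.numeric(n45), n55 = as.numeric(n55))
  if (any(is.na(n)) || any(n < 0)) stop("genotype counts must be non-negative")
  structure(n, total = sum(n), class = "genotype_counts")
}

#' @export
print.genotype_counts <- function(x, ...) {
  cat("Genotype counts (4/4, 4/5, 5/5):",
      paste(unclass(x), collapse = ", "),
      sprintf(" [total %d]\n", as.integer(attr(x, "total"))))
  invisible(x)
}

#' Tally genotype counts for one group
#'
#' @param records Data frame as returned by [readGenotypeTable()] (or
#'   [simulateCohort()]).
#' @param group Group label to tally; records in other groups are ignored.
#' @return A [genotypeCounts()] object. An empty group yields a table of
#'   zeros with a warning.
#' @export
countsFromRecords <- function(records, group) {
  sel <- records$group == group
  if (!any(sel)) warning("no records in group '", group, "'; returning zeros")
  tab <- table(factor(records$genotype[sel], levels = genotypeLevels()))
  genotypeCounts(tab[["4/4"]], tab[["4/5"]], tab[["5/5"]])
}

#' Path to a packaged example data file
#'
#' @param file File name under the package's `extdata` directory; with no
#'   argument, lists the available files.
#' @return Full file path (or a character vector of file names).
#' @export
vntrExample <- function(file = NULL) {
  dir <- system.file("extdata", package = "vntrtools")
  if (is.null(file)) return(list.files(dir))
  path <- file.path(dir, file)
  if (!file.exists(path)) stop("no packaged example file '", file, "'")
  path
}

#' Per-study genotype counts of the breast-cancer VNTR meta-analysis
#'
#' Returns the packaged per-study case/control genotype count table for the
#' five published case-control studies of the 4/5-repeat VNTR and breast
#' cancer (two primary cohorts plus three literature studies). One study
#' reports only the reference and combined-carrier rows; its heterozygote and
#' 5/5-homozygote cells are `NA` and the study is automatically excluded from
#' contrasts that need them.
#'
#' @return Data frame with one row per study and columns `study`,
#'   `case_n44`, `case_n45`, `case_n55`, `case_n4555`, `control_n44`,
#'   `control_n45`, `control_n55`, `control_n4555`.
#' @seealso [studyEffects()], [poolFixed()]
#' @export
studyCounts <- function() {
  df <- read.table(vntrExample("study_genotype_counts.tsv"), header = TRUE,
                   sep = "\t", stringsAsFactors = FALSE)
  df
}
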