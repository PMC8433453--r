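make_se <- function(mat, groups = NULL) {
  if (is.null(groups)) groups <- rep(NA_character_, ncol(mat))
  SummarizedExperiment::SummarizedExperiment(
    assays = list(exprs = mat),
    colData = S4Vectors::DataFrame(group = groups,
                                   row.names = colnames(mat)))
}

test_that("anchor profile gives exact Spearman correlations on toy data", {
  mat <- rbind(A = c(1, 2, 3, 4, 5),
               same = c(10, 20, 30, 40, 50),
               rev = c(5, 4, 3, 2, 1),
               tied = c(1, 2, 3, 5, 4))
  colnames(mat) <- paste0("s", 1:5)
  pr <- anchorProfile(mat, "A")
  expect_equal(unname(pr$rho["A"]), 1)
  expect_equal(unname(pr$rho["same"]), 1)
  expect_equal(unname(pr$rho["rev"]), -1)
  expect_equal(unname(pr$rho["tied"]), 0.9)  # sum d^2 = 2
  expect_equal(pr$n, 5L)

  expect_error(anchorProfile(mat, "missing"), "not present")
  mat2 <- rbind(mat, flat = rep(1, 5))
  expect_warning(pr2 <- anchorProfile(mat2, "A"), "constant")
  expect_true(is.na(pr2$rho["flat"]))
})

test_that("anchor profile is invariant under monotone transforms and respects groups", {
  set.seed(12)
  mat <- matrix(rnorm(50 * 30), 50,
                dimnames = list(paste0("g", 1:50), paste0("s", 1:30)))
  mat["g1", ] <- abs(mat["g1", ]) + 0.1
  pr <- anchorProfile(mat, "g1")
  warped <- mat
  warped["g2", ] <- exp(mat["g2", ])           # strictly increasing
  warped["g1", ] <- log(mat["g1", ])
  expect_equal(anchorProfile(warped, "g1")$rho, pr$rho)

  groups <- rep(c("x", "y"), each = 15)
  se <- make_se(mat, groups)
  prx <- anchorProfile(se, "g1", "x")
  expect_equal(prx$n, 15L)
  expect_equal(prx$rho,
               anchorProfile(mat[, 1:15], "g1")$rho)
  expect_error(anchorProfile(se, "g1", "zz"), "no samples")
})

test_that("missing values are dropped pairwise", {
  mat <- rbind(A = c(1, 2, 3, 4, 5, 6),
               g = c(2, 1, 4, 3, 6, NA))
  colnames(mat) <- paste0("s", 1:6)
  pr <- anchorProfile(mat, "A")
  expect_equal(unname(pr$rho["g"]),
               cor(c(1, 2, 3, 4, 5), c(2, 1, 4, 3, 6), method = "spearman"))
})

test_that("robust partner filter applies the strict two-dataset rule", {
  pa <- structure(list(anchor = "A",
                       rho = c(A = 1, G1 = 0.5, G2 = 0.5, G3 = 0.8, g4 = -0.6),
                       n = 100), class = "correlation_profile")
  pb <- structure(list(anchor = "A",
                       rho = c(A = 1, g1 = -0.45, G2 = 0.39, G4 = 0.7,
                               G5 = 0.9),
                       n = 80), class = "correlation_profile")
  got <- robustPartners(pa, pb, 0.4)
  expect_equal(got, c("G1", "G4"))          # case-insensitive matching
  expect_false("G2" %in% got)               # 0.39 fails the strict > 0.4
  expect_false("A" %in% got)                # anchor excluded
  expect_equal(got, robustPartners(pb, pa, 0.4))  # symmetric in its arguments

  ortho <- data.frame(a = "G3", b = "G5")
  expect_true("G5" %in% robustPartners(pa, pb, 0.4, orthologs = ortho))

  pc <- structure(list(anchor = "A", rho = c(A = 1, ZZZ = 0.9), n = 10),
                  class = "correlation_profile")
  pd <- structure(list(anchor = "B", rho = c(B = 1, YYY = 0.9), n = 10),
                  class = "correlation_profile")
  expect_error(robustPartners(pc, pd), "shared")
})

test_that("planted robust partners are recovered with high sensitivity and specificity", {
  planted <- sprintf("G%04d", 1:20)
  target <- c(rep(0.7, 20), rep(0, 480))
  se1 <- simulateExpression(list(healthy = target), c(healthy = 200),
                            seed = 301)
  se2 <- simulateExpression(list(healthy = target), c(healthy = 200),
                            seed = 302)
  p1 <- anchorProfile(se1, "ANCHOR", "healthy")
  p2 <- anchorProfile(se2, "ANCHOR", "healthy")
  found <- robustPartners(p1, p2, 0.4)
  sens <- length(intersect(found, planted)) / length(planted)
  spec <- 1 - length(setdiff(found, planted)) / 480
  expect_gte(sens, 0.95)
  expect_gte(spec, 0.95)
})

test_that("hypergeometric enrichment matches enumeration", {
  u <- paste0("g", 1:100)
  r <- hypergeometricEnrichment(u[1:10], u[1:10], u)
  expect_equal(r$overlap, 10L)
  expect_equal(r$p, 1 / choose(100, 10))

  u2 <- paste0("g", 1:1000)
  r2 <- hypergeometricEnrichment(u2[1:50], u2[49:98], u2)
  expect_equal(r2$overlap, 2L)
  expect_equal(r2$p, bruteHyperTail(2, 50, 1000, 50), tolerance = 1e-12)

  # degenerate: everything annotated, tail probability is 1
  expect_equal(hypergeometricEnrichment(u, u, u)$p, 1)
  expect_error(hypergeometricEnrichment(u[1:5], u[1:5], character(0)),
               "empty")
  expect_error(hypergeometricEnrichment(c(u[1], "zz"), u[1:5], u), "subset")
})

test_that("ranked list export is sorted, tie-stable and round-trips", {
  pr <- structure(list(anchor = "A",
                       rho = c(A = 1, b = 0.5, c = 0.5, a = 0.5, d = -0.2),
                       n = 10), class = "correlation_profile")
  path <- withr_local_tempfile(ext = ".rnk")
  exportRankedList(pr, path)
  back <- readRankedList(path)
  expect_equal(back$gene, c("a", "b", "c", "d"))  # ties alphabetical
  expect_equal(back$score, c(0.5, 0.5, 0.5, -0.2))
  # re-export of the re-read list preserves order
  pr2 <- structure(list(anchor = "none",
                        rho = setNames(back$score, back$gene), n = 10),
                   class = "correlation_profile")
  path2 <- withr_local_tempfile(ext = ".rnk")
  exportRankedList(pr2, path2)
  expect_equal(readRankedList(path2), back)
})

test_that("GMT gene sets parse", {
  path <- withr_local_tempfile(ext = ".gmt")
  writeLines(c("setA\tdesc\tg1\tg2\tg3", "setB\t-\tg2\tg4"), path)
  sets <- readGmt(path)
  expect_equal(names(sets), c("setA", "setB"))
  expect_equal(sets$setA, c("g1", "g2", "g3"))
})

test_that("Spearman estimates track the bivariate-normal identity", {
  # population Spearman of a Gaussian pair with Pearson a is (6/pi) asin(a/2)
  targets <- c(0.2, 0.5, 0.8)
  se <- simulateExpression(list(g = targets), c(g = 2000), seed = 77)
  pr <- anchorProfile(se, "ANCHOR", "g")
  expect_equal(unname(pr$rho[-1]), targets, tolerance = 0.05)
})
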