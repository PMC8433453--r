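test_that("effectFromCounts produces the hand-derived log OR and variance", {
  tb <- table1()
  e <- effectFromCounts(tb$Cohort1$cases, tb$Cohort1$controls, "HOM", "C1")
  # 2x2 table (148, 145, 761, 816)
  expect_equal(e$log_or, log((148 * 816) / (145 * 761)))
  expect_equal(e$variance, 1 / 148 + 1 / 145 + 1 / 761 + 1 / 816)
  expect_equal(round(e$log_or, 4), 0.0903)
  expect_equal(round(e$variance, 5), 0.01619)

  sym <- effectFromCounts(genotypeCounts(50, 30, 20),
                          genotypeCounts(50, 30, 20), "HOM")
  expect_equal(sym$log_or, 0)

  zhu <- effectFromCounts(tb$Zhu$cases, tb$Zhu$controls, "HOM")
  expect_equal(round(exp(zhu$log_or), 2), 1.47)
})

test_that("studyEffects drops studies lacking a contrast's counts", {
  sc <- studyCounts()
  expect_message(hom <- studyEffects(sc, "HOM"), "Wirth.*excluded")
  expect_length(hom, 4L)
  comb <- studyEffects(sc, "COMBINED")
  expect_length(comb, 5L)
  # the combined row of the split-less study comes from its printed totals
  w <- comb[[5L]]
  expect_equal(w$log_or, log((144 * 81) / (131 * 85)))
})

test_that("fixed-effect pooling matches its closed form and degenerates correctly", {
  e1 <- structure(list(study_id = "a", log_or = 0.2, variance = 0.04),
                  class = "study_effect")
  e2 <- structure(list(study_id = "b", log_or = -0.1, variance = 0.09),
                  class = "study_effect")
  r <- poolFixed(list(e1, e2))
  w <- c(1 / 0.04, 1 / 0.09)
  mu <- sum(w * c(0.2, -0.1)) / sum(w)
  expect_equal(r$pooled_log_or, mu)
  expect_equal(r$se, 1 / sqrt(sum(w)))
  expect_equal(r$Q, sum(w * (c(0.2, -0.1) - mu)^2))
  # pooled estimate lies within the study range
  expect_true(r$pooled_log_or >= -0.1 && r$pooled_log_or <= 0.2)

  single <- poolFixed(list(e1))
  expect_equal(single$pooled_log_or, 0.2)
  expect_equal(single$Q, 0)

  twin <- poolFixed(list(e1, e1))
  expect_equal(twin$pooled_log_or, 0.2)
  expect_equal(twin$se^2, 0.04 / 2)
  expect_equal(twin$Q, 0)
  expect_equal(twin$I2, 0)
  expect_error(poolFixed(list()), "at least one")
})

test_that("DerSimonian-Laird pooling matches its formula and widens the CI", {
  spread <- list(
    structure(list(study_id = "a", log_or = 5, variance = 0.01),
              class = "study_effect"),
    structure(list(study_id = "b", log_or = -5, variance = 0.01),
              class = "study_effect"))
  fr <- poolFixed(spread)
  rr <- poolRandom(spread)
  w <- rep(100, 2)
  tau2_hand <- max(0, (fr$Q - 1) / (sum(w) - sum(w^2) / sum(w)))
  expect_equal(rr$tau2, tau2_hand)
  expect_gt(rr$tau2, 0)
  expect_gt(rr$ci_high - rr$ci_low, fr$ci_high - fr$ci_low)

  ident <- list(
    structure(list(study_id = "a", log_or = 0.3, variance = 0.05),
              class = "study_effect"),
    structure(list(study_id = "b", log_or = 0.3, variance = 0.05),
              class = "study_effect"))
  expect_equal(poolRandom(ident)$tau2, 0)
  expect_error(poolRandom(ident[1]), "poolFixed")
})

test_that("pooling the published studies reproduces the printed meta-analysis", {
  eff <- suppressMessages(studyEffects(studyCounts(), "HOM"))
  fx <- poolFixed(eff)
  expect_equal(round(fx$pooled_or, 2), 1.17)
  expect_equal(round(fx$ci_low, 2), 0.97)
  expect_equal(round(fx$ci_high, 2), 1.42)
  expect_equal(round(fx$Q, 2), 2.07)
  expect_equal(fx$I2, 0)

  # Q < df, so the random-effects model collapses onto the fixed one
  rnd <- poolRandom(eff)
  expect_equal(rnd$tau2, 0)
  expect_equal(rnd$pooled_or, fx$pooled_or)
  expect_equal(rnd$ci_low, fx$ci_low)

  comb <- poolFixed(suppressMessages(studyEffects(studyCounts(), "COMBINED")))
  expect_equal(round(comb$Q, 2), 0.45)
  expect_equal(comb$df, 4L)
  expect_equal(comb$I2, 0)

  het <- poolFixed(suppressMessages(studyEffects(studyCounts(), "HET")))
  expect_equal(round(het$Q, 2), 0.48)
})

test_that("pooling agrees with the metafor reference implementation", {
  skip_if_not_installed("metafor")
  eff <- suppressMessages(studyEffects(studyCounts(), "HOM"))
  y <- vapply(eff, `[[`, 0, "log_or")
  v <- vapply(eff, `[[`, 0, "variance")
  fe <- metafor::rma(yi = y, vi = v, method = "FE")
  fx <- poolFixed(eff)
  expect_equal(fx$pooled_log_or, unname(as.numeric(fe$beta)), tolerance = 1e-10)
  expect_equal(fx$Q, fe$QE, tolerance = 1e-10)
  re <- metafor::rma(yi = y, vi = v, method = "DL")
  rn <- poolRandom(eff)
  expect_equal(rn$tau2, re$tau2, tolerance = 1e-10)
  expect_equal(rn$pooled_log_or, unname(as.numeric(re$beta)), tolerance = 1e-10)

  # and on a heterogeneous set, where tau2 > 0 actually matters
  y2 <- c(0.8, -0.3, 0.1, 0.6)
  v2 <- c(0.02, 0.05, 0.01, 0.04)
  eff2 <- Map(function(yy, vv, id) structure(
    list(study_id = id, log_or = yy, variance = vv), class = "study_effect"),
    y2, v2, letters[1:4])
  re2 <- metafor::rma(yi = y2, vi = v2, method = "DL")
  rn2 <- poolRandom(eff2)
  expect_gt(rn2$tau2, 0)
  expect_equal(rn2$tau2, re2$tau2, tolerance = 1e-10)
  expect_equal(rn2$pooled_log_or, unname(as.numeric(re2$beta)), tolerance = 1e-10)
  expect_equal(rn2$se, re2$se, tolerance = 1e-10)
})

test_that("heterogeneity p-values are calibrated on homogeneous studies", {
  hits <- 0
  nsim <- 400
  for (i in seq_len(nsim)) {
    effs <- lapply(1:5, function(j) {
      co <- simulateCohort(500, 500, 0.3, seed = i * 13 + j)
      effectFromCounts(countsFromRecords(co, "case"),
                       countsFromRecords(co, "control"),
                       "COMBINED", paste0("s", j))
    })
    if (poolFixed(effs)$p_het < 0.05) hits <- hits + 1
  }
  expect_gte(hits / nsim, 0.02)
  expect_lte(hits / nsim, 0.08)
})

test_that("forest data carries per-study ORs and weights summing to 100", {
  eff <- suppressMessages(studyEffects(studyCounts(), "HOM"))
  fd <- forestData(eff)
  expect_equal(nrow(fd), 4L)
  expect_equal(sum(fd$weight_pct), 100)
  expect_equal(round(fd$or[fd$study == "Zhu"], 2), 1.47)
})
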