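# Scratch file in the session temp dir (cleaned up when R exits).
withr_local_tempfile <- function(ext = "") tempfile(fileext = ext)

# Independent brute-force logrank statistic: explicit risk-set table at every
# event time. Used as the oracle for logrankTest().
bruteLogrankChi2 <- function(time, event, is_high) {
  O1 <- E1 <- V <- 0
  for (t in sort(unique(time[event == 1]))) {
    at1 <- sum(time >= t & is_high)
    at2 <- sum(time >= t & !is_high)
    nt <- at1 + at2
    d1 <- sum(time == t & event == 1 & is_high)
    d2 <- sum(time == t & event == 1 & !is_high)
    dt <- d1 + d2
    O1 <- O1 + d1
    E1 <- E1 + dt * at1 / nt
    if (nt > 1) V <- V + dt * (at1 / nt) * (at2 / nt) * (nt - dt) / (nt - 1)
  }
  (O1 - E1)^2 / V
}

# Hypergeometric upper tail by direct enumeration (oracle for
# hypergeometricEnrichment).
bruteHyperTail <- function(overlap, ann, universe, hits) {
  k <- overlap:min(ann, hits)
  sum(choose(ann, k) * choose(universe - ann, hits - k)) /
    choose(universe, hits)
}

# Table 1 genotype count fixtures as genotypeCounts pairs, keyed by study.
table1 <- function() {
  list(
    Cohort1 = list(cases = genotypeCounts(761, 666, 148),
                   controls = genotypeCounts(816, 679, 145)),
    Cohort2 = list(cases = genotypeCounts(245, 251, 64),
                   controls = genotypeCounts(268, 248, 51)),
    Zhu = list(cases = genotypeCounts(180, 175, 36),
               controls = genotypeCounts(206, 198, 28)),
    Dai = list(cases = genotypeCounts(1092, 406, 21),
               controls = genotypeCounts(1181, 395, 24)))
}

# Printed OR (95% CI) strings for every complete Table 1 row, by study and
# contrast, used to check 2-decimal reproduction.
table1Printed <- function() {
  rbind(
    data.frame(study = "Cohort1", contrast = c("HET", "HOM", "COMBINED"),
               or = c(1.05, 1.09, 1.06), lo = c(0.91, 0.85, 0.92),
               hi = c(1.22, 1.40, 1.22)),
    data.frame(study = "Cohort2", contrast = c("HET", "HOM", "COMBINED"),
               or = c(1.11, 1.37, 1.15), lo = c(0.87, 0.91, 0.91),
               hi = c(1.42, 2.06, 1.46)),
    data.frame(study = "Zhu", contrast = c("HET", "HOM", "COMBINED"),
               or = c(1.01, 1.47, 1.07), lo = c(0.76, 0.86, 0.81),
               hi = c(1.35, 2.51, 1.41)),
    data.frame(study = "Dai", contrast = c("HET", "HOM", "COMBINED"),
               or = c(1.11, 0.95, 1.10), lo = c(0.95, 0.52, 0.94),
               hi = c(1.31, 1.71, 1.29)))
}
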