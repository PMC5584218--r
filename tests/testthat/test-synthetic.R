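test_that("cohort generator reproduces design margins exactly", {
  subjects <- simulateCohort(seed = 1)
  expect_equal(sum(subjects$status == "case"), 4508)
  expect_equal(sum(subjects$status == "control"), 3368)
  expect_equal(sum(subjects$subtype == "hgs"), 3017)
  des <- defaultCohortDesign()
  byStudy <- table(subjects$study, subjects$status)
  expect_equal(as.vector(byStudy[des$study, "case"]), des$n_cases)
  expect_equal(as.vector(byStudy[des$study, "control"]), des$n_controls)
  # controls carry no subtype
  expect_true(all(subjects$subtype[subjects$status == "control"] == ""))
})

test_that("cohort generator handles edge designs and bad input", {
  one <- data.frame(study = "S", region = "UK", n_cases = 0,
                    n_controls = 10, hgs_fraction = 0)
  subjects <- simulateCohort(one, seed = 3)
  expect_equal(nrow(subjects), 10)
  expect_true(all(subjects$status == "control"))
  bad <- one; bad$n_cases <- -1
  expect_error(simulateCohort(bad, seed = 1), "must be >= 0")
  badRegion <- one; badRegion$region <- "Mars"
  expect_error(simulateCohort(badRegion, seed = 1), "region")
})

test_that("generators are deterministic under a fixed seed", {
  expect_identical(simulateCohort(seed = 7), simulateCohort(seed = 7))
  subjects <- simulateCohort(seed = 7)
  eff <- data.frame(gene = "G", f0 = 0.004, or_hgs = 2, or_other = 1,
                    recurrent_frac = 0.3)
  expect_identical(simulateCarrierStatus(subjects, eff, seed = 2),
                   simulateCarrierStatus(subjects, eff, seed = 2))
  u1 <- simulateGeneUniverse(nGenes = 50, seed = 9)
  u2 <- simulateGeneUniverse(nGenes = 50, seed = 9)
  expect_identical(u1, u2)
})

test_that("carrier frequencies match analytic targets (odds conversion)", {
  # p1 = f0 * OR / (1 - f0 + f0 * OR), computed by hand for the
  # reference setting f0 = 0.0038, OR = 2.5
  p1 <- 0.0038 * 2.5 / (1 - 0.0038 + 0.0038 * 2.5)
  expect_equal(p1, 0.009446, tolerance = 1e-4)
  n <- 100000
  subjects <- data.frame(subject_id = sprintf("s%06d", 1:n), study = "S",
                         region = "UK", status = "case", subtype = "hgs")
  eff <- data.frame(gene = "G", f0 = 0.0038, or_hgs = 2.5, or_other = 1)
  flags <- simulateCarrierStatus(subjects, eff, seed = 4)
  emp <- mean(flags$carrier)
  se <- sqrt(p1 * (1 - p1) / n)
  expect_lt(abs(emp - p1), 3 * se)
  # controls sit at f0
  subjects$status <- "control"; subjects$subtype <- ""
  flags0 <- simulateCarrierStatus(subjects, eff, seed = 5)
  se0 <- sqrt(0.0038 * (1 - 0.0038) / n)
  expect_lt(abs(mean(flags0$carrier) - 0.0038), 3 * se0)
})

test_that("null odds ratios and zero frequency behave as expected", {
  subjects <- simulateCohort(seed = 2)
  effNull <- data.frame(gene = "G", f0 = 0.01, or_hgs = 1, or_other = 1)
  flags <- simulateCarrierStatus(subjects, effNull, seed = 3)
  fCase <- mean(flags$carrier[subjects$status == "case"])
  fCtrl <- mean(flags$carrier[subjects$status == "control"])
  expect_lt(abs(fCase - fCtrl), 3 * sqrt(2 * 0.01 * 0.99 / 3368))
  effZero <- data.frame(gene = "G", f0 = 0, or_hgs = 2, or_other = 2)
  flags0 <- simulateCarrierStatus(subjects, effZero, seed = 3)
  expect_false(any(flags0$carrier))
  expect_error(
    simulateCarrierStatus(subjects,
                          data.frame(gene = "G", f0 = 0.1, or_hgs = 2,
                                     or_other = 1), seed = 1),
    "f0")
  bad <- subjects; bad$subtype[1] <- "mystery"
  expect_error(simulateCarrierStatus(bad, effNull, seed = 1),
               "unknown subtype")
})

test_that("read evidence drives calling as designed", {
  subjects <- data.frame(subject_id = sprintf("s%04d", 1:2000), study = "S",
                         region = "UK", status = "case", subtype = "hgs")
  flags <- data.frame(subject_id = subjects$subject_id, gene = "G",
                      carrier = rep(c(TRUE, FALSE), 1000),
                      variant_id = ifelse(rep(c(TRUE, FALSE), 1000),
                                          "G_v1", NA),
                      cdna_pos = 100L)
  obs <- simulateReadEvidence(flags, meanDepth = 600, errorRate = 0.01,
                              seed = 6)
  called <- applyCallingTiers(obs$depth, obs$alt_reads)
  # carriers at depth 600 are overwhelmingly called; background almost never
  expect_gt(mean(called[obs$true_carrier]), 0.99)
  expect_lt(mean(called[!obs$true_carrier]), 0.01)
  expect_error(simulateReadEvidence(flags, meanDepth = 0), "meanDepth")
})

test_that("gene universe respects Poisson mean structure", {
  # mu = 0 -> all counts zero
  u0 <- simulateGeneUniverse(nGenes = 100, mu = 0, seed = 1)
  expect_true(all(u0$genes$count == 0))
  # doubling lengths doubles the mean count (Poisson mean linearity)
  u1 <- simulateGeneUniverse(nGenes = 3000, mu = 2e-6, nCases = 412,
                             lengthMeanlog = log(1000), lengthSdlog = 0,
                             seed = 2)
  u2 <- simulateGeneUniverse(nGenes = 3000, mu = 2e-6, nCases = 412,
                             lengthMeanlog = log(2000), lengthSdlog = 0,
                             seed = 3)
  m1 <- mean(u1$genes$count); m2 <- mean(u2$genes$count)
  expect_equal(m2 / m1, 2, tolerance = 0.1)
  # explicit set referencing an unknown gene is rejected
  expect_error(simulateGeneUniverse(nGenes = 10,
                                    sets = list(s = "NOT_A_GENE")),
               "unknown gene")
})

test_that("incidence generator calibrates cumulative risk exactly", {
  inc <- simulateIncidenceTable(0.018)
  expect_equal(1 - exp(-sum(rates(inc) * 5)), 0.018, tolerance = 1e-9)
  # flat shape: every band rate equals -ln(1 - target) / 80 per year
  flat <- simulateIncidenceTable(0.018, shape = "flat")
  expect_equal(rates(flat), rep(-log(0.982) / 80, 16), tolerance = 1e-12)
  expect_error(simulateIncidenceTable(0), "targetRisk")
  expect_error(simulateIncidenceTable(0.5), "targetRisk")
})
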