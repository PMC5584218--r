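test_that("carrier frequencies reproduce printed-table arithmetic", {
  expect_equal(carrierFrequency(29, 3017), 0.96)
  expect_equal(carrierFrequency(36, 412, digits = 1), 8.7)
  expect_equal(carrierFrequency(0, 1000), 0)
  expect_error(carrierFrequency(1, 0), "n must be")
  expect_error(carrierFrequency(5, 4), "carriers")
})

test_that("crude odds ratio, CI and p-values match hand arithmetic", {
  res <- crudeOR(CarrierTable("FANCM", c(29, 2988, 13, 3355)))
  expect_equal(round(oddsRatio(res), 1), 2.5)
  expect_equal(oddsRatio(res), 29 * 3355 / (2988 * 13), tolerance = 1e-12)
  expect_equal(res@se, sqrt(1 / 29 + 1 / 2988 + 1 / 13 + 1 / 3355),
               tolerance = 1e-12)
  ci <- confint(res)
  expect_equal(round(ci[["lower"]], 1), 1.3)
  # symmetric table gives OR exactly 1
  expect_equal(oddsRatio(crudeOR(10, 990, 10, 990)), 1)
  # Haldane-Anscombe correction keeps a zero cell finite
  h <- crudeOR(1, 999, 0, 1000)
  expect_equal(oddsRatio(h), (1.5 * 1000.5) / (999.5 * 0.5),
               tolerance = 1e-12)
  expect_equal(round(oddsRatio(h), 2), 3.00)
  expect_error(crudeOR(0, 0, 5, 5), "margin")
})

test_that("odds ratio inverts under case/control swap", {
  set.seed(2)
  for (i in 1:20) {
    cells <- rpois(4, c(20, 2000, 10, 2000)) + 1
    a <- crudeOR(cells[1], cells[2], cells[3], cells[4])
    b <- crudeOR(cells[3], cells[4], cells[1], cells[2])
    expect_equal(oddsRatio(a), 1 / oddsRatio(b), tolerance = 1e-12)
  }
})

test_that("Mantel-Haenszel pooling matches the formula and reduces to crude", {
  # single stratum: exact equality with the crude estimator
  set.seed(3)
  for (i in 1:20) {
    cells <- rpois(4, c(15, 1500, 8, 1500)) + 1
    ct <- CarrierTable("G", cells)
    expect_equal(oddsRatio(stratifiedOR(ct)), oddsRatio(crudeOR(ct)),
                 tolerance = 1e-12)
    expect_equal(stratifiedOR(ct)@se, crudeOR(ct)@se, tolerance = 1e-12)
  }
  # two identical strata each with OR 2 pool to exactly 2
  ct2 <- CarrierTable("G", rbind(c(20, 80, 10, 80), c(20, 80, 10, 80)),
                      strata = c("s1", "s2"))
  res <- stratifiedOR(ct2)
  expect_equal(oddsRatio(res), 2, tolerance = 1e-12)
  # cross-check MH point estimate against the textbook formula and
  # stats::mantelhaen.test on a random stratified table
  set.seed(4)
  k <- 4
  cnt <- t(vapply(1:k, function(i) rpois(4, c(12, 900, 6, 900)) + 1,
                  numeric(4)))
  ct4 <- CarrierTable("G", cnt, strata = paste0("s", 1:k))
  ours <- oddsRatio(stratifiedOR(ct4))
  expect_equal(ours, oracleMH(cnt[, 1], cnt[, 2], cnt[, 3], cnt[, 4]),
               tolerance = 1e-12)
  arr <- array(0, c(2, 2, k))
  for (i in 1:k) arr[, , i] <- matrix(cnt[i, ], 2, byrow = TRUE)
  mh <- stats::mantelhaen.test(arr, correct = FALSE)
  expect_equal(unname(ours), unname(mh$estimate), tolerance = 1e-6)
})

test_that("logistic adjustment agrees with MH for rare carriers", {
  set.seed(6)
  cnt <- t(vapply(1:4, function(i) rpois(4, c(12, 1200, 6, 1200)) + 1,
                  numeric(4)))
  ct <- CarrierTable("G", cnt, strata = paste0("r", 1:4))
  mh <- stratifiedOR(ct, method = "mh")
  lg <- stratifiedOR(ct, method = "logistic")
  expect_equal(oddsRatio(lg), oddsRatio(mh), tolerance = 0.02)
})

test_that("region-confounded data is better estimated by pooling", {
  # carrier frequency and case fraction both vary by region, so the
  # crude OR is confounded; MH should land closer to the truth
  set.seed(8)
  trueOR <- 2
  errMH <- errCrude <- numeric(100)
  for (r in 1:100) {
    f0 <- c(0.002, 0.02); nCase <- c(500, 2000); nCtrl <- c(2000, 500)
    cnt <- t(vapply(1:2, function(i) {
      p1 <- f0[i] * trueOR / (1 - f0[i] + f0[i] * trueOR)
      a <- rbinom(1, nCase[i], p1); c0 <- rbinom(1, nCtrl[i], f0[i])
      c(a, nCase[i] - a, c0, nCtrl[i] - c0)
    }, numeric(4)))
    ct <- CarrierTable("G", cnt, strata = c("r1", "r2"))
    errMH[r] <- abs(log(oddsRatio(stratifiedOR(ct))) - log(trueOR))
    errCrude[r] <- abs(log(oddsRatio(crudeOR(ct))) - log(trueOR))
  }
  expect_lt(mean(errMH), mean(errCrude))
})

test_that("Wald CI coverage sits near nominal at the study's margins", {
  set.seed(11)
  n1 <- 3017; n0 <- 3368; f0 <- 0.0038; or <- 2.5
  p1 <- f0 * or / (1 - f0 + f0 * or)
  cover <- 0
  for (i in 1:1000) {
    a <- rbinom(1, n1, p1); c0 <- rbinom(1, n0, f0)
    ci <- confint(crudeOR(a, n1 - a, c0, n0 - c0))
    if (ci[1] <= or && or <= ci[2]) cover <- cover + 1
  }
  expect_gte(cover / 1000, 0.93)
  expect_lte(cover / 1000, 0.97)
})

test_that("case-case subtype contrast matches arithmetic", {
  res <- subtypeContrast(29, 3017, 6, 1491)
  expect_equal(oddsRatio(res), (29 * 1485) / (2988 * 6), tolerance = 1e-12)
  expect_equal(round(oddsRatio(res), 2), 2.40)
  expect_equal(oddsRatio(subtypeContrast(10, 1000, 10, 1000)), 1)
  zero <- subtypeContrast(3, 500, 0, 500)
  expect_true(is.finite(oddsRatio(zero)))
  expect_error(subtypeContrast(1, 0, 2, 10), "non-empty")
})

test_that("positional rank test behaves at its boundaries", {
  # identical position multisets carry no signal
  expect_equal(positionalDistributionTest(c(5, 10, 15), c(5, 10, 15)), 1)
  expect_equal(positionalDistributionTest(7, 9), 1)
  # complete separation at n = 5 vs 5: exact two-sided p = 2 / C(10,5)
  p <- positionalDistributionTest(1:5, 101:105)
  expect_equal(p, 2 / choose(10, 5), tolerance = 1e-12)
  expect_error(positionalDistributionTest(numeric(0), 1:3), "at least one")
})

test_that("carrier tables build correctly from subjects and flags", {
  subjects <- data.frame(
    subject_id = paste0("s", 1:8),
    study = "S",
    region = c("UK", "UK", "USA", "USA", "UK", "UK", "USA", "USA"),
    status = c(rep("case", 4), rep("control", 4)),
    subtype = c("hgs", "hgs", "other", "hgs", rep("", 4)))
  carriers <- data.frame(subject_id = paste0("s", c(1, 3, 5)), gene = "G",
                         carrier = TRUE,
                         variant_id = c("v1", "v2", "v1"),
                         cdna_pos = c(10L, 20L, 10L))
  ct <- buildCarrierTable(subjects, carriers, gene = "G", subset = "all")
  coll <- carrierCounts(collapseStrata(ct))[1, ]
  expect_equal(unname(coll), c(2, 2, 1, 3))
  # HGS-only drops the 'other' case
  cth <- buildCarrierTable(subjects, carriers, gene = "G", subset = "hgs")
  collh <- carrierCounts(collapseStrata(cth))[1, ]
  expect_equal(unname(collh), c(1, 2, 1, 3))
  # collapsing preserves margins
  expect_equal(sum(carrierCounts(ct)), 8)
})

test_that("re-classifying a recurrent variant refits the association", {
  subjects <- simulateCohort(seed = 20)
  eff <- data.frame(gene = "G", f0 = 0.004, or_hgs = 3, or_other = 1,
                    recurrent_frac = 0.4)
  flags <- simulateCarrierStatus(subjects, eff, seed = 21)
  base <- stratifiedOR(buildCarrierTable(subjects, flags, gene = "G",
                                         subset = "hgs"))
  # recoding a variant held by nobody changes nothing
  flags2 <- flags
  flags2$variant_id[which(flags2$carrier)[1]] <- "G_ghostcheck"
  expect_error(reclassifyAndRefit(subjects, flags, "G_nobody"),
               "unknown variant")
  res <- reclassifyAndRefit(subjects, flags, "G_recurrent", gene = "G",
                            subset = "hgs")
  expect_s4_class(res, "AssociationResult")
  # the recurrent allele (OR 1 by simulation symmetry here: it is drawn
  # from the same carrier pool) leaves fewer carriers behind
  nBefore <- sum(flags$carrier)
  nAfter <- sum(carrierCounts(collapseStrata(res@table))[, c(1, 3)])
  expect_lt(nAfter, nBefore)
})

test_that("recoding a null recurrent allele sharpens the refit estimate", {
  # simulate a gene whose recurrent allele carries no risk while private
  # alleles carry OR 4; dropping the recurrent allele should on average
  # raise the estimated OR
  set.seed(30)
  subjects <- simulateCohort(seed = 30)
  diffs <- numeric(40)
  for (r in 1:40) {
    effR <- data.frame(gene = "R", f0 = 0.002, or_hgs = 1, or_other = 1)
    effP <- data.frame(gene = "P", f0 = 0.002, or_hgs = 4, or_other = 1)
    fR <- simulateCarrierStatus(subjects, effR, seed = 300 + r)
    fP <- simulateCarrierStatus(subjects, effP, seed = 600 + r)
    fR$variant_id[fR$carrier] <- "G_recurrent"
    fR$gene <- "G"; fP$gene <- "G"
    comb <- fR
    comb$carrier <- fR$carrier | fP$carrier
    comb$variant_id <- ifelse(fP$carrier, fP$variant_id, fR$variant_id)
    orig <- stratifiedOR(buildCarrierTable(subjects, comb, gene = "G",
                                           subset = "hgs"))
    refit <- reclassifyAndRefit(subjects, comb, "G_recurrent", gene = "G",
                                subset = "hgs")
    diffs[r] <- log(oddsRatio(refit)) - log(oddsRatio(orig))
  }
  expect_gt(mean(diffs), 0)
})
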