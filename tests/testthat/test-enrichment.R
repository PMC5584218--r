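test_that("length-residual ranking reproduces closed-form OLS residuals", {
  # hand-computed OLS for lengths 1..5 kb, counts 0,1,1,2,5:
  # slope 1.1 per kb, intercept -1.5; residuals 0.4, 0.3, -0.8, -0.9, 1.0
  counts <- c(A = 0, B = 1, C = 1, D = 2, E = 5)
  lengths <- c(A = 1000, B = 2000, C = 3000, D = 4000, E = 5000)
  rg <- rankByLengthResidual(counts, lengths)
  expect_equal(rankedGenes(rg), c("E", "A", "B", "C", "D"))
  expect_equal(unname(rankMetric(rg)), c(1.0, 0.4, 0.3, -0.8, -0.9),
               tolerance = 1e-10)
})

test_that("ranking degenerates gracefully and breaks ties lexicographically", {
  # counts exactly proportional to length: all residuals 0, order A-Z
  counts <- c(B = 2, A = 1, C = 3)
  lengths <- c(B = 200, A = 100, C = 300)
  rg <- rankByLengthResidual(counts, lengths)
  expect_equal(unname(rankMetric(rg)), rep(0, 3), tolerance = 1e-12)
  expect_equal(rankedGenes(rg), c("A", "B", "C"))
  # a short gene with a huge count ranks first
  counts2 <- c(A = 50, B = 1, C = 2, D = 3)
  lengths2 <- c(A = 1000, B = 2000, C = 3000, D = 4000)
  expect_equal(rankedGenes(rankByLengthResidual(counts2, lengths2))[1], "A")
  # identical lengths: warn and rank on raw counts
  expect_warning(
    rg3 <- rankByLengthResidual(c(A = 1, B = 5), c(A = 100, B = 100)),
    "identical")
  expect_equal(rankedGenes(rg3), c("B", "A"))
  expect_error(rankByLengthResidual(c(A = 1), c(A = 0)), "positive coding")
})

test_that("enrichment score equals the brute-force walk on all small instances", {
  # exhaustive check over universes up to 12 genes, |S| <= 4
  set.seed(5)
  for (N in 3:12) {
    metric <- sort(round(rnorm(N), 3), decreasing = TRUE)
    rg <- toyRanking(metric)
    members <- rg@gene
    for (k in 1:min(4, N - 1)) {
      combs <- utils::combn(members, k)
      for (j in seq_len(ncol(combs))) {
        s <- combs[, j]
        hit <- rg@gene %in% s
        expect_equal(enrichmentScore(rg, s)$es,
                     oracleES(rg@metric, hit), tolerance = 1e-12)
      }
    }
  }
})

test_that("enrichment score sign, weighting and scale invariance behave", {
  metric <- c(5, 4, 3, 2, 1, 0.5, 0.4, 0.3, 0.2, 0.1)
  rg <- toyRanking(metric)
  top <- rankedGenes(rg)[1:3]
  bottom <- rev(rankedGenes(rg))[1:3]
  expect_gt(enrichmentScore(rg, top)$es, 0)
  expect_lt(enrichmentScore(rg, bottom)$es, 0)
  # p = 0 reduces to the unweighted KS statistic
  hit <- rg@gene %in% top
  expect_equal(enrichmentScore(rg, top, p = 0)$es,
               oracleES(rg@metric, hit, p = 0), tolerance = 1e-12)
  # with p = 1, scaling the metric by a positive constant leaves ES fixed
  rg2 <- toyRanking(metric * 7.3)
  expect_equal(enrichmentScore(rg2, top)$es, enrichmentScore(rg, top)$es,
               tolerance = 1e-12)
  expect_error(enrichmentScore(rg, character(0)), "non-empty")
  expect_error(enrichmentScore(rg, rankedGenes(rg)), "proper subset")
  expect_error(enrichmentScore(rg, "NOT_THERE"), "outside")
})

test_that("enrichment score agrees with an independent GSEA implementation", {
  set.seed(3)
  metric <- sort(rnorm(80), decreasing = TRUE)
  names(metric) <- sprintf("g%03d", 1:80)
  rg <- toyRanking(unname(metric), names(metric))
  for (i in 1:10) {
    s <- sample(names(metric), sample(5:15, 1))
    ours <- enrichmentScore(rg, s)$es
    ref <- fgsea::calcGseaStat(metric,
                               selectedStats = which(names(metric) %in% s),
                               gseaParam = 1)
    expect_equal(ours, ref, tolerance = 1e-10)
  }
})

test_that("permutation p-values are uniform under the null", {
  set.seed(12)
  N <- 200
  metric <- sort(rnorm(N), decreasing = TRUE)
  rg <- toyRanking(metric)
  pvals <- vapply(1:1000, function(i) {
    s <- sample(rg@gene, 15)
    permutationNull(rg, s, nPerm = 200, seed = 5000 + i)$p
  }, numeric(1))
  ks <- suppressWarnings(stats::ks.test(pvals, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("saturated sets hit the permutation floor; NES centers near one", {
  set.seed(9)
  metric <- sort(c(rep(10, 5), abs(rnorm(95))), decreasing = TRUE)
  rg <- toyRanking(metric)
  topSet <- rankedGenes(rg)[1:5]
  pn <- permutationNull(rg, topSet, nPerm = 500, seed = 2)
  # saturation: p sits at the floor of the same-sign null sample, and
  # never below the overall resolution floor 1/(nPerm + 1)
  expect_equal(pn$p, 1 / (1 + sum(pn$nullES > 0)), tolerance = 1e-12)
  expect_gte(pn$p, 1 / 501)
  expect_lte(pn$p, 0.005)
  expect_gt(pn$nes, 1)
  # NES of null-drawn sets distributes around +/- 1
  nes <- vapply(1:200, function(i)
    permutationNull(rg, sample(rg@gene, 10), nPerm = 150,
                    seed = 100 + i)$nes, numeric(1))
  expect_lt(abs(mean(abs(nes)) - 1), 0.15)
})

test_that("FDR separates an enriched set and stays honest under the null", {
  set.seed(21)
  u <- simulateGeneUniverse(nGenes = 300, mu = 2e-6, nCases = 412,
                            setSpecs = data.frame(
                              name = c("signal", paste0("null", 1:4)),
                              size = c(30, 25, 30, 35, 40),
                              multiplier = c(3, 1, 1, 1, 1)),
                            seed = 77)
  rg <- rankByLengthResidual(u$genes)
  res <- gseaPreranked(rg, u$sets, nPerm = 300, seed = 4)
  qs <- setNames(res$q, res$set)
  expect_lt(qs[["signal"]], min(qs[setdiff(names(qs), "signal")]))
  # an all-null collection keeps median q well off zero
  u0 <- simulateGeneUniverse(nGenes = 300, mu = 2e-6, nCases = 412,
                             setSpecs = data.frame(
                               name = paste0("n", 1:6),
                               size = c(20, 25, 30, 35, 40, 45),
                               multiplier = 1),
                             seed = 78)
  rg0 <- rankByLengthResidual(u0$genes)
  res0 <- gseaPreranked(rg0, u0$sets, nPerm = 300, seed = 5)
  expect_gte(stats::median(res0$q), 0.2)
  # duplicate identical sets give identical q under a fixed seed
  dup <- list(a = u0$sets$n3, b = u0$sets$n3)
  resd <- gseaPreranked(rg0, dup, nPerm = 200, seed = 6)
  expect_equal(resd$q[1], resd$q[2])
  expect_equal(resd$es[1], resd$es[2])
})

test_that("gsea results are reproducible and size-filtered", {
  set.seed(31)
  u <- simulateGeneUniverse(nGenes = 100, mu = 5e-6, nCases = 412,
                            setSpecs = data.frame(name = "s1", size = 20,
                                                  multiplier = 1),
                            seed = 3)
  rg <- rankByLengthResidual(u$genes)
  sets <- c(u$sets, list(tiny = u$sets$s1[1:5]))
  r1 <- gseaPreranked(rg, sets, nPerm = 200, seed = 11)
  r2 <- gseaPreranked(rg, sets, nPerm = 200, seed = 11)
  expect_identical(r1, r2)
  expect_false("tiny" %in% r1$set)  # below minSize
  expect_error(gseaPreranked(rg, list(tiny = u$sets$s1[1:5]),
                             nPerm = 200, seed = 1), "size window")
})
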