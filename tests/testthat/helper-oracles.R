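# Independent oracles used across the suite. These deliberately re-derive
# results by brute force / literal rule transcription, never by calling
# the implementation under test.

# Literal transcription of the tiered calling rule text: minimum
# coverage 15; called if (cov >= 500 & frac >= .10) or
# (250 <= cov < 500 & frac >= .15) or (30 <= cov < 250 & frac >= .20)
# or (15 <= cov < 30 & frac >= .30).
oracleTierCall <- function(cov, frac) {
  if (cov < 15) return(FALSE)
  (cov >= 500 && frac >= 0.10) ||
    (cov >= 250 && cov < 500 && frac >= 0.15) ||
    (cov >= 30 && cov < 250 && frac >= 0.20) ||
    (cov >= 15 && cov < 30 && frac >= 0.30)
}

# Literal transcription of the exome rule: depth >= 40, alt ratio >= 30%,
# MAF <= 5%.
oracleExomeCall <- function(depth, alt, maf = 0) {
  depth >= 40 && (depth > 0 && alt / depth >= 0.30) && maf <= 0.05
}

# Brute-force enrichment walk: explicit loop over every prefix position,
# signed maximum deviation from zero, positive extreme wins ties.
oracleES <- function(orderedMetric, hit, p = 1) {
  w <- abs(orderedMetric)^p
  nr <- sum(w[hit])
  k <- sum(hit); N <- length(hit)
  run <- 0; hiVal <- -Inf; loVal <- Inf
  for (i in seq_len(N)) {
    run <- run + if (hit[i]) {
      if (nr > 0) w[i] / nr else 1 / k
    } else -1 / (N - k)
    hiVal <- max(hiVal, run); loVal <- min(loVal, run)
  }
  if (hiVal + loVal >= -1e-12) hiVal else loVal
}

# Mantel-Haenszel pooled odds ratio computed straight from the textbook
# formula (no variance), for cross-checking.
oracleMH <- function(a, b, c, d) {
  n <- a + b + c + d
  sum(a * d / n) / sum(b * c / n)
}

# A small deterministic ranked list for enrichment tests.
toyRanking <- function(metric, genes = sprintf("g%02d", seq_along(metric))) {
  o <- order(-metric, genes)
  new("RankedGenes", gene = genes[o], metric = metric[o])
}
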