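#' Exact test of Hardy-Weinberg equilibrium
#'
#' Exact two-sided p-value for a biallelic genotype table by full
#' enumeration of the conditional distribution of heterozygote counts
#' given allele counts, summing the probabilities of all outcomes no
#' more probable than the observed one.
#'
#' @param nAA,nAa,naa genotype counts (major homozygote, heterozygote,
#'   minor homozygote).
#' @return Exact p-value.
#' @examples
#' hweExactTest(1000, 20, 0)
#' @export
hweExactTest <- function(nAA, nAa, naa) {
  stopifnot(nAA >= 0, nAa >= 0, naa >= 0)
  n <- nAA + nAa + naa
  if (n == 0) stop("empty genotype table")
  nMinor <- nAa + 2 * naa
  # heterozygote count has the parity of the minor-allele count
  hets <- seq(nMinor %% 2, min(nMinor, 2 * n - nMinor), by = 2)
  logProb <- vapply(hets, function(h) {
    hom2 <- (nMinor - h) / 2
    hom1 <- n - h - hom2
    lgamma(n + 1) - lgamma(hom1 + 1) - lgamma(h + 1) - lgamma(hom2 + 1) +
      h * log(2) + lgamma(nMinor + 1) + lgamma(2 * n - nMinor + 1) -
      lgamma(2 * n + 1)
  }, numeric(1))
  prob <- exp(logProb - max(logProb))
  prob <- prob / sum(prob)
  obs <- prob[match(nAa, hets)]
  sum(prob[prob <= obs + 1e-12])
}

#' Eligibility filter for rare-missense burden testing
#'
#' Keeps missense variants with minor allele frequency at most `maxMaf`
#' (1%), genotype call rate above `minCallRate` (80%), and control
#' genotype frequencies consistent with Hardy-Weinberg equilibrium
#' (exact p > `minHweP`, default 1e-5). HWE is assessed in controls
#' only, since cases may deviate under association.
#'
#' @param variants data.frame with columns `variant_id`, `consequence`,
#'   `maf`, `call_rate`, and control genotype counts `n_AA`, `n_Aa`,
#'   `n_aa`.
#' @param maxMaf,minCallRate,minHweP filter thresholds.
#' @return The eligible subset of `variants`, with an `hwe_p` column
#'   appended.
#' @export
burdenVariantFilter <- function(variants, maxMaf = 0.01,
                                minCallRate = 0.80, minHweP = 1e-5) {
  need <- c("variant_id", "consequence", "maf", "call_rate",
            "n_AA", "n_Aa", "n_aa")
  stopifnot(all(need %in% names(variants)))
  v <- variants[variants$consequence == "missense" &
                  variants$maf <= maxMaf &
                  variants$call_rate > minCallRate, , drop = FALSE]
  if (!nrow(v)) { v$hwe_p <- numeric(0); return(v) }
  v$hwe_p <- vapply(seq_len(nrow(v)), function(i)
    hweExactTest(v$n_AA[i], v$n_Aa[i], v$n_aa[i]), numeric(1))
  v[v$hwe_p > minHweP, , drop = FALSE]
}

# Profile log-likelihood of one variant's 2x2 carrier counts at a fixed
# log odds ratio. The nuisance control carrier frequency is profiled out
# in closed form: under a fixed odds ratio psi the constrained MLE of
# the control frequency solves the quadratic
#   N0(psi-1) f^2 + [N1 psi + N0 - m(psi-1)] f - m = 0,  m = a + c.
# Vectorized over variants (a, c).
.profileLogLik <- function(a, c, N1, N0, beta) {
  m <- a + c
  if (abs(beta) < 1e-12) {
    f <- m / (N1 + N0)
    p1 <- f
  } else {
    psi <- exp(beta)
    A <- N0 * (psi - 1)
    B <- N1 * psi + N0 - m * (psi - 1)
    f <- (-B + sqrt(B^2 + 4 * A * m)) / (2 * A)
    p1 <- psi * f / (1 + (psi - 1) * f)
  }
  term <- function(x, n, p) {
    out <- numeric(length(x))
    ok <- p > 0 & p < 1
    out[ok] <- x[ok] * log(p[ok]) + (n - x[ok]) * log1p(-p[ok])
    # p == 0 contributes 0 when x == 0 (and is impossible otherwise)
    out[!ok & x > 0 & p == 0] <- -Inf
    out[!ok & (n - x) > 0 & p == 1] <- -Inf
    out
  }
  if (length(p1) == 1L) p1 <- rep(p1, length(a))
  if (length(f) == 1L) f <- rep(f, length(a))
  term(a, N1, p1) + term(c, N0, f)
}

# Mixture log-likelihood at (pi, beta) given per-variant null loglik lv0.
.mixtureLogLik <- function(pi, beta, a, c, N1, N0, lv0) {
  lvb <- .profileLogLik(a, c, N1, N0, beta)
  # log(pi * exp(lvb) + (1 - pi) * exp(lv0)), stably
  hi <- pmax(lvb, lv0)
  sum(hi + log(pi * exp(lvb - hi) + (1 - pi) * exp(lv0 - hi)))
}

# Maximize sum log(pi * e + (1 - pi) * b) over pi in [0,1] for fixed
# per-variant likelihood ratios; concave in pi, solved by clamped
# Newton. Returns list(pi, value) where value is the log-likelihood
# *relative* offsets already included via (e, b) = exp(lv - hi).
.profilePi <- function(e, b, hi) {
  d <- e - b
  g <- function(p) sum(d / (p * d + b))          # derivative
  if (g(0) <= 0) p <- 0
  else if (g(1) >= 0) p <- 1
  else {
    p <- 0.5
    for (it in 1:30) {
      den <- p * d + b
      g1 <- sum(d / den)
      g2 <- -sum((d / den)^2)
      step <- g1 / g2
      pNew <- min(max(p - step, 1e-12), 1 - 1e-12)
      if (abs(pNew - p) < 1e-10) { p <- pNew; break }
      p <- pNew
    }
  }
  list(pi = p, value = sum(hi + log(p * e + (1 - p) * b)))
}

#' Fit the admixture maximum-likelihood burden model
#'
#' Maximizes `sum_v log[pi * L_v(beta) + (1 - pi) * L_v(0)]` over the
#' mixture proportion `pi` (probability a variant is risk-associated)
#' and the shared log odds ratio `beta` (either sign), where `L_v(beta)`
#' is the binomial likelihood of variant v's case/control carrier counts
#' with its nuisance control carrier frequency profiled out in closed
#' form.
#'
#' Since the mixture proportion enters the log-likelihood concavely for
#' fixed `beta`, `pi` is profiled out by a clamped Newton solve; the
#' remaining one-dimensional profile over `beta` (which may be bimodal,
#' risk and protective modes) is scanned on a grid and refined by golden
#' search around the best grid point.
#'
#' @param caseCarriers,controlCarriers integer vectors of per-variant
#'   carrier counts.
#' @param nCases,nControls cohort sizes.
#' @param betaMax box bound on `|beta|` (default 8, OR about 3000).
#' @param nGrid beta grid resolution for the profile scan.
#' @return An [AdmixtureFit-class].
#' @examples
#' fitAdmixtureML(c(9, 2, 1), c(3, 2, 2), 5000, 5000)
#' @export
fitAdmixtureML <- function(caseCarriers, controlCarriers, nCases,
                           nControls, betaMax = 8, nGrid = 33) {
  a <- as.numeric(caseCarriers); cc <- as.numeric(controlCarriers)
  stopifnot(length(a) == length(cc), length(a) >= 1,
            all(a >= 0), all(cc >= 0), all(a <= nCases),
            all(cc <= nControls))
  lv0 <- .profileLogLik(a, cc, nCases, nControls, 0)
  ll0 <- sum(lv0)
  profileBeta <- function(b) {
    lvb <- .profileLogLik(a, cc, nCases, nControls, b)
    hi <- pmax(lvb, lv0)
    .profilePi(exp(lvb - hi), exp(lv0 - hi), hi)
  }
  betaGrid <- seq(-betaMax, betaMax, length.out = nGrid)
  prof <- lapply(betaGrid, profileBeta)
  vals <- vapply(prof, `[[`, numeric(1), "value")
  # the profile can be bimodal (risk and protective modes): refine every
  # local grid maximum, then keep the overall best
  isLocalMax <- vals >= c(-Inf, vals[-nGrid]) &
    vals >= c(vals[-1], -Inf)
  cand <- which(isLocalMax)
  cand <- utils::head(cand[order(vals[cand], decreasing = TRUE)], 4)
  beta <- betaGrid[which.max(vals)]; best <- prof[[which.max(vals)]]
  for (i in cand) {
    loB <- betaGrid[max(1, i - 1)]; hiB <- betaGrid[min(nGrid, i + 1)]
    opt <- stats::optimize(function(b) profileBeta(b)$value,
                           interval = c(loB, hiB), maximum = TRUE,
                           tol = 1e-6)
    if (opt$objective > best$value) {
      beta <- opt$maximum; best <- profileBeta(beta)
    }
  }
  if (!is.finite(best$value))
    stop("admixture fit failed: non-finite likelihood (", length(a),
         " variants)")
  ll <- max(best$value, ll0)  # likelihood at pi = 0 equals the null
  new("AdmixtureFit", pi = best$pi, beta = beta,
      logLik = ll, logLik0 = ll0, nVariants = length(a),
      converged = TRUE)
}

#' Admixture burden test with permutation p-value
#'
#' Computes the likelihood-ratio statistic
#' `LRT = 2 (logLik_alt - logLik_null)` of the admixture fit and obtains
#' its p-value by case/control label permutation (the mixture LRT null
#' is non-standard, so asymptotic reference distributions are avoided).
#' Deterministic for a fixed seed; `p >= 1/(nPerm + 1)`.
#'
#' @param genotypes logical matrix, variants x subjects: does the
#'   subject carry the variant?
#' @param isCase logical vector over subjects.
#' @param nPerm number of permutations (>= 100).
#' @param seed integer seed.
#' @param gene gene label carried into the result.
#' @return A [BurdenResult-class].
#' @export
burdenTest <- function(genotypes, isCase, nPerm = 1000, seed = 1L,
                       gene = "NA") {
  if (nPerm < 100) stop("nPerm must be >= 100")
  stopifnot(is.matrix(genotypes), ncol(genotypes) == length(isCase))
  nCases <- sum(isCase); nControls <- sum(!isCase)
  a <- as.numeric(genotypes %*% isCase)
  tot <- rowSums(genotypes)
  fit <- fitAdmixtureML(a, tot - a, nCases, nControls)
  lrt <- max(0, 2 * (fit@logLik - fit@logLik0))
  set.seed(seed)
  exceed <- 0L
  for (i in seq_len(nPerm)) {
    permCase <- logical(length(isCase))
    permCase[sample.int(length(isCase), nCases)] <- TRUE
    ap <- as.numeric(genotypes %*% permCase)
    fp <- fitAdmixtureML(ap, tot - ap, nCases, nControls)
    lp <- max(0, 2 * (fp@logLik - fp@logLik0))
    if (lp >= lrt - 1e-10) exceed <- exceed + 1L
  }
  new("BurdenResult", gene = gene, stat = lrt,
      p = (1 + exceed) / (1 + nPerm), piHat = fit@pi, betaHat = fit@beta,
      nVariants = nrow(genotypes), nPerm = as.integer(nPerm))
}
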