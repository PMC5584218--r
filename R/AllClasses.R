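#' Stratified carrier 2x2 table
#'
#' Per-gene carrier counts for cases and controls, optionally stratified
#' (typically by geographical region). This is the unit of association
#' testing: every estimator in the association module consumes one.
#'
#' @slot gene single gene symbol the table refers to.
#' @slot counts integer-valued matrix, one row per stratum, columns
#'   `case_carrier`, `case_noncarrier`, `control_carrier`,
#'   `control_noncarrier`; rownames are the stratum labels.
#'
#' @seealso [CarrierTable()], [crudeOR()], [stratifiedOR()]
#' @export
setClass("CarrierTable",
  representation(gene = "character", counts = "matrix"),
  validity = function(object) {
    msg <- NULL
    cn <- c("case_carrier", "case_noncarrier", "control_carrier",
            "control_noncarrier")
    if (length(object@gene) != 1L)
      msg <- c(msg, "'gene' must be a single symbol")
    if (!identical(colnames(object@counts), cn))
      msg <- c(msg, paste("counts columns must be", paste(cn, collapse = ", ")))
    if (any(object@counts < 0) || any(object@counts != round(object@counts)))
      msg <- c(msg, "counts must be non-negative integers")
    if (nrow(object@counts) < 1L)
      msg <- c(msg, "at least one stratum required")
    if (is.null(msg)) TRUE else msg
  })

#' Construct a CarrierTable
#'
#' @param gene gene symbol.
#' @param counts matrix (strata x 4) with columns `case_carrier`,
#'   `case_noncarrier`, `control_carrier`, `control_noncarrier`, or a
#'   length-4 vector for a single stratum.
#' @param strata optional stratum labels (rownames).
#' @return A [CarrierTable-class] object.
#' @examples
#' ct <- CarrierTable("GENE1", c(29, 2988, 13, 3355))
#' carrierCounts(ct)
#' @export
CarrierTable <- function(gene, counts, strata = NULL) {
  if (is.null(dim(counts))) counts <- matrix(counts, nrow = 1L)
  counts <- as.matrix(counts)
  colnames(counts) <- c("case_carrier", "case_noncarrier",
                        "control_carrier", "control_noncarrier")
  if (!is.null(strata)) rownames(counts) <- strata
  else if (is.null(rownames(counts)))
    rownames(counts) <- if (nrow(counts) == 1L) "all" else
      paste0("stratum", seq_len(nrow(counts)))
  new("CarrierTable", gene = as.character(gene), counts = counts)
}

#' @describeIn CarrierTable counts accessor
#' @param object,x a `CarrierTable`.
#' @export
setMethod("carrierCounts", "CarrierTable", function(object) object@counts)

#' @describeIn CarrierTable sum counts over strata into one margin table
#' @export
setMethod("collapseStrata", "CarrierTable", function(object) {
  CarrierTable(object@gene, colSums(object@counts), strata = "all")
})

setMethod("show", "CarrierTable", function(object) {
  cat("CarrierTable for", object@gene, "(", nrow(object@counts), "strata )\n")
  print(object@counts)
})

#' Association estimate for a carrier table
#'
#' Odds ratio with Wald confidence interval, log-OR standard error, and
#' both Wald and Fisher exact p-values.
#'
#' @slot gene gene symbol.
#' @slot subset case subset label (e.g. "HGSOC", "other", "all").
#' @slot estimate odds ratio point estimate.
#' @slot ciLo,ciHi confidence limits at `level`.
#' @slot level confidence level (e.g. 0.95 or 0.80).
#' @slot se standard error of the log odds ratio.
#' @slot pWald two-sided Wald p-value.
#' @slot pFisher Fisher exact p-value (collapsed table).
#' @slot method estimator tag ("crude", "mh", "logistic").
#' @slot table the [CarrierTable-class] the estimate was computed from.
#' @export
setClass("AssociationResult",
  representation(gene = "character", subset = "character",
                 estimate = "numeric", ciLo = "numeric", ciHi = "numeric",
                 level = "numeric", se = "numeric",
                 pWald = "numeric", pFisher = "numeric",
                 method = "character", table = "CarrierTable"),
  validity = function(object) {
    msg <- NULL
    if (length(object@estimate) != 1L || object@estimate < 0)
      msg <- c(msg, "estimate must be a single non-negative number")
    if (!is.na(object@ciLo) && !is.na(object@ciHi)) {
      if (object@ciLo > object@ciHi)
        msg <- c(msg, "ciLo must not exceed ciHi")
      if (object@estimate < object@ciLo - 1e-12 ||
          object@estimate > object@ciHi + 1e-12)
        msg <- c(msg, "confidence interval must contain the estimate")
    }
    if (!(object@level > 0 && object@level < 1))
      msg <- c(msg, "level must be in (0,1)")
    if (is.null(msg)) TRUE else msg
  })

#' @describeIn AssociationResult odds ratio accessor
#' @param object an `AssociationResult`.
#' @export
setMethod("oddsRatio", "AssociationResult", function(object) object@estimate)

#' @describeIn AssociationResult p-value accessor;
#'   `method` is `"fisher"` (default headline) or `"wald"`
#' @param method which p-value to return.
#' @export
setMethod("pValue", "AssociationResult", function(object,
                                                  method = c("fisher", "wald")) {
  method <- match.arg(method)
  if (method == "fisher") object@pFisher else object@pWald
})

#' Confidence interval of an association result
#'
#' @param object an [AssociationResult-class].
#' @param parm ignored (single parameter).
#' @param level ignored; the interval is computed at the level stored in
#'   the object.
#' @param ... ignored.
#' @return Named numeric vector `c(lower, upper)`.
#' @export
setMethod("confint", "AssociationResult",
  function(object, parm, level, ...) c(lower = object@ciLo, upper = object@ciHi))

setMethod("show", "AssociationResult", function(object) {
  cat(sprintf("AssociationResult: %s [%s, %s]\n", object@gene, object@subset,
              object@method))
  cat(sprintf("  OR %.2f (%d%% CI %.2f - %.2f), p(Fisher) %.3g, p(Wald) %.3g\n",
              object@estimate, round(100 * object@level),
              object@ciLo, object@ciHi, object@pFisher, object@pWald))
})

#' Ranked gene list
#'
#' Genes ordered by a ranking metric (here: residuals of the
#' truncating-mutation count on coding length regression), descending.
#' Ties on the metric are broken lexicographically by symbol so the order
#' is total and deterministic.
#'
#' @slot gene character vector of gene symbols, best first.
#' @slot metric numeric ranking metric aligned with `gene`.
#' @export
setClass("RankedGenes",
  representation(gene = "character", metric = "numeric"),
  validity = function(object) {
    msg <- NULL
    if (length(object@gene) != length(object@metric))
      msg <- c(msg, "gene and metric lengths differ")
    if (anyDuplicated(object@gene))
      msg <- c(msg, "one entry per gene required")
    if (is.unsorted(rev(object@metric)))
      msg <- c(msg, "metric must be non-increasing")
    if (is.null(msg)) TRUE else msg
  })

#' @describeIn RankedGenes gene symbols in rank order
#' @param object a `RankedGenes`.
#' @export
setMethod("rankedGenes", "RankedGenes", function(object) object@gene)

#' @describeIn RankedGenes ranking metric in rank order
#' @export
setMethod("rankMetric", "RankedGenes", function(object) {
  stats::setNames(object@metric, object@gene)
})

setMethod("length", "RankedGenes", function(x) length(x@gene))

setMethod("show", "RankedGenes", function(object) {
  n <- length(object@gene)
  cat("RankedGenes with", n, "genes\n")
  k <- min(5L, n)
  print(data.frame(gene = object@gene[seq_len(k)],
                   metric = signif(object@metric[seq_len(k)], 4)))
  if (n > k) cat("  ...\n")
})

#' Age-band incidence table
#'
#' Annual disease incidence per contiguous half-open age band `[lo, hi)`
#' starting at age 0.
#'
#' @slot ageLo,ageHi band boundaries in years.
#' @slot rate annual incidence rate per band (per person-year).
#' @export
setClass("IncidenceTable",
  representation(ageLo = "numeric", ageHi = "numeric", rate = "numeric"),
  validity = function(object) {
    msg <- NULL
    n <- length(object@rate)
    if (length(object@ageLo) != n || length(object@ageHi) != n)
      msg <- c(msg, "ageLo, ageHi, rate lengths differ")
    if (n > 0) {
      if (object@ageLo[1] != 0)
        msg <- c(msg, "bands must start at age 0")
      if (any(object@ageHi <= object@ageLo))
        msg <- c(msg, "bands must have positive width")
      if (n > 1 && any(abs(object@ageLo[-1] - object@ageHi[-n]) > 1e-9))
        msg <- c(msg, "bands must be contiguous")
      if (any(object@rate < 0)) msg <- c(msg, "rates must be >= 0")
    }
    if (is.null(msg)) TRUE else msg
  })

#' Construct an IncidenceTable
#'
#' @param ageLo,ageHi numeric band boundaries (half-open `[lo, hi)`),
#'   contiguous from age 0.
#' @param rate annual incidence per band.
#' @return An [IncidenceTable-class].
#' @examples
#' inc <- IncidenceTable(c(0, 40), c(40, 80), c(1e-5, 5e-4))
#' rates(inc)
#' @export
IncidenceTable <- function(ageLo, ageHi, rate) {
  new("IncidenceTable", ageLo = as.numeric(ageLo), ageHi = as.numeric(ageHi),
      rate = as.numeric(rate))
}

#' @describeIn IncidenceTable annual rates accessor
#' @param object an `IncidenceTable`.
#' @export
setMethod("rates", "IncidenceTable", function(object) object@rate)

#' @describeIn IncidenceTable band boundary accessor
#' @export
setMethod("ageBands", "IncidenceTable", function(object) {
  cbind(lo = object@ageLo, hi = object@ageHi)
})

setMethod("show", "IncidenceTable", function(object) {
  cat("IncidenceTable:", length(object@rate), "bands, ages",
      min(object@ageLo), "-", max(object@ageHi), "\n")
  cat(sprintf("  cumulative risk to %g: %.4g\n", max(object@ageHi),
              1 - exp(-sum(object@rate * (object@ageHi - object@ageLo)))))
})

#' Relative-risk model for absolute-risk projection
#'
#' Log relative risk with its standard error, carrier frequency, and
#' optional log-normal polygenic / lifestyle modifier standard deviations
#' with a centile at which to evaluate the modified risk.
#'
#' @slot logRR log relative risk of carriers vs non-carriers.
#' @slot se standard error of `logRR`.
#' @slot carrierFreq population carrier frequency, in (0, 0.05).
#' @slot sigmaPg polygenic log-relative-risk standard deviation (>= 0).
#' @slot sigmaLs lifestyle log-relative-risk standard deviation (>= 0).
#' @slot centile centile of the modifier distribution, in (0, 1).
#' @export
setClass("RiskModel",
  representation(logRR = "numeric", se = "numeric", carrierFreq = "numeric",
                 sigmaPg = "numeric", sigmaLs = "numeric", centile = "numeric"),
  validity = function(object) {
    msg <- NULL
    if (object@carrierFreq <= 0 || object@carrierFreq >= 0.05)
      msg <- c(msg, "carrierFreq must be in (0, 0.05)")
    if (object@se < 0) msg <- c(msg, "se must be >= 0")
    if (object@sigmaPg < 0 || object@sigmaLs < 0)
      msg <- c(msg, "sigma values must be >= 0")
    if (object@centile <= 0 || object@centile >= 1)
      msg <- c(msg, "centile must be in (0,1)")
    if (is.null(msg)) TRUE else msg
  })

#' Construct a RiskModel
#'
#' @param or relative risk (odds ratio) of carriers; alternatively supply
#'   `logRR`.
#' @param se standard error of the log relative risk.
#' @param carrierFreq population carrier frequency.
#' @param sigmaPg,sigmaLs log-normal modifier standard deviations
#'   (polygenic, lifestyle); 0 disables the component.
#' @param centile modifier centile used by [polygenicCentileRisk()].
#' @param logRR log relative risk (overrides `or`).
#' @return A [RiskModel-class].
#' @examples
#' RiskModel(or = 2.1, se = 0.31, carrierFreq = 0.0038)
#' @export
RiskModel <- function(or = NULL, se = 0, carrierFreq = 0.0038,
                      sigmaPg = 0, sigmaLs = 0, centile = 0.8,
                      logRR = NULL) {
  if (is.null(logRR)) {
    if (is.null(or)) stop("supply 'or' or 'logRR'")
    logRR <- log(or)
  }
  new("RiskModel", logRR = logRR, se = se, carrierFreq = carrierFreq,
      sigmaPg = sigmaPg, sigmaLs = sigmaLs, centile = centile)
}

setMethod("show", "RiskModel", function(object) {
  cat(sprintf("RiskModel: RR %.2f (log-RR se %.3f), carrier freq %.4f\n",
              exp(object@logRR), object@se, object@carrierFreq))
  if (object@sigmaPg > 0 || object@sigmaLs > 0)
    cat(sprintf("  modifier sigma: polygenic %.2f, lifestyle %.2f, centile %.2f\n",
                object@sigmaPg, object@sigmaLs, object@centile))
})

#' Cumulative risk curve with confidence band
#'
#' Cumulative absolute risk evaluated at age-band boundaries, with a
#' confidence band at level `level` obtained by propagating the log-RR
#' confidence limits through the full projection.
#'
#' @slot age ages (band boundaries, starting at 0).
#' @slot central central cumulative-risk curve.
#' @slot lo,hi band curves (may be NA when no band was requested).
#' @slot level band confidence level.
#' @export
setClass("RiskCurve",
  representation(age = "numeric", central = "numeric", lo = "numeric",
                 hi = "numeric", level = "numeric"),
  validity = function(object) {
    msg <- NULL
    n <- length(object@age)
    if (length(object@central) != n)
      msg <- c(msg, "age and central lengths differ")
    if (any(diff(object@central) < -1e-12))
      msg <- c(msg, "cumulative risk must be non-decreasing")
    if (any(object@central < -1e-12 | object@central > 1 + 1e-12))
      msg <- c(msg, "risk must be in [0,1]")
    if (!anyNA(object@lo) && length(object@lo) == n &&
        (any(object@lo > object@central + 1e-9) ||
         any(object@hi < object@central - 1e-9)))
      msg <- c(msg, "band must contain central curve")
    if (is.null(msg)) TRUE else msg
  })

#' @describeIn RiskCurve cumulative risk at the final age
#' @param object a `RiskCurve`.
#' @export
setMethod("lifetimeRisk", "RiskCurve", function(object) {
  object@central[length(object@central)]
})

#' @describeIn RiskCurve ages at which the curve is evaluated
#' @export
setMethod("ageBands", "RiskCurve", function(object) {
  n <- length(object@age)
  cbind(lo = object@age[-n], hi = object@age[-1])
})

setMethod("show", "RiskCurve", function(object) {
  n <- length(object@age)
  cat(sprintf("RiskCurve to age %g: cumulative risk %.4g", object@age[n],
              object@central[n]))
  if (!anyNA(object@lo))
    cat(sprintf(" (%d%% band %.4g - %.4g)", round(100 * object@level),
                object@lo[n], object@hi[n]))
  cat("\n")
})

#' Coerce a RiskCurve to a data.frame
#'
#' @param x a [RiskCurve-class].
#' @param ... ignored.
#' @return data.frame with columns age, central, lo, hi.
#' @export
setMethod("as.data.frame", "RiskCurve", function(x, ...) {
  data.frame(age = x@age, central = x@central,
             lo = if (length(x@lo) == length(x@age)) x@lo else NA_real_,
             hi = if (length(x@hi) == length(x@age)) x@hi else NA_real_)
})

#' Admixture maximum-likelihood burden fit
#'
#' Fit of the two-parameter mixture in which each rare variant is
#' risk-associated with probability `pi`, associated variants sharing the
#' log odds ratio `beta`; per-variant nuisance carrier frequencies are
#' profiled out.
#'
#' @slot pi mixture proportion of risk-associated variants, in [0,1].
#' @slot beta shared log odds ratio of associated variants.
#' @slot logLik maximized mixture log-likelihood.
#' @slot logLik0 null (`pi = 0`) log-likelihood.
#' @slot nVariants number of variants in the fit.
#' @slot converged logical convergence flag.
#' @export
setClass("AdmixtureFit",
  representation(pi = "numeric", beta = "numeric", logLik = "numeric",
                 logLik0 = "numeric", nVariants = "integer",
                 converged = "logical"),
  validity = function(object) {
    msg <- NULL
    if (object@pi < 0 || object@pi > 1) msg <- c(msg, "pi must be in [0,1]")
    if (!is.finite(object@logLik)) msg <- c(msg, "log-likelihood not finite")
    if (is.null(msg)) TRUE else msg
  })

setMethod("show", "AdmixtureFit", function(object) {
  cat(sprintf("AdmixtureFit over %d variants: pi %.3f, beta %.3f (OR %.2f)\n",
              object@nVariants, object@pi, object@beta, exp(object@beta)))
  cat(sprintf("  logLik %.3f (null %.3f), LRT %.3f, converged: %s\n",
              object@logLik, object@logLik0,
              2 * (object@logLik - object@logLik0), object@converged))
})

#' Burden test result
#'
#' @slot gene gene symbol.
#' @slot stat likelihood-ratio statistic (>= 0).
#' @slot p permutation p-value.
#' @slot piHat,betaHat mixture parameter estimates.
#' @slot nVariants number of variants tested.
#' @slot nPerm number of permutations used.
#' @export
setClass("BurdenResult",
  representation(gene = "character", stat = "numeric", p = "numeric",
                 piHat = "numeric", betaHat = "numeric",
                 nVariants = "integer", nPerm = "integer"),
  validity = function(object) {
    msg <- NULL
    if (object@stat < -1e-8) msg <- c(msg, "LRT statistic must be >= 0")
    if (object@p <= 0 || object@p > 1) msg <- c(msg, "p must be in (0,1]")
    if (is.null(msg)) TRUE else msg
  })

#' @describeIn BurdenResult permutation p-value accessor
#' @param object a `BurdenResult`.
#' @export
setMethod("pValue", "BurdenResult", function(object) object@p)

setMethod("show", "BurdenResult", function(object) {
  cat(sprintf("BurdenResult for %s: LRT %.3f, p %.4g (%d permutations)\n",
              object@gene, object@stat, object@p, object@nPerm))
  cat(sprintf("  pi %.3f, beta %.3f, %d variants\n", object@piHat,
              object@betaHat, object@nVariants))
})

#' Tiered variant-calling thresholds
#'
#' Ordered coverage tiers, each with a minimum alternate-allele fraction,
#' plus an absolute minimum coverage below which nothing is called.
#'
#' @slot minCoverage absolute minimum read depth.
#' @slot tiers data.frame with columns `minCov`, `maxCov` (Inf allowed),
#'   `minAltFrac`; tiers contiguous and non-overlapping above
#'   `minCoverage`.
#' @export
setClass("CallingThresholds",
  representation(minCoverage = "numeric", tiers = "data.frame"),
  validity = function(object) {
    msg <- NULL
    t <- object@tiers
    if (!all(c("minCov", "maxCov", "minAltFrac") %in% names(t)))
      msg <- c(msg, "tiers need columns minCov, maxCov, minAltFrac")
    else {
      t <- t[order(t$minCov), , drop = FALSE]
      if (any(t$minAltFrac <= 0 | t$minAltFrac > 1))
        msg <- c(msg, "minAltFrac must be in (0,1]")
      if (nrow(t) > 0 && abs(t$minCov[1] - object@minCoverage) > 1e-9)
        msg <- c(msg, "lowest tier must start at minCoverage")
      if (nrow(t) > 1 && any(abs(t$minCov[-1] - t$maxCov[-nrow(t)]) > 1e-9))
        msg <- c(msg, "tiers must be contiguous and non-overlapping")
      if (nrow(t) > 0 && is.finite(t$maxCov[nrow(t)]))
        msg <- c(msg, "top tier must be open-ended (maxCov = Inf)")
    }
    if (is.null(msg)) TRUE else msg
  })

setMethod("show", "CallingThresholds", function(object) {
  cat("CallingThresholds (minimum coverage", object@minCoverage, ")\n")
  print(object@tiers)
})
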