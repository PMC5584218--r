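#' Non-carrier baseline hazard constrained to population incidence
#'
#' Given population incidence rates, the carrier frequency `f` and the
#' carrier relative risk `r`, solves band-by-band for the non-carrier
#' hazard such that the surviving-prevalence-weighted mixture of carrier
#' (hazard `r * lambda_nc`) and non-carrier (hazard `lambda_nc`)
#' incidence reproduces the population rate exactly:
#' `lambda_pop(a) = lambda_nc(a) * [f S_c(a) r + (1-f) S_nc(a)] /
#'                                 [f S_c(a) + (1-f) S_nc(a)]`,
#' where the survivor fractions `S_c`, `S_nc` are updated sequentially
#' from age 0.
#'
#' @param inc an [IncidenceTable-class].
#' @param f carrier frequency at birth.
#' @param r carrier relative risk (hazard ratio, age-constant).
#' @return Numeric vector of non-carrier annual hazards, one per band,
#'   with the carrier hazards (`r * value`) in the `"carrier"` attribute.
#' @examples
#' inc <- simulateIncidenceTable(0.018)
#' h <- baselineFromPopulation(inc, f = 0.0038, r = 2.5)
#' @export
baselineFromPopulation <- function(inc, f, r) {
  stopifnot(is(inc, "IncidenceTable"), f > 0, f < 1, r > 0)
  lam <- rates(inc)
  w <- ageBands(inc)[, "hi"] - ageBands(inc)[, "lo"]
  sc <- 1; snc <- 1
  out <- numeric(length(lam))
  for (i in seq_along(lam)) {
    mix <- (f * sc * r + (1 - f) * snc) / (f * sc + (1 - f) * snc)
    out[i] <- lam[i] / mix
    if (!is.finite(out[i]) || out[i] * r * w[i] > 700)
      stop("carrier hazard diverges; r * lambda too large")
    sc <- sc * exp(-r * out[i] * w[i])
    snc <- snc * exp(-out[i] * w[i])
  }
  attr(out, "carrier") <- r * out
  out
}

#' Cumulative risk curve from band hazards
#'
#' `F(T) = 1 - exp(-sum_{a < T} r * lambda(a) * width(a))`: pure
#' cumulative incidence with no competing mortality.
#'
#' @param hazards per-band annual hazards (e.g. the non-carrier baseline
#'   from [baselineFromPopulation()]).
#' @param inc the [IncidenceTable-class] supplying the age bands.
#' @param r hazard multiplier applied to `hazards` (carrier relative
#'   risk; 1 for the non-carrier curve).
#' @return Numeric vector of cumulative risks at every band boundary
#'   (length `nBands + 1`, starting at 0).
#' @export
cumulativeRisk <- function(hazards, inc, r = 1) {
  b <- ageBands(inc)
  w <- b[, "hi"] - b[, "lo"]
  c(0, 1 - exp(-cumsum(r * as.numeric(hazards) * w)))
}

#' Project a relative risk onto an absolute cumulative-risk curve
#'
#' Central curve from the point estimate; confidence band (level
#' `level`, default 80% as is conventional for clinical cumulative-risk
#' display) by propagating `exp(logRR -/+ z * se)` through the full
#' projection, i.e. the baseline is re-solved under each limit. Only
#' uncertainty in the log relative risk is propagated, not in the
#' incidence table.
#'
#' @param model a [RiskModel-class].
#' @param inc an [IncidenceTable-class].
#' @param level band confidence level (e.g. 0.80 or 0.95).
#' @return A [RiskCurve-class] for carriers; the population curve is in
#'   the `"population"` attribute.
#' @examples
#' inc <- simulateIncidenceTable(0.018)
#' m <- RiskModel(or = 2.1, se = 0.31, carrierFreq = 0.0038)
#' projectRisk(m, inc, level = 0.80)
#' @export
projectRisk <- function(model, inc, level = 0.80) {
  stopifnot(is(model, "RiskModel"), is(inc, "IncidenceTable"))
  carrierCurve <- function(r) {
    h <- baselineFromPopulation(inc, model@carrierFreq, r)
    cumulativeRisk(h, inc, r = r)
  }
  r0 <- exp(model@logRR)
  central <- carrierCurve(r0)
  if (model@se > 0) {
    z <- stats::qnorm(1 - (1 - level) / 2)
    lo <- carrierCurve(exp(model@logRR - z * model@se))
    hi <- carrierCurve(exp(model@logRR + z * model@se))
  } else {
    lo <- central; hi <- central
  }
  age <- c(ageBands(inc)[1, "lo"], ageBands(inc)[, "hi"])
  curve <- new("RiskCurve", age = age, central = central,
               lo = pmin(lo, central), hi = pmax(hi, central),
               level = level)
  pop <- c(0, 1 - exp(-cumsum(rates(inc) *
                                (ageBands(inc)[, "hi"] -
                                   ageBands(inc)[, "lo"]))))
  attr(curve, "population") <- pop
  curve
}

#' Carrier risk at a centile of a polygenic/lifestyle modifier
#'
#' The multiplicative risk modifier is log-normal with unit mean:
#' `m(q) = exp(sigma * qnorm(q) - sigma^2 / 2)`,
#' `sigma^2 = sigmaPg^2 + sigmaLs^2`. The modifier applies to carriers
#' and non-carriers alike, so the population constraint is re-imposed by
#' discretizing the modifier into `nQuantiles` equal-mass points and
#' solving the band-wise baseline hazard such that the
#' surviving-prevalence-weighted average over all
#' (carrier status x modifier) strata reproduces the population
#' incidence exactly.
#'
#' @param model a [RiskModel-class] with `sigmaPg` (and optionally
#'   `sigmaLs`) set; `centile` selects the point on the modifier
#'   distribution.
#' @param inc an [IncidenceTable-class].
#' @param level band confidence level (propagates log-RR uncertainty as
#'   in [projectRisk()]).
#' @param nQuantiles modifier discretization points (>= 32).
#' @return A [RiskCurve-class] for carriers at the requested centile.
#'   The per-band population reconstruction error is in the
#'   `"reconstruction"` attribute.
#' @export
polygenicCentileRisk <- function(model, inc, level = 0.80,
                                 nQuantiles = 64) {
  stopifnot(is(model, "RiskModel"), is(inc, "IncidenceTable"),
            nQuantiles >= 32)
  sigma <- sqrt(model@sigmaPg^2 + model@sigmaLs^2)
  f <- model@carrierFreq
  lam <- rates(inc)
  b <- ageBands(inc)
  w <- b[, "hi"] - b[, "lo"]
  mq <- exp(sigma * stats::qnorm((seq_len(nQuantiles) - 0.5) / nQuantiles) -
              sigma^2 / 2)
  centileMult <- exp(sigma * stats::qnorm(model@centile) - sigma^2 / 2)
  oneCurve <- function(r) {
    rr <- c(mq, r * mq)                    # non-carrier and carrier strata
    wt <- c(rep((1 - f) / nQuantiles, nQuantiles),
            rep(f / nQuantiles, nQuantiles))
    surv <- rep(1, 2 * nQuantiles)
    base <- numeric(length(lam))
    recon <- numeric(length(lam))
    for (i in seq_along(lam)) {
      mix <- sum(wt * surv * rr) / sum(wt * surv)
      base[i] <- lam[i] / mix
      recon[i] <- base[i] * mix
      surv <- surv * exp(-rr * base[i] * w[i])
    }
    list(curve = c(0, 1 - exp(-cumsum(r * centileMult * base * w))),
         recon = recon)
  }
  r0 <- exp(model@logRR)
  cen <- oneCurve(r0)
  if (model@se > 0) {
    z <- stats::qnorm(1 - (1 - level) / 2)
    lo <- oneCurve(exp(model@logRR - z * model@se))$curve
    hi <- oneCurve(exp(model@logRR + z * model@se))$curve
  } else {
    lo <- cen$curve; hi <- cen$curve
  }
  age <- c(b[1, "lo"], b[, "hi"])
  curve <- new("RiskCurve", age = age, central = cen$curve,
               lo = pmin(lo, cen$curve), hi = pmax(hi, cen$curve),
               level = level)
  attr(curve, "reconstruction") <- cen$recon - lam
  curve
}
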