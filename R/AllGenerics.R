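#' Odds ratio of an association result
#'
#' @param object an object holding an association estimate.
#' @param ... further arguments for methods.
#' @return Numeric odds ratio.
#' @export
setGeneric("oddsRatio", function(object, ...) standardGeneric("oddsRatio"))

#' P-value of a test result
#'
#' @param object a result object.
#' @param ... further arguments for methods (e.g. `method`).
#' @return Numeric p-value.
#' @export
setGeneric("pValue", function(object, ...) standardGeneric("pValue"))

#' Carrier counts of a stratified 2x2 table
#'
#' @param object a [CarrierTable-class] object.
#' @param ... further arguments for methods.
#' @return Integer matrix, one row per stratum, columns
#'   `case_carrier`, `case_noncarrier`, `control_carrier`,
#'   `control_noncarrier`.
#' @export
setGeneric("carrierCounts", function(object, ...) standardGeneric("carrierCounts"))

#' Collapse a stratified table over strata
#'
#' @param object a [CarrierTable-class] object.
#' @param ... further arguments for methods.
#' @return An object of the same class with a single stratum holding the
#'   margin totals.
#' @export
setGeneric("collapseStrata", function(object, ...) standardGeneric("collapseStrata"))

#' Cumulative risk at the oldest age of a risk curve
#'
#' @param object a [RiskCurve-class] object.
#' @param ... further arguments for methods.
#' @return Numeric cumulative risk (probability) at the final age boundary.
#' @export
setGeneric("lifetimeRisk", function(object, ...) standardGeneric("lifetimeRisk"))

#' Annual hazard rates of an incidence table
#'
#' @param object an [IncidenceTable-class] object.
#' @param ... further arguments for methods.
#' @return Numeric vector of per-year rates, one per age band.
#' @export
setGeneric("rates", function(object, ...) standardGeneric("rates"))

#' Age bands of an incidence table or risk curve
#'
#' @param object an [IncidenceTable-class] or [RiskCurve-class] object.
#' @param ... further arguments for methods.
#' @return Two-column matrix of band boundaries (half-open `[lo, hi)`).
#' @export
setGeneric("ageBands", function(object, ...) standardGeneric("ageBands"))

#' Genes of a ranked list, in rank order
#'
#' @param object a [RankedGenes-class] object.
#' @param ... further arguments for methods.
#' @return Character vector of gene symbols, best-ranked first.
#' @export
setGeneric("rankedGenes", function(object, ...) standardGeneric("rankedGenes"))

#' Ranking metric of a ranked gene list
#'
#' @param object a [RankedGenes-class] object.
#' @param ... further arguments for methods.
#' @return Numeric vector of ranking metrics, aligned with [rankedGenes()].
#' @export
setGeneric("rankMetric", function(object, ...) standardGeneric("rankMetric"))
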