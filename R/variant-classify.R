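#' Is a splice-site variant predicted to disrupt splicing?
#'
#' A splice-site variant is considered disruptive when its splice score
#' drops by more than 40% relative to the consensus-sequence score:
#' `(s_ref - s_var) / |s_ref| > 0.40`. A zero reference score makes the
#' relative drop indeterminate; such variants return `NA` and are
#' excluded from the deleterious set by callers.
#'
#' @param sRef consensus (reference) splice score.
#' @param sVar variant splice score.
#' @param cutoff relative score drop required (default 0.40).
#' @return Logical vector; `NA` where `sRef == 0` or a score is missing.
#' @examples
#' spliceDisruptive(8, 4)   # 50% drop -> TRUE
#' spliceDisruptive(8, 6)   # 25% drop -> FALSE
#' @export
spliceDisruptive <- function(sRef, sVar, cutoff = 0.40) {
  out <- (sRef - sVar) / abs(sRef) > cutoff
  out[!is.na(sRef) & sRef == 0] <- NA
  out
}

#' Classify variants as protein-truncating
#'
#' Protein-truncating (predicted deleterious) variants are nonsense
#' substitutions, frameshift indels, and splice-site variants whose
#' splice score drops by more than 40% ([spliceDisruptive()]).
#' Classification depends only on annotation, never on read evidence.
#'
#' @param consequence character vector of consequence classes
#'   (`nonsense`, `frameshift_indel`, `splice_site`, `missense`,
#'   `synonymous`, `other`), or a variant data.frame with columns
#'   `consequence`, `s_ref`, `s_var`.
#' @param sRef,sVar splice scores (used for `splice_site` only).
#' @return Logical vector; splice-site variants with indeterminate scores
#'   are `FALSE` (excluded from the deleterious set).
#' @examples
#' classifyTruncating("nonsense")
#' classifyTruncating("splice_site", sRef = 10, sVar = 5.9)
#' @export
classifyTruncating <- function(consequence, sRef = NA_real_,
                               sVar = NA_real_) {
  if (is.data.frame(consequence)) {
    v <- consequence
    consequence <- v$consequence
    sRef <- if (!is.null(v$s_ref)) v$s_ref else NA_real_
    sVar <- if (!is.null(v$s_var)) v$s_var else NA_real_
  }
  if (any(is.na(consequence))) stop("consequence must be populated")
  trunc <- consequence %in% c("nonsense", "frameshift_indel")
  sp <- consequence == "splice_site"
  if (any(sp)) {
    d <- spliceDisruptive(rep_len(sRef, length(consequence))[sp],
                          rep_len(sVar, length(consequence))[sp])
    trunc[sp] <- !is.na(d) & d
  }
  trunc
}

#' Exome discovery calling and rarity rules
#'
#' A variant observation passes the exome rules when read depth is at
#' least `minDepth` (40), the alternate allele ratio `alt_reads/depth` is
#' at least `minAltFrac` (30%), and the population minor allele frequency
#' does not exceed `maxMaf` (5%). Zero depth never passes.
#'
#' @param depth read depth at the locus.
#' @param altReads alternate-allele read count.
#' @param maf population minor allele frequency (fraction); `NA` is
#'   treated as rare (0).
#' @param minDepth,minAltFrac,maxMaf rule thresholds.
#' @return Logical vector.
#' @examples
#' passExomeRules(50, 20, 0.001)  # TRUE
#' passExomeRules(39, 39, 0)      # FALSE: depth below 40
#' @export
passExomeRules <- function(depth, altReads, maf = 0, minDepth = 40,
                           minAltFrac = 0.30, maxMaf = 0.05) {
  if (any(altReads > depth, na.rm = TRUE))
    stop("alt_reads must not exceed depth")
  maf[is.na(maf)] <- 0
  frac <- ifelse(depth > 0, altReads / depth, 0)
  depth >= minDepth & frac >= minAltFrac & maf <= maxMaf
}

#' Targeted-sequencing tiered calling thresholds
#'
#' The default profile: minimum coverage 15, and a variant is called when
#' (1) coverage >= 500 and alternate allele fraction >= 10%, or
#' (2) 250 <= coverage < 500 and fraction >= 15%, or
#' (3) 30 <= coverage < 250 and fraction >= 20%, or
#' (4) 15 <= coverage < 30 and fraction >= 30%.
#'
#' @return A [CallingThresholds-class].
#' @export
targetedCallingThresholds <- function() {
  new("CallingThresholds", minCoverage = 15,
      tiers = data.frame(minCov = c(15, 30, 250, 500),
                         maxCov = c(30, 250, 500, Inf),
                         minAltFrac = c(0.30, 0.20, 0.15, 0.10)))
}

#' Apply tiered depth/allele-fraction calling rules
#'
#' A variant observation is called when depth reaches the absolute
#' minimum coverage and the alternate-allele fraction meets the minimum
#' for the coverage tier the depth falls in (tiers half-open
#' `[minCov, maxCov)`).
#'
#' @param depth read depth.
#' @param altReads alternate-read count.
#' @param thresholds a [CallingThresholds-class]; default the targeted
#'   profile from [targetedCallingThresholds()].
#' @return Logical vector.
#' @examples
#' applyCallingTiers(600, 72)   # 12% at depth 600: called (tier 1)
#' applyCallingTiers(300, 36)   # 12% at depth 300: not called
#' @export
applyCallingTiers <- function(depth, altReads,
                              thresholds = targetedCallingThresholds()) {
  stopifnot(is(thresholds, "CallingThresholds"))
  if (any(altReads > depth, na.rm = TRUE))
    stop("alt_reads must not exceed depth")
  t <- thresholds@tiers[order(thresholds@tiers$minCov), , drop = FALSE]
  frac <- ifelse(depth > 0, altReads / depth, 0)
  called <- rep(FALSE, length(depth))
  for (i in seq_len(nrow(t))) {
    inTier <- depth >= t$minCov[i] & depth < t$maxCov[i]
    called[inTier] <- frac[inTier] >= t$minAltFrac[i]
  }
  called & depth >= thresholds@minCoverage
}

#' Per-sample target-coverage QC
#'
#' A sample fails QC when fewer than `minFraction` (80%) of its target
#' bases reach depth `minDepth` (15).
#'
#' @param depths either a named list of per-base depth vectors (one
#'   element per sample) or a data.frame with columns `sample_id` and
#'   `depth` (one row per target base).
#' @param minDepth per-base depth requirement (default 15).
#' @param minFraction fraction of target bases that must reach
#'   `minDepth` (default 0.80; a fraction of exactly 0.80 passes).
#' @return data.frame with columns `sample_id`, `frac_covered`, `pass`.
#' @examples
#' sampleQC(list(s1 = c(rep(20, 8), rep(5, 2))))   # 80%: pass
#' @export
sampleQC <- function(depths, minDepth = 15, minFraction = 0.80) {
  if (is.data.frame(depths)) {
    stopifnot(all(c("sample_id", "depth") %in% names(depths)))
    depths <- split(depths$depth, depths$sample_id)
  }
  if (!length(depths) || any(!lengths(depths)))
    stop("empty target: per-base depths required for every sample")
  frac <- vapply(depths, function(d) mean(d >= minDepth), numeric(1))
  data.frame(sample_id = names(depths), frac_covered = frac,
             pass = frac >= minFraction, row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Classify missense variants as damaging by predictor vote
#'
#' A missense variant is predicted damaging when more than one of three
#' in-silico tools votes damaging: SIFT score < 0.05, PolyPhen-2 class
#' `probably_damaging` or `damaging`, Provean score <= -2.5. When fewer
#' than two predictors are available the call is indeterminate and
#' treated as not damaging (conservative toward the null); such variants
#' are reported via a warning.
#'
#' @param sift SIFT scores in [0,1] (`NA` when unavailable).
#' @param polyphen PolyPhen-2 categories (`benign`,
#'   `possibly_damaging`, `probably_damaging`, `damaging`, `NA`).
#' @param provean Provean scores (`NA` when unavailable).
#' @return Logical vector.
#' @examples
#' classifyDamagingMissense(0.01, "probably_damaging", -1.0)  # 2 votes
#' @export
classifyDamagingMissense <- function(sift, polyphen, provean) {
  n <- max(length(sift), length(polyphen), length(provean))
  sift <- rep_len(sift, n); polyphen <- rep_len(polyphen, n)
  provean <- rep_len(provean, n)
  votes <- (!is.na(sift) & sift < 0.05) +
    (!is.na(polyphen) & polyphen %in% c("probably_damaging", "damaging")) +
    (!is.na(provean) & provean <= -2.5)
  available <- (!is.na(sift)) + (!is.na(polyphen)) + (!is.na(provean))
  if (any(available < 2))
    warning(sum(available < 2),
            " variant(s) with fewer than 2 predictor scores treated as",
            " not damaging")
  votes >= 2 & available >= 2
}

#' Filter per-case mutation tables for enrichment ranking
#'
#' Prepares the per-variant per-case table that feeds the length-adjusted
#' gene ranking: recurrent variants carried by more than a fraction
#' `maxRecurrentFrac` of cases (default 8/412, the 0.5% carrier rule) are
#' removed; genes whose symbols match open-reading-frame naming
#' (digits + "orf" + digits, case-insensitive) are dropped from the
#' universe; and only frameshift indels and nonsense substitutions are
#' retained for ranking.
#'
#' @param variants data.frame with columns `variant_id`, `gene`,
#'   `consequence`, `n_cases_carrying`.
#' @param nCases number of cases the counts refer to.
#' @param maxRecurrentFrac maximum carrier fraction retained (a variant
#'   at exactly the boundary is kept; the rule removes strictly greater).
#' @return Filtered data.frame, plus a per-gene count summary in the
#'   `"geneCounts"` attribute.
#' @examples
#' v <- data.frame(variant_id = c("a", "b"), gene = c("G1", "C9orf72"),
#'                 consequence = "nonsense", n_cases_carrying = c(3, 2))
#' enrichmentInputFilter(v, nCases = 412)
#' @export
enrichmentInputFilter <- function(variants, nCases,
                                  maxRecurrentFrac = 8 / 412) {
  need <- c("variant_id", "gene", "consequence", "n_cases_carrying")
  stopifnot(all(need %in% names(variants)))
  keep <- variants$n_cases_carrying / nCases <= maxRecurrentFrac
  keep <- keep & variants$consequence %in% c("frameshift_indel", "nonsense")
  keep <- keep & !grepl("[0-9]+orf[0-9]+", variants$gene, ignore.case = TRUE)
  out <- variants[keep, , drop = FALSE]
  gc <- tapply(out$n_cases_carrying, out$gene, sum)
  attr(out, "geneCounts") <- data.frame(gene = names(gc),
                                        count = as.vector(gc),
                                        stringsAsFactors = FALSE)
  out
}

#' Per-subject per-gene carrier calls from variant observations
#'
#' Combines truncating classification with a calling rule: a subject is
#' a carrier for a gene when at least one of its truncating variant
#' observations in that gene is called.
#'
#' @param variants variant-observation data.frame (TSV dialect).
#' @param rules `"targeted"` (tiered thresholds) or `"exome"`
#'   (depth >= 40, fraction >= 30%, MAF <= 5%).
#' @param thresholds optional [CallingThresholds-class] overriding the
#'   targeted profile.
#' @return data.frame `subject_id`, `gene`, `carrier`, `variant_id`
#'   (first qualifying variant), `cdna_pos`.
#' @export
callCarriers <- function(variants, rules = c("targeted", "exome"),
                         thresholds = NULL) {
  rules <- match.arg(rules)
  trunc <- classifyTruncating(variants)
  called <- if (rules == "targeted")
    applyCallingTiers(variants$depth, variants$alt_reads,
                      if (is.null(thresholds)) targetedCallingThresholds()
                      else thresholds)
  else passExomeRules(variants$depth, variants$alt_reads,
                      if (is.null(variants$maf)) 0 else variants$maf)
  hit <- trunc & called
  key <- interaction(variants$subject_id, variants$gene, drop = TRUE)
  agg <- do.call(rbind, lapply(split(seq_len(nrow(variants)), key),
    function(ix) {
      h <- ix[hit[ix]]
      data.frame(subject_id = variants$subject_id[ix[1]],
                 gene = variants$gene[ix[1]],
                 carrier = length(h) > 0,
                 variant_id = if (length(h)) variants$variant_id[h[1]]
                              else NA_character_,
                 cdna_pos = if (length(h) && !is.null(variants$cdna_pos))
                   variants$cdna_pos[h[1]] else NA_integer_,
                 stringsAsFactors = FALSE)
    }))
  rownames(agg) <- NULL
  agg
}
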