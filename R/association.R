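#' Carrier frequency as a percentage
#'
#' `100 * carriers / n`, rounded to `digits` decimals with R's
#' round-half-even convention (matching printed-table precision).
#'
#' @param carriers carrier count.
#' @param n denominator (> 0).
#' @param digits decimals to report (default 2).
#' @return Numeric percentage.
#' @examples
#' carrierFrequency(29, 3017)            # 0.96
#' carrierFrequency(36, 412, digits = 1) # 8.7
#' @export
carrierFrequency <- function(carriers, n, digits = 2) {
  if (any(n <= 0)) stop("n must be > 0")
  if (any(carriers < 0) || any(carriers > n))
    stop("carriers must be in [0, n]")
  round(100 * carriers / n, digits)
}

# Wald machinery shared by the estimators: log OR, its SE and CI on
# Haldane-Anscombe-corrected cells when any cell is zero.
.waldOR <- function(a, b, c, d, level) {
  if ((a + b) == 0 || (c + d) == 0 || (a + c) == 0 || (b + d) == 0)
    stop("a zero margin leaves the odds ratio undefined")
  if (min(a, b, c, d) == 0) {
    a <- a + 0.5; b <- b + 0.5; c <- c + 0.5; d <- d + 0.5
  }
  or <- (a * d) / (b * c)
  se <- sqrt(1 / a + 1 / b + 1 / c + 1 / d)
  z <- stats::qnorm(1 - (1 - level) / 2)
  list(or = or, se = se,
       lo = exp(log(or) - z * se), hi = exp(log(or) + z * se),
       pWald = 2 * stats::pnorm(-abs(log(or) / se)))
}

#' Crude odds ratio from a collapsed 2x2 carrier table
#'
#' Cross-product odds ratio with Wald confidence interval on the log
#' scale. When any cell is zero the Haldane-Anscombe 0.5 correction is
#' applied to all four cells before estimation. Both the Wald two-sided
#' p-value and Fisher's exact p-value (on the uncorrected table) are
#' reported; Fisher is the default headline p.
#'
#' @param table a [CarrierTable-class] (collapsed over strata first), or
#'   the count `a` when giving cells directly.
#' @param b,c,d remaining cells (`a` = case carriers, `b` = case
#'   non-carriers, `c` = control carriers, `d` = control non-carriers).
#' @param level confidence level (0.95 or 0.80 typical).
#' @param subset case-subset label carried into the result.
#' @return An [AssociationResult-class].
#' @examples
#' crudeOR(CarrierTable("GENE1", c(29, 2988, 13, 3355)))
#' @export
crudeOR <- function(table, b = NULL, c = NULL, d = NULL, level = 0.95,
                    subset = "all") {
  if (is(table, "CarrierTable")) {
    ct <- collapseStrata(table)
    cc <- carrierCounts(ct)[1, ]
    a <- cc[[1]]; b <- cc[[2]]; c <- cc[[3]]; d <- cc[[4]]
    gene <- table@gene
  } else {
    a <- table
    gene <- "NA"
    table <- CarrierTable(gene, c(a, b, c, d))
  }
  w <- .waldOR(a, b, c, d, level)
  pf <- stats::fisher.test(matrix(c(a, b, c, d), 2, byrow = TRUE))$p.value
  new("AssociationResult", gene = gene, subset = subset, estimate = w$or,
      ciLo = w$lo, ciHi = w$hi, level = level, se = w$se, pWald = w$pWald,
      pFisher = pf, method = "crude",
      table = if (is(table, "CarrierTable")) table
              else CarrierTable(gene, c(a, b, c, d)))
}

#' Stratum-adjusted odds ratio (Mantel-Haenszel or logistic)
#'
#' The primary adjusted estimator is the Mantel-Haenszel pooled odds
#' ratio over strata with the Robins-Breslow-Greenland variance for the
#' Wald interval; with a single stratum it reduces exactly to
#' [crudeOR()]. Alternatively a logistic regression of case status on
#' carrier status with stratum indicator covariates can be fitted; its
#' carrier coefficient is the adjusted log OR.
#'
#' @param table a [CarrierTable-class] with one row per stratum.
#' @param level confidence level.
#' @param method `"mh"` (default) or `"logistic"`.
#' @param subset case-subset label carried into the result.
#' @return An [AssociationResult-class]. The Fisher p refers to the
#'   collapsed table.
#' @export
stratifiedOR <- function(table, level = 0.95, method = c("mh", "logistic"),
                         subset = "all") {
  method <- match.arg(method)
  stopifnot(is(table, "CarrierTable"))
  cnt <- carrierCounts(table)
  if (nrow(cnt) == 1L) {
    res <- crudeOR(table, level = level, subset = subset)
    return(res)
  }
  if (sum(cnt[, "case_carrier"] + cnt[, "control_carrier"]) == 0)
    stop("no carriers in any stratum; odds ratio undefined")
  a <- cnt[, "case_carrier"]; b <- cnt[, "case_noncarrier"]
  c <- cnt[, "control_carrier"]; d <- cnt[, "control_noncarrier"]
  n <- a + b + c + d
  if (method == "mh") {
    R <- a * d / n; S <- b * c / n
    if (sum(S) == 0 || sum(R) == 0) {
      # degenerate pooled table: fall back to corrected collapsed OR
      res <- crudeOR(collapseStrata(table), level = level, subset = subset)
      return(res)
    }
    or <- sum(R) / sum(S)
    P <- (a + d) / n; Q <- (b + c) / n
    varlog <- sum(P * R) / (2 * sum(R)^2) +
      sum(P * S + Q * R) / (2 * sum(R) * sum(S)) +
      sum(Q * S) / (2 * sum(S)^2)
    se <- sqrt(varlog)
  } else {
    k <- nrow(cnt)
    cell <- data.frame(
      carrier = rep(rep(c(1, 0), 2), k),
      case = rep(c(1, 1, 0, 0), k),
      stratum = factor(rep(rownames(cnt), each = 4)),
      w = as.vector(t(cnt)))
    cell <- cell[cell$w > 0, ]
    fit <- stats::glm(case ~ carrier + stratum, family = stats::binomial,
                      data = cell, weights = cell$w)
    co <- summary(fit)$coefficients["carrier", ]
    or <- exp(co["Estimate"]); se <- co["Std. Error"]
  }
  z <- stats::qnorm(1 - (1 - level) / 2)
  coll <- carrierCounts(collapseStrata(table))[1, ]
  pf <- stats::fisher.test(matrix(coll, 2, byrow = TRUE))$p.value
  new("AssociationResult", gene = table@gene, subset = subset,
      estimate = unname(or), ciLo = unname(exp(log(or) - z * se)),
      ciHi = unname(exp(log(or) + z * se)), level = level,
      se = unname(se), pWald = unname(2 * stats::pnorm(-abs(log(or) / se))),
      pFisher = pf, method = method, table = table)
}

#' Case-case subtype contrast
#'
#' Compares carrier frequency between two case groups (e.g. high-grade
#' serous vs other histologies) as a 2x2 odds ratio with Fisher's exact
#' p-value.
#'
#' @param carriers1,n1 carrier count and total for the first group.
#' @param carriers2,n2 carrier count and total for the second group.
#' @param level confidence level.
#' @param gene gene label carried into the result.
#' @return An [AssociationResult-class] with subset `"case-case"`.
#' @examples
#' subtypeContrast(29, 3017, 6, 1491)  # OR 2.40
#' @export
subtypeContrast <- function(carriers1, n1, carriers2, n2, level = 0.95,
                            gene = "NA") {
  if (n1 <= 0 || n2 <= 0) stop("both case groups must be non-empty")
  a <- carriers1; b <- n1 - carriers1
  c <- carriers2; d <- n2 - carriers2
  w <- .waldOR(a, b, c, d, level)
  pf <- stats::fisher.test(matrix(c(a, b, c, d), 2, byrow = TRUE))$p.value
  new("AssociationResult", gene = gene, subset = "case-case",
      estimate = w$or, ciLo = w$lo, ciHi = w$hi, level = level, se = w$se,
      pWald = w$pWald, pFisher = pf, method = "crude",
      table = CarrierTable(gene, c(a, b, c, d)))
}

#' Rank test for positional clustering of mutations along a gene
#'
#' Two-sample rank-based comparison (Wilcoxon rank-sum) of the cDNA
#' coordinates of mutations found in cases vs controls, exact when both
#' groups are small and untied.
#'
#' @param casePos cDNA positions of case mutations.
#' @param controlPos cDNA positions of control mutations.
#' @return Two-sided p-value.
#' @examples
#' positionalDistributionTest(c(100, 200, 300), c(110, 250, 290))
#' @export
positionalDistributionTest <- function(casePos, controlPos) {
  if (!length(casePos) || !length(controlPos))
    stop("at least one mutation required in each group")
  suppressWarnings(
    stats::wilcox.test(casePos, controlPos, exact = NULL,
                       correct = TRUE)$p.value)
}

#' Build a stratified carrier table from subjects and carrier calls
#'
#' @param subjects subject data.frame ([simulateCohort()] /
#'   [readSubjects()]).
#' @param carriers data.frame with `subject_id` and logical `carrier`
#'   (and `gene`); when several genes are present, `gene` selects one.
#' @param gene gene to tabulate.
#' @param subset `"hgs"`, `"other"` or `"all"`: which cases enter.
#' @param strata subject column to stratify on (default `"region"`), or
#'   `NULL` for a single collapsed stratum.
#' @return A [CarrierTable-class].
#' @export
buildCarrierTable <- function(subjects, carriers, gene = NULL,
                              subset = c("all", "hgs", "other"),
                              strata = "region") {
  subset <- match.arg(subset)
  if (!is.null(gene)) carriers <- carriers[carriers$gene == gene, ]
  else gene <- if (!is.null(carriers$gene)) carriers$gene[1] else "NA"
  flag <- carriers$carrier[match(subjects$subject_id, carriers$subject_id)]
  flag[is.na(flag)] <- FALSE
  keep <- subjects$status == "control" |
    (subset == "all" | subjects$subtype == subset)
  s <- subjects[keep, ]; flag <- flag[keep]
  grp <- if (is.null(strata)) rep("all", nrow(s)) else s[[strata]]
  lev <- unique(grp)
  counts <- t(vapply(lev, function(g) {
    i <- grp == g
    c(sum(flag[i] & s$status[i] == "case"),
      sum(!flag[i] & s$status[i] == "case"),
      sum(flag[i] & s$status[i] == "control"),
      sum(!flag[i] & s$status[i] == "control"))
  }, numeric(4)))
  CarrierTable(gene, counts, strata = lev)
}

#' Re-classify a variant as non-deleterious and re-estimate association
#'
#' Carriers whose only qualifying variant is the named one are recoded
#' as non-carriers, the stratified carrier table is rebuilt, and the
#' association is re-estimated. Used to probe whether a recurrent
#' low-penetrance allele dilutes the gene-level estimate.
#'
#' @param subjects subject data.frame.
#' @param carriers carrier-call data.frame retaining `variant_id`.
#' @param variantId the variant to recode.
#' @param gene gene to analyse.
#' @param subset,strata,level,method passed to the table construction
#'   and [stratifiedOR()].
#' @return An [AssociationResult-class].
#' @export
reclassifyAndRefit <- function(subjects, carriers, variantId, gene = NULL,
                               subset = "all", strata = "region",
                               level = 0.95, method = "mh") {
  if (!is.null(gene)) carriers <- carriers[carriers$gene == gene, ]
  known <- unique(carriers$variant_id[!is.na(carriers$variant_id)])
  if (!variantId %in% known)
    stop("unknown variant id: ", variantId)
  recode <- !is.na(carriers$variant_id) & carriers$variant_id == variantId
  carriers$carrier[recode] <- FALSE
  carriers$variant_id[recode] <- NA_character_
  if (!any(carriers$carrier))
    stop("no carriers remain after re-classification")
  ct <- buildCarrierTable(subjects, carriers, gene = gene, subset = subset,
                          strata = strata)
  stratifiedOR(ct, level = level, method = method, subset = subset)
}
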