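#' Rank genes by length-adjusted truncating-mutation burden
#'
#' Regresses per-gene mutation counts on coding length by ordinary least
#' squares (with intercept) and uses the residuals as the ranking metric,
#' so that long genes are not favoured merely for their length. Genes are
#' sorted by descending residual; residual ties are broken
#' lexicographically by symbol so the order is total and deterministic.
#' When all coding lengths are identical the regression is degenerate;
#' the function warns and falls back to ranking on raw counts.
#'
#' @param counts named numeric vector of per-gene mutation counts, or a
#'   data.frame with columns `gene`, `count`, `coding_length`.
#' @param lengths named numeric vector of coding lengths (ignored when
#'   `counts` is a data.frame).
#' @return A [RankedGenes-class].
#' @examples
#' rankByLengthResidual(c(A = 0, B = 1, C = 1, D = 2, E = 5),
#'                      c(A = 1000, B = 2000, C = 3000, D = 4000, E = 5000))
#' @export
rankByLengthResidual <- function(counts, lengths = NULL) {
  if (is.data.frame(counts)) {
    lengths <- stats::setNames(counts$coding_length, counts$gene)
    counts <- stats::setNames(counts$count, counts$gene)
  }
  stopifnot(!is.null(names(counts)), !is.null(names(lengths)))
  lengths <- lengths[names(counts)]
  if (anyNA(lengths) || any(lengths <= 0))
    stop("every gene needs a positive coding length")
  if (any(counts < 0)) stop("counts must be >= 0")
  if (stats::var(lengths) == 0) {
    warning("all coding lengths identical; ranking on raw counts")
    metric <- as.numeric(counts)
  } else {
    fit <- stats::lm.fit(cbind(1, as.numeric(lengths)), as.numeric(counts))
    metric <- as.numeric(fit$residuals)
    # floating noise from an exact fit must not defeat lexicographic ties
    metric[abs(metric) < 1e-8 * max(1, max(abs(counts)))] <- 0
  }
  genes <- names(counts)
  o <- order(-metric, genes)
  new("RankedGenes", gene = genes[o], metric = metric[o])
}

# Hit/miss walk increments for a ranked metric and hit indicator.
# Returns the full running-sum profile (length N).
.esWalk <- function(metric, hit, p = 1) {
  w <- abs(metric)^p
  nr <- sum(w[hit])
  nMiss <- sum(!hit)
  step <- ifelse(hit,
                 if (nr > 0) w / nr else 1 / sum(hit),
                 -1 / nMiss)
  cumsum(step)
}

#' Weighted Kolmogorov-Smirnov enrichment score
#'
#' The classic pre-ranked GSEA walk: descending the ranked list, member
#' ("hit") genes increment the running sum by `|metric|^p` normalized
#' over the set, non-members decrement by `1/(N - |S|)`; the enrichment
#' score is the signed maximum deviation of the running sum from zero.
#' With `p = 0` this reduces to the unweighted Kolmogorov-Smirnov
#' statistic.
#'
#' @param ranked a [RankedGenes-class].
#' @param set character vector of member genes; must be a non-empty
#'   proper subset of the ranked universe.
#' @param p metric weight exponent (default 1, the GSEA convention).
#' @return list with `es` (signed maximum deviation) and `profile`
#'   (running sum at every rank position).
#' @examples
#' rg <- rankByLengthResidual(c(A = 9, B = 5, C = 1, D = 0, E = 0),
#'                            c(A = 1, B = 1, C = 1, D = 2, E = 1))
#' enrichmentScore(rg, c("A", "B"))$es
#' @export
enrichmentScore <- function(ranked, set, p = 1) {
  stopifnot(is(ranked, "RankedGenes"))
  genes <- ranked@gene
  set <- unique(set)
  if (!all(set %in% genes)) stop("set contains genes outside the universe")
  k <- length(set)
  if (k == 0L || k >= length(genes))
    stop("set must be a non-empty proper subset of the universe")
  hit <- genes %in% set
  profile <- .esWalk(ranked@metric, hit, p = p)
  hi <- max(profile); lo <- min(profile)
  # on a magnitude tie (within numerical noise of the bounded walk) the
  # positive extreme wins, deterministically across implementations
  list(es = if (hi + lo >= -1e-12) hi else lo, profile = profile)
}

# Fast ES for a set given as hit *positions* in the ranked list.
# Extremes of the walk occur just after a hit (local max) or just before
# a hit (local min), so only 2k points need inspection.
.esFast <- function(absw, N, idx) {
  idx <- sort(idx)
  k <- length(idx)
  nr <- sum(absw[idx])
  missStep <- 1 / (N - k)
  hitCum <- if (nr > 0) cumsum(absw[idx]) / nr else seq_len(k) / k
  missBefore <- (idx - seq_len(k)) * missStep
  after <- hitCum - missBefore            # value just after each hit
  before <- c(0, hitCum[-k]) - missBefore # value just before each hit
  hi <- max(after)
  # the walk ends at 0 and decreases between hits, so minima occur just
  # before a hit or at the very end
  lo <- min(c(before, 0))
  if (hi + lo >= -1e-12) hi else lo
}

#' Permutation null, nominal p and NES for one gene set
#'
#' Null enrichment scores are generated from random gene sets of the same
#' size drawn from the ranked universe (the standard pre-ranked
#' surrogate for phenotype permutation). The nominal p-value is
#' one-sided on the observed sign with the +1 correction,
#' `p = (1 + #(same-sign null with |ES| >= |ES_obs|)) / (1 + #same-sign null)`,
#' and the normalized enrichment score divides the observed ES by the
#' mean |ES| of same-sign null values.
#'
#' @param ranked a [RankedGenes-class].
#' @param set member genes.
#' @param nPerm number of null sets (>= 100).
#' @param seed integer seed.
#' @param p metric weight exponent.
#' @return list with `es`, `nes`, `p`, `nullES` (numeric vector of null
#'   scores).
#' @export
permutationNull <- function(ranked, set, nPerm = 1000, seed = 1L, p = 1) {
  if (nPerm < 100) stop("nPerm must be >= 100")
  obs <- enrichmentScore(ranked, set, p = p)$es
  set.seed(seed)
  N <- length(ranked@gene)
  k <- length(unique(set))
  absw <- abs(ranked@metric)^p
  nullES <- vapply(seq_len(nPerm), function(i)
    .esFast(absw, N, sample.int(N, k)), numeric(1))
  same <- nullES[sign(nullES) == sign(obs)]
  if (!length(same)) {
    warning("no same-sign null ES values; p at resolution floor")
    return(list(es = obs, nes = NA_real_, p = 1 / (nPerm + 1),
                nullES = nullES))
  }
  pval <- (1 + sum(abs(same) >= abs(obs))) / (1 + length(same))
  nes <- obs / mean(abs(same))
  list(es = obs, nes = nes, p = pval, nullES = nullES)
}

#' Pre-ranked gene-set enrichment over a collection
#'
#' Runs the weighted KS enrichment score, permutation null, NES and
#' nominal p for every set, then computes FDR q-values by the standard
#' sign-stratified observed-vs-null tail-ratio estimator: for a set with
#' normalized score NES*, q is the fraction of pooled same-sign null NES
#' values at least as extreme, divided by the fraction of observed
#' same-sign NES values at least as extreme, clipped to [0, 1].
#'
#' @param ranked a [RankedGenes-class].
#' @param sets named list of gene sets (e.g. from [readGmt()]).
#' @param nPerm permutations per set (>= 100).
#' @param seed integer seed (deterministic results for a fixed seed).
#' @param p metric weight exponent.
#' @param minSize,maxSize set-size restriction after intersecting each
#'   set with the ranked universe (defaults 15 and 500).
#' @return data.frame with columns `set`, `size`, `es`, `nes`, `p`, `q`,
#'   `n_perm`, ordered by `p`.
#' @export
gseaPreranked <- function(ranked, sets, nPerm = 1000, seed = 1L, p = 1,
                          minSize = 15, maxSize = 500) {
  stopifnot(is(ranked, "RankedGenes"), is.list(sets), !is.null(names(sets)))
  universe <- ranked@gene
  sets <- lapply(sets, function(s) intersect(unique(s), universe))
  size <- lengths(sets)
  keep <- size >= minSize & size <= pmin(maxSize, length(universe) - 1L)
  sets <- sets[keep]
  if (!length(sets)) stop("no sets within the size window")
  if (nPerm < 100) stop("nPerm must be >= 100")
  # shared permutation machinery: one null ES sample per distinct set
  # size, reused by every set of that size (duplicated sets therefore
  # get identical p, NES and q for a fixed seed)
  set.seed(seed)
  N <- length(universe)
  absw <- abs(ranked@metric)^p
  sizes <- sort(unique(lengths(sets)))
  seeds <- stats::setNames(sample.int(.Machine$integer.max,
                                      length(sizes)), sizes)
  nullBySize <- lapply(sizes, function(k) {
    set.seed(seeds[[as.character(k)]])
    vapply(seq_len(nPerm), function(i)
      .esFast(absw, N, sample.int(N, k)), numeric(1))
  })
  names(nullBySize) <- sizes
  res <- vector("list", length(sets))
  nullNES <- vector("list", length(sets))
  for (i in seq_along(sets)) {
    obs <- enrichmentScore(ranked, sets[[i]], p = p)$es
    nullES <- nullBySize[[as.character(length(sets[[i]]))]]
    same <- nullES[sign(nullES) == sign(obs)]
    if (!length(same)) {
      pv <- 1 / (nPerm + 1); nes <- NA_real_
    } else {
      pv <- (1 + sum(abs(same) >= abs(obs))) / (1 + length(same))
      nes <- obs / mean(abs(same))
    }
    res[[i]] <- data.frame(set = names(sets)[i], size = length(sets[[i]]),
                           es = obs, nes = nes, p = pv,
                           stringsAsFactors = FALSE)
    # normalize the null sample the same way as the observed score
    pos <- nullES[nullES > 0]; neg <- nullES[nullES < 0]
    nullNES[[i]] <- c(if (length(pos)) pos / mean(pos),
                      if (length(neg)) neg / abs(mean(neg)))
  }
  out <- do.call(rbind, res)
  pooledNull <- unlist(nullNES)
  out$q <- vapply(seq_len(nrow(out)), function(i) {
    nes <- out$nes[i]
    if (is.na(nes)) return(NA_real_)
    if (nes >= 0) {
      nullTail <- mean(pooledNull[pooledNull >= 0] >= nes)
      obsTail <- mean(out$nes[out$nes >= 0] >= nes)
    } else {
      nullTail <- mean(pooledNull[pooledNull < 0] <= nes)
      obsTail <- mean(out$nes[out$nes < 0] <= nes)
    }
    if (obsTail == 0) return(1)
    min(1, max(0, nullTail / obsTail))
  }, numeric(1))
  out$n_perm <- as.integer(nPerm)
  out[order(out$p), , drop = FALSE]
}
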