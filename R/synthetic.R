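#' Default multi-centre case-control cohort design
#'
#' Twelve study sites across Australia, continental Europe, the UK and the
#' USA totalling 4,508 cases (3,017 high-grade serous) and 3,368 controls,
#' the configuration the package's validation simulations are run under.
#' Several sites are case-only (clinical trial and registry series).
#'
#' @return data.frame with columns `study`, `region`, `n_controls`,
#'   `n_cases`, `hgs_fraction`, `age_lo`, `age_hi`.
#' @examples
#' colSums(defaultCohortDesign()[, c("n_controls", "n_cases")])
#' @export
defaultCohortDesign <- function() {
  d <- data.frame(
    study = c("AOC", "CAM", "GRR", "HJO", "ICN", "LAX", "MAY", "RMH",
              "SEA", "SRO", "STA", "UKO"),
    region = c("Australia", "UK", "USA", "Europe", "UK", "USA", "USA", "UK",
               "UK", "UK", "USA", "UK"),
    n_controls = c(629, 0, 0, 519, 0, 209, 660, 0, 835, 0, 147, 369),
    n_cases = c(589, 325, 124, 341, 412, 175, 650, 61, 700, 627, 151, 353),
    n_hgs = c(516, 196, 50, 107, 232, 175, 630, 61, 349, 318, 116, 267),
    age_lo = c(20, 19, 21, 18, 24, 32, 23, 27, 24, 18, 20, 25),
    age_hi = c(80, 90, 83, 88, 79, 90, 93, 73, 74, 84, 64, 90),
    stringsAsFactors = FALSE)
  d$hgs_fraction <- d$n_hgs / d$n_cases
  d$n_hgs <- NULL
  d
}

#' Simulate a case-control cohort
#'
#' Generates one record per subject with study, region, case/control
#' status, histologic subtype (`"hgs"` for high-grade serous, `"other"`
#' for other epithelial subtypes, `""` for controls) and an age drawn
#' uniformly within the study's age range. Per-study totals match the
#' design exactly; the number of high-grade serous cases per study is
#' `round(hgs_fraction * n_cases)`.
#'
#' @param design data.frame with columns `study`, `region`, `n_cases`,
#'   `n_controls`, `hgs_fraction` and optionally `age_lo`, `age_hi`;
#'   regions must be one of Australia, Europe, UK, USA.
#' @param seed integer seed; identical seeds give identical tables.
#' @return data.frame with columns `subject_id`, `study`, `region`,
#'   `status`, `subtype`, `age`.
#' @examples
#' subjects <- simulateCohort(seed = 1)
#' table(subjects$status)
#' @export
simulateCohort <- function(design = defaultCohortDesign(), seed = 1L) {
  need <- c("study", "region", "n_cases", "n_controls", "hgs_fraction")
  if (!all(need %in% names(design)))
    stop("design needs columns: ", paste(need, collapse = ", "))
  if (any(design$n_cases < 0) || any(design$n_controls < 0))
    stop("case and control counts must be >= 0")
  if (any(design$hgs_fraction < 0 | design$hgs_fraction > 1))
    stop("hgs_fraction must be in [0,1]")
  if (!all(design$region %in% c("Australia", "Europe", "UK", "USA")))
    stop("region must be one of Australia, Europe, UK, USA")
  set.seed(seed)
  rows <- lapply(seq_len(nrow(design)), function(i) {
    st <- design[i, ]
    nh <- round(st$hgs_fraction * st$n_cases)
    status <- c(rep("case", st$n_cases), rep("control", st$n_controls))
    subtype <- c(rep("hgs", nh), rep("other", st$n_cases - nh),
                 rep("", st$n_controls))
    n <- st$n_cases + st$n_controls
    if (n == 0L) return(NULL)
    age <- if (!is.null(st$age_lo) && !is.na(st$age_lo))
      sample(seq(st$age_lo, st$age_hi), n, replace = TRUE)
    else rep(NA_integer_, n)
    data.frame(subject_id = sprintf("%s_%04d", st$study, seq_len(n)),
               study = st$study, region = st$region, status = status,
               subtype = subtype, age = age, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Simulate per-gene carrier status with known effect sizes
#'
#' Controls carry a deleterious variant in a gene with probability `f0`;
#' cases carry with probability derived from the subtype-specific odds
#' ratio by exact odds conversion, `p1 = f0 * OR / (1 - f0 + f0 * OR)`.
#' Carrier status is drawn independently per gene (dominant single-carrier
#' model; with carrier frequencies well below 1% homozygotes are
#' negligible). Each carrier is assigned a variant identity: with
#' probability `recurrent_frac` the gene's designated recurrent allele
#' (fixed 3'-end cDNA position), otherwise a private variant at a uniform
#' cDNA position.
#'
#' @param subjects data.frame from [simulateCohort()].
#' @param effects data.frame with columns `gene`, `f0`, `or_hgs`,
#'   `or_other`, and optionally `recurrent_frac` (default 0) and
#'   `coding_length` (default 6000).
#' @param seed integer seed.
#' @return data.frame with one row per subject x gene: `subject_id`,
#'   `gene`, `carrier` (logical), `variant_id`, `cdna_pos` (NA for
#'   non-carriers).
#' @examples
#' subjects <- simulateCohort(seed = 1)
#' eff <- data.frame(gene = "GENE1", f0 = 0.0038, or_hgs = 2.5,
#'                   or_other = 1.0)
#' flags <- simulateCarrierStatus(subjects, eff, seed = 2)
#' mean(flags$carrier[subjects$status == "control"])
#' @export
simulateCarrierStatus <- function(subjects, effects, seed = 1L) {
  stopifnot(all(c("gene", "f0", "or_hgs", "or_other") %in% names(effects)))
  if (any(effects$f0 < 0 | effects$f0 >= 0.05))
    stop("f0 must be in [0, 0.05)")
  if (any(effects$or_hgs <= 0) || any(effects$or_other <= 0))
    stop("odds ratios must be > 0")
  bad <- !(subjects$subtype %in% c("hgs", "other", ""))
  if (any(bad)) stop("unknown subtype: ", unique(subjects$subtype[bad])[1])
  if (is.null(effects$recurrent_frac)) effects$recurrent_frac <- 0
  if (is.null(effects$coding_length)) effects$coding_length <- 6000L
  set.seed(seed)
  oddsToP <- function(f0, or) f0 * or / (1 - f0 + f0 * or)
  out <- lapply(seq_len(nrow(effects)), function(i) {
    e <- effects[i, ]
    p <- ifelse(subjects$status == "control", e$f0,
                ifelse(subjects$subtype == "hgs", oddsToP(e$f0, e$or_hgs),
                       oddsToP(e$f0, e$or_other)))
    carrier <- stats::rbinom(nrow(subjects), 1L, p) == 1L
    variant_id <- rep(NA_character_, nrow(subjects))
    cdna_pos <- rep(NA_integer_, nrow(subjects))
    idx <- which(carrier)
    if (length(idx)) {
      rec <- stats::rbinom(length(idx), 1L, e$recurrent_frac) == 1L
      variant_id[idx] <- ifelse(rec, paste0(e$gene, "_recurrent"),
                                paste0(e$gene, "_v", seq_along(idx)))
      recPos <- as.integer(round(0.95 * e$coding_length))
      cdna_pos[idx] <- ifelse(rec, recPos,
                              sample.int(e$coding_length, length(idx),
                                         replace = TRUE))
    }
    data.frame(subject_id = subjects$subject_id, gene = e$gene,
               carrier = carrier, variant_id = variant_id,
               cdna_pos = cdna_pos, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Simulate read-level evidence for carrier and non-carrier sites
#'
#' Every subject receives one sequencing observation per gene: read depth
#' drawn from a negative-binomial distribution, and alternate reads drawn
#' binomially at a latent allele fraction -- centred near 0.5 (truncated
#' to [0,1]) for true heterozygous carriers, or at the background
#' sequencing-error fraction for non-carriers. The emitted records carry
#' depth and alternate-read counts sufficient for the tiered calling
#' rules.
#'
#' @param carrierFlags data.frame from [simulateCarrierStatus()].
#' @param meanDepth mean read depth (> 0).
#' @param dispersion negative-binomial size parameter (larger = tighter).
#' @param hetCenter latent allele-fraction centre for carriers (~0.5).
#' @param hetSpread standard deviation of the latent carrier fraction.
#' @param errorRate background alternate-allele fraction for non-carriers.
#' @param seed integer seed.
#' @return data.frame of variant observations in the package TSV dialect
#'   (`subject_id`, `gene`, `variant_id`, `cdna_pos`, `consequence`,
#'   `depth`, `alt_reads`, `true_carrier`).
#' @export
simulateReadEvidence <- function(carrierFlags, meanDepth = 300,
                                 dispersion = 8, hetCenter = 0.5,
                                 hetSpread = 0.05, errorRate = 0.01,
                                 seed = 1L) {
  if (meanDepth <= 0) stop("meanDepth must be > 0")
  if (hetCenter < 0 || hetCenter > 1 || errorRate < 0 || errorRate > 1)
    stop("allele fractions must be in [0,1]")
  set.seed(seed)
  n <- nrow(carrierFlags)
  depth <- stats::rnbinom(n, size = dispersion, mu = meanDepth)
  frac <- ifelse(carrierFlags$carrier,
                 pmin(1, pmax(0, stats::rnorm(n, hetCenter, hetSpread))),
                 errorRate)
  alt <- stats::rbinom(n, depth, frac)
  data.frame(subject_id = carrierFlags$subject_id,
             gene = carrierFlags$gene,
             variant_id = ifelse(carrierFlags$carrier,
                                 carrierFlags$variant_id,
                                 paste0(carrierFlags$gene, "_bg")),
             cdna_pos = carrierFlags$cdna_pos,
             consequence = ifelse(carrierFlags$carrier, "nonsense", "other"),
             depth = depth, alt_reads = alt,
             true_carrier = carrierFlags$carrier,
             stringsAsFactors = FALSE)
}

#' Simulate a gene universe with pathway-enriched mutation counts
#'
#' Coding lengths are drawn log-normally; the total truncating-mutation
#' count of each gene over `nCases` cases is Poisson with expectation
#' `nCases * mu * length * multiplier`, where the multiplier exceeds 1
#' only for genes inside designated enriched sets.
#'
#' @param nGenes number of genes in the universe.
#' @param mu baseline truncating-mutation rate per coding base per case.
#' @param nCases number of cases the counts aggregate over.
#' @param setSpecs data.frame with columns `name`, `size`, `multiplier`
#'   (>= 1); members are sampled from the universe. Alternatively supply
#'   `sets`, an explicit named list of member vectors with a `multipliers`
#'   vector aligned to it.
#' @param sets explicit named list of gene sets (overrides `setSpecs`).
#' @param multipliers numeric vector parallel to `sets` when `sets` given.
#' @param lengthMeanlog,lengthSdlog log-normal coding-length parameters
#'   (defaults give a median near 1.5 kb).
#' @param seed integer seed.
#' @return list with `genes` (data.frame `gene`, `coding_length`,
#'   `count`) and `sets` (named list of member vectors).
#' @export
simulateGeneUniverse <- function(nGenes = 1000, mu = 2e-6, nCases = 412,
                                 setSpecs = NULL, sets = NULL,
                                 multipliers = NULL,
                                 lengthMeanlog = log(1500),
                                 lengthSdlog = 0.6, seed = 1L) {
  if (mu < 0) stop("mu must be >= 0")
  set.seed(seed)
  genes <- sprintf("G%04d", seq_len(nGenes))
  len <- round(stats::rlnorm(nGenes, lengthMeanlog, lengthSdlog))
  len <- pmax(len, 100)
  if (is.null(sets)) {
    sets <- list(); multipliers <- numeric()
    if (!is.null(setSpecs)) {
      if (any(setSpecs$size > nGenes))
        stop("set size exceeds universe size")
      if (any(setSpecs$multiplier < 1)) stop("multipliers must be >= 1")
      for (i in seq_len(nrow(setSpecs))) {
        sets[[setSpecs$name[i]]] <- sample(genes, setSpecs$size[i])
        multipliers <- c(multipliers, setSpecs$multiplier[i])
      }
    }
  } else {
    if (is.null(multipliers)) multipliers <- rep(1, length(sets))
    unknown <- setdiff(unlist(sets), genes)
    if (length(unknown))
      stop("set references unknown gene: ", unknown[1])
  }
  mult <- rep(1, nGenes)
  names(mult) <- genes
  for (i in seq_along(sets))
    mult[sets[[i]]] <- pmax(mult[sets[[i]]], multipliers[i])
  count <- stats::rpois(nGenes, nCases * mu * len * mult)
  list(genes = data.frame(gene = genes, coding_length = len, count = count,
                          stringsAsFactors = FALSE),
       sets = sets)
}

#' Simulate an age-band incidence table calibrated to a lifetime risk
#'
#' Builds 5-year age bands from 0 to `maxAge` with an age-increasing
#' shape (`rate` proportional to midpoint age raised to `exponent`, or
#' flat), then rescales all rates so the cumulative risk
#' `1 - exp(-sum(rate * width))` equals `targetRisk` exactly.
#'
#' @param targetRisk cumulative risk to `maxAge`, in (0, 0.1).
#' @param shape `"power"` (age-increasing) or `"flat"`.
#' @param exponent power-law exponent for the `"power"` shape.
#' @param maxAge final age boundary (default 80).
#' @param bandWidth band width in years (default 5).
#' @return An [IncidenceTable-class] whose cumulative risk matches
#'   `targetRisk` to well within 1e-6.
#' @examples
#' inc <- simulateIncidenceTable(0.018)
#' 1 - exp(-sum(rates(inc) * 5))
#' @export
simulateIncidenceTable <- function(targetRisk = 0.018,
                                   shape = c("power", "flat"),
                                   exponent = 5, maxAge = 80,
                                   bandWidth = 5) {
  shape <- match.arg(shape)
  if (targetRisk <= 0 || targetRisk >= 0.1)
    stop("targetRisk must be in (0, 0.1)")
  lo <- seq(0, maxAge - bandWidth, by = bandWidth)
  hi <- lo + bandWidth
  mid <- (lo + hi) / 2
  raw <- switch(shape, power = mid^exponent, flat = rep(1, length(mid)))
  totalHaz <- -log(1 - targetRisk)
  rate <- raw * totalHaz / sum(raw * bandWidth)
  inc <- IncidenceTable(lo, hi, rate)
  achieved <- 1 - exp(-sum(rate * bandWidth))
  if (abs(achieved - targetRisk) > 1e-6)
    stop("incidence calibration failed")
  inc
}
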