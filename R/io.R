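#' Read gene sets from a GMT file
#'
#' GMT: one set per line, tab-separated: name, description, members.
#'
#' @param path path to a GMT file.
#' @return Named list of character vectors (set members); the description
#'   field is kept in the `"description"` attribute of each element.
#' @export
readGmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  sets <- lapply(lines, function(l) {
    f <- strsplit(l, "\t", fixed = TRUE)[[1]]
    if (length(f) < 3L)
      stop("malformed GMT line (need name, description, >=1 member): ", l)
    members <- f[-(1:2)]
    members <- members[nzchar(members)]
    attr(members, "description") <- f[2]
    members
  })
  names(sets) <- vapply(lines, function(l)
    strsplit(l, "\t", fixed = TRUE)[[1]][1], character(1), USE.NAMES = FALSE)
  if (anyDuplicated(names(sets))) stop("duplicate gene-set names in GMT")
  sets
}

#' Write gene sets to a GMT file
#'
#' @param sets named list of character vectors.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeGmt <- function(sets, path) {
  stopifnot(is.list(sets), !is.null(names(sets)))
  lines <- vapply(names(sets), function(nm) {
    desc <- attr(sets[[nm]], "description")
    if (is.null(desc)) desc <- "na"
    paste(c(nm, desc, sets[[nm]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read an incidence table from CSV
#'
#' Expected columns: `age_lo`, `age_hi`, `rate_per_year`.
#'
#' @param path CSV path.
#' @return An [IncidenceTable-class].
#' @export
readIncidenceTable <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("age_lo", "age_hi", "rate_per_year")
  if (!all(need %in% names(d)))
    stop("incidence CSV needs columns: ", paste(need, collapse = ", "))
  d <- d[order(d$age_lo), , drop = FALSE]
  IncidenceTable(d$age_lo, d$age_hi, d$rate_per_year)
}

#' Write an incidence table to CSV
#'
#' @param inc an [IncidenceTable-class].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
writeIncidenceTable <- function(inc, path) {
  b <- ageBands(inc)
  utils::write.csv(data.frame(age_lo = b[, "lo"], age_hi = b[, "hi"],
                              rate_per_year = rates(inc)),
                   path, row.names = FALSE)
  invisible(path)
}

#' Read a subject table from CSV
#'
#' Expected columns: `subject_id`, `study`, `region`, `status`
#' (`case`/`control`), `subtype` (`hgs`/`other`/empty for controls) and
#' optionally `age`.
#'
#' @param path CSV path.
#' @return data.frame of subjects.
#' @export
readSubjects <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("subject_id", "study", "region", "status", "subtype")
  if (!all(need %in% names(d)))
    stop("subject CSV needs columns: ", paste(need, collapse = ", "))
  d$subtype[is.na(d$subtype)] <- ""
  d
}

#' Write a subject table to CSV
#'
#' @param subjects data.frame from [simulateCohort()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
writeSubjects <- function(subjects, path) {
  utils::write.csv(subjects, path, row.names = FALSE)
  invisible(path)
}

#' Read variant observations from the package TSV dialect
#'
#' Tab-separated with a header; minimally `subject_id`, `gene`,
#' `variant_id`, `consequence`, `depth`, `alt_reads`; optional columns
#' (`cdna_pos`, `maf`, `sift`, `polyphen`, `provean`, `s_ref`, `s_var`)
#' are carried through and filled with NA when absent.
#'
#' @param path TSV path.
#' @return data.frame of variant observations.
#' @export
readVariantsTSV <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("subject_id", "gene", "variant_id", "consequence", "depth",
            "alt_reads")
  if (!all(need %in% names(d)))
    stop("variant TSV needs columns: ", paste(need, collapse = ", "))
  for (col in c("cdna_pos", "maf", "sift", "provean", "s_ref", "s_var"))
    if (is.null(d[[col]])) d[[col]] <- NA_real_
  if (is.null(d$polyphen)) d$polyphen <- NA_character_
  if (any(d$alt_reads > d$depth, na.rm = TRUE))
    stop("alt_reads must not exceed depth")
  d
}

#' Write variant observations to the package TSV dialect
#'
#' @param variants data.frame of variant observations.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
writeVariantsTSV <- function(variants, path) {
  utils::write.table(variants, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read variant observations from a VCF with per-sample DP/AD
#'
#' Uses VariantAnnotation to parse a (plain-text) VCF whose genotype
#' fields carry read depth (`DP`) and allelic depths (`AD`), and whose
#' INFO field carries `GENE` and `CSQ` (consequence class) annotations,
#' and converts it to the package's variant-observation data.frame (one
#' row per sample with at least one alternate read).
#'
#' @param path VCF path.
#' @return data.frame as from [readVariantsTSV()].
#' @export
readVariantsVCF <- function(path) {
  if (!requireNamespace("VariantAnnotation", quietly = TRUE))
    stop("readVariantsVCF requires the VariantAnnotation package")
  vcf <- VariantAnnotation::readVcf(path)
  dp <- VariantAnnotation::geno(vcf)$DP
  ad <- VariantAnnotation::geno(vcf)$AD
  if (is.null(dp) || is.null(ad))
    stop("VCF must carry DP and AD genotype fields")
  info <- VariantAnnotation::info(vcf)
  gene <- as.character(info$GENE)
  csq <- as.character(info$CSQ)
  maf <- if (!is.null(info$AF)) as.numeric(unlist(info$AF)) else NA_real_
  ids <- rownames(vcf)
  samples <- colnames(dp)
  out <- do.call(rbind, lapply(seq_along(ids), function(i) {
    alt <- vapply(seq_along(samples), function(j) {
      x <- ad[i, j][[1]]
      if (length(x) >= 2) as.numeric(x[2]) else 0
    }, numeric(1))
    keep <- which(alt > 0)
    if (!length(keep)) return(NULL)
    data.frame(subject_id = samples[keep], gene = gene[i],
               variant_id = ids[i], consequence = csq[i],
               depth = as.numeric(dp[i, keep]), alt_reads = alt[keep],
               maf = maf[min(i, length(maf))], stringsAsFactors = FALSE)
  }))
  if (is.null(out))
    out <- data.frame(subject_id = character(), gene = character(),
                      variant_id = character(), consequence = character(),
                      depth = numeric(), alt_reads = numeric(),
                      maf = numeric(), stringsAsFactors = FALSE)
  for (col in c("cdna_pos", "sift", "provean", "s_ref", "s_var"))
    out[[col]] <- NA_real_
  out$polyphen <- NA_character_
  out
}

#' Read a two-column ranked gene list
#'
#' @param path TSV path with columns `gene`, `metric`.
#' @return A [RankedGenes-class] (re-sorted descending, ties broken
#'   lexicographically).
#' @export
readRankedGenes <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("gene", "metric") %in% names(d)))
    stop("ranked-list TSV needs columns gene, metric")
  o <- order(-d$metric, d$gene)
  new("RankedGenes", gene = d$gene[o], metric = d$metric[o])
}

#' Write a ranked gene list to TSV
#'
#' @param ranked a [RankedGenes-class].
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
writeRankedGenes <- function(ranked, path) {
  utils::write.table(data.frame(gene = rankedGenes(ranked),
                                metric = ranked@metric),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
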