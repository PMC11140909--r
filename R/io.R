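#' @include AllClasses.R
NULL

SUMMARY_HEADER <- c(CHR = "chrom", POS = "pos", ID = "id", EA = "ea",
                    OA = "oa", EAF = "eaf", BETA = "beta", SE = "se",
                    P = "p", N = "n", K = "k")

# Provenance header written at the top of every pipeline TSV; content is a
# pure function of (stage, seed, config) so reruns are byte-identical.
provenanceHeader <- function(stage, seed, configHash) {
  sprintf("## portaPRS stage=%s seed=%d config=%s", stage, seed, configHash)
}

writeTsv <- function(d, path, header = NULL) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  if (!is.null(header)) writeLines(header, con)
  utils::write.table(d, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a summary-statistics TSV
#'
#' Expects the fixed header CHR POS ID EA OA EAF BETA SE P N K (any order,
#' case-insensitive, K optional and defaulting to 1; extra columns are
#' tolerated and ignored; `##` comment lines are skipped). Rows with a
#' missing or non-positive SE are dropped and counted in
#' `attr(, "nDropped")`.
#'
#' @param path file path.
#' @return summary-stat data.frame (chrom, pos, id, ea, oa, eaf, beta, se,
#'   p, n, k).
#' @export
readSummaryStats <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE, comment.char = "#")
  names(d) <- toupper(names(d))
  need <- setdiff(names(SUMMARY_HEADER), "K")
  missing <- setdiff(need, names(d))
  if (length(missing))
    stop("summary-stat file lacks columns: ", paste(missing, collapse = ", "))
  if (!"K" %in% names(d)) d$K <- 1L
  out <- d[, names(SUMMARY_HEADER)]
  names(out) <- unname(SUMMARY_HEADER)
  bad <- !is.finite(out$se) | out$se <= 0
  attr(out, "nDropped") <- sum(bad)
  out <- out[!bad, , drop = FALSE]
  rownames(out) <- NULL
  out$chrom <- as.character(out$chrom)
  out
}

#' Write a summary-statistics TSV
#'
#' @param stats summary-stat data.frame (package column names).
#' @param path output path.
#' @param header optional provenance header line(s).
#' @export
writeSummaryStats <- function(stats, path, header = NULL) {
  out <- stats[, unname(SUMMARY_HEADER)[unname(SUMMARY_HEADER) %in% names(stats)]]
  names(out) <- names(SUMMARY_HEADER)[match(names(out), unname(SUMMARY_HEADER))]
  writeTsv(out, path, header)
}

#' Read genotypes from VCF or dosage TSV
#'
#' VCF v4.2 is parsed with vcfR: GT fields are converted to effect (ALT)
#' allele counts, multi-allelic records are dropped and counted, missing
#' genotypes are mean-imputed to twice the observed ALT frequency (counted
#' per variant in `attr(, "nImputed")`). Files ending in `.tsv` are read as
#' the package's dosage TSV (columns CHR POS ID REF ALT then one column per
#' individual).
#'
#' @param path path to a `.vcf` or `.tsv` file.
#' @param populations per-individual population labels (default "pop1").
#' @return a [GenotypePanel-class]; `attr(, "nMultiallelic")` counts dropped
#'   records for VCF input.
#' @export
readGenotypes <- function(path, populations = "pop1") {
  if (grepl("\\.vcf(\\.gz)?$", path)) readGenotypesVcf(path, populations)
  else readGenotypesTsv(path, populations)
}

readGenotypesVcf <- function(path, populations = "pop1") {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  multi <- grepl(",", fix$ALT) | nchar(fix$REF) != 1 | nchar(fix$ALT) != 1
  gt <- vcfR::extract.gt(v, element = "GT")
  gt <- gt[!multi, , drop = FALSE]
  fix <- fix[!multi, , drop = FALSE]
  count <- function(g) {
    a <- strsplit(gsub("\\|", "/", g), "/", fixed = TRUE)
    vapply(a, function(x) {
      x <- suppressWarnings(as.integer(x))
      if (anyNA(x)) NA_integer_ else sum(x > 0L)
    }, integer(1))
  }
  dos <- t(apply(gt, 1, count))
  nImp <- rowSums(is.na(dos))
  dosNum <- dos
  storage.mode(dosNum) <- "double"
  for (i in which(nImp > 0)) {
    # mean-impute to 2 x observed EAF, the convention of C+T scoring tools
    dosNum[i, is.na(dosNum[i, ])] <- mean(dosNum[i, ], na.rm = TRUE)
  }
  dos <- t(dosNum)
  panel <- genotypePanel(
    dos,
    data.frame(chrom = fix$CHROM, pos = as.numeric(fix$POS), id = fix$ID,
               ref = fix$REF, alt = fix$ALT, stringsAsFactors = FALSE),
    populations = populations)
  attr(panel, "nMultiallelic") <- sum(multi)
  attr(panel, "nImputed") <- sum(nImp)
  panel
}

readGenotypesTsv <- function(path, populations = "pop1") {
  d <- utils::read.delim(path, stringsAsFactors = FALSE, comment.char = "#",
                         check.names = FALSE)
  meta <- c("CHR", "POS", "ID", "REF", "ALT")
  stopifnot(all(meta %in% names(d)))
  dosCols <- setdiff(names(d), meta)
  dos <- t(as.matrix(d[, dosCols, drop = FALSE]))
  storage.mode(dos) <- "double"
  genotypePanel(dos,
                data.frame(chrom = as.character(d$CHR), pos = d$POS,
                           id = d$ID, ref = d$REF, alt = d$ALT,
                           stringsAsFactors = FALSE),
                populations = populations)
}

#' Write a GenotypePanel as dosage TSV
#'
#' Columns CHR POS ID REF ALT followed by one dosage column per individual.
#'
#' @param panel a [GenotypePanel-class].
#' @param path output path.
#' @param header optional provenance header line(s).
#' @export
writeGenotypesTsv <- function(panel, path, header = NULL) {
  v <- variants(panel)
  d <- cbind(data.frame(CHR = v$chrom, POS = v$pos, ID = v$id, REF = v$ref,
                        ALT = v$alt, stringsAsFactors = FALSE),
             as.data.frame(t(dosages(panel))))
  names(d)[-(1:5)] <- paste0("I", seq_len(nIndividuals(panel)))
  writeTsv(d, path, header)
}

#' Write a GenotypePanel as VCF v4.2 (GT field)
#'
#' Dosages 0/1/2 become 0/0, 0/1, 1/1; missing dosages become ./.;
#' positions are written 1-based.
#'
#' @param panel a [GenotypePanel-class].
#' @param path output path.
#' @export
writeGenotypesVcf <- function(panel, path) {
  v <- variants(panel)
  n <- nIndividuals(panel)
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", paste0("I", seq_len(n))),
                     collapse = "\t")), con)
  gtmap <- c("0/0", "0/1", "1/1")
  D <- dosages(panel)
  for (j in seq_len(nVariants(panel))) {
    g <- round(D[, j])
    gt <- ifelse(is.na(g), "./.", gtmap[g + 1L])
    writeLines(paste(c(v$chrom[j], v$pos[j], v$id[j], v$ref[j], v$alt[j],
                       ".", "PASS", ".", "GT", gt), collapse = "\t"), con)
  }
  invisible(path)
}

#' Write the simulation truth table
#'
#' Causal variant ids, their effects, and the architecture's interaction
#' coefficients, as a plain TSV for parameter-recovery checks.
#'
#' @param truth the `attr(, "truth")` list from [simulatePhenotypes()].
#' @param path output path.
#' @param header optional provenance header line(s).
#' @export
writeTruth <- function(truth, path, header = NULL) {
  d <- data.frame(ID = truth$causalId, BETA = truth$beta,
                  stringsAsFactors = FALSE)
  extra <- c(sprintf("## h2=%g sexEffectRatio=%g", truth$h2,
                     truth$sexEffectRatio),
             if (length(truth$gxeTerms))
               sprintf("## gxe %s=%g", names(truth$gxeTerms), truth$gxeTerms))
  writeTsv(d, path, c(header, extra))
}
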