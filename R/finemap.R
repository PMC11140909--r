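#' @include AllClasses.R utils.R
NULL

#' Define genome-wide-significant loci
#'
#' Greedy lead selection: repeatedly take the smallest remaining p-value
#' below the significance threshold as a lead SNP, discard all significant
#' variants within `minSeparation` of it on the same chromosome, and define
#' the locus as lead +/- `flank` (clipped at position 1). Distinct leads are
#' therefore separated by at least `minSeparation`.
#'
#' @param meta summary-stat table (chrom, pos, id, p at minimum).
#' @param pThreshold genome-wide significance threshold (default 5e-8).
#' @param minSeparation minimum lead separation in bp (default 1e6).
#' @param flank locus half-width in bp (default 1e6).
#' @return data.frame of loci: chrom, leadPos, leadId, leadP, start, end.
#' @export
defineLoci <- function(meta, pThreshold = 5e-8, minSeparation = 1e6,
                       flank = 1e6) {
  sig <- meta[!is.na(meta$p) & meta$p < pThreshold, , drop = FALSE]
  empty <- data.frame(chrom = character(), leadPos = numeric(),
                      leadId = character(), leadP = numeric(),
                      start = numeric(), end = numeric(),
                      stringsAsFactors = FALSE)
  if (!nrow(sig)) return(empty)
  sig <- sig[order(sig$p, sig$chrom, sig$pos), , drop = FALSE]
  active <- rep(TRUE, nrow(sig))
  leads <- integer()
  for (i in seq_len(nrow(sig))) {
    if (!active[i]) next
    leads <- c(leads, i)
    near <- active & sig$chrom == sig$chrom[i] &
      abs(sig$pos - sig$pos[i]) < minSeparation
    active[near] <- FALSE
  }
  L <- sig[leads, , drop = FALSE]
  out <- data.frame(chrom = L$chrom, leadPos = L$pos, leadId = L$id,
                    leadP = L$p, start = pmax(1, L$pos - flank),
                    end = L$pos + flank, stringsAsFactors = FALSE)
  out[order(out$chrom, out$leadPos), , drop = FALSE]
}

#' Approximate Bayes factor from a meta-analysis z-score
#'
#' \deqn{BF_i = \exp[(Z_i^2 - \log K_i)/2],} where K_i is the number of
#' studies reporting the variant. Computed in log space; `log = TRUE`
#' returns log(BF) directly, which is the form all downstream arithmetic
#' uses (z around 40 overflows the naive exponential).
#'
#' @param z association z-score(s).
#' @param k per-variant study count(s), >= 1.
#' @param log return log(BF) instead of BF.
#' @return Bayes factor(s) (or their logs).
#' @examples
#' bayesFactor(0, 1)            # 1
#' bayesFactor(5.45, 2)         # ~1.99e6
#' @export
bayesFactor <- function(z, k, log = FALSE) {
  if (any(k < 1)) stop("k must be >= 1")
  if (any(!is.finite(z))) stop("z must be finite")
  lbf <- (z^2 - base::log(k)) / 2
  if (log) lbf else exp(lbf)
}

#' 99% credible set for one locus
#'
#' Posterior probability that variant i drives the locus signal:
#' \eqn{\pi_i = BF_i / \sum_j BF_j}, evaluated via log-sum-exp. Variants are
#' ranked by posterior (ties broken by larger |z|, then smaller position)
#' and the minimal prefix whose cumulative posterior reaches the coverage
#' target forms the set.
#'
#' @param locusRows data.frame with columns id, pos, z, k for every variant
#'   at the locus.
#' @param coverageTarget required cumulative posterior (default 0.99).
#' @param locus optional locus descriptor list (as from [defineLoci()] rows).
#' @return a [CredibleSet-class].
#' @export
credibleSet <- function(locusRows, coverageTarget = 0.99, locus = list()) {
  if (!nrow(locusRows)) stop("empty locus")
  if (any(!is.finite(locusRows$z))) stop("z must be finite")
  lbf <- bayesFactor(locusRows$z, locusRows$k, log = TRUE)
  lpi <- lbf - logSumExp(lbf)
  pi <- exp(lpi)
  ord <- order(-pi, -abs(locusRows$z), locusRows$pos)
  r <- locusRows[ord, , drop = FALSE]
  pi <- pi[ord]
  cum <- cumsum(pi)
  nset <- which(cum >= coverageTarget - 1e-12)[1]
  if (is.na(nset)) nset <- nrow(r)
  rows <- data.frame(id = r$id, pos = r$pos, z = r$z, k = r$k,
                     logBF = lbf[ord], posterior = pi, cumulative = cum,
                     inSet = seq_len(nrow(r)) <= nset,
                     stringsAsFactors = FALSE)
  new("CredibleSet", locus = locus, rows = rows,
      coverage = cum[nset], coverageTarget = coverageTarget)
}

#' Fine-map all loci of a meta-analysis
#'
#' Defines loci with [defineLoci()] and builds one [credibleSet()] per locus
#' from all analyzed variants inside the locus window. Variants lacking a
#' usable z or k (e.g. reported in fewer than two studies and so absent from
#' the meta-analysis) are excluded from the credible-set denominator and
#' counted in the audit attribute.
#'
#' @param meta meta-analysis summary-stat table (needs chrom, pos, id, beta,
#'   se, k; z is beta/se).
#' @param pThreshold,minSeparation,flank locus-definition parameters.
#' @param coverageTarget credible-set coverage (default 0.99).
#' @return named list of [CredibleSet-class] objects keyed by
#'   "chrom:leadPos"; the locus table is attached as `attr(, "loci")`.
#' @export
fineMapLoci <- function(meta, pThreshold = 5e-8, minSeparation = 1e6,
                        flank = 1e6, coverageTarget = 0.99) {
  loci <- defineLoci(meta, pThreshold, minSeparation, flank)
  sets <- list()
  z <- meta$beta / meta$se
  for (i in seq_len(nrow(loci))) {
    inWin <- meta$chrom == loci$chrom[i] & meta$pos >= loci$start[i] &
      meta$pos <= loci$end[i] & is.finite(z)
    rows <- data.frame(id = meta$id[inWin], pos = meta$pos[inWin],
                       z = z[inWin], k = meta$k[inWin],
                       stringsAsFactors = FALSE)
    key <- paste0(loci$chrom[i], ":", loci$leadPos[i])
    sets[[key]] <- credibleSet(rows, coverageTarget,
                               locus = list(chrom = loci$chrom[i],
                                            leadId = loci$leadId[i],
                                            leadPos = loci$leadPos[i],
                                            leadP = loci$leadP[i],
                                            start = loci$start[i],
                                            end = loci$end[i]))
  }
  attr(sets, "loci") <- loci
  sets
}

#' Compare fine-mapping resolution between two analyses
#'
#' For loci shared between two credible-set collections (matched by locus
#' key), reports the median set size and single-variant-set count of each
#' analysis, plus the per-locus size pairs behind a resolution scatter.
#'
#' @param setsA,setsB named lists of [CredibleSet-class] objects.
#' @return list with `medianA`, `medianB`, `singlesA`, `singlesB`, and
#'   `pairs` (locus, sizeA, sizeB).
#' @export
compareResolution <- function(setsA, setsB) {
  shared <- intersect(names(setsA), names(setsB))
  if (!length(shared)) stop("no shared loci between the two analyses")
  sizeA <- vapply(setsA[shared], setSize, integer(1))
  sizeB <- vapply(setsB[shared], setSize, integer(1))
  list(medianA = stats::median(sizeA), medianB = stats::median(sizeB),
       singlesA = sum(sizeA == 1L), singlesB = sum(sizeB == 1L),
       pairs = data.frame(locus = shared, sizeA = sizeA, sizeB = sizeB,
                          row.names = NULL, stringsAsFactors = FALSE))
}
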