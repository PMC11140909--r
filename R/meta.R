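#' @include utils.R
NULL

STRAND_AMBIGUOUS <- c("A/T", "T/A", "C/G", "G/C")

variantKey <- function(chrom, pos, a1, a2) {
  paste(chrom, pos, pmin(a1, a2), pmax(a1, a2), sep = ":")
}

#' Harmonize summary statistics across studies
#'
#' Variants are keyed by (chromosome, position, sorted allele pair) — variant
#' ID strings are ignored since ID conventions differ across sources. Effect
#' sizes are flipped onto the orientation of the first study reporting each
#' key; strand-ambiguous pairs (A/T, C/G) are dropped, as are records whose
#' allele pair cannot be oriented. Duplicate keys within one study are an
#' error.
#'
#' @param studies named list of summary-stat tables (columns chrom, pos, id,
#'   ea, oa, eaf, beta, se, p, n).
#' @return a list with `beta`, `se`, `eaf`, `n` (variant-by-study matrices,
#'   NA where a study lacks the variant), `info` (key, chrom, pos, id, ea,
#'   oa of the reference orientation, k = study count) and `dropLog`
#'   (key, reason).
#' @export
harmonizeStudies <- function(studies) {
  if (is.null(names(studies)) || any(names(studies) == ""))
    names(studies) <- paste0("study", seq_along(studies))
  drop <- list()
  keyed <- lapply(names(studies), function(s) {
    d <- studies[[s]]
    key <- variantKey(d$chrom, d$pos, d$ea, d$oa)
    if (anyDuplicated(key)) {
      bad <- key[duplicated(key)][1]
      stop(sprintf("duplicate variant key '%s' in study '%s'", bad, s))
    }
    amb <- paste(d$ea, d$oa, sep = "/") %in% STRAND_AMBIGUOUS
    if (any(amb))
      drop[[s]] <<- data.frame(key = key[amb], reason = "strand_ambiguous",
                               study = s, stringsAsFactors = FALSE)
    d <- d[!amb, , drop = FALSE]
    d$key <- key[!amb]
    d
  })
  names(keyed) <- names(studies)
  allKeys <- unique(unlist(lapply(keyed, `[[`, "key")))
  S <- length(keyed)
  mk <- function() matrix(NA_real_, length(allKeys), S,
                          dimnames = list(allKeys, names(keyed)))
  B <- mk(); SE <- mk(); EAF <- mk(); N <- mk()
  info <- NULL
  for (s in seq_len(S)) {
    d <- keyed[[s]]
    i <- match(d$key, allKeys)
    if (is.null(info)) {
      info <- data.frame(key = allKeys, chrom = NA_character_, pos = NA_real_,
                         id = NA_character_, ea = NA_character_,
                         oa = NA_character_, stringsAsFactors = FALSE)
    }
    newKeys <- is.na(info$ea[i])
    info$chrom[i[newKeys]] <- d$chrom[newKeys]
    info$pos[i[newKeys]] <- d$pos[newKeys]
    info$id[i[newKeys]] <- d$id[newKeys]
    info$ea[i[newKeys]] <- d$ea[newKeys]
    info$oa[i[newKeys]] <- d$oa[newKeys]
    flip <- d$ea == info$oa[i] & d$oa == info$ea[i]
    same <- d$ea == info$ea[i] & d$oa == info$oa[i]
    bad <- !(flip | same)
    if (any(bad))
      drop[[paste0(names(keyed)[s], "_mismatch")]] <-
        data.frame(key = d$key[bad], reason = "allele_mismatch",
                   study = names(keyed)[s], stringsAsFactors = FALSE)
    sgn <- ifelse(flip, -1, 1)
    ok <- !bad
    B[i[ok], s] <- sgn[ok] * d$beta[ok]
    SE[i[ok], s] <- d$se[ok]
    EAF[i[ok], s] <- ifelse(flip[ok], 1 - d$eaf[ok], d$eaf[ok])
    N[i[ok], s] <- d$n[ok]
  }
  info$k <- rowSums(!is.na(B))
  dropLog <- if (length(drop)) do.call(rbind, unname(drop)) else
    data.frame(key = character(), reason = character(), study = character(),
               stringsAsFactors = FALSE)
  list(beta = B, se = SE, eaf = EAF, n = N, info = info, dropLog = dropLog)
}

#' Fixed-effects inverse-variance-weighted meta-analysis
#'
#' Combines per-study effects with weights \eqn{w_i = 1/SE_i^2}:
#' \eqn{\beta = \sum w_i \beta_i / \sum w_i}, \eqn{SE = (\sum w_i)^{-1/2}},
#' p from a two-sided normal test of beta/SE.
#'
#' @param betas,ses numeric vectors (one entry per study); all ses > 0.
#' @return list with `beta`, `se`, `p`, `z`.
#' @examples
#' ivwMeta(c(0.1, 0.1), c(0.05, 0.05))
#' @export
ivwMeta <- function(betas, ses) {
  if (!length(betas)) stop("need at least one study")
  if (any(ses <= 0)) stop("all standard errors must be positive")
  w <- 1 / ses^2
  beta <- sum(w * betas) / sum(w)
  se <- 1 / sqrt(sum(w))
  z <- beta / se
  list(beta = beta, se = se, p = 2 * stats::pnorm(-abs(z)), z = z)
}

# Row-wise IVW across the columns of beta/se matrices with NA gaps.
ivwMetaMatrix <- function(B, SE) {
  W <- 1 / SE^2
  W[is.na(B)] <- NA
  sw <- rowSums(W, na.rm = TRUE)
  beta <- rowSums(W * B, na.rm = TRUE) / sw
  se <- 1 / sqrt(sw)
  z <- beta / se
  data.frame(beta = beta, se = se, z = z, p = 2 * stats::pnorm(-abs(z)))
}

#' Genomic-control lambda
#'
#' \eqn{\lambda = median(z^2) / 0.4549364}, the ratio of the observed median
#' association chi-square to its null expectation. The value is reported
#' unclamped; correction routines clamp at 1 when applying it.
#'
#' @param zScores vector of association z-scores.
#' @param minVariants floor on the number of finite z-scores (default 100).
#' @return the lambda estimate.
#' @export
genomicControlLambda <- function(zScores, minVariants = 100L) {
  z <- zScores[is.finite(zScores)]
  if (length(z) < minVariants)
    stop(sprintf("need at least %d finite z-scores, got %d",
                 minVariants, length(z)))
  stats::median(z^2) / CHISQ1_MEDIAN
}

#' Meta-analysis with double genomic control
#'
#' Stage 1: each study's SEs are multiplied by the square root of its
#' supplied correction factor (an LDSC-intercept analogue; in `"auto"` mode
#' the study's own genomic-control lambda, clamped at 1, is used; studies
#' with an NA factor get 1). Stage 2: fixed-effects IVW meta-analysis of the
#' corrected statistics, keeping variants reported in at least `minStudies`
#' studies. Stage 3: the meta-analysis lambda is computed on the stage-2
#' z-scores and the meta SEs are inflated by its square root (clamped at 1),
#' with p-values recomputed.
#'
#' @param studies named list of summary-stat tables.
#' @param intercepts `"auto"`, or a numeric vector (one per study, NA for
#'   studies without an intercept, which get factor 1).
#' @param minStudies minimum study count per retained variant (default 2).
#' @return a list: `result` (final table with chrom, pos, id, ea, oa, eaf,
#'   beta, se, p, n, k and `stage` = "gc2"), `stages` (raw/gc1/gc2 audit
#'   tables of beta/se/z/p), `lambda` (perStudy, raw, gc1, gc2, applied),
#'   `dropLog` from harmonization.
#' @export
doubleGcMeta <- function(studies, intercepts = "auto", minStudies = 2L) {
  h <- harmonizeStudies(studies)
  S <- ncol(h$beta)
  Z <- h$beta / h$se
  lamStudy <- vapply(seq_len(S), function(s) {
    z <- Z[, s]
    z <- z[is.finite(z)]
    if (length(z) >= 100) stats::median(z^2) / CHISQ1_MEDIAN else NA_real_
  }, numeric(1))
  names(lamStudy) <- colnames(h$beta)
  if (identical(intercepts, "auto")) {
    fac <- pmax(lamStudy, 1)
    fac[is.na(fac)] <- 1
  } else {
    if (length(intercepts) != S)
      stop("need one intercept per study")
    if (any(intercepts <= 0, na.rm = TRUE))
      stop("intercepts must be positive")
    fac <- ifelse(is.na(intercepts), 1, intercepts)
  }
  keep <- h$info$k >= minStudies
  B <- h$beta[keep, , drop = FALSE]
  SE0 <- h$se[keep, , drop = FALSE]
  SE1 <- sweep(SE0, 2, sqrt(fac), `*`)
  raw <- ivwMetaMatrix(B, SE0)
  gc1 <- ivwMetaMatrix(B, SE1)
  lamRaw <- stats::median(raw$z^2, na.rm = TRUE) / CHISQ1_MEDIAN
  lamMeta <- stats::median(gc1$z^2, na.rm = TRUE) / CHISQ1_MEDIAN
  applied <- sqrt(max(lamMeta, 1))
  gc2 <- gc1
  gc2$se <- gc1$se * applied
  gc2$z <- gc2$beta / gc2$se
  gc2$p <- 2 * stats::pnorm(-abs(gc2$z))
  lamFinal <- stats::median(gc2$z^2, na.rm = TRUE) / CHISQ1_MEDIAN
  info <- h$info[keep, , drop = FALSE]
  eaf <- rowMeans(h$eaf[keep, , drop = FALSE], na.rm = TRUE)
  ntot <- rowSums(h$n[keep, , drop = FALSE], na.rm = TRUE)
  result <- data.frame(chrom = info$chrom, pos = info$pos, id = info$id,
                       ea = info$ea, oa = info$oa, eaf = eaf,
                       beta = gc2$beta, se = gc2$se, p = gc2$p,
                       n = ntot, k = info$k, stage = "gc2",
                       stringsAsFactors = FALSE)
  list(result = result,
       stages = list(raw = raw, gc1 = gc1, gc2 = gc2),
       lambda = list(perStudy = lamStudy, raw = lamRaw, gc1 = lamMeta,
                     gc2 = lamFinal, applied = applied^2),
       dropLog = h$dropLog)
}
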