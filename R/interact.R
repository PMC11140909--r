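#' @include prs.R
NULL

REFERENCE_LEVELS <- c(sex = "M", smoking = "never", alcohol = "never",
                      region = "East", physical_activity = "low",
                      ses = "low")

# Order a factor so the field's conventional reference level (never-smoker,
# never-consumer, male, East region, ...) is the baseline when known.
withReference <- function(x, name, reference = NULL) {
  x <- factor(x)
  ref <- reference
  if (is.null(ref) && name %in% names(REFERENCE_LEVELS) &&
      REFERENCE_LEVELS[[name]] %in% levels(x))
    ref <- REFERENCE_LEVELS[[name]]
  if (!is.null(ref)) x <- stats::relevel(x, ref = ref)
  x
}

#' Test PRS-by-modifier interaction
#'
#' OLS of the trait on standardized PRS, the modifier, their product and the
#' covariates. Categorical modifiers are dummy-coded against the reference
#' level (never/male/East by convention, overridable); continuous modifiers
#' are standardized. One estimate/SE/p row is returned per interaction
#' contrast, plus an omnibus F-test of all interaction terms jointly.
#'
#' @param pheno phenotype table with trait and covariates.
#' @param score per-individual PRS vector.
#' @param modifier name of the modifier column in `pheno`.
#' @param covariates covariate column names.
#' @param reference optional reference level for a categorical modifier.
#' @param standardizePrs standardize the PRS first (default TRUE).
#' @param traitCol trait column name.
#' @return list with `contrasts` (data.frame: term, estimate, se, pInt, n),
#'   `omnibusP`, `omnibusF`, `n`.
#' @export
fitInteraction <- function(pheno, score, modifier, covariates = character(),
                           reference = NULL, standardizePrs = TRUE,
                           traitCol = "trait") {
  stopifnot(length(score) == nrow(pheno))
  d <- pheno
  d$.prs <- if (standardizePrs) as.numeric(scale(score)) else score
  mod <- d[[modifier]]
  if (is.null(mod)) stop("modifier column not found: ", modifier)
  if (is.character(mod) || is.factor(mod)) {
    mod <- withReference(mod, modifier, reference)
    mod <- droplevels(mod)
    if (nlevels(mod) < 2) stop("modifier has a single level")
    d$.mod <- mod
  } else {
    if (stats::sd(mod, na.rm = TRUE) == 0) stop("modifier is constant")
    d$.mod <- as.numeric(scale(mod))
  }
  covTerm <- if (length(covariates))
    paste("+", paste(covariates, collapse = " + ")) else ""
  fFull <- stats::as.formula(
    paste(traitCol, "~ .prs * .mod", covTerm))
  fNull <- stats::as.formula(
    paste(traitCol, "~ .prs + .mod", covTerm))
  full <- stats::lm(fFull, data = d)
  null <- stats::lm(fNull, data = d)
  sm <- summary(full)$coefficients
  rows <- grep("^\\.prs:\\.mod", rownames(sm))
  lev <- sub("^\\.prs:\\.mod", "", rownames(sm)[rows])
  terms <- ifelse(lev == "", paste0("PRS x ", modifier),
                  paste0("PRS x ", modifier, "[", lev, "]"))
  contrasts <- data.frame(term = terms, estimate = sm[rows, 1],
                          se = sm[rows, 2], pInt = sm[rows, 4],
                          n = stats::nobs(full), row.names = NULL,
                          stringsAsFactors = FALSE)
  an <- stats::anova(null, full)
  list(contrasts = contrasts,
       omnibusP = an[["Pr(>F)"]][2], omnibusF = an[["F"]][2],
       n = stats::nobs(full))
}

#' Stratum-wise PRS evaluation with a pooled interaction test
#'
#' Evaluates the PRS's incremental R-squared separately in each level of a
#' stratifying column (e.g. region or sex) and tests PRS-by-stratum
#' interaction in the pooled model.
#'
#' @param pheno phenotype table.
#' @param score per-individual PRS vector.
#' @param stratum stratifying column name (>= 2 non-empty levels).
#' @param covariates covariate column names.
#' @param traitCol trait column name.
#' @return list with `perStratum` (stratum, n, incremental, r2Full, pPrs)
#'   and `interaction` (the pooled [fitInteraction()] result).
#' @export
stratifiedPrsEval <- function(pheno, score, stratum,
                              covariates = character(), traitCol = "trait") {
  lab <- factor(pheno[[stratum]])
  lab <- droplevels(lab)
  if (nlevels(lab) < 2) stop("need at least 2 strata")
  rows <- lapply(levels(lab), function(lv) {
    idx <- which(lab == lv)
    if (length(idx) <= length(covariates) + 2)
      stop("stratum '", lv, "' too small for the model")
    ev <- incrementalR2(pheno[idx, , drop = FALSE], score[idx],
                        covariates, traitCol)
    data.frame(stratum = lv, n = ev$n, incremental = ev$incremental,
               r2Full = ev$r2Full, pPrs = ev$pPrs,
               stringsAsFactors = FALSE)
  })
  inter <- fitInteraction(pheno, score, stratum, covariates,
                          traitCol = traitCol)
  list(perStratum = do.call(rbind, rows), interaction = inter)
}

#' Allele-frequency correlation between two panels
#'
#' Pearson correlation of effect-allele frequencies for variants shared by
#' two genotype panels (matched by id, oriented to the same effect allele).
#' Symmetric in its panel arguments.
#'
#' @param panelA,panelB [GenotypePanel-class] objects.
#' @param variantIds variants to compare (default: all shared ids).
#' @return list with `r`, `n`, and `table` (id, freqA, freqB).
#' @export
alleleFreqCorrelation <- function(panelA, panelB, variantIds = NULL) {
  vA <- variants(panelA)
  vB <- variants(panelB)
  ids <- if (is.null(variantIds)) intersect(vA$id, vB$id) else variantIds
  iA <- match(ids, vA$id)
  iB <- match(ids, vB$id)
  if (anyNA(iA) || anyNA(iB)) stop("some variants absent from a panel")
  fA <- alleleFrequencies(panelA)[iA]
  fB <- alleleFrequencies(panelB)[iB]
  flip <- vB$alt[iB] == vA$ref[iA] & vB$ref[iB] == vA$alt[iA]
  fB[flip] <- 1 - fB[flip]
  list(r = stats::cor(fA, fB), n = length(ids),
       table = data.frame(id = ids, freqA = as.numeric(fA),
                          freqB = as.numeric(fB), stringsAsFactors = FALSE))
}

#' LD decay profile of a panel
#'
#' Dosage-correlation r-squared for all variant pairs within `maxDistance`
#' on the same chromosome, binned by physical distance.
#'
#' @param panel a [GenotypePanel-class].
#' @param variantIds variants to profile (default all).
#' @param maxDistance maximum pair distance in bp.
#' @param bins number of distance bins.
#' @return data.frame with binStart, binEnd, binMid, meanR2, nPairs.
#' @export
ldDecayProfile <- function(panel, variantIds = NULL, maxDistance = 250000,
                           bins = 25) {
  v <- variants(panel)
  idx <- if (is.null(variantIds)) seq_len(nrow(v)) else match(variantIds, v$id)
  D <- dosages(panel)[, idx, drop = FALSE]
  storage.mode(D) <- "double"
  pos <- v$pos[idx]
  chrom <- v$chrom[idx]
  R <- suppressWarnings(stats::cor(D))
  pair <- which(upper.tri(R), arr.ind = TRUE)
  dist <- abs(pos[pair[, 1]] - pos[pair[, 2]])
  same <- chrom[pair[, 1]] == chrom[pair[, 2]]
  ok <- same & dist <= maxDistance
  r2 <- R[pair][ok]^2
  dist <- dist[ok]
  if (!length(dist)) stop("no variant pairs within maxDistance")
  edges <- seq(0, maxDistance, length.out = bins + 1)
  bin <- cut(dist, edges, include.lowest = TRUE, labels = FALSE)
  agg <- tapply(r2, bin, mean, na.rm = TRUE)
  cnt <- tapply(r2, bin, length)
  b <- as.integer(names(agg))
  data.frame(binStart = edges[b], binEnd = edges[b + 1],
             binMid = (edges[b] + edges[b + 1]) / 2,
             meanR2 = as.numeric(agg), nPairs = as.integer(cnt))
}

#' Fit the haplotype-correlation decay scale to an LD profile
#'
#' The simulator realizes LD through thresholded Gaussian haplotypes whose
#' latent correlation at distance d is exp(-d/s). For alleles near frequency
#' one-half the allele-indicator correlation is the arcsine-transformed
#' latent correlation, so the binned dosage r-squared follows
#' \deqn{r^2(d) \approx a\,[(2/\pi)\,\arcsin(e^{-d/s})]^2,}
#' which this routine fits by nonlinear least squares (a plain
#' a*exp(-2d/s) profile is the fallback if the fit fails). `s` is directly
#' comparable to the simulator's `ldDecayBp`.
#'
#' @param profile output of [ldDecayProfile()].
#' @return list with `scaleBp` and `amplitude`.
#' @export
fitLdDecay <- function(profile) {
  d <- profile$binMid
  y <- profile$meanR2
  pos <- y > 1e-6
  slope <- stats::coef(stats::lm(log(y[pos]) ~ d[pos]))[2]
  sStart <- if (is.finite(slope) && slope < 0) -2 / slope else max(d) / 2
  fit <- try(stats::nls(y ~ a * ((2 / pi) * asin(exp(-d / s)))^2,
                        start = list(a = max(y), s = sStart),
                        control = stats::nls.control(warnOnly = TRUE)),
             silent = TRUE)
  if (inherits(fit, "try-error"))
    fit <- try(stats::nls(y ~ a * exp(-2 * d / s),
                          start = list(a = max(y), s = sStart),
                          control = stats::nls.control(warnOnly = TRUE)),
               silent = TRUE)
  if (inherits(fit, "try-error"))
    return(list(scaleBp = as.numeric(sStart), amplitude = max(y)))
  co <- stats::coef(fit)
  list(scaleBp = unname(co["s"]), amplitude = unname(co["a"]))
}
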