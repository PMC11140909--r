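#' @include AllClasses.R assoc.R
NULL

#' LD clumping against a target genotype panel
#'
#' Greedy pass in ascending p-value order (ties broken by smaller position):
#' each index variant is retained and every not-yet-processed variant within
#' `distance` bp whose dosage-correlation r-squared with the index exceeds
#' `r2Threshold` is removed. LD is computed in the supplied target panel, as
#' C+T implementations do when clumping against target genotypes. Summary
#' variants absent from the panel are dropped and counted.
#'
#' @param summary summary-stat table (chrom, pos, id, p).
#' @param panel target [GenotypePanel-class] providing LD.
#' @param distance clumping window half-width in bp (default 250000).
#' @param r2Threshold r-squared above which a neighbor is removed
#'   (default 0.8).
#' @return the retained subset of `summary`, ordered by ascending p;
#'   `attr(, "nUnmatched")` counts summary variants missing from the panel.
#' @export
clumpVariants <- function(summary, panel, distance = 250000,
                          r2Threshold = 0.8) {
  idx <- match(summary$id, variants(panel)$id)
  unmatched <- sum(is.na(idx))
  keep <- !is.na(idx) & is.finite(summary$p)
  if (!any(keep)) stop("no overlap between summary statistics and panel")
  s <- summary[keep, , drop = FALSE]
  pidx <- idx[keep]
  ord <- order(s$p, s$pos)
  s <- s[ord, , drop = FALSE]
  pidx <- pidx[ord]
  D <- dosages(panel)
  storage.mode(D) <- "double"
  active <- rep(TRUE, nrow(s))
  retained <- logical(nrow(s))
  for (i in seq_len(nrow(s))) {
    if (!active[i]) next
    retained[i] <- TRUE
    active[i] <- FALSE
    cand <- which(active & s$chrom == s$chrom[i] &
                    abs(s$pos - s$pos[i]) <= distance)
    if (!length(cand)) next
    r <- suppressWarnings(
      stats::cor(D[, pidx[i]], D[, pidx[cand], drop = FALSE]))
    r2 <- as.numeric(r)^2
    r2[is.na(r2)] <- 0
    active[cand[r2 > r2Threshold]] <- FALSE
  }
  out <- s[retained, , drop = FALSE]
  attr(out, "nUnmatched") <- unmatched
  out
}

#' Score individuals with a PRS model
#'
#' Additive scoring: each individual's score is the sum over model variants
#' of beta times the dosage of the effect allele. Model variants whose
#' effect allele matches the panel's other allele are counted on the flipped
#' dosage (2 - d); variants absent from the panel contribute 0 and are
#' counted. Missing dosages are mean-imputed to twice the panel allele
#' frequency.
#'
#' @param panel a [GenotypePanel-class].
#' @param model a [PRSModel-class].
#' @param maxUnmatched maximum tolerated fraction of unmatched model
#'   variants (default 0.5).
#' @return numeric vector of per-individual scores; `attr(, "nUnmatched")`
#'   counts unmatched model variants.
#' @export
scorePanel <- function(panel, model, maxUnmatched = 0.5) {
  w <- prsWeights(model)
  v <- variants(panel)
  j <- match(w$id, v$id)
  matched <- !is.na(j)
  if (nrow(w) && mean(!matched) > maxUnmatched)
    stop(sprintf("%.0f%% of model variants unmatched in panel",
                 100 * mean(!matched)))
  score <- rep(0, nIndividuals(panel))
  if (any(matched)) {
    jm <- j[matched]
    D <- dosages(panel)[, jm, drop = FALSE]
    storage.mode(D) <- "double"
    if (anyNA(D)) {
      for (col in which(colSums(is.na(D)) > 0)) {
        f <- mean(D[, col], na.rm = TRUE)
        D[is.na(D[, col]), col] <- f
      }
    }
    ea <- w$effectAllele[matched]
    flip <- ea == v$ref[jm] & ea != v$alt[jm]
    bad <- ea != v$alt[jm] & ea != v$ref[jm]
    if (any(bad)) {
      D <- D[, !bad, drop = FALSE]
      flip <- flip[!bad]
      b <- w$beta[matched][!bad]
    } else b <- w$beta[matched]
    if (any(flip)) D[, flip] <- 2 - D[, flip]
    score <- as.numeric(D %*% b)
  }
  attr(score, "nUnmatched") <- sum(!matched)
  score
}

#' Incremental variance explained by a PRS
#'
#' Fits the full model (covariates + PRS) and the null model (covariates
#' only) by OLS on complete cases and reports both R-squared values, their
#' difference (the incremental variance explained), and the two-sided t-test
#' p-value of the PRS coefficient in the full model.
#'
#' @param pheno phenotype/covariate table with a trait column.
#' @param score per-individual PRS vector.
#' @param covariates covariate column names (factors dummy-coded).
#' @param traitCol trait column name (default "trait").
#' @return list with `r2Full`, `r2Null`, `incremental`, `pPrs`, `n`,
#'   `betaPrs`, `sePrs`.
#' @export
incrementalR2 <- function(pheno, score, covariates = character(),
                          traitCol = "trait") {
  stopifnot(length(score) == nrow(pheno))
  d <- pheno
  d$.score <- score
  use <- stats::complete.cases(d[, c(traitCol, covariates, ".score")])
  d <- d[use, , drop = FALSE]
  y <- d[[traitCol]]
  Xn <- covariateDesign(d, covariates)
  Xf <- cbind(Xn, prs = d$.score)
  if (nrow(Xf) <= ncol(Xf)) stop("fewer rows than model parameters")
  fitF <- stats::lm.fit(Xf, y)
  rssF <- sum(fitF$residuals^2)
  tss <- sum((y - mean(y))^2)
  r2Full <- 1 - rssF / tss
  r2Null <- olsR2(Xn, y)
  dfF <- nrow(Xf) - fitF$rank
  # PRS coefficient and SE by Frisch-Waugh residualization: robust when the
  # score is (near-)collinear with the covariates
  fitN <- stats::lm.fit(Xn, y)
  eS <- stats::lm.fit(Xn, d$.score)$residuals
  ess <- sum(eS^2)
  if (ess > 1e-12 * sum(d$.score^2)) {
    betaPrs <- sum(eS * fitN$residuals) / ess
    sePrs <- sqrt(rssF / dfF / ess)
    t <- betaPrs / sePrs
  } else {
    betaPrs <- 0; sePrs <- Inf; t <- 0
  }
  list(r2Full = r2Full, r2Null = r2Null,
       incremental = max(0, r2Full - r2Null),
       pPrs = if (is.finite(sePrs)) 2 * stats::pt(-abs(t), dfF) else NA_real_,
       n = nrow(d), betaPrs = unname(betaPrs), sePrs = sePrs)
}

#' Search the p-value threshold grid for the best PRS
#'
#' Clumps the discovery summary statistics against the validation panel
#' once, then for each p-value threshold builds the weight set of clumped
#' variants passing the threshold, scores the validation individuals, and
#' records the incremental R-squared over the covariates. The returned model
#' is the grid argmax, with ties going to the smaller (stricter) threshold.
#'
#' @param summary discovery summary-stat table.
#' @param panelValid validation [GenotypePanel-class].
#' @param phenoValid validation phenotype table.
#' @param grid p-value thresholds to scan (default spans 5e-8 to 1).
#' @param clumpDistance,clumpR2 clumping parameters (defaults 250 kb, 0.8).
#' @param covariates covariate columns for the evaluation models.
#' @param source label recorded in the returned model.
#' @return list with `best` (a [PRSModel-class], or NULL if every grid cell
#'   is empty) and `grid` (threshold, nVariants, r2Full, incremental, pPrs).
#' @export
thresholdSearch <- function(summary, panelValid, phenoValid,
                            grid = c(5e-8, 1e-6, 1e-5, 1e-4, 1e-3, 0.01,
                                     0.05, 0.1, 0.2, 0.5, 1),
                            clumpDistance = 250000, clumpR2 = 0.8,
                            covariates = character(), source = "discovery") {
  clumped <- clumpVariants(summary, panelValid, clumpDistance, clumpR2)
  grid <- sort(grid)
  rows <- list()
  best <- NULL
  bestInc <- -Inf
  for (t in grid) {
    sel <- clumped[clumped$p <= t, , drop = FALSE]
    if (!nrow(sel)) {
      rows[[length(rows) + 1L]] <-
        data.frame(threshold = t, nVariants = 0L, r2Full = NA_real_,
                   incremental = NA_real_, pPrs = NA_real_)
      next
    }
    model <- prsModel(
      data.frame(id = sel$id, effectAllele = sel$ea, beta = sel$beta,
                 stringsAsFactors = FALSE),
      params = list(clumpDistanceBp = clumpDistance, clumpR2 = clumpR2,
                    pThreshold = t),
      source = source)
    sc <- scorePanel(panelValid, model)
    ev <- incrementalR2(phenoValid, sc, covariates)
    rows[[length(rows) + 1L]] <-
      data.frame(threshold = t, nVariants = nrow(sel), r2Full = ev$r2Full,
                 incremental = ev$incremental, pPrs = ev$pPrs)
    if (ev$incremental > bestInc + 1e-15) {
      bestInc <- ev$incremental
      best <- model
    }
  }
  list(best = best, grid = do.call(rbind, rows))
}

#' Mean-trait contrast across PRS deciles
#'
#' Individuals are assigned to deciles by score rank (ties share the lower
#' decile); the output is each decile's mean trait minus that of decile 1.
#'
#' @param score per-individual PRS vector (n >= 10).
#' @param trait per-individual trait vector.
#' @return data.frame with decile, n, meanTrait, diff (diff[1] = 0).
#' @export
decileContrast <- function(score, trait) {
  n <- length(score)
  if (n < 10) stop("need at least 10 individuals")
  stopifnot(length(trait) == n)
  r <- rank(score, ties.method = "min")
  dec <- pmin(floor((r - 1) * 10 / n) + 1L, 10L)
  mt <- tapply(trait, factor(dec, levels = 1:10), mean)
  cnt <- tapply(rep(1, n), factor(dec, levels = 1:10), sum)
  cnt[is.na(cnt)] <- 0
  data.frame(decile = 1:10, n = as.integer(cnt), meanTrait = as.numeric(mt),
             diff = as.numeric(mt) - as.numeric(mt)[1])
}

#' Stratified validation/test split
#'
#' Randomly assigns individuals to validation and test sets within each
#' stratum (e.g. sex-by-region cell) so both sexes and all regions keep
#' their representation in each subset, mirroring biobank target-set splits.
#'
#' @param pheno phenotype table.
#' @param fracValidation validation fraction in (0, 1).
#' @param strata character vector of stratification columns.
#' @param seed integer seed.
#' @return list with `assignment` (factor "validation"/"test"), `strata`
#'   labels used, and the seed; deterministic under the seed.
#' @export
stratifiedSplit <- function(pheno, fracValidation, strata = c("sex", "region"),
                            seed = 1L) {
  stopifnot(fracValidation > 0, fracValidation < 1)
  missing <- setdiff(strata, names(pheno))
  if (length(missing))
    stop("strata columns absent: ", paste(missing, collapse = ", "))
  lab <- interaction(pheno[, strata, drop = FALSE], drop = TRUE)
  assign <- rep("test", nrow(pheno))
  set.seed(subSeed(seed, "prs/split"))
  for (lv in levels(lab)) {
    idx <- which(lab == lv)
    nv <- round(fracValidation * length(idx))
    if (nv > 0) assign[sample(idx, nv)] <- "validation"
  }
  list(assignment = factor(assign, levels = c("validation", "test")),
       strata = lab, seed = seed)
}
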