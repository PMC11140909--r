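#' @include pipeline.R
NULL

# Reference experiments: fixed simulated study designs exercising the whole
# stack end to end. Both the test suite and the reproduction script run
# these; their defaults are the package's study conditions, documented in
# the methods vignette.

#' Genomic-control calibration under injected population structure
#'
#' Simulates several discovery studies, each an even mix of two diverged
#' subpopulations whose membership also shifts the (otherwise null) trait;
#' the GWAS deliberately omits any structure adjustment, so every study is
#' inflated. Returns the meta-analysis lambda before and after double
#' genomic control.
#'
#' @param seed integer seed.
#' @param nVariants number of null variants (default 50000).
#' @param nStudies number of discovery studies (default 3).
#' @param nPerStudy individuals per study (default 1000, split evenly
#'   between the two subpopulations).
#' @param fst subpopulation divergence within each study (default 0.05).
#' @param shift trait shift attached to subpopulation membership, in SD
#'   units (default 0.5).
#' @return list with `lambdaPre` (raw meta-analysis lambda), `lambdaPost`
#'   (after double GC), `lambdaStudies` (per-study).
#' @export
gcCalibrationExperiment <- function(seed, nVariants = 50000, nStudies = 3,
                                    nPerStudy = 1000, fst = 0.05,
                                    shift = 0.5) {
  m <- nVariants
  set.seed(subSeed(seed, "exp/gc/anc"))
  anc <- stats::runif(m, 0.1, 0.9)
  pos <- seq_len(m) * 100
  ref <- rep(c("A", "C"), length.out = m)
  alt <- rep(c("G", "T"), length.out = m)
  ids <- paste0("v", seq_len(m))
  studies <- list()
  for (s in seq_len(nStudies)) {
    nHalf <- nPerStudy %/% 2
    p1 <- drawSubpopulationFrequencies(anc, fst,
                                       subSeed(seed, paste0("gc/p1/", s)))
    p2 <- drawSubpopulationFrequencies(anc, fst,
                                       subSeed(seed, paste0("gc/p2/", s)))
    set.seed(subSeed(seed, paste0("exp/gc/geno/", s)))
    g1 <- matrix(stats::rbinom(nHalf * m, 2, rep(p1, each = nHalf)), nHalf, m)
    g2 <- matrix(stats::rbinom(nHalf * m, 2, rep(p2, each = nHalf)), nHalf, m)
    G <- rbind(g1, g2)
    y <- shift * rep(c(0, 1), each = nHalf) + stats::rnorm(2 * nHalf)
    panel <- genotypePanel(G, data.frame(chrom = "1", pos = pos, id = ids,
                                         ref = ref, alt = alt,
                                         stringsAsFactors = FALSE))
    # structure adjustment deliberately withheld
    studies[[paste0("s", s)]] <- runGwas(panel, data.frame(trait = y))
  }
  meta <- doubleGcMeta(studies, intercepts = "auto")
  list(lambdaPre = meta$lambda$raw, lambdaPost = meta$lambda$gc2,
       lambdaStudies = meta$lambda$perStudy)
}

# One fine-mapping locus: cohorts sharing a causal variant, drawn from a
# population A and a diverged population B with half the LD decay scale.
# Default design follows the real comparison, where the single-ancestry
# cohort sits wholly inside the multi-ancestry meta-analysis: single = A
# alone, meta = A + B. With matchedN = TRUE both analyses carry the same
# total n (A1+A2 vs A1+B), isolating the LD-diversity effect from the
# added sample size.
simulateLocusPair <- function(seed, mLocus = 60, spacingBp = 1500,
                              nSingle = 4000, nAdded = 2000,
                              ldA = 50000, ldB = 25000, fst = 0.1,
                              q2 = 0.006, matchedN = FALSE) {
  pos <- seq(1, by = spacingBp, length.out = mLocus)
  set.seed(subSeed(seed, "exp/locus/anc"))
  anc <- stats::runif(mLocus, 0.1, 0.9)
  causal <- mLocus %/% 2
  cohort <- function(name, n, ld, key) {
    f <- drawSubpopulationFrequencies(anc, fst, subSeed(seed, key))
    spec <- populationSpec(name, fst = fst, ldDecayBp = ld,
                           nIndividuals = n)
    panel <- simulateGenotypes(spec, f, pos, seed = subSeed(seed, key))
    g <- dosages(panel)[, causal]
    b <- sqrt(q2 / (1 - q2)) / stats::sd(g)
    set.seed(subSeed(seed, paste0(key, "/y")))
    y <- b * g + stats::rnorm(n)
    runGwas(panel, data.frame(trait = y))
  }
  metaZ <- function(s1, s2) {
    w <- 1 / cbind(s1$se, s2$se)^2
    b <- (w[, 1] * s1$beta + w[, 2] * s2$beta) / rowSums(w)
    b * sqrt(rowSums(w))
  }
  ssB <- cohort("B", nAdded, ldB, "exp/locus/B")
  if (matchedN) {
    ssA1 <- cohort("A1", nSingle - nAdded, ldA, "exp/locus/A1")
    ssA2 <- cohort("A2", nAdded, ldA, "exp/locus/A2")
    zSingle <- metaZ(ssA1, ssA2)
    zMeta <- metaZ(ssA1, ssB)
    ids <- ssA1
  } else {
    ssA <- cohort("A", nSingle, ldA, "exp/locus/A")
    zSingle <- ssA$beta / ssA$se
    zMeta <- metaZ(ssA, ssB)
    ids <- ssA
  }
  ok <- is.finite(zSingle) & is.finite(zMeta)
  rows <- function(z, k) data.frame(id = ids$id[ok], pos = ids$pos[ok],
                                    z = z[ok], k = k)
  list(single = setSize(credibleSet(rows(zSingle, if (matchedN) 2 else 1))),
       meta = setSize(credibleSet(rows(zMeta, 2))))
}

#' Fine-mapping resolution experiment
#'
#' Simulates `nLoci` loci, each with one shared causal variant observed in a
#' cohort from population A and one from a diverged population B with half
#' the LD-decay scale, and compares the 99% credible-set size of the
#' multi-ancestry meta-analysis (A+B) against the single-ancestry analysis
#' (A alone), mirroring the design in which the single-ancestry cohort is a
#' subset of the meta-analysis. Pass `matchedN = TRUE` for the matched-n
#' variant (A1+A2 vs A1+B) that isolates LD diversity from sample size.
#'
#' @param seed integer seed.
#' @param nLoci loci per replicate (default 50).
#' @param ... size overrides passed to the per-locus simulation.
#' @return list with `medianSingle`, `medianMeta`, and the per-locus
#'   `sizes` data.frame.
#' @export
resolutionExperiment <- function(seed, nLoci = 50, ...) {
  sizes <- vapply(seq_len(nLoci), function(i) {
    r <- simulateLocusPair(subSeed(seed, paste0("exp/res/", i)), ...)
    c(r$single, r$meta)
  }, numeric(2))
  list(medianSingle = stats::median(sizes[1, ]),
       medianMeta = stats::median(sizes[2, ]),
       sizes = data.frame(single = sizes[1, ], meta = sizes[2, ]))
}

#' PRS portability experiment
#'
#' One full discovery-to-target cycle under controlled divergence: a large
#' discovery GWAS in population A, a smaller one in population B (FST 0.15
#' from A's ancestral pool, half the LD-decay scale), and target cohorts
#' matching each. A C+T score is trained on the A-target validation split
#' and evaluated in both targets; then A-only and A+B meta-analysis scores
#' are trained on the B-target validation split and evaluated in the
#' B-target test split.
#'
#' @param seed integer seed.
#' @param nDiscoveryA,nDiscoveryB discovery sample sizes (defaults 20000,
#'   5000).
#' @param nTarget per-target sample size (default 2500).
#' @param nVariants,nCausal,h2 architecture (defaults 1500, 50, 0.3).
#' @param fstA,fstB divergence of the A- and B-like populations from the
#'   shared ancestral pool (defaults 0.02, 0.15).
#' @param ldA,ldB LD-decay scales (defaults 50 kb, 25 kb).
#' @param maskCausalFrac fraction of causal variants hidden from the
#'   analyzed variant set (default 0.5), emulating untyped causal variants:
#'   their signal is carried by tag SNPs whose LD with the causal alleles is
#'   population-specific — the mechanism behind cross-ancestry attenuation —
#'   while the typed remainder rewards the better-powered discovery set.
#' @return list with `incrementalA` and `incrementalB` (the A-trained score
#'   in the A- and B-like test sets), and `incrementalBOnlyA` /
#'   `incrementalBMeta` (A-only vs A+B-meta scores, both tuned on the
#'   B-target validation split).
#' @export
portabilityExperiment <- function(seed, nDiscoveryA = 20000,
                                  nDiscoveryB = 5000, nTarget = 2500,
                                  nVariants = 800, nCausal = 50, h2 = 0.3,
                                  fstA = 0.02, fstB = 0.15,
                                  ldA = 50000, ldB = 25000,
                                  maskCausalFrac = 0.5) {
  specs <- list(
    populationSpec("discA", fst = fstA, ldDecayBp = ldA,
                   nIndividuals = nDiscoveryA,
                   envDistributions = list(region = "A")),
    populationSpec("discB", fst = fstB, ldDecayBp = ldB,
                   nIndividuals = nDiscoveryB,
                   envDistributions = list(region = "B")),
    populationSpec("targA", fst = fstA, ldDecayBp = ldA,
                   nIndividuals = nTarget,
                   envDistributions = list(region = "A")),
    populationSpec("targB", fst = fstB, ldDecayBp = ldB,
                   nIndividuals = nTarget,
                   envDistributions = list(region = "B")))
  arch <- architectureSpec(nVariants, nCausal, h2, seed = seed)
  sims <- simulateMultistudy(specs, arch, chromLengthBp = nVariants * 6000)
  covars <- c("age", "sex")
  causal <- attr(sims, "causalIdx")
  nMask <- round(maskCausalFrac * length(causal))
  set.seed(subSeed(seed, "exp/port/mask"))
  drop <- if (nMask) sort(sample(causal, nMask)) else integer()
  gwasOf <- function(nm) {
    ph <- sims[[nm]]$pheno
    ph$trait <- inverseNormalTransform(ph$trait)
    ss <- runGwas(sims[[nm]]$panel, ph, covars)
    if (length(drop)) ss[-drop, , drop = FALSE] else ss
  }
  ssA <- gwasOf("discA")
  ssB <- gwasOf("discB")
  meta <- doubleGcMeta(list(discA = ssA, discB = ssB), intercepts = "auto")

  splitOf <- function(nm) {
    ph <- sims[[nm]]$pheno
    ph$trait <- inverseNormalTransform(ph$trait)
    sp <- stratifiedSplit(ph, 0.1, strata = "sex",
                          seed = subSeed(seed, paste0("exp/port/", nm)))
    list(pheno = ph, val = sp$assignment == "validation")
  }
  tA <- splitOf("targA")
  tB <- splitOf("targB")
  trainOn <- function(summary, target, val, source) {
    thresholdSearch(summary, sims[[target]]$panel[val, ],
                    getElement(if (target == "targA") tA else tB, "pheno")[val, ],
                    covariates = covars, source = source)$best
  }
  evalOn <- function(model, target, test, phenoTab) {
    sc <- scorePanel(sims[[target]]$panel[test, ], model)
    incrementalR2(phenoTab[test, ], sc, covars)$incremental
  }
  modelA <- trainOn(ssA, "targA", tA$val, "A-only")
  incrA <- evalOn(modelA, "targA", !tA$val, tA$pheno)
  incrB <- evalOn(modelA, "targB", !tB$val, tB$pheno)
  modelAforB <- trainOn(ssA, "targB", tB$val, "A-only")
  modelMeta <- trainOn(meta$result, "targB", tB$val, "A+B meta")
  incrBOnlyA <- evalOn(modelAforB, "targB", !tB$val, tB$pheno)
  incrBMeta <- evalOn(modelMeta, "targB", !tB$val, tB$pheno)
  list(incrementalA = incrA, incrementalB = incrB,
       incrementalBOnlyA = incrBOnlyA, incrementalBMeta = incrBMeta)
}

#' Sex-dimorphism decile experiment
#'
#' Simulates a cohort whose genetic effects are `sexEffectRatio`-fold larger
#' in females, scores individuals with the true polygenic score, and
#' contrasts the top-vs-bottom score decile of the trait within each sex.
#'
#' @param seed integer seed.
#' @param n cohort size (default 4000).
#' @param nVariants,nCausal,h2 architecture (defaults 300, 30, 0.3).
#' @param sexEffectRatio female/male genetic-effect ratio (default 2).
#' @return list with `femaleContrast`, `maleContrast` (decile-10 minus
#'   decile-1 mean trait within each sex).
#' @export
sexDimorphismExperiment <- function(seed, n = 4000, nVariants = 300,
                                    nCausal = 30, h2 = 0.3,
                                    sexEffectRatio = 2) {
  spec <- populationSpec("cohort", fst = 0, ldDecayBp = 50000,
                         nIndividuals = n)
  set.seed(subSeed(seed, "exp/sex/anc"))
  freqs <- stats::runif(nVariants, 0.1, 0.9)
  panel <- simulateGenotypes(spec, freqs,
                             seq(1, by = 10000, length.out = nVariants),
                             seed = subSeed(seed, "exp/sex/geno"))
  covar <- simulateCovariates(spec, seed = subSeed(seed, "exp/sex/covar"))
  arch <- architectureSpec(nVariants, nCausal, h2,
                           sexEffectRatio = sexEffectRatio,
                           seed = subSeed(seed, "exp/sex/arch"))
  ph <- simulatePhenotypes(panel, covar, arch)
  score <- attr(ph, "truth")$score
  contrastIn <- function(sx) {
    idx <- ph$sex == sx
    dc <- decileContrast(score[idx], ph$trait[idx])
    dc$diff[10]
  }
  list(femaleContrast = contrastIn("F"), maleContrast = contrastIn("M"))
}
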