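#' @include AllClasses.R utils.R
NULL

#' Draw subpopulation allele frequencies under the Balding-Nichols model
#'
#' Each subpopulation frequency is drawn from
#' Beta(p(1-F)/F, (1-p)(1-F)/F) around the ancestral frequency p, so that
#' the expected divergence between independent draws equals the target FST.
#' Frequencies falling outside `bounds` are resampled (a rare-variant guard
#' mirroring the MAF >= 0.01 filters applied throughout the source GWAS);
#' set `bounds = c(0, 1)` to disable.
#'
#' @param ancestralFreqs vector of ancestral frequencies, all in (0, 1).
#' @param fst divergence parameter in [0, 1); 0 returns the input unchanged.
#' @param seed integer seed.
#' @param bounds length-2 vector; draws outside are resampled.
#' @return a vector of subpopulation frequencies, same length as input.
#' @examples
#' drawSubpopulationFrequencies(c(0.2, 0.5), fst = 0.1, seed = 1)
#' @export
drawSubpopulationFrequencies <- function(ancestralFreqs, fst, seed,
                                         bounds = c(0.01, 0.99)) {
  if (any(ancestralFreqs <= 0 | ancestralFreqs >= 1))
    stop("ancestral frequencies must lie strictly in (0, 1)")
  if (fst < 0 || fst >= 1)
    stop("fst must lie in [0, 1); fst = 1 is a degenerate Beta")
  if (fst == 0) return(ancestralFreqs)
  set.seed(subSeed(seed, "synthdata/freqs"))
  a <- ancestralFreqs * (1 - fst) / fst
  b <- (1 - ancestralFreqs) * (1 - fst) / fst
  p <- stats::rbeta(length(ancestralFreqs), a, b)
  bad <- which(p < bounds[1] | p > bounds[2])
  tries <- 0L
  while (length(bad) && tries < 100L) {
    p[bad] <- stats::rbeta(length(bad), a[bad], b[bad])
    bad <- bad[p[bad] < bounds[1] | p[bad] > bounds[2]]
    tries <- tries + 1L
  }
  if (length(bad)) p[bad] <- pmin(pmax(p[bad], bounds[1]), bounds[2])
  p
}

# Simulate one haplotype block as a thresholded Gaussian Markov chain:
# correlation between adjacent latent variables is exp(-d/ldDecayBp), so the
# latent correlation between any two sites is exp(-distance/ldDecayBp)
# (the exponential kernel on a line is Markov). The latent vector is
# thresholded at qnorm(freq) so the marginal allele frequency matches freqs.
# Returns an nHap x m 0/1 matrix.
simulateHaplotypes <- function(nHap, freqs, positions, ldDecayBp) {
  m <- length(freqs)
  H <- matrix(0L, nHap, m)
  thr <- stats::qnorm(freqs)
  z <- stats::rnorm(nHap)
  H[, 1] <- as.integer(z < thr[1])
  if (m > 1) {
    rho <- exp(-diff(positions) / ldDecayBp)
    for (j in 2:m) {
      z <- rho[j - 1] * z + sqrt(1 - rho[j - 1]^2) * stats::rnorm(nHap)
      H[, j] <- as.integer(z < thr[j])
    }
  }
  H
}

#' Simulate genotypes with population-specific LD decay
#'
#' Generates two haplotypes per individual from a Gaussian-copula haplotype
#' model whose latent correlation between sites at distance d is
#' exp(-d / ldDecayBp); dosages are the haplotype sums, with marginal
#' allele frequency matching `freqs`.
#'
#' @param popSpec a [PopulationSpec-class] (supplies the LD decay scale,
#'   population size and label).
#' @param freqs per-variant allele frequencies in this population.
#' @param positions strictly increasing 1-based positions (bp).
#' @param seed integer seed.
#' @param chrom chromosome label (default "1").
#' @param ids variant ids (default "v1"..."vm").
#' @return a [GenotypePanel-class].
#' @export
simulateGenotypes <- function(popSpec, freqs, positions, seed, chrom = "1",
                              ids = NULL) {
  m <- length(freqs)
  if (length(positions) != m)
    stop("freqs and positions must have the same length")
  if (any(diff(positions) <= 0))
    stop("positions must be strictly increasing")
  n <- popSpec@nIndividuals
  set.seed(subSeed(seed, paste0("synthdata/geno/", popSpec@name)))
  H1 <- simulateHaplotypes(n, freqs, positions, popSpec@ldDecayBp)
  H2 <- simulateHaplotypes(n, freqs, positions, popSpec@ldDecayBp)
  dos <- H1 + H2
  if (is.null(ids)) ids <- paste0("v", seq_len(m))
  # deterministic, strand-unambiguous allele pairs (never A/T or C/G)
  ref <- rep(c("A", "C"), length.out = m)
  alt <- rep(c("G", "T"), length.out = m)
  genotypePanel(dos,
                data.frame(chrom = chrom, pos = positions, id = ids,
                           ref = ref, alt = alt, afreq = freqs,
                           stringsAsFactors = FALSE),
                populations = popSpec@name)
}

#' Simulate environmental covariates for one population
#'
#' Draws sex, age, smoking, alcohol, physical activity and socioeconomic
#' status from the distributions in the population spec, and attaches the
#' region label.
#'
#' @param popSpec a [PopulationSpec-class].
#' @param seed integer seed.
#' @return a data.frame with one row per individual.
#' @export
simulateCovariates <- function(popSpec, seed) {
  n <- popSpec@nIndividuals
  env <- popSpec@envDistributions
  set.seed(subSeed(seed, paste0("synthdata/covar/", popSpec@name)))
  drawCat <- function(d) sample(names(d), n, replace = TRUE, prob = d)
  out <- data.frame(
    iid = paste0(popSpec@name, "_", seq_len(n)),
    sex = drawCat(env$sex),
    age = stats::rnorm(n, env$age["mean"], env$age["sd"]),
    smoking = drawCat(env$smoking),
    alcohol = drawCat(env$alcohol),
    physical_activity = drawCat(env$physical_activity),
    ses = drawCat(env$ses),
    region = env$region,
    population = popSpec@name,
    stringsAsFactors = FALSE
  )
  out$age2 <- out$age^2
  out
}

#' Simulate a polygenic quantitative trait with sex-dimorphic and GxE effects
#'
#' Generative model on top of a genotype panel:
#' \deqn{y = \sqrt{h^2}\,\gamma(sex)\,G + \sum_c \alpha_c E_c +
#'       \sum_c \delta_c\,G\,E_c + \varepsilon,}
#' where G is the standardized true polygenic score (causal dosages weighted
#' by normal effects), \eqn{\gamma} is 1 for males and `sexEffectRatio` for
#' females, covariates enter through a standardized numeric coding, and the
#' noise variance is \eqn{1 - h^2} so the genetic variance share equals h2
#' when interactions are absent and the sex ratio is 1.
#'
#' @param panel a [GenotypePanel-class].
#' @param covariates data.frame from [simulateCovariates()] (needs any
#'   columns named by the architecture's effect terms, plus `sex`).
#' @param arch an [ArchitectureSpec-class]; its seed drives the draws.
#' @return the covariate table with a `trait` column appended; the truth
#'   (causal indices, betas, score, coefficients) is attached as
#'   `attr(, "truth")` for parameter-recovery tests.
#' @export
simulatePhenotypes <- function(panel, covariates, arch) {
  if (arch@h2 < 0 || arch@h2 > 1) stop("h2 must lie in [0, 1]")
  n <- nIndividuals(panel)
  if (nrow(covariates) != n)
    stop("covariates must have one row per individual")
  set.seed(subSeed(arch@seed, "synthdata/pheno"))
  causal <- sort(sample.int(nVariants(panel), arch@nCausal))
  beta <- stats::rnorm(arch@nCausal)
  simulatePhenotypesFixed(panel, covariates, arch, causal, beta)
}

# Phenotype generation with externally fixed causal indices and effects —
# used by simulateMultistudy so every study shares one architecture.
simulatePhenotypesFixed <- function(panel, covariates, arch, causal, beta,
                                    noiseKey = "synthdata/pheno/noise") {
  n <- nIndividuals(panel)
  g <- dosages(panel)[, causal, drop = FALSE] %*% beta
  sdg <- stats::sd(g)
  G <- if (sdg > 0) (g - mean(g)) / sdg else rep(0, n)
  sexMult <- ifelse(covariates$sex == "F", arch@sexEffectRatio, 1)
  y <- sqrt(arch@h2) * sexMult * G
  for (nm in names(arch@envEffects))
    y <- y + arch@envEffects[[nm]] * covariateNumeric(covariates[[nm]])
  for (nm in names(arch@gxeTerms))
    y <- y + arch@gxeTerms[[nm]] * G * covariateNumeric(covariates[[nm]])
  set.seed(subSeed(arch@seed, paste0(noiseKey, "/", panel@populations[1])))
  y <- y + stats::rnorm(n, sd = sqrt(1 - arch@h2))
  out <- covariates
  out$trait <- as.numeric(y)
  attr(out, "truth") <- list(
    causalIdx = causal, causalId = variants(panel)$id[causal], beta = beta,
    score = as.numeric(G), h2 = arch@h2,
    sexEffectRatio = arch@sexEffectRatio,
    envEffects = arch@envEffects, gxeTerms = arch@gxeTerms)
  out
}

#' Simulate a multi-study, multi-population cohort collection
#'
#' Draws one ancestral frequency spectrum and variant map, then realizes each
#' population spec against it: Balding-Nichols frequency divergence at the
#' spec's FST, LD at the spec's decay scale, covariates from its environment
#' distributions, and the trait from one shared architecture (same causal
#' variants and effects in every study when `sharedCausals` is TRUE).
#'
#' @param specs list of [PopulationSpec-class] objects (>= 2).
#' @param arch an [ArchitectureSpec-class].
#' @param sharedCausals share causal variants/effects across studies
#'   (default TRUE); FALSE redraws effects per study.
#' @param chromLengthBp length of the single simulated chromosome; variants
#'   are uniformly spaced along it.
#' @param ancestralRange range the ancestral frequencies are drawn from.
#' @return a named list (one element per spec) of lists with `panel`,
#'   `pheno` and `truth`; the shared variant map and ancestral frequencies
#'   are attached as attributes.
#' @export
simulateMultistudy <- function(specs, arch, sharedCausals = TRUE,
                               chromLengthBp = 10e6,
                               ancestralRange = c(0.05, 0.95)) {
  if (length(specs) < 2) stop("need at least 2 population specs")
  m <- arch@nVariants
  positions <- round(seq(1, chromLengthBp, length.out = m))
  positions <- positions + seq_len(m) - 1L  # guarantee strict increase
  set.seed(subSeed(arch@seed, "synthdata/ancestral"))
  anc <- stats::runif(m, ancestralRange[1], ancestralRange[2])
  causal <- sort(sample.int(m, arch@nCausal))
  beta <- stats::rnorm(arch@nCausal)
  out <- list()
  for (i in seq_along(specs)) {
    spec <- specs[[i]]
    freqs <- drawSubpopulationFrequencies(
      anc, spec@fst, subSeed(arch@seed, paste0("bn/", spec@name)))
    panel <- simulateGenotypes(spec, freqs, positions,
                               seed = arch@seed)
    covar <- simulateCovariates(spec, seed = arch@seed)
    if (!sharedCausals) {
      set.seed(subSeed(arch@seed, paste0("synthdata/arch/", spec@name)))
      causal_i <- sort(sample.int(m, arch@nCausal))
      beta_i <- stats::rnorm(arch@nCausal)
    } else {
      causal_i <- causal
      beta_i <- beta
    }
    pheno <- simulatePhenotypesFixed(panel, covar, arch, causal_i, beta_i)
    out[[spec@name]] <- list(panel = panel, pheno = pheno,
                             truth = attr(pheno, "truth"))
  }
  attr(out, "positions") <- positions
  attr(out, "ancestralFreqs") <- anc
  attr(out, "causalIdx") <- causal
  attr(out, "causalBeta") <- beta
  out
}
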