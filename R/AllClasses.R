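#' @import methods
NULL

#' PopulationSpec: one simulated population
#'
#' Describes a population to simulate: its divergence from the shared
#' ancestral population (Balding-Nichols FST), the physical scale of its
#' haplotype correlation (LD decay), its size, and the distributions of its
#' environmental covariates (sex, age, smoking, alcohol, physical activity,
#' socioeconomic status, region label).
#'
#' @slot name population label.
#' @slot fst divergence from the ancestral population, in [0, 1).
#' @slot ldDecayBp distance (bp) at which haplotype correlation falls to 1/e.
#' @slot nIndividuals number of diploid individuals (>= 2).
#' @slot envDistributions named list: categorical covariates as named
#'   probability vectors (each summing to 1), `age` as c(mean=, sd=),
#'   `region` as a single label.
#' @export
setClass("PopulationSpec",
  representation(
    name = "character",
    fst = "numeric",
    ldDecayBp = "numeric",
    nIndividuals = "integer",
    envDistributions = "list"
  )
)

setValidity("PopulationSpec", function(object) {
  msg <- character()
  if (length(object@fst) != 1 || object@fst < 0 || object@fst >= 1)
    msg <- c(msg, "fst must be a single value in [0, 1)")
  if (length(object@ldDecayBp) != 1 || object@ldDecayBp <= 0)
    msg <- c(msg, "ldDecayBp must be positive")
  if (object@nIndividuals < 2L)
    msg <- c(msg, "nIndividuals must be >= 2")
  for (nm in names(object@envDistributions)) {
    d <- object@envDistributions[[nm]]
    if (nm %in% c("age", "region")) next
    if (is.numeric(d) && !is.null(names(d))) {
      if (abs(sum(d) - 1) > 1e-9)
        msg <- c(msg, sprintf("category probabilities for '%s' must sum to 1", nm))
      if (any(d < 0))
        msg <- c(msg, sprintf("category probabilities for '%s' must be non-negative", nm))
    }
  }
  if (length(msg)) msg else TRUE
})

#' Construct a PopulationSpec
#'
#' @param name population label.
#' @param fst Balding-Nichols divergence from the ancestral population.
#' @param ldDecayBp LD decay scale in base pairs.
#' @param nIndividuals number of individuals.
#' @param envDistributions named list of covariate distributions; omitted
#'   entries fall back to neutral defaults (balanced sexes, age 50 (10),
#'   mostly never-smokers, mixed alcohol/physical-activity/SES categories).
#' @return a [PopulationSpec-class] object.
#' @examples
#' populationSpec("west", fst = 0.12, ldDecayBp = 25000, nIndividuals = 500)
#' @export
populationSpec <- function(name, fst, ldDecayBp, nIndividuals,
                           envDistributions = list()) {
  defaults <- list(
    sex = c(M = 0.5, F = 0.5),
    age = c(mean = 50, sd = 10),
    smoking = c(never = 0.75, ever = 0.25),
    alcohol = c(never = 0.4, current_nonproblematic = 0.35,
                current_problematic = 0.1, former = 0.15),
    physical_activity = c(low = 1 / 3, moderate = 1 / 3, high = 1 / 3),
    ses = c(low = 1 / 3, middle = 1 / 3, high = 1 / 3),
    region = name
  )
  env <- utils::modifyList(defaults, envDistributions)
  new("PopulationSpec", name = name, fst = fst, ldDecayBp = ldDecayBp,
      nIndividuals = as.integer(nIndividuals), envDistributions = env)
}

#' ArchitectureSpec: the shared polygenic trait architecture
#'
#' Generative assumptions for the quantitative trait: number of variants and
#' causal variants, the narrow-sense heritability target, sex dimorphism of
#' genetic effects, main environmental effects and PRS-by-environment
#' interaction coefficients.
#'
#' @slot nVariants total variants on the simulated chromosome.
#' @slot nCausal number of causal variants (<= nVariants).
#' @slot h2 narrow-sense heritability target in [0, 1] (defined for the
#'   reference sex when `sexEffectRatio` differs from 1).
#' @slot sexEffectRatio multiplier on genetic effects in females vs males.
#' @slot envEffects named numeric: per-SD main effect of each covariate.
#' @slot gxeTerms named numeric: interaction coefficient of the standardized
#'   genetic score with each (numerically coded) covariate.
#' @slot seed integer random seed governing all draws.
#' @export
setClass("ArchitectureSpec",
  representation(
    nVariants = "integer",
    nCausal = "integer",
    h2 = "numeric",
    sexEffectRatio = "numeric",
    envEffects = "numeric",
    gxeTerms = "numeric",
    seed = "integer"
  )
)

setValidity("ArchitectureSpec", function(object) {
  msg <- character()
  if (object@nCausal > object@nVariants)
    msg <- c(msg, "nCausal must not exceed nVariants")
  if (object@h2 < 0 || object@h2 > 1)
    msg <- c(msg, "h2 must lie in [0, 1]")
  if (object@sexEffectRatio < 0)
    msg <- c(msg, "sexEffectRatio must be non-negative")
  if (length(msg)) msg else TRUE
})

#' Construct an ArchitectureSpec
#'
#' @param nVariants,nCausal variant counts.
#' @param h2 heritability target in [0, 1].
#' @param sexEffectRatio genetic-effect multiplier in females (default 1).
#' @param envEffects named numeric vector of covariate main effects.
#' @param gxeTerms named numeric vector of score-by-covariate interactions.
#' @param seed integer seed.
#' @return an [ArchitectureSpec-class] object.
#' @examples
#' architectureSpec(1000, 50, h2 = 0.3, seed = 1)
#' @export
architectureSpec <- function(nVariants, nCausal, h2, sexEffectRatio = 1,
                             envEffects = numeric(), gxeTerms = numeric(),
                             seed = 1L) {
  new("ArchitectureSpec", nVariants = as.integer(nVariants),
      nCausal = as.integer(nCausal), h2 = h2,
      sexEffectRatio = sexEffectRatio,
      envEffects = envEffects, gxeTerms = gxeTerms, seed = as.integer(seed))
}

#' GenotypePanel: individuals-by-variants dosage matrix with metadata
#'
#' The central genotype container: an integer dosage matrix (rows are
#' individuals, columns variants, values 0/1/2 counting effect-allele copies,
#' NA for missing), a variant table (chrom, pos, id, ref, alt, afreq) and a
#' per-individual population label.
#'
#' @slot dosages numeric matrix, individuals x variants; simulated panels
#'   carry hard calls 0/1/2, read-in panels may carry imputed dosages.
#' @slot variants data.frame with columns chrom, pos (1-based), id, ref, alt,
#'   afreq (ancestral/effect-allele frequency used at simulation, NA if
#'   unknown).
#' @slot populations character vector, one label per individual.
#' @export
setClass("GenotypePanel",
  representation(
    dosages = "matrix",
    variants = "data.frame",
    populations = "character"
  )
)

setValidity("GenotypePanel", function(object) {
  msg <- character()
  d <- object@dosages
  v <- object@variants
  need <- c("chrom", "pos", "id", "ref", "alt")
  if (!all(need %in% names(v)))
    msg <- c(msg, paste("variants must have columns", paste(need, collapse = ", ")))
  if (ncol(d) != nrow(v))
    msg <- c(msg, "ncol(dosages) must equal nrow(variants)")
  if (length(object@populations) != nrow(d))
    msg <- c(msg, "populations must have one label per individual")
  vals <- d[!is.na(d)]
  if (length(vals) && (min(vals) < 0 || max(vals) > 2))
    msg <- c(msg, "dosages must lie in [0, 2] (hard calls 0/1/2 or imputed dosages)")
  if (all(need %in% names(v)) && nrow(v) > 1) {
    for (ch in unique(v$chrom)) {
      p <- v$pos[v$chrom == ch]
      if (any(diff(p) <= 0)) {
        msg <- c(msg, "positions must be strictly increasing within chromosome")
        break
      }
    }
  }
  if (all(need %in% names(v)) && nrow(v) > 0) {
    ok <- nchar(v$ref) == 1 & nchar(v$alt) == 1 & v$ref != v$alt
    if (!all(ok)) msg <- c(msg, "ref/alt must be single, unequal bases")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a GenotypePanel
#'
#' @param dosages integer matrix (individuals x variants) of 0/1/2 dosages.
#' @param variants variant metadata data.frame (chrom, pos, id, ref, alt,
#'   optionally afreq).
#' @param populations per-individual population labels (recycled if length 1).
#' @return a [GenotypePanel-class] object.
#' @export
genotypePanel <- function(dosages, variants, populations = "pop1") {
  if (!is.numeric(dosages)) storage.mode(dosages) <- "double"
  if (is.null(variants$afreq)) variants$afreq <- NA_real_
  if (length(populations) == 1L) populations <- rep(populations, nrow(dosages))
  colnames(dosages) <- variants$id
  new("GenotypePanel", dosages = dosages,
      variants = as.data.frame(variants, stringsAsFactors = FALSE),
      populations = populations)
}

#' CredibleSet: fine-mapping result for one locus
#'
#' Per-variant posterior table for a locus, sorted by posterior probability,
#' with the minimal prefix reaching the coverage target flagged.
#'
#' @slot locus list with chrom, leadId, leadPos, leadP, start, end.
#' @slot rows data.frame: id, pos, z, k, logBF, posterior, cumulative, inSet.
#' @slot coverage attained cumulative posterior of the flagged set.
#' @slot coverageTarget requested coverage.
#' @export
setClass("CredibleSet",
  representation(
    locus = "list",
    rows = "data.frame",
    coverage = "numeric",
    coverageTarget = "numeric"
  )
)

setValidity("CredibleSet", function(object) {
  msg <- character()
  r <- object@rows
  if (nrow(r)) {
    if (abs(sum(r$posterior) - 1) > 1e-9)
      msg <- c(msg, "posteriors must sum to 1 within 1e-9")
    if (is.unsorted(rev(r$posterior)))
      msg <- c(msg, "rows must be sorted by posterior, descending")
    if (any(diff(r$inSet) > 0))
      msg <- c(msg, "inSet variants must form a prefix of the sorted rows")
  }
  if (length(msg)) msg else TRUE
})

#' PRSModel: a polygenic score weight table plus its selection parameters
#'
#' @slot weights data.frame with columns id, effectAllele, beta.
#' @slot params list: clumpDistanceBp, clumpR2, pThreshold.
#' @slot source label of the discovery analysis the weights came from.
#' @export
setClass("PRSModel",
  representation(
    weights = "data.frame",
    params = "list",
    source = "character"
  )
)

setValidity("PRSModel", function(object) {
  msg <- character()
  w <- object@weights
  if (!all(c("id", "effectAllele", "beta") %in% names(w)))
    msg <- c(msg, "weights must have columns id, effectAllele, beta")
  else {
    if (anyDuplicated(w$id)) msg <- c(msg, "variant ids must be unique")
    if (nrow(w) && any(!is.finite(w$beta))) msg <- c(msg, "betas must be finite")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a PRSModel
#'
#' @param weights data.frame with columns id, effectAllele, beta.
#' @param params list of selection parameters (clumpDistanceBp, clumpR2,
#'   pThreshold).
#' @param source label of the discovery analysis.
#' @return a [PRSModel-class] object.
#' @export
prsModel <- function(weights, params = list(), source = "unspecified") {
  new("PRSModel", weights = as.data.frame(weights, stringsAsFactors = FALSE),
      params = params, source = source)
}
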