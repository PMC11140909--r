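#' @include AllGenerics.R
NULL

#' @rdname accessors
#' @export
setMethod("dosages", "GenotypePanel", function(x) x@dosages)

#' @rdname accessors
#' @export
setMethod("variants", "GenotypePanel", function(x) x@variants)

#' @rdname accessors
#' @export
setMethod("populations", "GenotypePanel", function(x) x@populations)

#' @rdname accessors
#' @export
setMethod("nIndividuals", "GenotypePanel", function(x) nrow(x@dosages))

#' @rdname accessors
#' @export
setMethod("nVariants", "GenotypePanel", function(x) ncol(x@dosages))

#' @rdname accessors
#' @export
setMethod("alleleFrequencies", "GenotypePanel", function(x) {
  f <- colMeans(x@dosages, na.rm = TRUE) / 2
  names(f) <- x@variants$id
  f
})

#' Subset a GenotypePanel
#'
#' `x[i, j]` keeps individuals `i` and variants `j`.
#'
#' @param x a [GenotypePanel-class].
#' @param i individual index.
#' @param j variant index (position in the variant table, or variant id).
#' @param ... ignored.
#' @param drop ignored; a panel is always returned.
#' @export
setMethod("[", "GenotypePanel", function(x, i, j, ..., drop = FALSE) {
  if (missing(i)) i <- seq_len(nrow(x@dosages))
  if (missing(j)) j <- seq_len(ncol(x@dosages))
  if (is.character(j)) j <- match(j, x@variants$id)
  new("GenotypePanel",
      dosages = x@dosages[i, j, drop = FALSE],
      variants = x@variants[j, , drop = FALSE],
      populations = x@populations[i])
})

setMethod("show", "GenotypePanel", function(object) {
  cat("GenotypePanel:", nrow(object@dosages), "individuals x",
      ncol(object@dosages), "variants\n")
  tab <- table(object@populations)
  cat("populations:",
      paste(sprintf("%s (%d)", names(tab), as.integer(tab)), collapse = ", "),
      "\n")
  v <- object@variants
  if (nrow(v))
    cat(sprintf("chrom %s, positions %s..%s\n", v$chrom[1],
                format(min(v$pos), big.mark = ","),
                format(max(v$pos), big.mark = ",")))
})

setMethod("show", "PopulationSpec", function(object) {
  cat(sprintf("PopulationSpec '%s': n=%d, FST=%.3f, LD decay=%s bp\n",
              object@name, object@nIndividuals, object@fst,
              format(object@ldDecayBp, big.mark = ",")))
})

setMethod("show", "ArchitectureSpec", function(object) {
  cat(sprintf(
    "ArchitectureSpec: %d variants (%d causal), h2=%.2f, sex ratio=%.2f\n",
    object@nVariants, object@nCausal, object@h2, object@sexEffectRatio))
  if (length(object@gxeTerms))
    cat("GxE terms:", paste(sprintf("%s=%.3g", names(object@gxeTerms),
                                    object@gxeTerms), collapse = ", "), "\n")
})

#' @rdname accessors
#' @export
setMethod("prsWeights", "PRSModel", function(x) x@weights)

#' @rdname accessors
#' @export
setMethod("scoreParams", "PRSModel", function(x) x@params)

setMethod("show", "PRSModel", function(object) {
  cat(sprintf("PRSModel (%s): %d variants\n", object@source,
              nrow(object@weights)))
  p <- object@params
  if (length(p))
    cat("params:", paste(sprintf("%s=%s", names(p), unlist(p)),
                         collapse = ", "), "\n")
})

#' @rdname accessors
#' @export
setMethod("setSize", "CredibleSet", function(x) sum(x@rows$inSet))

#' @rdname accessors
#' @export
setMethod("credibleRows", "CredibleSet", function(x) x@rows)

setMethod("show", "CredibleSet", function(object) {
  l <- object@locus
  cat(sprintf("CredibleSet at %s:%s (lead %s, p=%.3g)\n", l$chrom,
              format(l$leadPos, big.mark = ","), l$leadId, l$leadP))
  cat(sprintf("%d variants in locus; %d in the %.0f%% set (coverage %.4f)\n",
              nrow(object@rows), sum(object@rows$inSet),
              100 * object@coverageTarget, object@coverage))
})
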