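#' @include AllClasses.R utils.R
NULL

#' Inverse rank-normal transformation
#'
#' Maps a quantitative trait to standard-normal quantiles before association
#' testing: \eqn{\Phi^{-1}((r - c) / (n - 2c + 1))} with the Blom offset
#' c = 3/8 and average ranks for ties. The output is monotone in the input
#' with mean approximately zero.
#'
#' @param values numeric vector, length >= 2, all finite.
#' @param offset rank offset constant (default 3/8, Blom).
#' @return the transformed vector.
#' @examples
#' inverseNormalTransform(c(5, 1, 9))
#' @export
inverseNormalTransform <- function(values, offset = 3 / 8) {
  if (length(values) < 2) stop("need at least 2 values")
  if (any(!is.finite(values))) stop("values must be finite")
  if (length(unique(values)) == 1L)
    stop("all values identical: no rank information")
  r <- rank(values, ties.method = "average")
  stats::qnorm((r - offset) / (length(values) - 2 * offset + 1))
}

#' Principal components of a genotype panel
#'
#' Columns are standardized (monomorphic variants dropped), the top-k left
#' singular vectors are returned as orthonormal score columns, and each
#' component's sign is fixed so its largest-magnitude variant loading is
#' positive.
#'
#' @param panel a [GenotypePanel-class].
#' @param k number of components, 0 < k < min(n, m).
#' @return an individuals-by-k matrix (columns `PC1`..`PCk`); singular
#'   values are attached as `attr(, "d")`, dropped-variant count as
#'   `attr(, "nMonomorphic")`.
#' @export
computePCs <- function(panel, k) {
  if (k <= 0) stop("k must be positive")
  X <- dosages(panel)
  storage.mode(X) <- "double"
  sds <- apply(X, 2, stats::sd)
  keep <- which(sds > 0)
  X <- scale(X[, keep, drop = FALSE])
  if (k >= min(dim(X))) stop("k must be smaller than min(n individuals, n variants)")
  sv <- svd(X, nu = k, nv = k)
  u <- sv$u
  for (j in seq_len(k)) {
    i <- which.max(abs(sv$v[, j]))
    if (sv$v[i, j] < 0) u[, j] <- -u[, j]
  }
  colnames(u) <- paste0("PC", seq_len(k))
  attr(u, "d") <- sv$d[seq_len(k)]
  attr(u, "nMonomorphic") <- ncol(dosages(panel)) - length(keep)
  u
}

# Build a fixed-effects design matrix (intercept + covariate columns, with
# factor/character columns expanded to dummies) from a phenotype table.
covariateDesign <- function(pheno, covariates) {
  if (!length(covariates)) {
    X <- matrix(1, nrow(pheno), 1)
    colnames(X) <- "(Intercept)"
    return(X)
  }
  missing <- setdiff(covariates, names(pheno))
  if (length(missing))
    stop("covariate columns absent from table: ", paste(missing, collapse = ", "))
  f <- stats::as.formula(paste("~", paste(covariates, collapse = " + ")))
  stats::model.matrix(f, data = pheno)
}

#' Per-variant GWAS by ordinary least squares
#'
#' Regresses the (already inverse-rank-normalized) trait on each variant's
#' dosage plus the covariates, one variant at a time, via a single
#' residualization pass: trait and dosages are projected off the covariate
#' design once, then per-variant slope, SE and two-sided t-test follow in
#' closed form. Monomorphic variants yield rows with missing beta/SE and are
#' counted in `attr(, "nSkipped")`.
#'
#' @param panel a [GenotypePanel-class].
#' @param pheno phenotype/covariate table with a `trait` column.
#' @param covariates character vector of covariate column names in `pheno`
#'   (may be empty); factors are dummy-coded.
#' @param traitCol name of the trait column (default "trait").
#' @param blockSize variants processed per block (memory control).
#' @return a summary-statistics data.frame with columns chrom, pos, id, ea,
#'   oa, eaf, beta, se, p, n, k (k = 1 for a single-study scan).
#' @export
runGwas <- function(panel, pheno, covariates = character(),
                    traitCol = "trait", blockSize = 1024L) {
  if (!traitCol %in% names(pheno)) stop("trait column not found")
  y <- pheno[[traitCol]]
  n <- length(y)
  stopifnot(n == nIndividuals(panel))
  X <- covariateDesign(pheno, covariates)
  qrX <- qr(X)
  Q <- qr.Q(qrX)
  yr <- y - Q %*% crossprod(Q, y)
  m <- nVariants(panel)
  beta <- se <- pval <- rep(NA_real_, m)
  eaf <- rep(NA_real_, m)
  df <- n - ncol(X) - 1L
  nSkipped <- 0L
  for (start in seq(1L, m, by = blockSize)) {
    idx <- start:min(start + blockSize - 1L, m)
    G <- dosages(panel)[, idx, drop = FALSE]
    storage.mode(G) <- "double"
    eaf[idx] <- colMeans(G) / 2
    mono <- apply(G, 2, function(g) length(unique(g)) == 1L)
    Gr <- G - Q %*% crossprod(Q, G)
    gss <- colSums(Gr^2)
    gss[mono] <- NA_real_
    b <- colSums(Gr * as.numeric(yr)) / gss
    rss <- sum(yr^2) - b^2 * gss
    s2 <- rss / df
    s <- sqrt(s2 / gss)
    t <- b / s
    beta[idx] <- b
    se[idx] <- s
    pval[idx] <- 2 * stats::pt(-abs(t), df)
    nSkipped <- nSkipped + sum(mono)
  }
  v <- variants(panel)
  out <- data.frame(chrom = v$chrom, pos = v$pos, id = v$id,
                    ea = v$alt, oa = v$ref, eaf = eaf, beta = beta, se = se,
                    p = pval, n = n, k = 1L, stringsAsFactors = FALSE)
  attr(out, "nSkipped") <- nSkipped
  out
}
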