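# Internal numerical and RNG helpers shared across modules.

# Median of the chi-square(1) distribution, fixed to 10 figures so genomic
# control lambdas are reproducible across platforms.
CHISQ1_MEDIAN <- 0.4549364

#' Derive a reproducible sub-stream seed
#'
#' All randomness in the package flows from one user-supplied seed; each
#' module/purpose pair gets its own deterministic sub-stream so that adding a
#' stage never perturbs the draws of another.
#'
#' @param seed integer base seed.
#' @param key character label of the consuming (module, purpose).
#' @return an integer seed strictly below 2^31.
#' @keywords internal
subSeed <- function(seed, key) {
  h <- 0
  for (ch in utf8ToInt(key)) h <- (h * 131 + ch) %% 1000000007
  as.integer((as.numeric(seed) * 2654435 + h) %% 2147483647L)
}

#' Numerically stable log(sum(exp(x)))
#' @keywords internal
logSumExp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

#' Hudson FST estimator from paired allele frequencies
#'
#' Ratio-of-averages Hudson estimator. When `n1`/`n2` are finite they are
#' haplotype sample sizes and the numerator is corrected for sampling noise in
#' the frequency estimates; with the default infinite sizes the frequencies
#' are treated as exact (appropriate for Balding-Nichols draws).
#'
#' @param p1,p2 numeric vectors of allele frequencies in the two populations.
#' @param n1,n2 haplotype counts behind each frequency estimate.
#' @return a single FST estimate.
#' @export
hudsonFst <- function(p1, p2, n1 = Inf, n2 = Inf) {
  stopifnot(length(p1) == length(p2))
  num <- (p1 - p2)^2
  if (is.finite(n1)) num <- num - p1 * (1 - p1) / (n1 - 1)
  if (is.finite(n2)) num <- num - p2 * (1 - p2) / (n2 - 1)
  den <- p1 * (1 - p2) + p2 * (1 - p1)
  mean(num) / mean(den)
}

# Numeric coding for covariates entering generative or regression models:
# numerics are standardized; factors/characters become 0-based level indices,
# then standardized. Constant columns map to all zeros.
covariateNumeric <- function(x) {
  if (is.character(x)) x <- factor(x)
  if (is.factor(x)) x <- as.numeric(x) - 1
  s <- stats::sd(x)
  if (!is.finite(s) || s == 0) return(rep(0, length(x)))
  (x - mean(x)) / s
}

# R^2 of an OLS fit by QR, given a design matrix (no intercept added) and y.
olsR2 <- function(X, y) {
  fit <- stats::lm.fit(X, y)
  rss <- sum(fit$residuals^2)
  tss <- sum((y - mean(y))^2)
  if (tss == 0) return(0)
  1 - rss / tss
}
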