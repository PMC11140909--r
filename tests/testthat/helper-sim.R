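# Shared fixtures: small cohorts built in code at test time.

quickSpec <- function(name = "pop1", fst = 0, ldDecayBp = 50000, n = 100) {
  populationSpec(name, fst = fst, ldDecayBp = ldDecayBp, nIndividuals = n)
}

quickPanel <- function(n = 100, m = 20, freq = 0.3, spacingBp = 10000,
                       ldDecayBp = 50000, seed = 1, name = "pop1") {
  simulateGenotypes(quickSpec(name, ldDecayBp = ldDecayBp, n = n),
                    freqs = rep(freq, m),
                    positions = seq(1, by = spacingBp, length.out = m),
                    seed = seed)
}

# Direct, division-by-max brute-force credible-set oracle: raw-scale
# posteriors (scaled by the locus maximum to stay in float range), sorted
# and accumulated without log-sum-exp.
bruteForceCredible <- function(z, k, pos, coverage = 0.99) {
  e <- (z^2 - log(k)) / 2
  w <- exp(e - max(e))
  pi <- w / sum(w)
  ord <- order(-pi, -abs(z), pos)
  cum <- cumsum(pi[ord])
  nset <- which(cum >= coverage - 1e-12)[1]
  if (is.na(nset)) nset <- length(z)
  sort(ord[seq_len(nset)])
}

# Summary table wrapper for hand-built inputs.
sumstatTable <- function(chrom, pos, id, ea, oa, eaf, beta, se, p, n,
                         k = 1L) {
  data.frame(chrom = chrom, pos = pos, id = id, ea = ea, oa = oa, eaf = eaf,
             beta = beta, se = se, p = p, n = n, k = k,
             stringsAsFactors = FALSE)
}
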