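---
title: "Models and methods behind portaPRS"
author: "portaPRS authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind portaPRS}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(portaPRS)
```

portaPRS studies why polygenic scores (PRS) built from genome-wide
association studies (GWAS) of one ancestry transfer poorly to others, and
what a multi-ancestry meta-analysis buys in fine-mapping resolution and
prediction. Because individual-level biobank data of this kind are
controlled-access, the package pairs every analysis stage with a simulator
that reproduces the relevant statistical structure, so the full pipeline is
testable end to end.

## The simulator

**Allele-frequency divergence.** Populations diverge from a shared
ancestral pool under the Balding–Nichols model: a variant with ancestral
frequency $p$ has subpopulation frequency
$p' \sim \mathrm{Beta}\!\big(p\tfrac{1-F}{F},\,(1-p)\tfrac{1-F}{F}\big)$,
so $\mathrm{E}[p'] = p$ and $\mathrm{Var}[p'] = F\,p(1-p)$, giving direct
single-parameter control of FST. A rare-variant guard resamples draws
outside $[0.01, 0.99]$, mirroring the MAF $\ge 1\%$ filters of the source
GWAS; it is configurable and disabled in the variance tests.

**Linkage disequilibrium.** Haplotypes are thresholded Gaussian vectors: a
latent standard-normal Markov chain along the chromosome with correlation
$\exp(-d/L)$ between sites at distance $d$ ($L$ = `ldDecayBp`, the distance
at which the latent correlation falls to $1/e$), thresholded at
$\Phi^{-1}(p)$ so marginal frequencies are exact. The exponential kernel is
Markov on a line, so simulation is a single $O(nm)$ pass. Thresholding
attenuates correlations — for frequency-$\tfrac12$ alleles the indicator
correlation is $\tfrac{2}{\pi}\arcsin(\rho)$ — which is why
`fitLdDecay()` fits $r^2(d) = a\big[\tfrac{2}{\pi}\arcsin(e^{-d/s})\big]^2$
rather than a bare exponential; $s$ is then directly comparable to
`ldDecayBp` and recovers it within a few percent at $n = 5{,}000$.

**Phenotypes.** With $G$ the standardized true polygenic score over
`nCausal` causal variants (normal effect sizes),

$$y = \sqrt{h^2}\,\gamma(\text{sex})\,G
      + \textstyle\sum_c \alpha_c E_c
      + \textstyle\sum_c \delta_c\,G\,E_c
      + \varepsilon,\qquad
      \varepsilon \sim N(0,\,1-h^2),$$

where $\gamma$ is 1 for males and `sexEffectRatio` for females, and the
covariates $E_c$ enter through a standardized numeric coding. With no
interactions and ratio 1 the genetic variance share equals $h^2$ exactly in
expectation; when the ratio differs from 1, $h^2$ is defined for the
reference (male) stratum. Every generated table carries its truth (causal
ids, effects, score, coefficients) for parameter-recovery tests.

**What the simulator does not emulate:** coalescent genealogies,
recombination hotspots, selection, cryptic relatedness, genotyping error,
and imputation uncertainty. Tests passing on these cohorts show the
*statistical machinery* is correct and the paper-level directions are
reproduced under the stated generative assumptions — not that effect sizes
on real African cohorts would match numerically.

## Association scans

Traits are inverse-rank normalized, $\Phi^{-1}\big((r - 3/8)/(n + 1/4)\big)$
with average ranks for ties (the Blom offset; the offset is configurable
since conventions differ). Per-variant statistics come from OLS of the
transformed trait on dosage plus covariates (age, age², sex and principal
components by default), computed by residualizing trait and dosages against
the covariate design once and sweeping variants in blocks. Linear mixed
models were deliberately replaced by OLS with PC adjustment: the simulated
cohorts contain no relatedness, and downstream stages consume only
$(\beta, \mathrm{SE})$. Principal components are the left singular vectors
of the standardized dosage matrix (monomorphic variants dropped), returned
orthonormal with a fixed sign convention (largest-magnitude loading
positive).

## Meta-analysis with double genomic control

Studies are harmonized by (chromosome, position, sorted allele pair) —
variant-ID strings are ignored because ID conventions differ across
sources; strand-ambiguous pairs (A/T, C/G) are dropped; effects are flipped
onto the orientation of the first study reporting each variant; variants
reported by fewer than two studies are excluded. Fixed-effects
inverse-variance weighting gives
$\beta = \sum w_i\beta_i / \sum w_i$, $\mathrm{SE} = (\sum w_i)^{-1/2}$,
$w_i = \mathrm{SE}_i^{-2}$.

Genomic control uses $\lambda = \mathrm{median}(z^2)/0.4549364$, the
$\chi^2_1$ median fixed to ten figures for cross-platform reproducibility.
The double-control schedule multiplies each study's SEs by the square root
of its correction factor (a supplied LDSC-intercept-style constant, or in
`"auto"` mode the study's own $\lambda$; studies without a usable factor
get 1), meta-analyzes, computes the meta-analysis $\lambda$, and inflates
the meta SEs by its square root. Applied factors are clamped at 1 — the
correction never deflates SEs — while the unclamped $\lambda$ is always
reported. All three stages are retained for audit.

## Fine-mapping

Loci are defined greedily: the smallest remaining $p < 5\times10^{-8}$
becomes a lead, significant variants within 1 Mb of it are consumed, and
the locus spans lead $\pm$ 1 Mb (coordinates 1-based, intervals closed;
overlapping flanks of distinct loci are kept, so a variant may appear in
two sets). Per variant, the approximate Bayes factor is
$BF_i = \exp\!\big[(Z_i^2 - \log K_i)/2\big]$ with $K_i$ the number of
contributing studies, and the locus posterior is
$\pi_i = BF_i / \sum_j BF_j$. All arithmetic stays in log space with
log-sum-exp — leads near $|z| = 40$ overflow the naive exponential — and
the 99% credible set is the minimal posterior-sorted prefix reaching 0.99,
with boundary ties broken deterministically (larger $|z|$, then smaller
position). Variants inside the window but absent from the meta-analysis
(fewer than two studies) are excluded from the denominator.

## Polygenic scores

Clumping-and-thresholding follows the classic recipe: greedy by ascending
p-value, removing unprocessed variants within 250 kb at squared dosage
correlation above 0.8 (LD measured in the target panel, as C+T tools do),
then filtering at each threshold of a grid spanning $5\times10^{-8}$ to 1
(the default grid interleaves decades; only the range is fixed by
convention). The best threshold maximizes incremental $R^2$ — full model
(covariates + PRS) minus covariates-only — on a validation split that is
stratified by sex and region and disjoint from the test split; ties go to
the stricter threshold, and both the full-model and incremental $R^2$ are
reported for every grid cell. Tuning happens on the validation split only:
tuning on the combined data before splitting leaks information, so that
ordering is not offered as a default. Scores are additive in effect-allele
dosage with orientation resolved against the panel, unmatched variants
contributing zero (an error above 50% unmatched), and missing genotypes
mean-imputed to twice the observed allele frequency. Decile contrasts
assign individuals by score rank (ties to the lower decile) and report each
decile's mean trait minus decile 1's.

## Interactions and regional analysis

PRS-by-modifier interactions are OLS fits of
trait ~ PRS + modifier + PRS:modifier + covariates with the PRS
standardized; categorical modifiers are dummy-coded against the field's
conventional reference levels (never-smoker, never-consumer, male, East
region), and both per-contrast t-tests and an omnibus F-test are reported,
since a single published interaction p-value per multi-level factor can
correspond to either. Region-stratified evaluation reuses the incremental
$R^2$ contract per stratum and tests PRS-by-stratum interaction in the
pooled model. Allele-frequency correlation between panels pairs
effect-allele frequencies (orientation-aware), and LD-decay profiles bin
pairwise dosage $r^2$ by physical distance.

## Reference experiments and their design

`scripts/acceptance.R` and the heaviest tests run four fixed experiments
whose defaults are the package's study conditions:

- **`gcCalibrationExperiment`** — three studies of 1,000 individuals, each
  an even mix of two subpopulations at FST 0.05 whose membership shifts an
  otherwise null trait by 0.5 SD, scanned over 50,000 independent variants
  with no structure adjustment. Uncorrected meta-analysis $\lambda$ lands
  near 3; double genomic control returns it to 1 by construction of the
  median rescaling.
- **`resolutionExperiment`** — 50 loci of 60 variants at 1.5 kb spacing,
  one causal variant explaining 0.6% of trait variance, population A
  (LD scale 50 kb, $n = 4{,}000$) versus A plus a diverged cohort B
  (FST 0.1 from the shared ancestral pool, LD scale 25 kb,
  $n = 2{,}000$). The default comparison mirrors the real design, where
  the single-ancestry cohort is a subset of the meta-analysis; the
  matched-n variant (`matchedN = TRUE`) splits A into halves so both
  analyses carry the same total n, isolating the LD-diversity effect,
  which is directionally consistent but much weaker — an honest caveat on
  how much of the headline resolution gain is diversity versus sample
  size.
- **`portabilityExperiment`** — discovery GWAS in population A
  ($n = 20{,}000$, FST 0.02, LD 50 kb) and B ($n = 5{,}000$, FST 0.15,
  LD 25 kb), targets of 2,500 matching each, 800 variants at 6 kb spacing,
  50 causal variants at $h^2 = 0.3$, with half the causal variants masked
  from the analyzed set. Masking emulates untyped causal variants — the
  mechanism that makes tag-SNP LD, and hence the score, population
  specific; with every causal typed the discovery scan simply selects the
  causal variants and portability loss nearly vanishes, while the typed
  half preserves the benefit of adding a B-like study to the meta-analysis.
- **`sexDimorphismExperiment`** — one cohort of 4,000 with genetic effects
  doubled in females; the female top-versus-bottom score-decile contrast
  exceeds the male contrast in essentially every replicate.

Numerical conventions throughout: coordinates are 1-based with closed
intervals; every random draw flows from one user seed through keyed
sub-streams (`subSeed`), so adding a stage never perturbs another stage's
draws and reruns are byte-identical; monomorphic variants yield missing
association rows and are counted, never silently dropped; empty grid cells
are reported as missing rather than raised as errors; and the $\chi^2_1$
median constant, INT offset, clumping tie-breaks and credible-set
tie-breaks are all fixed and documented above.

## Worked example

```{r pipeline, eval = FALSE}
library(portaPRS)
res <- runPipeline(outDir = "demo_run")
res$meta$lambda$raw       # uncorrected meta-analysis lambda
sapply(res$sets, setSize) # credible-set sizes at the demo scale
res$evalTest$incremental  # PRS incremental R2 in the target test split
```

The demo configuration (three discovery populations, two target regions,
800 variants, 30 causal variants, $h^2 = 0.3$, sex-effect ratio 1.5, a
physical-activity main effect and interaction) runs in well under a minute
and writes every artifact as a TSV with a provenance header. Problem sizes
in the tests and the reproduction script (20 replicates per direction
claim, 50,000-variant calibration, 1,000-locus oracle sweeps) were chosen
so each claim's Monte Carlo error is small relative to the margin being
tested.

## Known limitations

The LD model cannot produce indicator correlations arbitrarily close to 1
except at vanishing distance (the arcsine attenuation), so extremely tight
proxy structure is under-represented relative to real haplotypes. The
fixed-effects meta-analysis deliberately omits random-effects and
heterogeneity machinery. Fine-mapping assumes a single causal variant per
locus, as the approximate-Bayes-factor formulation requires. Lifestyle
covariates enter as already-categorized labels; instrument scoring is out
of scope.
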