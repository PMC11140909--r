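# portaPRS

Why does a polygenic score (PRS) trained in one ancestry lose accuracy in
another, and what does a multi-ancestry GWAS meta-analysis buy back?
portaPRS is an R package for researchers studying PRS portability: it
implements the full analysis chain —

- **per-study GWAS** of an inverse-rank-normalized quantitative trait
  (Blom scores, OLS with age/age²/sex/principal-component adjustment),
- **fixed-effects inverse-variance-weighted meta-analysis** with *double
  genomic control* (per-study SE inflation by √intercept, then a second
  √λ inflation of the meta-analysis SEs, λ = median(z²)/0.4549364),
- **Bayesian fine-mapping** with approximate Bayes factors
  `BF_i = exp[(Z_i² − log K_i)/2]` (K_i = number of contributing studies),
  posterior `π_i = BF_i / Σ BF_j`, and 99% credible sets computed in log
  space,
- **clumping-and-thresholding PRS** (250 kb / r² 0.8 clumping against the
  target panel, p-threshold grid from 5e-8 to 1, sex/region-stratified
  validation–test splits, incremental-R² selection, decile contrasts), and
- **PRS × sex/region/lifestyle interaction models** plus region-level
  allele-frequency correlation and LD-decay comparisons —

together with a **multi-population cohort simulator** (Balding–Nichols
allele-frequency divergence at controlled FST, Gaussian-copula haplotypes
with population-specific exponential LD decay, a shared polygenic
architecture with sex-dimorphic effects and gene–environment interaction)
so that every stage is testable without controlled-access biobank data.

The central data objects are S4 classes: `GenotypePanel` (dosage matrix +
variant map + population labels), `PRSModel` (weights + the clumping and
threshold parameters that produced them), `CredibleSet` (a locus's ranked
posterior table), with `PopulationSpec`/`ArchitectureSpec` describing what
to simulate. See the methods vignette
(`vignettes/portaPRS-methods.Rmd`) for the models, assumptions and design
choices.

## Worked example

The bundled demonstration pipeline simulates three discovery populations
(European-, East-Asian- and African-like divergence) and two African-like
target regions sharing one trait architecture (800 variants, 30 causal,
h² = 0.3, sex-effect ratio 1.5, a physical-activity interaction), then
runs GWAS → meta-analysis → fine-mapping → PRS → interactions:

```r
library(portaPRS)
res <- runPipeline(outDir = "demo_run")

res$meta$lambda$raw
#> [1] 2.738716          # uncorrected meta-analysis lambda (polygenic +
#>                       # structural inflation at demo scale)
nrow(attr(res$sets, "loci")); sapply(res$sets, setSize)
#> [1] 5                 # genome-wide-significant loci
#> 1 1 1 1 1             # every 99% credible set resolves to one variant
res$evalTest$incremental
#> [1] 0.2371613         # PRS incremental R2 in the held-out target test set
res$regional$perStratum
#>   stratum    n incremental    r2Full         pPrs
#> 1   South 1080   0.2569146 0.2604099 1.033804e-71
#> 2    West 1080   0.2701735 0.2771912 2.934809e-76
res$interactions$sex
#>           term  estimate         se         pInt    n     omnibusP
#> 1 PRS x sex[F] 0.2033707 0.03725538 5.344003e-08 2160 5.344003e-08
```

Read the numbers as follows: the raw λ of 2.74 reflects both true
polygenicity and the deliberately divergent discovery ancestries, and
double genomic control rescales the meta-analysis back to a calibrated
median; at this small, strong-effect demo scale each significant locus
fine-maps to a single variant; the PRS explains ~24% of trait variance
beyond age and sex in the target test split; and the simulated
female-amplified genetic effects surface as a positive PRS × sex[F]
interaction. Every artifact is also written under `demo_run/` as TSVs with
provenance headers, and rerunning with the same configuration reproduces
them byte for byte.

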