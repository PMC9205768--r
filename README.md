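# twinclock

Lineage tracing and Bayesian timing of a somatic clone shared by
monozygotic twins.

When the same somatic clone — for example a *CALR*-mutant
myeloproliferative neoplasm (MPN) — is found in both members of a twin
pair, the two tumors descend from a single ancestral cell transmitted
across the shared placenta before birth. Whole-genome sequencing of the
malignant cells in each twin then splits somatic mutations into those
*shared* by the twins (acquired before the most recent common ancestor,
MRCA, of the two tumors) and those *private* to each twin (acquired
afterwards). Because clock-like N[C>T]pG mutations (CpG deamination)
accrue at a near-constant rate, that partition dates the MRCA — and hence
the in utero transmission. `twinclock` is for analysts who want to run,
check, or stress-test this style of analysis: it implements every
computational stage, plus a synthetic twin generator so the whole
pipeline is exercisable without protected sequencing data.

## The model at the core

All times are years from fertilization; twin *i* is sampled at
T<sub>i</sub> = age<sub>i</sub> + 0.767 (40 weeks gestation). With
mutation rate λ (mutations/genome/year) and MRCA time t<sub>MRCA</sub>:

- s ~ Poisson(λ · t<sub>MRCA</sub>) — mutations shared by the twins,
- n<sub>i</sub> ~ Poisson(λ · E<sub>i</sub>) — mutations private to twin
  *i*, with exposure E<sub>i</sub> = t<sub>i</sub> − t<sub>MRCA</sub>
  (latent endpoint, default) or T<sub>i</sub> − t<sub>MRCA</sub> (fixed
  endpoint),
- priors λ ~ Exponential(mean μ, optionally truncated),
  t<sub>MRCA</sub> ~ U(0, U), t<sub>i</sub> ~ U(t<sub>MRCA</sub>, T<sub>i</sub>).

The posterior is fitted by adaptive MCMC (`fitMcmc()`) and independently
by deterministic two-dimensional quadrature (`posteriorQuadrature()`;
the latent endpoints integrate out through incomplete gamma functions),
with bridge-sampling log marginal likelihoods
(`marginalLikelihoodBridge()`, `compareModels()`) for comparing the two
exposure conventions.

Upstream of the model: three-caller consensus calling and twin
shared/unique classification (`readCallerVcf()`, `intersectCallers()`,
`classifySharedUnique()`, `filterVafDepth()`, `mergeSvCalls()`),
purity/copy-number adjusted cancer cell fractions
(`estimateMultiplicity()`, `computeCcf()`), Dirichlet-process binomial
mixture clustering (`clusterCcf()`, `pruneClusters()`), pigeonhole
lineage assignment (`assignLineagesPigeonhole()`), and clock-mutation
counting (`classifyNcptg()`, `assembleLineageCounts()`,
`burdenPerMb()`). `runPipeline()` orchestrates the stages from a single
config; `simulateTwinHistory()` / `simulateObservations()` /
`emitCallerCallsets()` generate fully ground-truthed synthetic inputs.

## Worked example

Time the MRCA from the clock-mutation count triple (2 shared, 89 and 114
private N[C>T]pG substitutions) with a cohort-derived rate prior of
1.71 N[C>T]pG/genome/year:

```r
library(twinclock)

counts <- lineageCounts(2, 89, 114, contextClass = "ncptg")
counts
#> LineageCounts [ ncptg ]: shared = 2 , unique A = 89 , unique B = 114

cfg <- timingConfig(counts, ratePriorMean = 1.71, seed = 1)
posteriorQuadrature(cfg)
#> TimingFit (quadrature)
#>   param    mean  median    q2.5  q97.5
#>  lambda  3.6855  3.4529  2.6426  6.089
#>  t_mrca  0.8271  0.7274  0.1592  2.048
#>      t1 26.3401 26.6235 14.7453 37.068
#>      t2 32.1219 33.3088 18.7239 39.025
#>   log marginal likelihood: -16.8281 (se 0)
```

Reading the output: the mutation rate posterior centers near 3.7
N[C>T]pG/genome/year; the MRCA time posterior has mean 0.83 years after
fertilization with a 95% credible upper bound of 2.05 years — a small
fraction of the 37.8-year prior range, i.e. the data place the clone's
common ancestor in very early life, consistent with in utero
transmission. `fitMcmc(cfg)` reproduces these numbers by MCMC (checked
to 2% on λ and 0.05 y on t<sub>MRCA</sub>) and adds a bridge-sampling
log marginal likelihood for model comparison.

The genome-wide burden summary from the case's per-twin variant
tallies:

```r
burdenPerMb(c(514, 705), c(240, 44))$rounded
#> [1] 0.24
```

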