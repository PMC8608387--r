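# pathwaynoise

Intrinsic/extrinsic noise decomposition for stochastic gene expression,
built for people analysing single-cell copy-number snapshots: analytic
Telegraph-model distributions and their extrinsic-noise compounds, numerical
certification of the integral representations that make transcription
parameters non-identifiable from snapshot data, exact Gillespie (SSA)
simulators for five gene-expression networks, and the pathway-reporter
estimator that decomposes expression noise from a single gene.

## The science in brief

The Telegraph model — a promoter switching on at rate λ and off at rate μ,
transcribing at rate K while on, transcripts decaying at rate δ = 1 — has
stationary copy-number law

    p(n) = K^n λ^(n) / (n! (λ+μ)^(n)) · ₁F₁(λ+n; λ+μ+n; −K),

with x^(n) the rising factorial. Any such law can be written *exactly* as a
compound of a narrower Telegraph law whose transcription rate varies across
cells with a scaled-beta distribution, and the negative binomial laws of
bursty expression admit analogous gamma and scaled-beta-prime mixtures. The
copy-number distribution alone therefore cannot tell dynamic (intrinsic)
variability from population (extrinsic) heterogeneity, and heterogeneity
always inflates apparent burstiness.

The decomposition of total noise (squared coefficient of variation,
η² = Var X / (E X)²) into η²_int + η²_ext classically needs two identical,
conditionally independent reporter genes, with η²_ext = Cov(X₁,X₂)/(E X₁ E X₂).
This package implements the *pathway-reporter* alternative: two different
species of one gene's pathway — nascent mRNA, mature mRNA, protein — whose
conditional means share a common transcription-throughput factor, so their
normalised covariance identifies the extrinsic noise on that factor. For
constitutive genes the identification is exact; for bursty genes it carries
a quantifiable intrinsic-overshoot bias that the package estimates and maps
as heatmaps over (λ, δ_P).

## A worked example

```r
library(pathwaynoise)

# 500 cells of the constitutive maturation model M1, with 20% extrinsic
# noise (squared CV 0.2) on the transcription rate and 12.5% on the
# maturation rate; two reporter copies share each cell's parameter draw
pop <- simulate_population(
  model_spec("M1"), gene_params(KN = 50, KM = 10),
  noise = list(KN = noise_gamma(5, 10), KM = noise_gamma(8, 1.25)),
  n_cells = 500, dual_reporter = TRUE, seed = 1)

pathway_reporter_estimate(pop$nascent, pop$mature)
#> <noise_decomposition (pathway-reporter, upstream-downstream, n=500)>
#>   eta2 total 0.5464 = int 0.3544 + ext 0.1921

dual_reporter_decompose(pop$mature, pop$mature2)
#> <noise_decomposition (dual-reporter, copy1-copy2, n=500)>
#>   eta2 total 0.2208 = int 0.0211 + ext 0.1997
```

Both estimators recover the injected transcription-rate noise of 0.2: the
pathway estimate (0.1921) from a single gene's nascent and mature counts,
the dual estimate (0.1997) from the two mature-mRNA copies. The pathway
total (0.546) is the nascent-mRNA noise — Poissonian intrinsic noise around
a mean of 5 (≈ 0.2, here 0.354 by sampling) plus the extrinsic part — while
the dual total (0.221) is the mature-mRNA noise, whose intrinsic part is
small at a mean of 50.

Certifying the non-identifiability representations:

```r
head(verify_representations(), 3)
#>    case max_abs_error     mean_gap support_max
#> 1 row1a  2.463307e-15 5.471179e-13         113
#> 2 row1b  6.605827e-15 2.193801e-13         112
#> 3 row2a  4.344095e-14 1.413980e-12         113
```

Higher-level drivers regenerate the benchmark comparisons:
`run_table2()` / `run_table3()` (constitutive models M1/M2),
`run_table4()` (bursty model M4), `run_heatmap()` (intrinsic-overshoot
grids) and `run_generality()` (delayed maturation, multiscale bursting,
cell-cycle features). A thin command-line wrapper with the same
functionality ships as `inst/scripts/pathwaynoise`; shipped configurations
live in `inst/configs/`.

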