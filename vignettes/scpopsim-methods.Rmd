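---
title: "The scpopsim simulation model and its evaluation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The scpopsim simulation model and its evaluation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`scpopsim` simulates single-cell RNA-seq counts for cohorts of
genotyped individuals with planted genetic, group, condition and batch
effects. This vignette is the package's account of the model: what is
assumed, which parameters matter, how the numerical corners are
handled, and what the shipped tests do and do not demonstrate.

## The two-layer model

The simulation is a gamma-Poisson hierarchy split into a population
layer and a cell layer.

### Population layer

For gene $i$, a population-wide mean $\lambda_i \sim
\Gamma(\alpha_m, \beta_m)$ is drawn. With probability `out_prob` a
gene is an expression outlier: its mean is replaced by the median mean
times a $\mathrm{logN}(\mu_{out}, \sigma_{out})$ factor, and the flag
and factor are recorded in the key.

Across-individual variability follows the mean-variance trend: genes
are binned by mean (ten equal-count bins by default) and each gene
draws a coefficient of variation $\sigma_i \sim \Gamma(\alpha_v^{(b)},
s_v\,\beta_v^{(b)})$ from its bin's fit. The similarity scale $s_v$
(dimensionless, default 1) multiplies the rate: $s_v > 1$ shrinks
between-individual differences. Baseline means per individual are
$\lambda_{ij} \sim N(\lambda_i, \lambda_i \sigma_i)$. Two deliberate
numerical choices live here:

* the second argument of the normal is interpreted as the **standard
  deviation** — $\sigma_i$ is fit to coefficients of variation, so
  $\lambda_i\sigma_i$ is an SD, and simulating with it as a variance
  would square away the units;
* negative draws are **floored at 0**. The floor matters only when
  $\sigma_i \gtrsim 0.5$ (the probability of a negative draw is
  $\Phi(-1/\sigma_i)$); see "Known limitations".

When the population parameters come from bulk RNA-seq, each
individual's means are quantile normalized onto the single-cell target
$\Gamma(\alpha_{sc}, \beta_{sc})$ at plotting positions
$(k - 0.5)/n$, with ties sharing the average-rank quantile.
Normalization runs after outlier injection and before any eQTL or DE
effect, so planted effects survive on the normalized scale. In
replication mode a user-supplied genes × individuals matrix replaces
the sampled baseline entirely (and quantile normalization applies only
if the matrix is flagged bulk-derived).

eQTL effects: a fraction `eqtl_prob` of genes become eGenes, each
paired with an eSNP drawn uniformly among SNPs on the same chromosome
within `dist_max` bp (default 1 Mb) and with minor allele frequency in
`[maf_min, maf_max]` (default [0.05, 0.5]). Effect sizes are
$\omega_i \sim \Gamma(\alpha_e, \beta_e)$ and enter multiplicatively,
$\lambda_{ij} \leftarrow \lambda_{ij}(1 + G_{ij}\omega_i)$, where
$G_{ij}$ is the 0/1/2 dosage. Outside co-regulation, eSNPs are drawn
**without replacement**, so the fraction of eGenes sharing an eSNP
equals `coreg_prop` exactly (up to pairing parity): shared eSNPs carry
information in downstream co-expression analyses, and accidental
sharing would blur the planted truth. Co-regulated pairs share the
first member's eSNP but draw independent effect sizes — sharing the
regulator, not its strength. Effects can be restricted to one cell
group (applied to that group's slice of the mean tensor) or one
condition cohort (applied to its individuals' columns); effect sizes
are strictly positive by construction, with an optional sign-flip
probability (default 0) provided as an explicit extension for users
who want bidirectional effects.

DE effects between groups or cohorts multiply means by
$\mathrm{logN}(\mu_{de}, \sigma_{de})$ factors, inverted with
probability `de_down_prob`; factors are recorded per gene per
group/cohort in the key. With a single group (or cohort) no group (or
condition) DE is drawn, since the factors are only identified relative
to another group.

### Cell layer

Individuals are assigned to batches of exactly `batch_size` distinct
members; when batch slots exceed the cohort, replicate slots go to the
least-replicated individuals (uniformly at random among ties), so
every individual appears at least once and technical replicates are
spread evenly. Cells split evenly across a batch's members, cell
groups are drawn per cell from `group_probs`, and condition cohorts
are apportioned over individuals by largest remainder.

Each batch applies per-gene multiplicative
$\mathrm{logN}(loc_b, scale_b)$ factors, replaced by their reciprocal
with probability 0.5 — batch distortions push in both directions.
Expected cell means are the individual/group slice times the batch
factor, rescaled so each cell's means sum to its expected library size
$L_c \sim \mathrm{logN}(lib_{loc}, lib_{scale})$; rescaling makes the
absolute scale of the population layer irrelevant and puts all
depth information into the library size. Counts then follow the
BCV-inflated gamma-Poisson:
$B_i = (bcv_{common} + 1/\sqrt{\mu})\sqrt{df/\chi^2_{df}}$ with **one
chi-square draw per gene** (cells of a gene share their trended
dispersion; a per-entry option would decouple them),
$\mu' \sim \Gamma(1/B^2, \mu B^2)$, count $\sim$ Poisson($\mu'$).
Note the $1/\sqrt{\mu}$ term means the gamma layer always contributes
one extra unit of mean-scaled variance: even at $bcv_{common}=0$ and
$df \to \infty$, var/mean $\to 2$, not 1. Optional dropout zeroes
entries with probability
$1/(1+e^{-k(\ln\mu - x_0)})$; with the default $k=-1$ the keep
probability rises logistically with log mean. Zero-mean entries always
yield zero counts.

### Seeding

One master seed spawns named substreams (genotypes, annotation,
conditions, base means, variances, individual means, eQTL, DE, design,
batch factors, library sizes, BCV, counts, dropout) via a string hash
kept below $2^{31}$. Identical parameters, genotypes and master seed
reproduce the bundle bit for bit, and changing only cell-level
parameters leaves the population-layer key untouched — useful for
simulating cohorts that share biology but differ in chemistry.

## Parameter estimation

* **Population** (`estimate_population_params`): genes with expression
  below 0.1 in more than half the individuals are excluded; a gamma is
  fit to the surviving gene means; genes are split into ten
  equal-count mean bins and a gamma is fit to the cv values of each
  bin. All gamma fits are maximum likelihood with method-of-moments
  starting values (the fitter itself is standard; moment matching is
  the independent oracle in the tests). Degenerate inputs
  (zero-variance, all-filtered, a bin with fewer than two positive-cv
  genes) raise errors naming the problem rather than returning
  infinite shapes.
* **Effect sizes** (`estimate_eqtl_params`): gamma fit to absolute
  effect sizes (at least ten finite non-zero values); sign flips are
  counted and reported, since the model's effects are magnitudes.
* **Single cell** (`estimate_sc_params`): log-normal fit to library
  sizes; outliers flagged by an upper MAD rule (log2 ratio to the
  median normalized mean exceeding 2 MADs above its median; the
  multiplier is an argument); gamma fit to the winsorized (10% per
  tail) non-outlier means; BCV common dispersion and degrees of
  freedom from a trended dispersion fit (edgeR); dropout midpoint and
  shape from a logistic least-squares fit of zero proportion against
  log mean, falling back to defaults with a warning when the fit is
  singular. Estimation never switches dropout on by itself.

## Defaults

Single-cell defaults follow the published splat model (library
log-normal (11, 0.2), outliers (0.05, 4, 0.5), BCV (0.1, 60), dropout
(0, −1) disabled). Population and effect-size defaults are embedded
constants representing a filtered population-scale reference panel:
gene-mean gamma (0.34, 0.008) with its deciles as bin edges; per-bin
mean cv declining from 0.40 (lowest decile) to 0.15 with within-bin
gamma shapes 6–24 (variability across individuals is modest and
tightens with expression once lowly expressed genes are filtered);
effect-size gamma (3.6, 12), i.e. mean multiplicative effect 0.3 per
allele. The default design is deliberately minimal: 6 individuals,
100 cells each, one batch, one group, one condition, eQTL on half the
genes within 1 Mb. These constants are stand-ins for fits to real
reference data — anyone with a reference panel should estimate rather
than accept them.

## What the generator emulates, and what it does not

Simulated genotypes are unstructured: per-SNP allele frequencies
uniform in a range, independent binomial dosages, uniform positions.
There is no linkage disequilibrium, kinship, or population
stratification — so mapping on simulated genotypes faces independent
cis-SNPs rather than LD blocks, and no confounding structure. Real
genotypes can be supplied as VCF to recover realistic structure.
Counts are UMI-free gamma-Poisson draws: no ambient RNA, doublets,
demultiplexing errors, or gene-length effects. Gene means are sampled
independently per gene, so co-expression exists only where planted
via shared eSNPs; replication mode reproduces empirical inter-gene and
inter-individual correlation instead. Passing tests therefore
demonstrate correctness of the planted-truth machinery, not that any
particular real dataset is matched; matching a dataset requires
estimating parameters from it.

## The evaluation suite and its biases

`de_test_pseudobulk` sums counts per individual and applies two-sided
Wilcoxon rank-sum tests with BH correction — deliberately simple and
robust. `map_eqtl_simple` mean-aggregates, inverse-normal transforms
per gene ($(rank-0.5)/n$ positions), fits per-cis-SNP OLS within
100 kb, takes each gene's top SNP and BH-adjusts top-SNP p-values
across genes. This replaces a mixed-model workflow with per-gene
permutation calibration; taking the minimum over ~dozens of cis SNPs
without per-gene multiplicity correction makes the procedure
**anti-conservative** — at 100 individuals its realized FDR against
the simulated truth is around 0.2 at a nominal q < 0.05, and its TPR
correspondingly high. The covariate hook exists for users who want to
residualize on known structure; with unstructured genotypes there is
nothing to residualize by default.

A consequence worth stating explicitly: the correlation between
estimated and planted effect sizes among true positives is bounded
well below 1 under this mapper. The estimated slope lives on the
inverse-normal (SD-unit) scale, roughly
$\omega\big/\sqrt{\sigma_i^2 + 2\,\mathrm{maf}(1-\mathrm{maf})\,\omega^2 + \text{noise}}$,
so it is diluted by each gene's own variability, saturates in
$\omega$, and is perturbed by top-SNP selection over independent
cis-SNPs. Monte-Carlo of that expression alone caps the correlation
near 0.8 at 100 individuals even with homogeneous $\sigma$, and the
full pipeline typically yields 0.45–0.60 (the acceptance script
reports ~0.52). Reference workflows with mixed models, LD-structured
genotypes and permutation-calibrated gene-level p-values report much
higher values (~0.95); closing that gap requires those components,
which are intentionally outside this package's scope.

## Numerical choices and degenerate inputs

* Gamma fits refuse zero-variance input; the MLE falls back to the
  moment estimate if the optimizer fails.
* Equal-count bins break mean ties by order of appearance; bin edges
  are midpoints between adjacent bins' extremes, with 0 and ∞ as outer
  edges; genes outside all recorded bins use the nearest bin.
* `filter_genotypes` keeps SNPs with recomputed MAF strictly greater
  than the threshold (a SNP at exactly 0.05 is removed); MAFs are
  always recomputed from dosages, never trusted from input.
* Monomorphic simulated SNPs are redrawn (up to a cap) so every SNP is
  usable.
* Silhouette widths define singleton clusters as 0; variance explained
  returns 0 for constant genes.
* Parameter serialization writes 17 significant digits so JSON and
  YAML round-trips are bit-exact.
* Counts are stored sparse; the cell pipeline runs in column blocks of
  about two million entries, and dense intermediates are kept only
  behind `keep_intermediates`.

## Problem sizes in the shipped tests

The test-suite simulations are sized for quick, repeated runs while
keeping every distributional check well-powered: module tests use
150–500 genes and up to a few hundred cells; distributional oracles
use 10,000 draws; the end-to-end evaluation checks use 504 genes ×
100 individuals with up to 500 cells per individual, three to five
seeds per property. Estimation round-trips run at 10,000 genes × 200
individuals.

## Known limitations

* The floor at zero in the individual-mean normal biases high-cv
  regimes: for bins with mean cv ≳ 0.5 the realized cv distribution is
  compressed and a re-estimated $\alpha_v$ drifts upward by ~15–20%.
  Parameter recovery is therefore exact only where the normal layer is
  effectively untruncated (cv ≲ 0.4), which is where filtered
  reference panels sit.
* The BH-on-top-SNP mapper is anti-conservative (above); treat its
  q-values as a ranking device against known truth, not calibrated
  error control.
* Group-specific effects duplicate the mean tensor per group, so
  memory grows linearly in groups; designs with many groups and large
  cohorts should keep intermediates off.
* Effect sizes are per-allele multiplicative and positive; dominance,
  epistasis and trans effects are not modeled.
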