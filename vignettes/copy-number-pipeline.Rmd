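---
title: "From windowed copy ratios to copy-number genotypes, differentiation scans and association"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From windowed copy ratios to copy-number genotypes, differentiation scans and association}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(canidcnv)
```

## The problem

Whole-genome read depth, averaged over fixed 1-kb windows and calibrated so
that diploid regions sit near 2, yields a continuous *copy ratio* (CR) per
sample and window. `canidcnv` discretizes these ratios into integer copy
numbers (CN), merges non-diploid windows into CNV events, and carries the
calls through the population analyses used in canid cohort studies: breed
differentiation scans, copy-number phylogenies, and genome-wide association
against breed-standard phenotypes. Because breed standards describe the
breed rather than the individual, every sample of a breed inherits the
breed's trait value — a design decision with statistical consequences that
recur throughout this vignette.

## Genotyping model

### Emission model

Each window's CR is modelled as Gaussian around the hidden integer CN
$N$, with spread proportional to both $N$ and the sample's diploid
dispersion $\sigma_{CR}$ (the standard deviation of CR over control
regions, estimated per sample):

$$\mathrm{sd}(N) = \max(0.5\,N\,\sigma_{CR},\; 0.5\,\sigma_{CR}).$$

The proportional term reflects that read-depth noise scales with the
number of copies generating reads. At $N = 0$ the proportional formula
degenerates to zero spread, so the scale is floored at
$0.5\,\sigma_{CR}$ — the same half-dispersion the deletion mixture model
(below) assigns to its CN 0 and CN 1 components. Hidden states are the
integers 0–20 plus one aggregate state for CN above 20, which emits an
equal-weight mixture of Gaussians with means 21–50; amplifications beyond
CN 20 are rare and poorly resolved by read depth, so they are reported as a
flagged "21+" call rather than as distinct states.

### Transitions and decoding

The 22-state transition matrix is trained by Baum–Welch on designated
training samples (each chromosome an independent chain), with emissions
held fixed at their dispersion-law values: the emission side is fully
determined by $\sigma_{CR}$, so only the chain's persistence structure
needs learning. Initialization is 0.9 self-transition with the remainder
uniform, start mass 0.9 on CN 2; EM stops when the mean per-window
log-likelihood improves by less than $10^{-4}$ or after 100 iterations.
Decoding uses the scaled forward–backward recursion (posteriors per window,
no underflow for $10^5$-window chromosomes). Training samples are dropped
from the genotyped cohort, so the transition matrix is never fit to the
samples it decodes.

### Cohort smoothing and credible sets

Genotypes are then updated jointly across the cohort. For each window $w$,
the posteriors of *all* samples over a five-window sliding range centred on
$w$ (four-window overlap between successive ranges; ranges truncated to
three and four windows at chromosome ends rather than padded) are averaged
into a local prior $p(N)$, and each sample's CR at $w$ is re-scored through
Bayes' rule:

$$p(CN = N \mid cr) =
  \frac{\mathrm{PDF}(cr;\, N, \mathrm{sd}(N))\; p(N)}
       {\sum_M \mathrm{PDF}(cr;\, M, \mathrm{sd}(M))\; p(M)}.$$

The "expected joint probability within the range" is implemented as the
arithmetic mean of single-window posteriors over the 5-window × all-samples
block: a literal joint distribution over five windows and 22 states does
not define a prior over one window's state, while the block mean is exactly
the exchangeable-prior reading of the same quantity. Smoothing runs in a
single pass over the ranges; iterating it would repeatedly sharpen the
prior toward the cohort consensus with no stopping criterion to justify.

The reported genotype is the credible CN interval: states are accumulated
in order of decreasing smoothed posterior until 0.95 mass is reached, and
the interval $[\min, \max]$ of that set is output together with the MAP
state. Ties in the accumulation order are broken toward the state nearer
CN 2, then toward the lower CN — degenerate posteriors thus default to the
least surprising genotype. The MAP state always lies inside the interval.

A practical calibration note: with $\sigma_{CR} = 0.15$ a CN 3 carrier
needs $cr \gtrsim 2.55$ for the 0.95-mass set to exclude CN 2, so roughly
2% of genuinely CN-3 windows retain 2 in their interval. Coverage of the
credible sets is correspondingly conservative-to-nominal (the acceptance
suite checks ≥ 93% empirical coverage at 0.95 nominal), while MAP accuracy
is limited only by emission overlap.

## From calls to events

A window is a *duplication* if at least one sample's credible interval lies
entirely above 2, a *deletion* if one lies entirely below; intervals
touching 2 are diploid, and a window may be both. Maximal same-type runs —
adjacent in grid order, so masked gaps between consecutive windows are
ignored — merge into events, with a 1-kb floor that keeps single full
windows. Windows that are simultaneously dup and del yield two overlapping
events of different types rather than a forced arbitration.

Two refinements operate on the per-window genotypes:

* **Duplication interval classification.** Credible intervals at a
  duplicated window are reduced to disjoint CN categories: the modal
  interval and the most distant non-overlapping interval(s) seed the
  categories, remaining ranges join the category of maximal Jaccard
  overlap, ranges overlapping nothing spawn intermediate categories, and
  the assignment iterates to a fixed point (cap 50, idempotent on its own
  output). The intermediate-category rule is a reconstruction — the
  original procedure's exact rule is not published — and is documented as
  such rather than asserted.
* **Deletion re-genotyping.** Deletion windows are refit with a
  three-component Gaussian mixture with fixed means 0, 1, 2 and fixed
  scales $\sigma_{CR}/2, \sigma_{CR}/2, \sigma_{CR}$; EM updates the
  weights only. The published component scales are read as standard
  deviations, not variances, which keeps them commensurate with the HMM
  emission scale (on the variance reading, the CN 2 component would be
  $\sqrt{2}$ times *wider* than the emission model's, and CN 0/1 narrower
  by $\sqrt{2}$ than their own floor). The cohort-averaged posteriors act
  as the prior for each sample's MAP genotype — the same
  empirical-Bayes pattern as the HMM smoothing.

Gene overlap flags events covering ≥ 5% of a gene (partial) or containing
it entirely (full). The gain/loss clustering statistic — per-chromosome
mean nearest-neighbour distance between event midpoints against uniform
random placement, aggregated across chromosomes by Fisher's
$-2\sum\ln p_i$ on $2k$ df — is a reconstruction: only the Fisher
aggregation of the original test is documented.

## Population structure

**V_ST.** For two groups of CN values,
$$V_{ST} = 1 - \frac{n_1 \mathrm{Var}(x_1) + n_2 \mathrm{Var}(x_2)}
                    {(n_1 + n_2)\,\mathrm{Var}([x_1, x_2])},$$
with sample variances ($n-1$ denominator, the R `var` convention; the
formula's `Var` is ambiguous and this choice is recorded). Values are ≤ 1,
equal 1 exactly for fixed between-group differences, and may be negative;
negatives are retained so that medians over subsamples stay unbiased.
Because small groups bias the genomic V_ST distribution, every clade is
subsampled to six individuals 1000 times and the median kept; clades of
exactly six admit no subsampling freedom and are evaluated once,
deterministically.

**PCA.** A common basis is fit on a random clade-balanced subset (equal
samples per clade) of the centred, scaled CN matrix; all other samples are
projected with the stored centering/scaling/rotation, so over-represented
clades cannot dominate the axes and projection is exact on the basis
samples.

**Trees.** Euclidean distances on CN vectors feed neighbour-joining
(UPGMA available behind a flag; NJ is the default because it is consistent
on additive distances and the conventional choice for distance matrices of
this kind). To compare trees over different sample sets, the sample
distance matrix is collapsed to breed level through the indicator
projection $B(B^\top B)^{-1}B^\top D$, column-averaged within breeds,
symmetrized by $(A + A^\top)/2$ and zero-diagonaled — "propagated across
the diagonal" is ambiguous in the source and symmetrization + zero
diagonal is the reading adopted. Matrices are compared by Pearson
correlation of upper off-diagonal entries and by the Frobenius norm of the
difference after scaling each to unit Frobenius norm, making the
comparison scale-free. The haplotype-sharing correction removes deletion
windows overlapping shared-haplotype intervals and rescales squared
distances by the retained-window fraction.

## Association

Two tests, chosen by phenotype type, both restricted to the
duplication/deletion window space:

* **Generalized CMH** (categorical, or split continuous traits): the
  Landis correlation-type statistic with integer scores — CN category and
  binary group code — summed over strata, $\chi^2_1$ reference. With one
  stratum it reduces exactly to $(n-1)r^2$. Traits are split at the 30th
  percentile (boundary ties to the bottom group; the source does not say
  which side the boundary breed joins, and "bottom" makes the bottom group
  never empty). Stratification into two similarly sized breed-tree
  substrata — the bipartition of the CNV NJ tree whose tip split is
  closest to half — is applied only when the genomic inflation factor
  $\lambda$ (median observed $\chi^2_1$ over 0.4549) exceeds 1.1; the
  trigger policy is stated only qualitatively in the source, and 1.1 is
  the conventional GWAS rule of thumb.
* **Linear regression** (continuous traits): trait on CN with the first
  four PCs of the scaled CN matrix as stratification covariates, two-sided
  t-test on the CN coefficient.

Two thresholds are reported: primary $-\log_{10}(0.05/n_{\text{windows}})$
(Bonferroni over CNV windows) and secondary one decade below, acknowledging
that successive windows of one event are not independent tests. No further
correction is applied; the dual-threshold report *is* the output. Disease
cohorts are selected by prevalence: breeds under one affected in 2000 are
ineligible as cases; the top prevalence quantile becomes cases, the bottom
controls, with a warning under 21 case breeds.

## Annotation cross-references

* **Hi-C:** for each bin overlapping a CNV region, off-diagonal support is
  divided by the bin's self-support; the 95th quantile of the pooled ratio
  distribution (pooled, not per-row — per-row quantiles over a few dozen
  ratios would be dominated by discreteness) sets the significance
  threshold, strict inequality. The ratio direction (other/self) keeps
  ratios comparable across bins of different coverage.
* **CTCF:** a called contact is verified when its left anchor carries at
  least one plus-strand motif and its right anchor at least one
  minus-strand motif — convergent, inward-facing orientation.
* **lncRNA:** association signals are paired with lncRNAs within 10 kb and
  tabulated trait × top-expression tissue; under an independent-margins
  multinomial null, cell excesses are reported as
  $z = (obs - exp)/\sqrt{n p q (1 - pq)}$ with $p, q$ the marginal
  proportions — the source says only "in terms of standard deviations",
  and the multinomial cell SD is the natural reading.
* **Conservation:** elements above the 95th score quantile are "conserved";
  associated vs background non-exonic variants are tested for conservation
  overlap with a two-sided Fisher exact test.
* **Leading SNP:** structural-variant p-values within ±1 Mb of a leading
  SNP are binned into 10 equal 200-kb blocks (the source fixes neither the
  count; 10 gives blocks comfortably larger than typical events) and the
  SNP's block is ranked by its count of sub-threshold p-values.

## The synthetic cohort generator

The generator is the package's ground truth: clade → breed → sample
hierarchies, planted CN events (clade-, breed- or cohort-scoped; carriers
drawn per sample or per breed — the latter emulating breed-fixed variants),
per-sample dispersion $\sigma_s$ drawn uniformly from a configured range
(real cohorts mix coverages), and copy ratios drawn from the emission
model's own law $\mathrm{CR} \sim N(\text{CN}, \max(0.5\,\text{CN}\,
\sigma_s, 0.5\,\sigma_s))$. Breed phenotypes are
$\text{intercept} + \beta \cdot \overline{\text{CN}}_{\text{breed}} +
N(0, \sigma_e)$, identical for all samples of a breed; binary traits
threshold the latent value at its 70th percentile, mirroring the 70/30
case–control construction. Annotation tracks include a planted long-range
Hi-C contact at ten times background support flanked by convergent CTCF
motifs, plus random genes, tissue-labelled lncRNAs, conservation scores
and shared-haplotype intervals.

Planted QC violations cycle through three types: inflated dispersion
(σ = 0.8, far above the 0.45 cap), a bimodal block shift (half the genome
at 1.5, half at 2.7 — a Gaussian *mean* shift alone is invisible to a
moment-fitted Kolmogorov distance, so the planted violation expresses
faulty normalization through shape), and strong AR(1) neighbour
correlation (φ = 0.9). Default QC cutoffs are 0.45 on CR dispersion (the
published hard threshold) and, where the source gives no number, 0.1 on
Kolmogorov distance and 0.3 on |lag-1 correlation| — both far beyond the
sampling noise of genome-scale window counts, both configurable.

What the generator does *not* emulate: GC and mappability bias, gaps and
masked-region geometry, sex chromosomes, linkage between events,
within-breed phenotype variance, and measurement error in breed standards.
Tests passing on this cohort therefore validate the inference machinery —
decoding, smoothing, calibration, test statistics — not robustness to
normalization artifacts, which the QC stage is designed to reject rather
than repair.

### Study-scale designs used by the validation suites

The genotyper recovery suite uses 100 samples, 2 chromosomes × 2000
windows, $\sigma_{CR} \in [0.1, 0.2]$ and 20 planted events of CN 0–5 at
frequencies 0.3–0.65. The GWAS power suite uses 30 breeds × 4 samples and
1000 variant windows: six 50-window breed-fixed clade blocks (the
clade-level structure the PC covariates are meant to absorb — on real
cohorts the top PCs capture population structure because it spans many
windows), 34 smaller sample-level background events, and one breed-fixed
causal deletion at frequency 0.5 whose per-copy effect is 1.5 trait SDs.
Effects are expressed in units of the total across-breed trait SD (the
standard GWAS convention for standardized effects): with carrier frequency
0.5 this puts the residual SD at 0.661 and means the variant explains
roughly half the across-breed trait variance, consistent with the
large-effect loci that underlie breed-standard morphometrics. Null
calibration (type-I error, inflation factor, permuted phenotypes) is
checked at 1000 replicates.

## Known limitations

* Breakpoints are window-resolution; events below 1 kb are out of scope.
* The aggregate "21+" state reports no point estimate beyond the flag.
* The clustering test and the duplication-interval intermediate-category
  rule are reconstructions of sparsely documented procedures and are
  labelled as such above.
* Breed-standard phenotypes induce within-breed pseudo-replication; the
  regression treats samples as exchangeable, as the original design does,
  so nominal p-values are anti-conservative whenever genotypes are
  breed-structured but unrelated to the trait. The inflation factor and
  the stratified re-test exist precisely to catch this.
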