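---
title: "Methods and design of the mixploidy analysis pipeline"
author: "mixploidy maintainers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and design of the mixploidy analysis pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mixploidy)
```

# Scope

`mixploidy` implements a complete desk-scale analysis for heteroploid
(mixed diploid--tetraploid) population genomics, of the kind used to study
big sagebrush (*Artemisia tridentata*) and similar polyploid complexes:
ploidy determination from flow-cytometry relative fluorescence, dosage
genotyping from allele read counts, variant filtering and thinning,
mixed-ploidy relatedness with principal coordinates, dosage-aware
admixture with cluster-number selection and introgression classification,
inference of auto- vs allopolyploid inheritance, and presence-raster
overlap accounting for climate-niche projections. A synthetic-data module
generates every input the downstream stages consume, so the whole chain is
testable without field data.

# The synthetic study design

`simConfig()` describes a set of gene pools and the observation model;
`studyConfig()` is the default design: two diploid pools, two tetraploid
pools, fifteen individuals each, six diploid hybrids at
$q = (0.5, 0.5)$, and 300 biallelic loci.

**Drift model.** Cluster allele frequencies follow a Balding--Nichols
parameterisation: given an ancestral frequency $p$ and drift parameter
$F$, a cluster frequency is drawn from
$\mathrm{Beta}\!\left(p\,\tfrac{1-F}{F},\,(1-p)\tfrac{1-F}{F}\right)$,
which has mean $p$ and variance $F\,p(1-p)$. Ancestral frequencies are
drawn $\mathrm{Uniform}(0.05, 0.95)$ so that simulated markers resemble
the discovery-panel SNPs that survive a minor-allele-frequency filter;
this is deliberately *not* a neutral site-frequency spectrum (see
Limitations). Each cluster may drift from the shared ancestor or, via the
`progenitor` option, from an earlier cluster -- the latter expresses
tetraploid lineages descended from a specific diploid subspecies, which
is what makes progenitor-specific relatedness contrasts testable.

**Why unequal drift defaults (0.3 / 0.15).** In the systems this pipeline
targets, the diploid subspecies are anciently diverged while tetraploid
lineages arose recently (e.g. via Pleistocene whole-genome duplication),
so the default study design uses deeper drift for the diploid pools than
for the tetraploid pools. This also balances the statistical information
of successive cluster splits: a tetraploid individual carries twice the
allele copies of a diploid, so with equal drift the likelihood gain from
separating the two tetraploid pools is about twice that from separating
the diploid pools, and second-difference statistics on the likelihood
profile (delta-K) then cannot resolve the true cluster number. With the
deep-diploid/shallow-tetraploid contrast the successive gains are
comparable and the four-pool structure is cleanly recoverable.

**Segregation.** Diploids and tetrasomic tetraploids draw dosage
$\mathrm{Binomial}(v, \pi_{il})$ with
$\pi_{il} = \sum_k q_{ik} f_{kl}$ (each allele copy's cluster of origin
i.i.d. from $q_i$). Disomic tetraploids draw the sum of two independent
$\mathrm{Binomial}(2, \cdot)$ subgenome contributions with no
inter-subgenome exchange. Subgenome frequencies interpolate with the
divergence parameter $\delta$: $f_1 = f(1-\delta)$ and
$f_2 = f + \delta(1 - f)$, so $\delta = 1$ fixes the subgenomes for
opposite alleles at every site (the allopolyploid extreme in which every
individual is the duplex heterozygote), and $\delta = 0$ collapses to
tetrasomic-equivalent behaviour.

**Reads.** Total depth per cell is $\mathrm{Poisson}(\bar d)$ (mean 50 by
default, a typical target for dosage calling in tetraploids); alternate
reads are $\mathrm{Binomial}(n, (d/v)(1-e) + (1-d/v)e)$ with per-site
error $e$ (default 0.01) folded in symmetrically. Overdispersed depth is
not modelled.

**Fluorescence.** Relative fluorescence (sample/standard channel ratio)
is Normal within a ploidy band, truncated positive; defaults place the
diploid band at mean 6.73 (SD 0.15) and the tetraploid band at 12.2
(SD 0.49), i.e. at twice the diploid signal, matching genome-size
doubling.

All generators are deterministic given (configuration, seed); the
pipeline fans a single seed out to fixed per-stage offsets so enabling or
disabling one stage never changes another stage's draws.

# Ploidy calling

`callPloidy()` uses a diploid band centre $c$ (calibrated as the median
RF of known diploids -- robust to an occasional mis-labelled tetraploid)
and a relative tolerance $t$ (default 0.15): diploid if the replicate
mean lies in $c(1 \pm t)$, tetraploid if in $2c(1 \pm t)$, otherwise
ambiguous -- the analogue of excluding field samples with inconclusive RF.
With the default bands, which are more than ten SDs apart, simulated
samples essentially never misclassify at $t = 0.15$; the tolerance was
chosen as roughly four band SDs, and no numeric rule tighter than that is
claimed. Replicate coefficients of variation above 0.05 are flagged but
do not force ambiguity, since replicate scatter and band membership are
separate questions.

# Dosage genotyping

For alternate-read count $a$ of $n$ reads at ploidy $v$ and site error
$e$, the genotype likelihood for dosage $d$ is
$\mathrm{Binomial}\!\left(a \mid n, \tfrac{d}{v}(1-e) +
(1-\tfrac{d}{v})e\right)$. With a flat prior the posterior is the
normalised likelihood and the call is the MAP dosage, ties broken toward
the lower dosage for determinism. An empirical-Bayes mode iterates a
per-site genotype-frequency prior (prior $\leftarrow$ mean posterior)
to convergence ($10^{-8}$, at most 10,000 iterations); with a flat prior
the posterior is closed-form and no iteration is needed. Per-site error
rates come from pileup counts as the fraction of reads matching neither
allele, floored at $10^{-3}$ and capped at 0.49. Cells with depth not
exceeding 5 (strict) are missing.

At mean depth 50 the adjacent tetraploid dosage classes (expected
alternate-read fractions 0.2575, 0.50, 0.7425 at $e=0.01$) are about 3.4
binomial SDs apart, so heterozygous tetraploid classes retain an
irreducible 4--7% confusion rate; diploid calls are essentially
error-free. Overall recovery on the default study design is therefore
about 98.7--98.9%, dominated entirely by adjacent-class swaps in
tetraploids; recovery approaches 100% as depth grows, and the error rate
decreases monotonically with depth.

# Variant filtering and thinning

`filterSites()` retains biallelic sites with QUAL strictly above 100,
missing fraction at most 10%, and ploidy-weighted alternate allele
frequency (alternate dosage sum over allele copies among non-missing
calls) strictly above 0.04, evaluating all rules on the input matrix and
applying them jointly. The frequency is computed on the combined
heteroploid sample because filtering follows the diploid/tetraploid
intersection step in the pipeline order. `thinOnePerWindow()` emulates
one-SNP-per-locus selection with greedy 139-bp windows (the read length)
anchored at the first unconsumed SNP per chromosome; within a window the
least-missing SNP wins, ties to the lowest position. Both operations are
idempotent, monotone in their thresholds, and independent of individual
ordering.

# Mixed-ploidy coancestry

For a locus with alternate frequency $p$ and dosage fractions
$x = d_x/v_x$, $y = d_y/v_y$, the product-moment coancestry is
$$\hat\theta_\ell = \frac{x y}{p} + \frac{(1-x)(1-y)}{1-p} - 1,$$
averaged over pairwise-complete loci (sites with $p \in \{0, 1\}$
excluded) and rescaled as $\hat r = \hat\theta\sqrt{v_x v_y}$. The
rescaling makes the non-inbred expectations ploidy-free: 1 for
self-comparison (unscaled $\hat\theta$ is $1/2$ for diploids and $1/4$
for tetraploids), $1/2$ for diploid parent--offspring, 0 for
non-relatives. Estimates outside $[0, 1]$ are ordinary sampling noise of
method-of-moments relatedness and are not truncated. The exact estimator
behind the published tool for polyploid relatedness is not printed
anywhere we can cite, so this form -- chosen to satisfy the stated
self/non-relative expectations at both ploidies -- is validated by
calibration against pedigreed simulations and a brute-force oracle, not
by bit-for-bit agreement with that tool. Allele frequencies default to
ploidy-weighted estimates from the full sample; with few individuals
this induces the usual $O(1/N)$ downward bias of frequency-plug-in
relatedness estimators, which disappears when true (or external)
frequencies are supplied.

Principal coordinates are extracted by direct eigen-decomposition of the
symmetrised relatedness matrix (no distance conversion), coordinates
scaled by the square root of the non-negative eigenvalues, and variance
explained reported against the sum of positive eigenvalues. Group
contrasts (e.g. a tetraploid lineage against each candidate diploid
progenitor pool) use a two-sided Wilcoxon rank-sum test on the pairwise
values.

# Admixture, cluster number, introgression

`fitAdmixture()` maximises
$\sum_{i\ell} \log \mathrm{Binomial}(d_{i\ell} \mid v_i, \textstyle\sum_k
q_{ik} f_{k\ell})$ by EM on latent allele-copy ancestries (compiled in
C++), with Dirichlet(1) starts for $q$, pooled-frequency-plus-noise
starts for $f$, frequencies clipped to $[10^{-8}, 1-10^{-8}]$, and
monotone log-likelihood asserted in the tests. This is a
maximum-likelihood stand-in for Bayesian MCMC clustering with a polyploid
model: the estimand ($q$, $f$) is the same, the fit is deterministic
given a seed, and restarts replace chain replication.

**Cluster number.** The delta-K statistic,
$\Delta K = |\bar L(K+1) - 2\bar L(K) + \bar L(K-1)| / \mathrm{SD}(L(K))$,
presumes stochastic replicate likelihoods. A converged deterministic EM
gives replicates whose SD is numerical stopping noise, which degenerates
the ratio; `runAdmixtureScan()` therefore defines a replicate as a refit
on a random 80% subsample of loci (fresh random start, log-likelihood
rescaled to the full locus count), so the SD reflects locus-sampling
variance on a scale comparable across K. Replicates with zero SD leave
delta-K undefined at that K, and a flat profile (all second differences
zero) selects no K rather than an arbitrary one. On the default study
design the true K = 4 is selected in 9--10 of 10 replicate experiments.

**Introgression.** An individual's home cluster is its argmax-q cluster;
at threshold $t \in \{0.05, 0.10, 0.15\}$ it is introgressed by donor
cluster $j$ iff $q_{ij} > t$ (strict, matching a "q > 0.1" style rule).
The summary table reports percentages of each home cluster's membership,
necessarily non-increasing in $t$. Argmax assignment is used because
sampling-locality labels do not exist for synthetic data.

# Inheritance mode

The genotype-frequency vs allele-frequency spectrum is binned at width
0.05 (half-open bins); the decision statistic sums, over loci whose
allele frequency lies in $[0.4, 0.6)$, the log-likelihood of the observed
dosage-class counts under tetrasomic segregation
($\mathrm{Binomial}(4, p)$) against the disomic extreme (convolution of
$\mathrm{Binomial}(2, p_1)$ and $\mathrm{Binomial}(2, p_2)$ with
$p_1 = \min(2p, 1)$, $p_2 = \max(2p-1, 0)$ -- at $p = 0.5$, the pure
duplex class). Expected class probabilities are floored at $10^{-6}$ and
renormalised so the structural zeros of the extreme model keep the
statistic finite; one non-duplex genotype then contributes roughly
$+12.8$ nats, which makes the classifier decisive once a handful of
central-bin loci are available. The call is tetrasomic above $+\Lambda$,
disomic below $-\Lambda$ ($\Lambda = 10$ nats), indeterminate otherwise,
and the count of distinct observed genotype classes in the central bins
is reported alongside (five is the tetrasomic hallmark, one -- the duplex
-- the fixed-subgenome hallmark). Because the comparator is the fixed
extreme, the statistic saturates away from $\delta \approx 1$: it is
monotone in subgenome homogenisation near the allopolyploid extreme
(where the call flips, around $\delta \approx 0.97$ under the default
sample sizes) but not across the whole $\delta$ range. Intermediate
disomic models are generator options, deliberately not classifier
hypotheses.

# Niche-raster accounting

Vote rasters are thresholded at a strict cutoff (default 0.6), merged
per cell into four classes (A-only, B-only, co-occurring, absent), and
class areas are cell counts times a uniform nominal cell area (1 km^2
grids are assumed; geographic area distortion is out of scope). Percent
loss against a reference scenario is
$100\,(\mathrm{ref} - \mathrm{scen})/\mathrm{ref}$, rounded half-up to
two decimals to match the conventional table formatting; co-occurrence
shares are rounded to whole percent. ESRI ASCII grids are read and
written directly (six-line header plus a numeric matrix).

# Numerical choices

* EM stopping: relative log-likelihood change below $10^{-8}$ (default)
  or 2,000 iterations; the K-scan uses $10^{-6}$/600 because subsample
  SDs (hundreds of log-units) dwarf stopping deficits there.
* Frequency clips: $10^{-8}$ in the EM, $10^{-12}$ in the generator;
  dosage-likelihood floors never apply because the flat-prior posterior
  is closed-form.
* Ties: MAP dosage ties break to the lower dosage; thinning ties to the
  lowest position; argmax-q ties to the first cluster.
* Degenerate inputs: all-zero likelihoods yield a missing call; pairs
  with zero shared loci yield a missing relatedness entry (logged);
  empty matrices pass through filters with a warning.

# Problem sizes

The shipped tests and the acceptance script use desk-scale sizes chosen
to keep Monte-Carlo standard errors meaningful: 66 individuals x 300
loci for structure recovery (10 replicate experiments, K = 1..6, 10
subsample replicates each), 2,000 loci for relatedness calibration, 200
individuals x 300 loci for inheritance-mode simulations, and mean depth
50 for genotyping. These are the package's standing defaults for
synthetic studies; all scale up by configuration.

# Limitations

* The generator draws loci independently: no linkage, no coalescent
  history, no selection; the thinning step's effect on real linkage
  structure is not represented.
* The uniform base-frequency design overweights intermediate-frequency
  sites relative to a real SFS; genotyping error rates on real data
  (mostly low-frequency sites) will be lower than the simulated ones.
* Passing recovery tests on this generator demonstrates correctness of
  the estimators under their own model assumptions -- binomial dosages,
  symmetric read error, independent loci -- not robustness to
  model-misspecified field data.
* Pooled-sample fluorescence deconvolution is not implemented; each
  record is one individual.
* The delta-K subsample-replicate construction is a pragmatic answer to
  pairing a deterministic optimiser with a statistic designed for MCMC
  replicates; where it is indecisive, inspecting the likelihood profile
  and the q-matrices directly remains the sensible fallback.
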