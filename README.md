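# mixploidy

Population-genomic analysis for **heteroploid** systems — samples that mix
diploid (2n = 2x) and tetraploid (2n = 4x) individuals, as in big sagebrush
(*Artemisia tridentata*) and many other polyploid plant complexes. The
package covers the full analysis chain a study of such a system needs:

* **Ploidy calling** from replicated flow-cytometry relative fluorescence
  (RF = sample/standard channel ratio): diploid if the mean RF falls in a
  calibrated band `c(1 ± t)`, tetraploid in `2c(1 ± t)`, otherwise
  ambiguous and excluded.
* **Dosage genotyping** from allele read counts: for dosage *d* of ploidy
  *v*, alternate reads are `Binomial(n, (d/v)(1−e) + (1−d/v)e)` with
  per-site error *e*; flat-prior MAP calls (an empirical-Bayes
  genotype-frequency prior is available), cells at depth ≤ 5 set missing.
* **Variant filtering** (biallelic, QUAL > 100, ≤ 10% missing,
  ploidy-weighted alternate allele frequency > 0.04) and greedy
  one-SNP-per-139-bp **window thinning**.
* **Mixed-ploidy coancestry**: per locus
  `θ̂ = xy/p + (1−x)(1−y)/(1−p) − 1` on dosage fractions, averaged over
  pairwise-complete loci and rescaled by `√(v_x v_y)` so self-comparisons
  expect 1 and non-relatives 0 at any ploidy; PCoA by direct
  eigen-decomposition; Wilcoxon contrasts of pair groups.
* **Dosage-aware admixture** by EM on
  `d ~ Binomial(v, Σ_k q_k f_k)` (C++ core), Evanno-style ΔK selection of
  the cluster number over replicate scans, and strict q-threshold
  introgression tables at q > 0.05/0.10/0.15.
* **Inheritance-mode inference** (auto- vs allopolyploid): the
  genotype-frequency spectrum near allele frequency 0.5 is scored by a
  log-likelihood ratio of tetrasomic `Binomial(4, p)` against the
  fixed-subgenome disomic extreme (pure duplex AATT at p = 0.5).
* **Niche-raster accounting**: threshold normalised vote grids at > 0.6,
  merge two subspecies models into presence classes, class areas and
  percent habitat loss between climate scenarios; ESRI ASCII grid I/O.
* A **synthetic-data generator** (gene-pool drift, tetrasomic/disomic
  segregation, read counts, fluorescence, vote rasters) so the entire
  pipeline runs and is tested end-to-end without external data.

Data containers are Bioconductor-style S4: `DosageSet` and `ReadCountSet`
extend `SummarizedExperiment` (sites × individuals, ploidy in `colData`);
`CoancestryMatrix`, `QMatrix` and `PresenceGrid` are lightweight validated
classes. Ploidy-aware VCF (GT like `0/0/0/1`, AD read depths) and TSV
import/export are included.

## Worked example

Simulate the default study design (two diverged diploid pools, two
younger tetraploid pools, six diploid hybrids at q = 0.5) and run the
whole pipeline:

```r
library(mixploidy)
cfg <- pipelineConfig(sim = studyConfig(seed = 11), Ks = 1:5,
                      nReps = 4, seed = 11)
bundle <- runPipeline(cfg)
reportBundle(bundle)
```

```
== mixploidy pipeline report ==
Ploidy calls: ambiguous=1, diploid=36, tetraploid=29
Sites retained after filtering/thinning: 295
Best-fit K (delta-K): 4
Introgression (% of home cluster, by threshold):
 home donor    t_0.05     t_0.1   t_0.15
    1     2  0.000000  0.000000  0.00000
    1     3  6.666667  0.000000  0.00000
    1     4 13.333333  6.666667  0.00000
    2     1 38.095238 28.571429 28.57143
    ...
Inheritance mode: tetrasomic (LLR 6163.8, 5 classes)
Niche areas (km^2): A-only 75, B-only 75, co-occurring 50, total 200 (overlap 25%)
```

Reading the output: 65 of 66 simulated individuals get a conclusive
ploidy call (the ambiguous one mirrors field samples with inconclusive
RF). ΔK correctly recovers the four simulated gene pools. The
introgression table's `home 2 / donor 1` row shows 28.6% at q > 0.1 —
exactly the six true hybrids among the 21 individuals whose largest
ancestry component is cluster 2. The tetraploids simulate tetrasomically,
and the spectrum shows all five dosage classes at allele frequency 0.5,
so the mode call is tetrasomic (autopolyploid-consistent) with a strongly
positive log-likelihood ratio.

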