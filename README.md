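# islandload

Comparative population genomics of a bottlenecked **island** population and
its **mainland** counterpart: genome-wide diversity, runs of homozygosity
(ROH) and inbreeding, genetic load across mutational-effect categories, and
differentially fixed variants — the analysis core used to ask whether small
insular populations of primates (or any diploid species) are accumulating or
purging deleterious variation.

The package is aimed at conservation and population genomicists who have a
multi-sample VCF, sample metadata (island/mainland), outgroup genotypes and a
VEP-style consequence table — or nobody's data at all: a built-in forward
Wright–Fisher simulator generates fully ground-truthed datasets in the same
file formats, so every stage is testable end to end.

## The statistics at the core

* **Calibrated ROH detection.** The minimum number of SNPs in a ROH is scaled
  by the within-species mean heterozygosity,
  `L = ceil( ln(alpha / (n_s * n_i)) / ln(1 - het) )` with `alpha = 0.05`,
  and the PLINK-style scanning window is set equal to `L`.
* **F_ROH against a synthetic homozygous genome.**
  `F_ROH = L_ROH / L_ROH,HOM`, where the denominator is the ROH total of the
  same genome with every heterozygote forced homozygous — the maximal
  detectable ROH extent under identical parameters.
* **ROH recombination clock.** `g = 100 / (2 r l)` (equivalently
  `l = 50 / (r g)`); with `r = 0.448` cM/Mb and `g = 110` generations the
  boundary is ~1 Mb, so ROH ≥ 1 Mb are classed "contemporary" (~last 1200
  years at an 11-year generation time) and shorter ROH "historical".
* **Genetic load as relative abundance of derived alleles.**
  `RA = (n_R/A + 2 n_A/A) / (2 n_p)` per individual and category
  (LoF, deleterious missense at EX ≤ 0.256, tolerated missense, synonymous),
  with `n_p` the species-wide number of derived sites in the category.
  Under pure drift RA is conserved; island deficits in the LoF class relative
  to synonymous are the purging signal.
* **Differential fixation.** Coding sites homozygous for opposite alleles in
  the two populations, with genes containing any LoF variant removed as
  putative pseudogenes, and gene sets intersected across species.

Upstream of these, genotypes are masked for skewed allelic balance
(minor-allele support < 0.25) and outlying depth (< 0.5× or > 2× the sample
mean), and alleles are polarised as ancestral/derived by requiring all three
outgroups to be homozygous for the same allele.

## Worked example

Simulate the reference scenario — a 500-diploid mainland and a 50-diploid
island founded 200 generations ago, eight 2.5-Mb chromosomes — and run the
whole pipeline on the emitted VCF:

```r
library(islandload)
cfg <- pipeline_config(sim = sim_config(seed = 1), seed = 1)
res <- run_pipeline(cfg, "islandload_out")
```

The report (`islandload_out/report.txt`) prints:

```
island-mainland diversity and load pipeline
seed: 1
sites read: 5589; samples: 16
genotypes masked (allelic balance < 0.25): 13
genotypes masked (depth < 0.5x or > 2x sample mean): 142
sites retained after outgroup polarisation: 5365
sites after invariant removal: 1577
ROH parameters: L = 494 SNPs (alpha = 0.05), window = 494
age boundary: 1 Mb (~110 generations, ~1210 years)
fixed differences (coding, LoF-gene filtered): 29
island genes with fixed homozygous LoF: 3
```

5589 simulated SNPs survive masking; ~4% of sites are lost to deliberately
corrupted outgroups at polarisation; 1577 sites carry a derived allele in the
16 sampled genomes.  The calibrated ROH threshold is L = 494 SNPs.  Per
sample:

```
  sample_id population    het n_roh f_roh f_roh_contemporary f_roh_historical
1    isl_01     island 0.0135     3 0.341              0.341                0
2    isl_02     island 0.0138     2 0.240              0.240                0
3    isl_03     island 0.0194     1 0.125              0.125                0
...
15   mnl_07   mainland 0.0457     0 0.000              0.000                0
16   mnl_08   mainland 0.0367     1 0.085              0.085                0
```

Island genomes are roughly half as heterozygous as mainland ones and carry
substantial F_ROH, almost entirely in the contemporary (≥ 1 Mb) class — the
signature of inbreeding after a recent bottleneck.  The packaged Welch
comparison confirms the diversity contrast
(`res$comparisons$heterozygosity`: t = −10.3, p ≈ 3e−07) and the inbreeding
contrast (`res$comparisons$f_roh`: t = 3.18, p ≈ 0.013).  Per-category RA
contrasts (`res$comparisons$ra_*`) fluctuate seed by seed under neutrality —
their conservation is a cross-replicate property, which the test suite
checks over 20 seeds.

A shell entry point with the same behaviour lives at
`inst/cli/islandload.R`:

```sh
Rscript inst/cli/islandload.R --outdir out --seed 1
```

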