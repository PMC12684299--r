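---
title: "Diversity, inbreeding and genetic load in island-mainland population pairs"
author: "islandload"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Diversity, inbreeding and genetic load in island-mainland population pairs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The scientific problem

Small, isolated island populations drift fast: they lose heterozygosity,
accumulate long runs of homozygosity (ROH) through inbreeding, and convert
*masked* genetic load (deleterious alleles hidden in heterozygotes) into
*realised* load (expressed homozygotes).  Whether such populations are
accumulating deleterious mutations or purging the worst of them is a central
question in conservation genomics.  `islandload` implements a complete,
desk-scale analysis for one island-mainland species pair:

1. genotype-quality masking (allelic balance, read depth),
2. ancestral-allele polarisation against three outgroup genomes,
3. individual heterozygosity, calibrated ROH detection, and the inbreeding
   coefficient F~ROH~ with a recombination-clock age classification,
4. per-category genetic load via the relative abundance of derived alleles,
5. scans for variants differentially fixed between the two populations.

Every stage can be driven by a built-in forward-time Wright-Fisher simulator
whose ground truth (selection class per site, true ancestral allele, pedigree
inbreeding) makes the whole pipeline verifiable without external data.

## Models and statistics

### Genotype masking

Heterozygous genotypes with minor-allele read fraction strictly below 0.25
(`min(AD)/DP < 0.25`) are set to missing, as are genotypes whose depth is
strictly below half or strictly above double the sample's genome-wide mean
depth.  Boundary values are retained ("less than half", "more than double"
are strict).  The per-sample mean is computed once from the depth evidence of
all originally called genotypes, so the two masks commute and are idempotent.
Masking only ever converts a genotype to missing; it never rewrites a value.

### Ancestral-allele polarisation

A site is polarised if and only if all three outgroup genotypes are
non-missing, homozygous, mutually identical, and the shared allele matches the
site's REF or ALT.  That shared allele is ancestral; the other is derived;
genotypes are recoded to derived-allele counts.  Sites with no observed
derived allele are then removed.  Sites *fixed* for the derived allele are
kept: they are variable relative to the ancestor, they carry load, and they
are exactly the sites the differential-fixation scan needs.  (Whether the
original analyses kept fixed-derived sites is not stated; this choice is
deliberate and flagged — dropping them would only affect the fixed-difference
counts and the `n_p` totals, not the per-individual contrasts.)

### ROH detection and F~ROH~

The minimum number of SNPs constituting a ROH is calibrated by the
within-species mean heterozygosity,

$$L = \left\lceil \frac{\ln\!\big(\alpha/(n_s\,n_i)\big)}{\ln(1-het)} \right\rceil,$$

with $n_s$ genotyped SNPs, $n_i$ genotyped individuals and the false-positive
threshold $\alpha = 0.05$.  The ceiling keeps the false-positive control
conservative.  The scanning window length equals $L$.  The window dialect is
the classic PLINK `--homozyg` family with its defaults: at most 1 heterozygous
and 5 missing calls per hit window, SNP eligibility above a hit fraction of
0.05 (strict `>`, ties not eligible), maximum gap 1000 kb, maximum density
50 kb/SNP.  One deliberate departure: the minimum segment length defaults to
100 kb rather than the upstream tool's 1000 kb, because sub-megabase
("historical") ROH are a reported object of study and a 1 Mb floor cannot
yield them; the parameter is exposed in `roh_params()`.

F~ROH~ is normalised not by an assumed genome length but by the same
individual's *synthetic homozygous genome* — every het forced homozygous —
scored under identical parameters:

$$F_{ROH} = L_{ROH} / L_{ROH,HOM}.$$

This absorbs genome-specific artefacts (uncallable regions, SNP-sparse
stretches) and guarantees $F_{ROH} \in [0,1]$ with a self-normalisation value
of exactly 1.

### The ROH recombination clock

The expected coalescence age of a ROH of length $l$ Mb at recombination rate
$r$ cM/Mb is $g = 100/(2 r l)$ generations, equivalently $l = 50/(r g)$.
With the rhesus macaque genome-wide average $r = 0.448$ cM/Mb and $g = 110$
generations, $l = 1.01$ Mb, which rounds to the 1 Mb boundary separating
"contemporary" ROH (length $\ge$ 1 Mb, inbreeding within roughly the last
1200 years at an 11-year generation time) from older "historical" ROH.  The
boundary is length-inclusive.

### Genetic load

Derived variants are classified from their picked VEP-style consequence:
loss-of-function (transcript ablation, stop gained/lost, start lost,
frameshift, splice acceptor/donor/region — the splice *region* class is
honoured deliberately, unusual as it is), missense, and synonymous.  Missense
variants split on the experimental amino-acid exchangeability score at
EX $\le$ 0.256 (boundary inclusive) into likely-deleterious vs tolerated.
EX scores are consumed from the site annotation table; the package does not
recompute exchangeability from experimental data, and it does not bundle the
published 20x20 exchangeability matrix — the simulator's toy annotator draws
per-class EX scores instead, which exercises the classification boundary
end-to-end without fabricating third-party data.

Individual load per category is the relative abundance of derived alleles,

$$RA = \frac{n_{R/A} + 2\,n_{A/A}}{2\,n_p},$$

where $n_{R/A}$ and $n_{A/A}$ are the individual's derived heterozygous and
homozygous site counts and $n_p$ is the number of derived sites in the
category across *all* genomes of the species, island and mainland pooled.
Because neutral drift does not change the expected count of derived alleles,
RA is expected to be equal across populations in the absence of selection —
that conservation is what makes it a purging diagnostic.  Missing genotypes
leave a site inside $n_p$ as long as any genome carries the derived allele.
The complementary realised-load statistic is the derived homozygosity
$n_{A/A}/(n_{R/A}+n_{A/A})$, reported per individual (the pooled alternative
is not offered; the per-individual form matches per-individual RA).

### Differential fixation

A coding site is differentially fixed when all non-missing island genotypes
are homozygous for one allele, all non-missing mainland genotypes homozygous
for the other, and both populations have at least one genotyped individual.
Missing genotypes do not disqualify a site; a strict "all genotyped" rule
would empty small cohorts, and the permissive rule is the documented dialect
(fixation is judged on observed genotypes).  To keep drift-accumulated
pseudogene variation out, every gene containing any LoF variant anywhere in
the combined dataset is removed.  Across species, gene sets are intersected;
"shared" means present in at least two species.

Group contrasts (heterozygosity, F~ROH~, RA) use Welch's unequal-variance
t-test, and only when both groups have at least three genomes; smaller
contrasts are reported as not testable rather than tested badly.

## The synthetic-data generator

`wf_simulate()` runs a discrete-generation Wright-Fisher model: monoecious
random mating with selfing, fitness-weighted parent sampling (per-site
genotype fitness $1$, $1-hs$, $1-s$, multiplicative across sites), Poisson
crossovers per chromosome at the configured cM/Mb, and infinite-sites
mutation so every variant has an unambiguous founder (ancestral) allele.  A
mainland population burns in alone; the island is founded as a bottleneck
draw and the pair then evolves in complete isolation (no migration).
Pedigree kinship is tracked exactly, so every sampled individual carries a
realised pedigree inbreeding coefficient for recovery tests.  Sequencing
noise (Poisson depth, binomial allele split for hets) is applied only at VCF
emission, keeping truth genotypes clean so masking tests know exactly what
was corrupted.  Outgroup tables are emitted with configurable fractions of
discordant or heterozygous outgroup sites to exercise the polarisation
filter.

### The reference scenario and why its values are what they are

| parameter | default | why |
|---|---|---|
| mainland / island size | 500 / 50 diploids | an order-of-magnitude census contrast typical of island systems |
| split | 200 generations before present | recent-bottleneck regime in which contemporary ROH accumulate |
| burn-in | 60 generations | enough standing variation for all stages; full coalescent equilibrium is not needed for contrasts |
| genome | 8 chromosomes x 2.5 Mb | eight independent linkage groups let per-run drift outcomes average out, as a multi-chromosome genome does; each chromosome still dwarfs the calibrated minimum ROH span |
| mutation rate | 2.5e-8 /site/gen | scaled above the primate point rate so the 20-Mb genome reaches a SNP density at which inter-SNP spacing is small relative to bottleneck IBD segments — the regime whole-genome data occupy |
| recombination | 0.448 cM/Mb | rhesus macaque genome-wide average, also used by the ROH clock |
| class fractions | 0.5 / 0.2 / 0.2 / 0.1 (syn / tolerated / deleterious / LoF) | coding-variant proportions of the right order for VEP-annotated SNPs |
| selection | all $s=0$ by default; LoF $h=0$ | neutrality is the null in which RA conservation is provable; purging scenarios switch on $s_{lof}=0.5$, $h=0$ explicitly |
| depth | 30x Poisson | typical whole-genome resequencing depth |
| samples | 8 + 8 | enough genomes for Welch tests on both sides |

What the generator deliberately does **not** emulate: genotype-calling error
(genotypes are true; only depth/balance evidence is noisy), gene conversion,
migration after the split, realistic chromosome counts and lengths,
population structure within either population, and linked-selection effects
beyond the explicit per-site fitness model.  Passing tests therefore
demonstrate that the *statistics and algorithms* behave as specified under a
known demography — not that any particular wild population matches the
simulated one.  Demographic parameters are illustrative, not calibrated to
any species.

## Numerical and dialect choices

- Coordinates are 1-based inclusive everywhere; segment length is
  `end - start + 1`.
- Multi-allelic records and indels are rejected at VCF read time.
- Window eligibility uses strict `>` against the hit-fraction threshold;
  masking thresholds use strict `<` / `>`; the EX and 1 Mb boundaries are
  inclusive.  Each of these is asserted by a boundary unit test.
- Windows exist only where a full window of SNPs exists; chromosomes with
  fewer SNPs than the window yield no calls.
- `L` is rounded up (ceiling); a degenerate `het` of 0 or 1 is an error.
- F~ROH~ returns 0 when numerator and denominator are both empty and errors
  if only the denominator is empty (impossible under identical parameters).
- Mean RA comparisons across replicate simulations use per-seed differences;
  with eight linkage groups the neutral island/mainland RA ratio stays within
  [0.9, 1.1] when averaged over 20 seeds.
- The simulator prunes lost (and, pre-split, fixed) sites lazily every four
  generations; loss and fixation are absorbing, so the final state is
  identical to per-generation pruning.
- Identical seeds give byte-identical outputs, including the emitted files
  and the pipeline manifest (no timestamps are written).

## Problem sizes used by the test suite

The packaged checks run the reference scenario (about 5,500 segregating SNPs
over 20 Mb, 16 sampled genomes) for 20 replicate seeds in the neutral and in
the purging configuration, a few seconds per replicate; the ROH caller is
additionally validated against a literal window-enumeration oracle on 200
random SNP maps of up to 1,000 SNPs.  These sizes are the package's chosen
desk scale: large enough for every stage to operate in its intended regime,
small enough to rerun casually.

## Known limitations

- The window-based caller inherits the resolution limits of its dialect:
  IBD segments shorter than the calibrated minimum SNP count are invisible,
  so individual F~ROH~ values of zero occur on the island even when pedigree
  inbreeding is substantial; population means remain well separated.
- RA is standardised within species; it says nothing about absolute fitness
  effects, and comparisons across categories depend on the annotation.
- The pseudogene proxy (drop genes containing any LoF variant) is
  deliberately blunt and can discard genuinely interesting genes.
- With fewer than three genomes per group no significance statements are
  produced, by design.

## Running the pipeline

```{r}
library(islandload)
cfg <- pipeline_config(sim = sim_config(seed = 1), seed = 1)
res <- run_pipeline(cfg, "islandload_out")
res$sample_summary
res$comparisons$heterozygosity
```

Each stage is also exported on its own (`mask_allelic_balance()`,
`mask_depth()`, `polarize()`, `drop_invariant()`, `detect_roh()`,
`load_summary()`, `differentially_fixed()`, ...) so the pipeline can be
re-composed or intercepted at any point, and
`inst/cli/islandload.R` wraps `run_pipeline()` for shell use.
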