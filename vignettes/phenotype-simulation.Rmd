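---
title: "Simulating phenotypes on coalescent genotypes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating phenotypes on coalescent genotypes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(coalpheno)
```

## Why attach phenotypes to coalescent output

Coalescent simulators (ms, msHOT, msms and genome-scale relatives) generate
haplotypes under rich demographic models orders of magnitude faster than
forward-in-time simulation, but they produce genotypes only. Power studies of
genome-wide association (GWAS) methods additionally need phenotypes with a
known causal architecture: which sites are causal, how much variance each
explains, whether effects interact. coalpheno closes that gap. It parses
coalescent output (or generates synthetic haplotypes), designates causal
sites under user constraints, attaches a qualitative or quantitative trait,
subsamples the population the way a real study would, and writes the files
that association tools consume. Because the causal truth is known, the
downstream tool's hit list can be scored directly.

## The quantitative trait model

For haploid individuals the trait of individual $i$ is

$$Y_i = \sum_j \beta_j\, a_{ij} + \varepsilon_i, \qquad
  \varepsilon_i \sim N(0, 1),$$

where $a_{ij} \in \{0, 1\}$ is the allelic state at the $j$-th causal site
(QTN), ancestral or derived. Diploids under the additive model replace
$a_{ij}$ by $Q_{ij} \in \{-1, 0, +1\}$ (homozygous ancestral, heterozygous,
homozygous derived); under dominance the 0/1 carrier indicator is used
instead, so heterozygous and homozygous-derived individuals are
interchangeable.

Each QTN is specified not by a raw coefficient but by the proportion
$\pi_j$ of total phenotypic variance it should explain; the sum
$h^2 = \sum_j \pi_j\ (+\ \pi_E)$ is the trait heritability and must stay
below 1. With unit environmental variance, the unique coefficient scaling
that realizes this partition for independent causal sites is

$$\beta_j = \sqrt{\frac{\pi_j}{v_j\,(1 - h^2)}},$$

with $v_j$ the variance of the genotype coding: $f_j(1-f_j)$ for 0/1 codings
(haploid alleles, dominant carrier status), $2f_j(1-f_j)$ for the diploid
$\{-1,0,+1\}$ coding under Hardy–Weinberg proportions. The total genetic
variance is then $h^2/(1-h^2)$, the phenotypic variance $1/(1-h^2)$, and
every QTN's share of variance is exactly $\pi_j$. Frequencies $f_j$ are the
*realized* sample frequencies, not nominal targets, so the partition holds
in the simulated sample rather than only in expectation. The test suite and
`scripts/acceptance.R` verify this by regression: the $R^2$ of the phenotype
on the causal design columns converges to $h^2$, and each column's
incremental $R^2$ (full-model $R^2$ minus the $R^2$ without that column) to
its $\pi$. Throughout the package "partial $R^2$" means this incremental
$R^2$, the quantity that the variance partition pins down.

### Epistasis as a fictive third QTN

A positive pairwise interaction between exactly two QTNs is modelled as a
fictive third QTN whose allele $a_{iE}$ is 1 when individual $i$ carries at
least one derived allele at *both* basal QTNs (`epistatic_state()`). The
fictive allele is a deterministic function of the basal genotypes, so its
indicator column is partially collinear with the basal QTN columns — for
independent haploid QTNs, the variance of $a_{iE}$ that is orthogonal to the
main effects is $f_1 f_2 (1-f_1)(1-f_2)$, substantially less than its raw
variance $f_E(1-f_E)$. Scaling the raw indicator would therefore let the
main-effect columns absorb much of the intended interaction variance and
break the partition.

coalpheno instead residualizes the indicator against the basal QTN coding
columns (ordinary least squares, with intercept) and scales the residual by
$\beta_E = \sqrt{\pi_E / (v_r (1-h^2))}$, $v_r$ being the realized residual
variance. This is the package's deliberate design choice where the design
was genuinely open, and it is the only construction under which all three
statements hold simultaneously: each basal QTN contributes $\pi_j$, the
epistatic term contributes $\pi_E$ *beyond* the main effects, and the total
equals $h^2$ — the variance-partition contract the model is specified by.
The phenotype remains a linear combination of the columns
$\{a_1, a_2, a_{iE}\}$, so any regression on those raw columns spans the
same model space. A degenerate sample in which the fictive allele is
monomorphic (the derived alleles never co-occur, or always do) is rejected
with advice to re-select QTNs, e.g. within a higher frequency range.

### Placing causal sites

`select_qtns()` draws causal sites uniformly from the eligible pool:
polymorphic sites, optionally restricted to a derived-allele frequency range
(low-frequency risk alleles have systematically different genealogies and
linkage patterns than common ones, so frequency control matters for
realism). Sites can also be pinned manually. For a pair of interacting QTNs
the selection can be restricted to a common haploblock, emulating a causal
haplotype or allelic heterogeneity within one gene.

Haploblocks are maximal left-to-right runs of sites that are mutually
compatible under the four-gamete test (two biallelic sites are incompatible
with a single recombination-free tree iff all four gametes 00/01/10/11 are
observed). The block-construction rule is a genuine choice: coalpheno uses
greedy left-to-right extension requiring *all-pairs* compatibility within a
block, which is deterministic, order-stable, and gives a strict partition of
the sites; requiring only adjacent-pair compatibility would yield longer,
internally inconsistent blocks. With the haploblock constraint active, QTN
pairs are drawn uniformly over all eligible within-block pairs, so blocks
with more eligible sites are proportionally more likely to host the pair.

## Qualitative traits

Case/control traits are defined by penetrance: the probability of being
affected for each genotype at one causal locus, or for each of the
$3\times3$ (diploid) or $2\times2$ (haploid) genotype combinations at two
loci — the two-locus table admits arbitrary interactions. Status is assigned
by independent Bernoulli draws. `expected_prevalence()` gives the closed-form
population prevalence $\sum_g P(g)\,\text{pen}(g)$, which the empirical case
fraction matches within binomial sampling error; the test suite checks this
against exact binomial confidence intervals over randomly drawn tables.

Risk alleles at low frequency produce few cases, so `sample_plan()` supports
the ascertainment used by real case/control studies: simulate a large
population, then sample a minimum number of cases plus a set number of
controls. When too few cases exist the error reports how many are available;
the remedy is a larger simulated population, not a silent shortfall.

## Subsampling and export

Operations run in a fixed order: phenotype assignment on the full
population, optional deletion of the causal columns (the causal mutation is
frequently not genotyped on real arrays), marker subsampling (uniform
without replacement, re-sorted by position), then individual subsampling or
ascertainment — genotype–phenotype pairing is preserved throughout, and the
order (causal removal before the marker draw) guarantees a removed causal
site can never re-enter via the marker sample.

Writers produce PLINK PED/MAP, transposed TPED/TFAM (the layout EMMAX
consumes), EMMA numeric matrices, and a generic TSV pair. Alleles are
written as A (ancestral) / T (derived) — arbitrary fixed letters, since
coalescent output carries no nucleotides; the chromosome field is fixed to 1
(one simulated region per replicate); case/control status uses PLINK's
1 = control / 2 = case convention; the missing-phenotype sentinel -9 never
occurs because simulated data are complete. All writers are
byte-deterministic (LF endings, no timestamps), which the suite asserts by
checksum, and fractional ms positions are converted to strictly increasing
integer base pairs (`round` half-up; collisions bumped +1 bp with a
warning) because map files need distinct integer coordinates. The default
locus length for that conversion is 1 Mbp, a typical single-region scale;
set `locus_length_bp` to match the simulated region.

## The fixture generator

`generate_fixture()` draws each site independently: Bernoulli alleles at a
per-site target frequency (default: uniform on $[0.2, 0.8]$, the
common-variant regime) and uniform sorted positions. It emulates exactly
what the trait models need — controlled allele frequencies and reproducible
matrices — and deliberately nothing more: there is no linkage
disequilibrium, no site-frequency-spectrum shape, no demography. Passing
variance-recovery tests on fixtures therefore validates the phenotype
models' scaling, not the behaviour of association methods on realistically
correlated markers; for the latter, feed real coalescent output in via
`parse_ms()`/`parse_genome()`. On fixture data the four-gamete test segments
haplotypes heavily (independent common sites are usually incompatible), so
haploblock-constrained scenarios are exercised on small constructed
matrices where block structure is explicit.

## Reproducibility and numerical choices

Every stochastic stage takes a seed, and the pipeline derives per-stage,
per-replicate child seeds from one root seed with a Lehmer-generator mix
(`derive_seed()`), so changing, say, the subsampling plan never perturbs the
phenotype draws. RNG state is saved and restored around every seeded
operation, leaving the caller's stream untouched. Ties in QTN selection are
resolved by scanning eligible sites in column order before sampling.
Degenerate inputs fail loudly at the stage that detects them — monomorphic
causal sites, heritability at or above 1, penetrance tables of the wrong
shape, odd chromosome counts at diploid pairing — and the pipeline isolates
failures per replicate, aborting only when every replicate fails.

The bundled checks use problem sizes chosen so Monte-Carlo error is well
inside the asserted bands: variance recovery uses 50 replicates of 20,000
haploid individuals at 200 sites (per-replicate sampling error of a
two-QTN $R^2$ at that size is a few parts in a thousand), prevalence checks
use 10,000 individuals per table, and block-partition checks run against a
brute-force all-pairs oracle on 1,000 random matrices of up to 30 sites.

## Limitations

- Epistasis is pairwise only, between exactly two QTNs; higher-order
  interaction schemes require composing phenotypes manually from
  `epistatic_state()` and custom columns.
- Dominance is a recoding (carrier indicator), not a separate dominance
  variance component; there is no per-QTN dominance-degree parameter.
- Diploids are formed by pairing consecutive chromosomes, i.e. random union
  of gametes; population structure, inbreeding and relatedness are out of
  scope and should come from the upstream simulator.
- Writers target PED/MAP, TPED/TFAM, EMMA and TSV; other association-tool
  formats are not produced.
- The GENOME-style reader targets the documented dialect described in
  `?parse_genome`; output of other bp-position simulators may need a thin
  reformatting step.
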