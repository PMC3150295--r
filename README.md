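# coalpheno

Phenotype simulation on coalescent genotypes, for GWAS power studies.

Coalescent simulators (ms, msHOT, msms, genome-scale tools) produce
haplotypes under complex demographic models quickly — but genotypes only.
Assessing the statistical power of genome-wide association methods also
requires phenotypes with a *known* causal architecture. coalpheno attaches
one: it reads coalescent output (or generates synthetic haplotypes),
designates causal sites under user constraints, simulates a qualitative or
quantitative trait, subsamples markers and individuals the way a real study
would, and writes the input files of common association tools (PLINK
PED/MAP, TPED/TFAM for EMMAX, EMMA matrices, generic TSV). Intended users
are population geneticists and methods developers benchmarking association
methods in humans, plants or animals.

## The model

A quantitative trait is built from quantitative trait nucleotides (QTNs).
For haploids,

    Y_i = Σ_j β_j a_ij + ε_i,   ε_i ~ N(0, 1),

with `a_ij ∈ {0,1}` the ancestral/derived allele at QTN *j*; diploids use
the `{-1, 0, +1}` genotype code (or a 0/1 carrier indicator under
dominance). Each QTN is specified by the proportion π_j of phenotypic
variance it explains; `h² = Σ_j π_j (+ π_E)` is the heritability, and the
coefficients are scaled as

    β_j = sqrt( π_j / ( v_j (1 − h²) ) ),

with `v_j` the variance of the genotype coding at the realized allele
frequency — the unique scaling under which each QTN explains π_j and the
causal sites jointly explain h². Epistasis between two QTNs is a fictive
third QTN that is "derived" when an individual carries at least one derived
allele at both basal sites; its column is orthogonalized against the main
effects so the interaction contributes exactly π_E beyond them. Qualitative
traits use one- or two-locus penetrance tables (probability of being
affected per genotype combination), with case/control ascertainment from a
large simulated population. Causal sites can be restricted to an allele
frequency range or to a common haploblock under the four-gamete test. See
`vignettes/phenotype-simulation.Rmd` for the full account.

## Worked example

```r
library(coalpheno)

# 2,000 haploid chromosomes at 50 sites (stand-in for an ms run;
# use parse_ms("run.ms") for real coalescent output)
m <- generate_fixture(2000, 50, seed = 11)

# two causal sites with 5% variance each, restricted to common alleles
q <- select_qtns(m, 2, effects = c(0.05, 0.05), freq_range = c(0.2, 0.8),
                 seed = 12)
q
#>   site effect derived_freq
#> 1    3   0.05       0.4985
#> 2   28   0.05       0.2105

model <- quant_trait_model(q)
y <- generate_quantitative(m, model, seed = 13)

# QC: how much variance do the causal columns actually explain?
rv <- recovered_variance(m, model, y)
round(rv$total_r2, 3)
#> [1] 0.119
round(rv$partial_r2, 3)
#>  site3 site28
#>  0.054  0.061

# drop the causal markers (they are rarely genotyped), keep 30 markers,
# and export for an association tool
s <- subsample(m, y, q, sample_plan(n_markers = 30, remove_causal = TRUE,
                                    seed = 14))
d <- gwas_dataset(s$genotypes, s$phenotypes)
write_plink_ped_map(d, "sim")   # sim.ped + sim.map
```

The realized total R² (0.119 here) fluctuates around the configured
h² = 0.10 with a spread set by the sample size; averaged over replicates it
converges to h², which is what the acceptance analysis below measures. The
two `partial_r2` entries are each QTN's incremental R², converging to its
π_j = 0.05.

An end-to-end run, driven by a key-value config file, is available from the
shell via the installed `exec/coalpheno` script:

```sh
coalpheno run --config run.cfg --seed 7 --format tped,tsv --out sim
coalpheno fixture --chromosomes 400 --sites 200 --seed 1 --out fixture.ms
```

Each replicate writes its own `_rep<N>` file set plus a JSON manifest with
realized causal positions, frequencies, case counts and file checksums;
identical seed and config give identical checksums.

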