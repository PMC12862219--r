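# haplodnm

Germline de novo mutation (DNM) and postzygotic mutation (PZM) detection in
**highly heterozygous diploid genomes**, using haplotype-resolved
(allele-aware) **parental assemblies as the alignment reference**.

## The problem

Pedigree-based mutation-rate estimation needs two numbers: the count of
mutations present in an offspring but in neither parent, and the number of
genomic positions at which such a mutation could have been confidently
called (the *callable genome*).  In species with percent-level
heterozygosity (some invertebrates reach 3–4%), a single haploid reference
breaks both: reads misalign against a reference several percent diverged
from either allele, and inherited heterozygous variants drown candidate
DNMs.

`haplodnm` instead aligns offspring reads against the concatenation of both
parents' allele-aware contig assemblies.  Offspring reads settle on the
allele they inherited, so a DNM appears as a clean homozygous-ALT site on a
parental contig — and the parent of origin of every mutation is simply the
parent that owns the contig.  The package implements the bookkeeping this
design requires:

* **Contig zygosity classification** — assembler "non-bubble" contigs are a
  mixture of heterozygous and homozygous sequence; contig mean read depth
  (heterozygous contigs sit near half the sequencing depth) plus
  reciprocal-best-hit self-alignment (coverage and identity ≥ 0.7) sorts
  them into bubble-like, true non-bubble, and uncertain.
* **Two-stage inheritance inference** — per offspring and contig, a
  weighted cosine/Jaccard similarity of 50-bp-binned depth profiles decides
  which parental allele was transmitted; bubble-pair Mendelian logic and a
  *parental similarity score* (same similarity between the two parents'
  profiles; > 0.5 means the locus is confounded) refine the calls so that
  exactly one allele per pair is inherited.
* **Callable genome** — inherited contigs minus unphasable loci, minus
  100-bp contig ends, minus positions above 3× the offspring's mean depth;
  unphased loci count at half length.
* **Mutation filters** — seven DNM criteria (callable, hom-ALT with
  DP > 10 and parental DP > 5, ≤ 2 parental alternative alleles,
  QUAL ≥ 220 for the pileup caller, ±20 bp from INDELs, gene-conversion
  mask, no heterozygous sibling), sibling-shared DNM grouping, and PZM
  calling with a one-sided `prop.test` of the variant allele fraction
  against 0.25.
* **Estimators** — mutation rate `μ = n_DNM / (L_callable × (1 − FNR))`
  with an exact Poisson CI, spike-in false-negative rate
  `FNR = 1 − detected/spiked`, male mutation bias α (raw and
  callable-corrected), folded substitution spectra with a CpG>TpG class,
  annotation-context rates via PAF coordinate projection, and
  `N_e = π / (4μ)`.
* **Synthetic pedigree generator** — simulates heterozygous diploid
  parents, contigized assemblies with mislabeled classes, Mendelian
  transmission, negative-binomial depth profiles with allele cross-mapping,
  and spiked DNMs/PZMs with full truth records, standing in for the
  assembler and aligner so the whole pipeline is testable end to end.

## Worked example

Published-style summary inputs — 242 DNMs across 104 offspring with a mean
callable genome of 414.8 Mb and a spike-in FNR of 4.8%, plus a synonymous
nucleotide diversity of 0.0397:

```r
library(haplodnm)
est <- mutation_rate(242, 104 * 414.8e6, fnr = 0.048)
print(est)
#> mutation rate: 5.893e-09 per base per generation (242 DNMs / 4.314e+10 bp, FNR 0.048)
#>   95% CI [5.174e-09, 6.684e-09] (poisson_exact)
effective_population_size(0.0397, est$mu)$ne
#> 1684318
```

A mutation rate of ~5.9 × 10⁻⁹ per base per generation is vertebrate-like;
combined with π ≈ 0.04 it implies an effective population size of ~1.7
million, i.e. extreme heterozygosity explained by population size rather
than an elevated mutation rate.

End-to-end on synthetic data (a 2-Mb diploid pedigree with four offspring):

```r
cfg <- sim_config(genome_length = 1e6, n_offspring = 4, seed = 42)
run_benchmarks(cfg)
#> pedigree benchmark (seed 42)
#>   non-bubble classification accuracy: 1.000
#>   positive control (bubble re-het):   1.000 / 1.000
#>   inheritance error rate:             0.0000
#>   unresolved contig fraction:         0.0000
#>   mean callable / diploid genome:     0.970
#>   spike-in FNR:                       0.0183
#>   DNM detection: 122/124   PZM detection: 34/40
```

The report reads: all mislabeled non-bubble contigs were correctly
re-classified; every resolved inheritance call matched the transmission
truth; ~97% of the (clean, fully assembled) diploid genome was callable;
the spike-in harness measured a 1.8% false-negative rate (dominated by the
QUAL tail of the simulated pileup caller); and 122 of 124 spiked DNMs and
34 of 40 spiked PZMs were recovered (PZM losses are mostly candidates whose
simulated VAF drew too few alternative reads to be called, plus
high-VAF candidates that the 0.25 test is designed to reject).

A thin command-line wrapper is installed at `inst/cli/haplodnm.R`
(`simulate`, `benchmark`, `classify`, `rates` subcommands); the R functions
are the primary interface.

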