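---
title: "Detecting de novo mutations against allele-aware parental assemblies"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting de novo mutations against allele-aware parental assemblies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Estimating the germline mutation rate from a pedigree means finding, in each
offspring, the handful of de novo mutations (DNMs) that neither parent
carries, and dividing by the number of positions at which such a mutation
*could* have been found (the callable genome).  In species with percent-level
heterozygosity this is hard with a single haploid reference: reads from the
two alleles of a locus differ from the reference by several percent, misalign
or cross-align, and inherited heterozygous variants swamp candidate DNMs.

`haplodnm` takes the opposite route.  Both parents are assembled with an
allele-aware assembler into haplotype-resolved contigs, and the *union* of
the two parents' contigs is the alignment reference.  Offspring reads then
align to the exact allele they inherited; an offspring is homozygous (for
the contig allele) almost everywhere on an inherited contig, a DNM shows up
as a clean homozygous-ALT site, and the parent-of-origin of a mutation is
simply the parent that owns the contig.  The price of this design is a new
set of bookkeeping problems, each of which is a package stage:

1. Which contigs are heterozygous (one allele of a pair) and which are
   homozygous sequence?  (`classify_contigs()`)
2. Which parental contigs did a given offspring actually inherit?
   (`infer_inheritance()`)
3. Over which positions could a DNM have been called?  (`callable_set()`)
4. Which variant calls survive the DNM / postzygotic-mutation (PZM)
   filters?  (`dnm_filter()`, `pzm_filter()`)
5. What are the rate, sex bias, spectrum, and implied effective population
   size?  (`mutation_rate()` and friends)

## Contig zygosity classification

Allele-aware assemblers emit heterozygous loci as "bubble" contig pairs and
homozygous sequence as single "non-bubble" contigs, but the non-bubble set
is in practice a mixture.  Two orthogonal signals separate it:

* **Contig mean depth.** A heterozygous contig carries one of the parent's
  two haplotypes, so the parent's reads cover it at roughly half the
  individual's sequencing depth; a homozygous contig collects both
  haplotypes' reads.  The depth windows are `[10, 50]`x for candidate
  heterozygous and `(50, 100]`x for candidate homozygous at an 80x
  calibration, and scale linearly with the supplied sequencing depth
  (`default_thresholds()`).  Pass the individual-level mean sequencing
  depth (e.g. from mosdepth summaries), not the mean over the diploid
  assembly, which is dragged down by the haploid-coverage contigs.
* **Reciprocal best hits (RBH).** A heterozygous contig has a
  high-coverage, high-identity alignment partner -- its other allele --
  somewhere in the assembly.  Alignment blocks between a pair of contigs
  are aggregated (identity = total matches / total block length; coverage =
  merged aligned span over contig length, taken as the minimum over the two
  members so a short contig contained in a long one cannot qualify
  one-sidedly), pairs need coverage and identity >= 0.7, and each contig's
  best hit is the qualifying pair with the most matches, with ties treated
  as no best hit.

Candidate heterozygous contigs that are mutual best hits become
`bubble_like` pairs and are treated as bubbles downstream.  Candidate
homozygous contigs are screened "negatively": *any* qualifying RBH demotes
them to `uncertain`; only RBH-free candidates are `true_non_bubble`.
Assembler bubbles are a natural positive control: stripped of their labels
and pushed through the same machinery they should come back heterozygous
(`positive_control_fraction()`).

## Inheritance inference

Whether offspring `o` inherited parental contig `c` is decided from binned
read-depth profiles.  Each contig is cut into 50-bp bins (a trailing
partial bin is dropped) and the profile similarity of two individuals on
the same contig is a weighted sum of

* cosine similarity over the bins where both are covered, and
* agreement on zero coverage (zero-in-both / zero-in-at-least-one) over the
  remaining bins,

with weights equal to the two bin-class fractions.  The score is symmetric,
lives in `[0, 1]`, and is 1 exactly for identical zero patterns with
proportional positive parts.  The zero-coverage component is the one place
where the underlying idea admits more than one reading; the package defines
it as agreement on zeros, which makes disjoint coverage score 0 and
identical all-zero profiles score 1, and tests pin this definition against
a brute-force oracle.

**Stage 1** calls each contig independently: a contig whose mean depth in
the offspring is below `max(10, offspring mean depth / 4)` is non-inherited
(`low_depth`); otherwise the contig is inherited iff the offspring's
profile is more similar to the parent-of-origin's profile than to the other
parent's.  The offspring mean depth here is the length-weighted mean over
all contigs of the combined parental reference.

**Stage 2** overlays Mendelian structure.  Homozygous (`true_non_bubble`)
contigs are always inherited.  Within each bubble/bubble-like pair exactly
one member must be inherited, so: a low-depth member forces its partner
inherited; otherwise the member whose *parental similarity score* (the same
profile similarity computed between the two parents on that contig; scores
above 0.5 mean the parents are indistinguishable there) is at or below 0.5
is trusted with its stage-1 call and the partner gets the complement; if
both members are trustworthy but conflict symmetrically (both inherited, or
both not), the lower parental-similarity member wins.  Pairs whose two
members are both confounded (scores > 0.5) stay `unresolved` and the locus
is treated as unphased downstream.  Uncertain non-bubble contigs keep their
stage-1 call unless confounded, in which case they are excluded.  A stage-1
tie defers to stage 2 rather than guessing, and any pair scenario not
covered by these rules maps to `unresolved`.

## Callable genome

Starting from the inherited contigs of an offspring: contigs with parental
similarity > 0.5 and no cross-parent homolog are removed (we cannot know
whether the other parent's identical allele was co-inherited); for each
highly similar cross-parent allele pair (cross-parent RBH with both
parental similarity scores > 0.5), both members inherited means both are
dropped (variants there cannot be phased and PZMs confound DNMs), exactly
one inherited means that member is retained *unphased* and counted at half
its length (the offspring inherited exactly one of two near-identical
alleles, and which one is unknowable); 100 bp are trimmed from each contig
end (assembly/alignment edge artifacts); and positions with depth above 3x
the offspring's mean (over inherited contigs) are excised as a repeat
proxy.  Trimming before capping is a fixed order, though the result is a
set intersection and order-free.  Callable sizes are integers; the half
rule uses floor.

`callable_expectation()` gives a closed-form expectation of the per-offspring
callable size conditional on the realized transmission, used as a
consistency check (observed sizes match within 2% on generator fixtures).
On the real data this framework was built for, per-offspring callable
fractions fall well below such clean-simulation values (roughly a third to a
half of the diploid genome), because real assemblies carry a large load of
uncertain contigs, collapsed repeats and fragmented alleles that the
generator deliberately does not emulate; passing the simulation checks
therefore validates the *bookkeeping*, not the messiness of real assemblies.

## Variant filtering

DNM candidates must satisfy all of: (i) inside the offspring's callable
set; (ii) homozygous-ALT in the offspring with DP > 10 and DP > 5 in the
contig's parent at the site; (iii) at most two alternative alleles observed
in each parent (from the AD fields -- the VCF is the ingestion surface, so
allele observations are read from per-allele depths, an allele counting as
observed with >= 1 read); (iv) QUAL >= 220, applied to the pileup-style
caller only (haplotype-caller genotype likelihoods are not comparable on
that scale); (v) no INDEL within 20 bp, the bound exclusive so a site 21 bp
away passes; (vi) not in the supplied gene-conversion site mask (ambiguous
conversion-vs-mutation events at parental heterozygous sites are far more
often conversions); (vii) no heterozygous genotype at the same contig site
in any other offspring (heterozygosity implies an inherited variant or
alignment error; a homozygous-ALT sibling is instead evidence of a shared
early-germline DNM, grouped by `group_shared_dnms()`).  On contigs in
high-similarity regions only haplotype-caller calls are consulted;
elsewhere both callers contribute and a site is reported once however many
callers called it.

Manual inspection of clustered calls cannot be automated faithfully; its
stand-in is a per-contig cap (default 2 candidates per contig per
offspring) that routes denser clusters to a review table instead of the
retained set.  The cap is a prior about real mutation densities (a few per
hundred megabases) and is therefore disabled inside spike-in harnesses,
whose densities are orders of magnitude higher by design.

PZM candidates follow the same criteria with three changes: unphased
regions are excluded entirely, heterozygous offspring genotypes are what is
*kept* (a homozygous-ALT call is germline), and no other sample -- parent
or sibling -- may carry more than two alternative reads at the position.
The VAF denominator spans both inherited alleles: focal-contig depth plus
the depth of the other parent's inherited allelic contig at the collinear
position (the generator's allelic contigs share coordinates; with real
data this lookup requires the reference-projected allele map).  Candidates
whose VAF is significantly greater than 0.25 are dropped, using
`stats::prop.test(alternative = "greater")` -- the one-sided
continuity-corrected chi-square score test -- at `p > 0.05` for retention;
its retain/reject decisions coincide with the exact binomial test at every
depth the pipeline produces, which the tests assert.

## Rates and summaries

* `false_negative_rate()`: `1 - detected/spiked` from the spike-in harness.
* `mutation_rate()`: `mu = n / (L * (1 - FNR))` with `L` the callable size
  *summed* over offspring and *not* doubled -- the inherited contig set of
  an offspring already represents its (approximately) diploid genome.  The
  CI is an exact Poisson interval on the count pushed through the same
  denominator; the method name is recorded in the output because the CI
  construction is a choice, not a given.
* `alpha_estimate()`: paternal/maternal count ratio, optionally normalized
  by parent-specific callable sizes, with a Clopper-Pearson CI on the
  paternal fraction mapped to the ratio scale.
* `substitution_class()` folds the twelve substitutions to six classes on
  an A/C reference convention and splits out `CpG>TpG` purely from the
  dinucleotide context of the contig sequence.
* `project_annotation()` transfers reference annotation contexts
  (exonic/intronic/intergenic) onto contigs through block-wise linear PAF
  coordinate maps; `context_rates()` then forms per-context rates over
  context-specific callable denominators.
* `effective_population_size()`: `Ne = pi / (4 mu)` under neutrality.
* `origin_contrast()`: Fisher's exact test for 2x2 origin contrasts, with
  a degenerate margin reported as `p = 1` and flagged.

## The synthetic pedigree generator

The generator (`sim_config()`, `simulate_pedigree()`) replaces everything
upstream of the package's inputs -- sequencing, assembly, alignment,
calling -- with parametric models of exactly the quantities the algorithms
consume.  Defaults are the study conditions: 3% heterozygosity, 80x
diploid sequencing depth, 50-bp bins, half of the bubble pairs mislabeled
as non-bubble contigs.

* **Genomes.** A random reference (default 3 Mb; the pipeline sees the
  6 Mb diploid); heterozygous SNPs placed by window-based inhomogeneous
  Poisson sampling (windows of 100 kb, uniform weights by default or
  Gamma-distributed to mimic empirical SNP-density variation), excluding
  planted no-variant intervals that become the true homozygous contigs.
  Each parent additionally carries homozygous substitutions at rate 0.015
  so that the two parents stay divergent even where each is internally
  homozygous, as unrelated individuals are -- without this, no-variant
  regions would be spuriously identical *between* parents.
* **Contigs.** The genome is segmented at no-variant boundaries and
  otherwise into log-normal pieces (median ~7 kb, matching short-read
  allele-aware assembly contig sizes).  Mislabeling operates at the pair
  level: an affected bubble pair is emitted as two unpaired non-bubble
  contigs, which is the failure mode classification must repair.
* **Shared ancestry.** In a fraction (default 5%, an inbred-population
  signature) of doubly heterozygous segments the father's haplotype 1 is
  replaced by the mother's, creating the near-identical cross-parent
  allele pairs that drive the unphased/unresolved machinery.
* **Depth.** Every individual's expected haplotype dose on every contig is
  computed (parents 1 per bubble member and 2 per homozygous contig;
  offspring per transmitted haplotype; shared-haplotype reads split evenly
  between the two identical contigs; a cross-mapping fraction, default
  0.02, bleeds between bubble-pair members), then per-bin depths are drawn
  negative-binomially (size 10) around dose x depth/2.  The bin-level
  noise model keeps the contig-mean depth histogram sharply bimodal;
  configurations that break the bimodality break classification by
  construction and are a config error, not a test case.
* **Alignments.** Self- and cross-parent PAFs are generated from the true
  allelic structure with match counts from exact Hamming distances, plus
  spurious partial hits (coverage ~0.4) that the RBH coverage filter must
  reject.
* **Mutations and observations.** DNMs are spiked uniformly into phased
  callable intervals (as spike-in FNR experiments do), shared DNMs into a
  common position of a contig inherited by `k` offspring, PZMs with true
  VAFs from a Beta(3, 15).  Variant records are then generated at truth
  sites with depths read off the simulated profiles, hom-ALT genotypes for
  DNMs, het genotypes with binomial allele counts for PZMs, QUAL drawn
  from a Normal(250, 15) for the pileup caller (its sub-220 tail is the
  dominant false-negative source, a few percent), and decoy records --
  INDELs, gene-conversion-masked sites, sites with an artifactual
  heterozygous sibling -- that each exercise one filter.  Haplotype-caller
  records exist only on high-similarity contigs, mirroring how such
  callers are deployed.

What the generator does *not* model: read-level errors, repeat families,
structural variation, real assembly fragmentation and collapse, and
alignment against a diverged public reference.  Green benchmarks therefore
demonstrate that the algorithms are implemented correctly and are
well-behaved under calibrated noise, not that real data will be as clean.

## Benchmarks and problem sizes

`run_benchmarks()` chains generation, classification, inheritance, callable
determination, the spike-in FNR harness and mutation detection, scoring
everything against truth.  The package's own test suite runs the full
chain on a 1 Mb-diploid pedigree with four offspring for unit-level
properties and on a 10 Mb-diploid pedigree with 30 offspring for the
benchmark checks (classification accuracy >= 95%, inheritance error <= 3%)
and for rate recovery: 100 replicates of the mutation layer (spike at
`mu* = 1e-6`, regenerate observations, re-detect, re-estimate with a fixed
spike-in FNR) on the fixed pedigree, requiring >= 90% CI coverage of
`mu*`.  Replicating only the mutation layer keeps the check inside a
sensible compute envelope while still exercising everything downstream of
transmission; pedigree-level variation is covered by the seed-level
determinism and distributional tests.  DNM spikes are placed in phased
intervals, while the rate denominator also counts the small unphased
contribution, biasing recovery conservatively by roughly the unphased
fraction (about 1% at defaults) -- well inside the Poisson CI width at
these counts.

`scripts/acceptance.R` reruns the generation + classification +
inheritance chain on a 6 Mb diploid genome with one offspring and reports
the two headline metrics as percentages.

## Known limitations

* The per-contig inheritance model has no within-contig recombination:
  a real crossover inside a contig produces a chimeric depth profile that
  stage 1 can only call one way.  Short contigs make this rare.
* Unphased loci contribute half their length to the callable genome but
  receive no spiked mutations in the harnesses; their contribution is
  bounded by the shared-ancestry fraction.
* The clustered-candidate cap and the conversion mask stand in for manual
  review and a companion conversion analysis; neither claims to reproduce
  a human curation step.
* `prop.test`'s normal approximation is used exactly because it is the
  field's habitual tool; at depths below ~20 its decisions can in
  principle diverge from the exact test, though not at the depths this
  pipeline retains (DP > 10 on both alleles).
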