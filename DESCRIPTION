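Package: haplodnm
Title: De Novo Mutation Detection in Highly Heterozygous Genomes Using
    Parental Allele-Aware Assemblies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Detects germline de novo mutations (DNMs) and postzygotic
    mutations (PZMs) in offspring of highly heterozygous diploid species by
    using haplotype-resolved (allele-aware) parental genome assemblies as the
    alignment reference.  Provides contig zygosity reclassification from read
    depth and reciprocal-best-hit self-alignment, two-stage inference of
    per-contig inheritance from binned read-depth profile similarity,
    per-offspring callable-genome determination, multi-criterion DNM and PZM
    filtering with parental-origin assignment, mutation-rate estimation with
    false-negative-rate correction, male mutation bias (alpha), folded
    mutation spectra, annotation-context rates, and effective population size
    from nucleotide diversity.  A synthetic pedigree generator replaces the
    assembler and aligner stages so the whole pipeline can be exercised and
    benchmarked against ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    stats,
    utils,
    jsonlite,
    yaml,
    Biostrings,
    IRanges,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
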