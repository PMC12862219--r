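# Configuration of the synthetic pedigree generator.

#' Synthetic pedigree configuration
#'
#' Parameters of the generator that stands in for the wet-lab + assembler +
#' aligner stages: two highly heterozygous diploid parents, contigized
#' allele-aware assemblies, Mendelian transmission to offspring, parametric
#' depth profiles with cross-mapping between similar alleles, and spiked
#' mutations with truth records.  All randomness is governed by `seed`.
#'
#' @param genome_length Haploid reference length in bp (default 3e6; the
#'   diploid genome the pipeline sees is twice this).
#' @param window_size SNP-density window for the inhomogeneous Poisson
#'   placement (default 1e5 bp).
#' @param window_weight_shape When non-`NULL`, per-window weights are drawn
#'   from a Gamma with this shape (mean 1) to mimic empirical SNP-density
#'   variation; `NULL` (default) uses uniform weights.
#' @param heterozygosity Target within-parent heterozygosity (default 0.03).
#' @param hom_divergence Rate of parent-specific homozygous substitutions
#'   relative to the reference (default 0.015); keeps the two parents
#'   divergent even inside no-variant intervals, as unrelated individuals
#'   are.
#' @param n_no_variant_intervals,no_variant_length Number and length (bp) of
#'   planted intervals with no heterozygous SNPs in either parent; these
#'   become the true homozygous (non-bubble) contigs.
#' @param n_offspring Number of offspring (default 2).
#' @param depth_mean Mean diploid sequencing depth per individual (default
#'   80); a contig carrying one haplotype dose sits near `depth_mean / 2`.
#' @param nb_size Negative-binomial size (dispersion) of per-bin depth
#'   (default 10; smaller = noisier).
#' @param bin_size Depth bin width in bp (default 50).
#' @param cross_mapping_rate Fraction of reads from one allele of a bubble
#'   pair that mis-map to the partner allele (default 0.02, a few percent as
#'   seen between alleles at ~3\% divergence; keeps non-carrier bleed depth
#'   far below both the stage-1 depth floor and the similarity threshold).
#' @param shared_ancestry_fraction Fraction of heterozygous segments where
#'   the parents share one near-identical haplotype (default 0.05), creating
#'   high parental-similarity loci.
#' @param nonbubble_mislabel_fraction Fraction of true bubble pairs emitted
#'   by the "assembler" as two unpaired non-bubble contigs (default 0.5);
#'   these are what classification must recover.
#' @param segment_mean,segment_sdlog,segment_min Log-normal contig length
#'   model (bp): median around `segment_mean` (default 7000), log-sd
#'   `segment_sdlog` (default 0.4), minimum `segment_min` (default 600).
#' @param dnm_per_offspring,pzm_per_offspring Spiked mutation counts per
#'   offspring for benchmark harnesses (defaults 30 and 10).
#' @param shared_dnm_groups,shared_dnm_k Number of early-germline DNM groups
#'   spiked into `shared_dnm_k` offspring each (defaults 2 and 2).
#' @param pzm_vaf_shape1,pzm_vaf_shape2 Beta parameters of the true PZM VAF
#'   (defaults 3 and 15: mean ~0.17, range mostly 0.05--0.35).
#' @param indel_decoys,conversion_decoys,artifact_het_sites Numbers of decoy
#'   records injected per offspring to exercise the INDEL-proximity,
#'   gene-conversion-mask and sibling-heterozygosity filters (defaults 30,
#'   30, 20).
#' @param qual_mean,qual_sd Normal model of pileup-caller QUAL at true sites
#'   (defaults 250 and 15; the tail below the QUAL threshold is the main
#'   false-negative source).
#' @param n_decoy_alignments Spurious partial self-alignment hits added to
#'   the simulated PAF (default 50; coverage ~0.4, so they must not survive
#'   the RBH coverage filter).
#' @param seed Integer seed (mandatory).
#' @return List of class `sim_config`.
#' @export
sim_config <- function(genome_length = 3e6,
                       window_size = 1e5,
                       window_weight_shape = NULL,
                       heterozygosity = 0.03,
                       hom_divergence = 0.015,
                       n_no_variant_intervals = 20,
                       no_variant_length = 2e4,
                       n_offspring = 2,
                       depth_mean = 80,
                       nb_size = 10,
                       bin_size = 50,
                       cross_mapping_rate = 0.02,
                       shared_ancestry_fraction = 0.05,
                       nonbubble_mislabel_fraction = 0.5,
                       segment_mean = 7000,
                       segment_sdlog = 0.4,
                       segment_min = 600,
                       dnm_per_offspring = 30,
                       pzm_per_offspring = 10,
                       shared_dnm_groups = 2,
                       shared_dnm_k = 2,
                       pzm_vaf_shape1 = 3,
                       pzm_vaf_shape2 = 15,
                       indel_decoys = 30,
                       conversion_decoys = 30,
                       artifact_het_sites = 20,
                       qual_mean = 250,
                       qual_sd = 15,
                       n_decoy_alignments = 50,
                       seed = NULL) {
  if (is.null(seed)) stop("sim_config requires an explicit seed")
  cfg <- as.list(environment())
  fracs <- c("heterozygosity", "hom_divergence", "cross_mapping_rate",
             "shared_ancestry_fraction", "nonbubble_mislabel_fraction")
  for (f in fracs) {
    if (cfg[[f]] < 0 || cfg[[f]] > 1) stop(f, " must be in [0, 1]")
  }
  stopifnot(genome_length >= 10 * segment_mean, depth_mean > 0, nb_size > 0,
            n_offspring >= 1, segment_min >= 150 + 2 * bin_size)
  if (n_no_variant_intervals * no_variant_length > 0.5 * genome_length)
    stop("no-variant intervals would cover more than half the genome")
  structure(cfg, class = "sim_config")
}

#' Read a generator configuration from YAML
#' @param path YAML file whose keys are [sim_config()] arguments.
#' @return `sim_config` object.
#' @export
read_sim_config <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(sim_config))
  bad <- setdiff(names(vals), known)
  if (length(bad))
    stop("unknown config key(s): ", paste(bad, collapse = ", "))
  do.call(sim_config, vals)
}
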