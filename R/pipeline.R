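# End-to-end orchestration of the analysis stages on a simulated pedigree
# (or on equivalently shaped real inputs loaded through the io readers).

#' Run the analysis pipeline on a simulated pedigree
#'
#' Classification (per parent), parental similarity scores, two-stage
#' inheritance inference, cross-parent homology, and per-offspring callable
#' sets plus allelic counterpart maps.
#'
#' @param sim A `pedigree_sim` object.
#' @param sequencing_depth Per-individual mean sequencing depth used to
#'   scale the zygosity depth thresholds (defaults to the generator's
#'   `depth_mean`; with real data, supply the mosdepth individual-level
#'   mean).
#' @param min_coverage,min_identity RBH thresholds.
#' @param sim_threshold Parental-similarity cutoff.
#' @param min_depth Stage-1 absolute depth floor.
#' @param end_trim,depth_cap_multiplier Callable-genome filters.
#' @return List of class `haplodnm_pipeline`: `zygosity`, `calls`
#'   (inheritance), `parental_similarity`, `cross_rbh`, `similar_pairs`,
#'   `high_similarity_contigs`, `callable` (named list of `callable_set`),
#'   `counterpart` (named list of tables), `params`.
#' @export
run_pipeline <- function(sim, sequencing_depth = sim$cfg$depth_mean,
                         min_coverage = 0.7, min_identity = 0.7,
                         sim_threshold = 0.5, min_depth = 10,
                         end_trim = 100, depth_cap_multiplier = 3) {
  contigs <- sim$contigs
  all_lens <- setNames(as.numeric(contigs$length_bp), contigs$contig_id)
  th <- default_thresholds(sequencing_depth)
  zyg <- list()
  for (p in c("maternal", "paternal")) {
    ind <- if (p == "maternal") "mother" else "father"
    cc <- contigs[parent_of_origin == p]
    md <- contig_means_from_bins(sim, ind)[contig_id %in% cc$contig_id]
    lens <- all_lens[cc$contig_id]
    rbh <- rbh_pairs(sim$self_paf[[p]], lens, min_coverage, min_identity)
    zyg[[p]] <- classify_contigs(cc, md, rbh, th)
  }
  zygosity <- data.table::rbindlist(zyg)
  calls <- infer_inheritance(sim$bins, contigs, zygosity, "mother", "father",
                             sim$offspring_ids, min_depth, sim_threshold)
  par_sim <- calls[offspring_id == sim$offspring_ids[1],
                   setNames(parental_similarity, contig_id)]
  cross_rbh <- rbh_pairs(sim$cross_paf, all_lens, min_coverage, min_identity)
  similar_pairs <- find_similar_allele_pairs(
    sim$cross_paf, contigs, par_sim, min_coverage, min_identity,
    sim_threshold)
  high_sim <- union(similar_pairs$maternal_contig_id,
                    similar_pairs$paternal_contig_id)
  callable <- list()
  for (off in sim$offspring_ids) {
    track <- make_depth_track(sim, off)
    callable[[off]] <- callable_set(
      off, calls, contigs, similar_pairs, track,
      end_trim = end_trim, depth_cap_multiplier = depth_cap_multiplier,
      sim_threshold = sim_threshold)
  }
  counterpart <- counterpart_maps(contigs, zygosity, cross_rbh, calls,
                                  sim$offspring_ids)
  structure(list(zygosity = zygosity, calls = calls,
                 parental_similarity = par_sim, cross_rbh = cross_rbh,
                 similar_pairs = similar_pairs,
                 high_similarity_contigs = high_sim,
                 callable = callable, counterpart = counterpart,
                 params = list(sequencing_depth = sequencing_depth,
                               min_coverage = min_coverage,
                               min_identity = min_identity,
                               sim_threshold = sim_threshold,
                               min_depth = min_depth, end_trim = end_trim,
                               depth_cap_multiplier = depth_cap_multiplier)),
            class = "haplodnm_pipeline")
}

# For each offspring and contig, the other parent's allelic contig that the
# offspring inherited (cross-parent RBH partner, or the partner's allelic
# mate, whichever is called inherited).
counterpart_maps <- function(contigs, zygosity, cross_rbh, calls,
                             offspring_ids) {
  cross <- setNames(
    c(cross_rbh$contig_b, cross_rbh$contig_a),
    c(cross_rbh$contig_a, cross_rbh$contig_b))
  ap <- allelic_pairs(zygosity, contigs)
  mate <- setNames(ap$partner, ap$contig_id)
  cids <- contigs$contig_id
  cand1 <- unname(cross[cids])
  # no direct cross-parent hit: go through the contig's own allelic mate
  own_mate <- unname(mate[cids])
  cand1 <- ifelse(is.na(cand1) & !is.na(own_mate),
                  unname(cross[own_mate]), cand1)
  cand2 <- unname(mate[cand1])
  out <- list()
  for (off in offspring_ids) {
    st <- calls[offspring_id == off, setNames(state, contig_id)]
    pick <- ifelse(!is.na(cand1) & st[cand1] == "inherited", cand1,
                   ifelse(!is.na(cand2) & st[cand2] == "inherited", cand2,
                          NA_character_))
    out[[off]] <- data.table::data.table(contig_id = cids,
                                         counterpart_id = unname(pick))
  }
  out
}

# depth (bin value) of an individual at single positions
depth_at <- function(sim, individual, contig, pos) {
  b <- sim$bins[[individual]]
  bs <- sim$cfg$bin_size
  vapply(seq_along(contig), function(i) {
    v <- b[[contig[i]]]
    j <- min(pos[i] %/% bs + 1L, length(v))
    v[j]
  }, numeric(1))
}
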