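# Per-offspring callable genome: the positions where a DNM could have been
# confidently called, and the denominator of the mutation-rate estimator.

#' Highly similar cross-parent allele pairs
#'
#' Cross-parent reciprocal best hits (same machinery as the self-alignment
#' RBH step) whose members both carry a parental similarity score above the
#' threshold.  Such pairs mark loci where the offspring's two inherited
#' alleles cannot be told apart, which breaks phasing.
#'
#' @param cross_paf PAF `data.table` from aligning the maternal assembly to
#'   the paternal one and vice versa.
#' @param contigs Contig table (for lengths and parent of origin).
#' @param parental_similarity Named vector contig -> parental similarity.
#' @param min_coverage,min_identity RBH thresholds (default 0.7).
#' @param sim_threshold Parental-similarity cutoff (default 0.5).
#' @return `data.table(maternal_contig_id, paternal_contig_id,
#'   parental_similarity)` where the score is the maximum over the pair.
#' @export
find_similar_allele_pairs <- function(cross_paf, contigs,
                                      parental_similarity,
                                      min_coverage = 0.7,
                                      min_identity = 0.7,
                                      sim_threshold = 0.5) {
  lens <- setNames(as.numeric(contigs$length_bp), contigs$contig_id)
  org <- setNames(contigs$parent_of_origin, contigs$contig_id)
  rbh <- rbh_pairs(cross_paf, lens, min_coverage, min_identity)
  if (!nrow(rbh)) {
    return(data.table::data.table(maternal_contig_id = character(),
                                  paternal_contig_id = character(),
                                  parental_similarity = numeric()))
  }
  rbh <- rbh[org[contig_a] != org[contig_b]]
  ps <- parental_similarity
  rbh[, `:=`(
    maternal_contig_id = ifelse(org[contig_a] == "maternal", contig_a, contig_b),
    paternal_contig_id = ifelse(org[contig_a] == "maternal", contig_b, contig_a))]
  ps_m <- unname(ps[rbh$maternal_contig_id])
  ps_p <- unname(ps[rbh$paternal_contig_id])
  out <- rbh[, list(maternal_contig_id, paternal_contig_id)]
  out[, parental_similarity := pmax(ps_m, ps_p)]
  out[ps_m > sim_threshold & ps_p > sim_threshold]
}

#' Callable genome of one offspring
#'
#' Starts from the contigs called inherited after stage 2, removes loci that
#' cannot be phased (both members of a highly similar cross-parent allele
#' pair inherited; contigs with high parental similarity but no cross-parent
#' homolog), moves similar-pair loci with exactly one inherited member to an
#' unphased set counted at half length, trims `end_trim` bp off each contig
#' end, and excises positions whose depth exceeds
#' `depth_cap_multiplier x` the offspring's mean depth (a repeat proxy).
#'
#' @param offspring Offspring ID.
#' @param calls Stage-2 inheritance calls for this offspring.
#' @param contigs Contig table.
#' @param similar_pairs Output of [find_similar_allele_pairs()].
#' @param depth_track Offspring depth `data.table` (run-length).
#' @param offspring_depth_mean Mean depth used by the cap; when `NULL`,
#'   the length-weighted mean over inherited contigs is computed from the
#'   track (the same statistic family as stage 1).
#' @param end_trim Bases removed from each contig end (default 100).
#' @param depth_cap_multiplier Depth cap as a multiple of the mean (default 3).
#' @param sim_threshold Parental-similarity cutoff (default 0.5).
#' @return List of class `callable_set`: `offspring_id`, `phased_intervals`
#'   (`data.table(contig_id, start, end)`, 0-based half-open),
#'   `unphased_contigs`, `total_bp`, `phased_bp`, `unphased_bp_contribution`,
#'   and `phased_bp_by_parent`.
#' @export
callable_set <- function(offspring, calls, contigs, similar_pairs,
                         depth_track, offspring_depth_mean = NULL,
                         end_trim = 100, depth_cap_multiplier = 3,
                         sim_threshold = 0.5) {
  calls <- calls[offspring_id == offspring]
  unknown <- setdiff(calls$contig_id, contigs$contig_id)
  if (length(unknown))
    stop("inheritance call references unknown contig(s): ",
         paste(head(unknown, 5), collapse = ", "))
  lens <- setNames(as.numeric(contigs$length_bp), contigs$contig_id)
  inh <- calls[state == "inherited"]
  # unphasable: high parental similarity without a cross-parent homolog
  in_pair <- union(similar_pairs$maternal_contig_id,
                   similar_pairs$paternal_contig_id)
  inh <- inh[!(parental_similarity > sim_threshold & !(contig_id %in% in_pair))]
  inh_ids <- inh$contig_id
  # similar-pair logic
  drop <- character(0); unphased <- character(0)
  if (nrow(similar_pairs)) {
    both <- similar_pairs[maternal_contig_id %in% inh_ids &
                            paternal_contig_id %in% inh_ids]
    drop <- union(both$maternal_contig_id, both$paternal_contig_id)
    one <- similar_pairs[xor(maternal_contig_id %in% inh_ids,
                             paternal_contig_id %in% inh_ids)]
    unphased <- intersect(union(one$maternal_contig_id,
                                one$paternal_contig_id), inh_ids)
  }
  phased_ids <- setdiff(inh_ids, union(drop, unphased))
  # trimmed spans minus high-depth runs
  if (is.null(offspring_depth_mean)) {
    tr <- depth_track[contig_id %in% inh_ids]
    offspring_depth_mean <- sum(tr$depth * (tr$end - tr$start)) /
      sum(tr$end - tr$start)
  }
  cap <- depth_cap_multiplier * offspring_depth_mean
  ivs <- callable_intervals(phased_ids, lens, depth_track, end_trim, cap)
  phased_bp <- if (nrow(ivs)) sum(ivs$end - ivs$start) else 0
  org <- setNames(contigs$parent_of_origin, contigs$contig_id)
  by_parent <- if (nrow(ivs))
    ivs[, list(bp = sum(end - start)), by = list(parent = org[contig_id])]
  else data.table::data.table(parent = character(), bp = numeric())
  unphased_bp <- floor(sum(lens[unphased]) / 2)
  structure(list(
    offspring_id = offspring,
    phased_intervals = ivs,
    unphased_contigs = unphased,
    phased_bp = phased_bp,
    unphased_bp_contribution = unphased_bp,
    total_bp = phased_bp + unphased_bp,
    phased_bp_by_parent = setNames(as.numeric(by_parent$bp), by_parent$parent),
    depth_mean = offspring_depth_mean), class = "callable_set")
}

# trimmed contig spans with depth-cap runs excised, via IRanges set algebra
callable_intervals <- function(ids, lens, depth_track, end_trim, cap) {
  if (!length(ids)) {
    return(data.table::data.table(contig_id = character(), start = integer(),
                                  end = integer()))
  }
  hot <- depth_track[contig_id %in% ids & depth > cap]
  out <- vector("list", length(ids))
  for (i in seq_along(ids)) {
    cid <- ids[i]
    len <- lens[[cid]]
    if (len <= 2 * end_trim) next
    span <- IRanges::IRanges(start = end_trim + 1L, end = len - end_trim)
    h <- hot[contig_id == cid]
    if (nrow(h)) {
      span <- IRanges::setdiff(
        span, IRanges::reduce(IRanges::IRanges(start = h$start + 1L,
                                               end = h$end)))
    }
    if (length(span)) {
      out[[i]] <- data.table::data.table(
        contig_id = cid, start = IRanges::start(span) - 1L,
        end = IRanges::end(span))
    }
  }
  data.table::rbindlist(out)
}

#' Is a site inside a callable set?
#'
#' @param cs A `callable_set`.
#' @param contig,pos Vectors of contig IDs and 0-based positions.
#' @param include_unphased Count unphased contigs as callable (default TRUE;
#'   DNMs there are retained as unphased, PZM calling excludes them).
#' @return Logical vector.
#' @export
in_callable <- function(cs, contig, pos, include_unphased = TRUE) {
  res <- logical(length(contig))
  iv <- cs$phased_intervals
  if (nrow(iv)) {
    dt <- data.table::data.table(contig_id = contig, pos = pos,
                                 i = seq_along(contig))
    m <- iv[dt, on = list(contig_id, start <= pos, end > pos), nomatch = 0L,
            allow.cartesian = TRUE]
    res[unique(m$i)] <- TRUE
  }
  if (include_unphased) res <- res | (contig %in% cs$unphased_contigs)
  res
}

#' Summarize callable sets across offspring
#'
#' @param callable_list List of `callable_set` objects.
#' @return `data.table(offspring_id, total_bp, phased_bp,
#'   unphased_bp_contribution, n_contigs)`.
#' @export
callable_summary <- function(callable_list) {
  data.table::rbindlist(lapply(callable_list, function(cs) {
    data.table::data.table(
      offspring_id = cs$offspring_id, total_bp = cs$total_bp,
      phased_bp = cs$phased_bp,
      unphased_bp_contribution = cs$unphased_bp_contribution,
      n_contigs = length(unique(cs$phased_intervals$contig_id)) +
        length(cs$unphased_contigs))
  }))
}
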