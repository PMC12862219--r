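# Two-stage inference of per-contig inheritance from read-depth profiles.
#
# A parental contig inherited by an offspring collects that offspring's reads
# along its whole length, so the offspring's binned depth profile resembles
# the profile of the parent the contig came from.  Stage 1 scores each contig
# independently with a weighted cosine/Jaccard similarity; stage 2 enforces
# Mendelian logic within allelic (bubble) pairs and uses the "parental
# similarity score" -- the same similarity computed between the two parents'
# profiles on one contig -- to detect loci where the parents are too alike to
# separate.

#' Bin a per-base depth vector into fixed-width bins
#'
#' Mean depth per `bin_size`-bp bin; a trailing bin shorter than `bin_size`
#' is discarded.
#'
#' @param depth Numeric vector of per-base depths.
#' @param bin_size Bin width in bp (default 50).
#' @return Numeric vector of `floor(length(depth)/bin_size)` bin means.
#' @export
bin_depths <- function(depth, bin_size = 50) {
  n <- length(depth) %/% bin_size
  if (n < 1L) stop("contig shorter than one bin cannot be scored")
  colMeans(matrix(depth[seq_len(n * bin_size)], nrow = bin_size))
}

#' Bin a run-length depth track
#'
#' @param track Depth `data.table` rows for one contig.
#' @param contig Contig ID.
#' @param len Contig length in bp.
#' @param bin_size Bin width in bp.
#' @return Numeric vector of bin means.
#' @export
bin_depths_track <- function(track, contig, len, bin_size = 50) {
  bin_depths(expand_depth(track, contig, len), bin_size)
}

# fast scalar core shared by depth_similarity() and the pipeline
similarity_value <- function(u, v) {
  nz <- u > 0 & v > 0
  b <- length(u)
  k <- sum(nz)
  w_nz <- k / b
  cos_p <- if (k) {
    un <- u[nz]; vn <- v[nz]
    sum(un * vn) / sqrt(sum(un * un) * sum(vn * vn))
  } else 1
  zz <- b - k
  jac_p <- if (zz) sum(u == 0 & v == 0) / zz else 1
  w_nz * cos_p + (1 - w_nz) * jac_p
}

#' Weighted cosine/Jaccard similarity of two depth profiles
#'
#' Bins where both profiles are positive contribute a cosine similarity;
#' bins where at least one profile is zero contribute a Jaccard-style
#' agreement on zero coverage (zero-in-both over zero-in-at-least-one).  The
#' two parts are weighted by the fractions of such bins, so the score lies in
#' \[0, 1\], is symmetric, and equals 1 for identical profiles (including the
#' all-zero case).
#'
#' @param u,v Numeric bin vectors of equal length (same contig, same binning).
#' @return List of class `similarity_score` with elements `value`,
#'   `cosine_part`, `jaccard_part`, `weight_nonzero`, `weight_zero`.
#' @export
depth_similarity <- function(u, v) {
  if (length(u) != length(v))
    stop("bin-count mismatch: ", length(u), " vs ", length(v))
  if (!length(u)) stop("empty depth vectors")
  nz <- u > 0 & v > 0
  b <- length(u)
  k <- sum(nz)
  cos_p <- if (k) {
    un <- u[nz]; vn <- v[nz]
    sum(un * vn) / sqrt(sum(un * un) * sum(vn * vn))
  } else 1
  zz <- b - k
  jac_p <- if (zz) sum(u == 0 & v == 0) / zz else 1
  w_nz <- k / b
  structure(list(value = w_nz * cos_p + (1 - w_nz) * jac_p,
                 cosine_part = cos_p, jaccard_part = jac_p,
                 weight_nonzero = w_nz, weight_zero = 1 - w_nz),
            class = "similarity_score")
}

#' Parental similarity score of one contig
#'
#' Depth-profile similarity between the two parents' reads on the same
#' contig.  Values above 0.5 mean the parents are nearly indistinguishable
#' there (shared ancestry / near-identical alleles) and inheritance calls on
#' the contig are unreliable.
#'
#' @param maternal_bins,paternal_bins Bin vectors of the two parents on the
#'   contig.
#' @return Scalar in \[0, 1\].
#' @export
parental_similarity_score <- function(maternal_bins, paternal_bins) {
  depth_similarity(maternal_bins, paternal_bins)$value
}

#' Stage-1 inheritance call for one offspring x contig
#'
#' The contig is low-depth (not inherited) when its mean depth in the
#' offspring is below `max(min_depth, offspring_mean_depth / 4)`; otherwise
#' it is called inherited iff the offspring's profile is more similar to the
#' profile of the contig's parent of origin than to the other parent's, with
#' an exact tie left unresolved.
#'
#' @param sim_origin Similarity of the offspring profile to the
#'   parent-of-origin profile.
#' @param sim_other Similarity to the other parent's profile.
#' @param contig_mean Offspring's mean depth on the contig.
#' @param offspring_mean_depth Offspring's genome-wide mean depth
#'   (length-weighted over all contigs of the parental reference).
#' @param min_depth Absolute depth floor (default 10).
#' @return List with `state` (`inherited`/`not_inherited`/`unresolved`) and
#'   `basis` (`low_depth`/`similarity`).
#' @export
stage1_call <- function(sim_origin, sim_other, contig_mean,
                        offspring_mean_depth, min_depth = 10) {
  stopifnot(offspring_mean_depth > 0)
  if (contig_mean < max(min_depth, offspring_mean_depth / 4))
    return(list(state = "not_inherited", basis = "low_depth"))
  if (sim_origin > sim_other) list(state = "inherited", basis = "similarity")
  else if (sim_origin < sim_other)
    list(state = "not_inherited", basis = "similarity")
  else list(state = "unresolved", basis = "similarity")
}

# Resolve one allelic pair given its two stage-1 rows (list columns of a
# data.table would be slow here; plain vectors in, small data.frame out).
resolve_pair <- function(st, ps, low, sim_threshold = 0.5) {
  # st: stage-1 states (2); ps: parental similarity; low: low-depth flags
  out <- function(states, bases) list(states = states, bases = bases)
  if (all(ps > sim_threshold)) {
    return(out(c("unresolved", "unresolved"),
               c("high_parental_similarity", "high_parental_similarity")))
  }
  if (any(low)) {
    if (all(low)) {
      w <- which.min(ps)
      states <- c("not_inherited", "not_inherited"); states[w] <- "inherited"
      bases <- c("low_depth", "low_depth"); bases[w] <- "parental_similarity"
      return(out(states, bases))
    }
    states <- ifelse(low, "not_inherited", "inherited")
    bases <- ifelse(low, "low_depth", "partner_forced")
    return(out(states, bases))
  }
  elig <- ps <= sim_threshold
  if (sum(elig) == 1L) {
    w <- which(elig)
    if (st[w] == "inherited") {
      states <- c("not_inherited", "not_inherited"); states[w] <- "inherited"
      bases <- c("partner_forced", "partner_forced"); bases[w] <- "similarity"
    } else if (st[w] == "not_inherited") {
      states <- c("inherited", "inherited"); states[w] <- "not_inherited"
      bases <- c("partner_forced", "partner_forced"); bases[w] <- "similarity"
    } else {
      states <- c("not_inherited", "not_inherited"); states[w] <- "inherited"
      bases <- c("partner_forced", "partner_forced")
      bases[w] <- "parental_similarity"
    }
    return(out(states, bases))
  }
  # both members separable from the other parent
  if (identical(sort(st), c("inherited", "not_inherited"))) {
    return(out(st, c("similarity", "similarity")))
  }
  w <- which.min(ps)
  states <- c("not_inherited", "not_inherited"); states[w] <- "inherited"
  bases <- c("parental_similarity", "parental_similarity")
  out(states, bases)
}

#' Stage-2 resolution of inheritance calls
#'
#' Applies, per offspring: (a) true non-bubble (homozygous) contigs are
#' always inherited; (b)--(c) within each bubble / bubble-like pair exactly
#' one member ends up inherited, using low-depth evidence first, then the
#' stage-1 similarity call of whichever member has parental similarity at or
#' below the threshold, then the lower parental similarity score; (d) pairs
#' whose two members both exceed the parental-similarity threshold are left
#' unresolved (the locus is treated as unphased downstream); (e) uncertain
#' non-bubble contigs keep their stage-1 call unless their parental
#' similarity exceeds the threshold, in which case they are unresolved.
#'
#' @param stage1 `data.table` of stage-1 calls: `offspring_id, contig_id,
#'   state, basis, similarity_mother, similarity_father`.
#' @param zygosity Zygosity table from [classify_contigs()] (categories and
#'   bubble-like partners).
#' @param contigs Contig table (assembler bubble partners).
#' @param parental_similarity Named numeric vector, contig -> parental
#'   similarity score.
#' @param sim_threshold Parental-similarity cutoff (default 0.5).
#' @return `data.table(offspring_id, contig_id, state, stage, basis,
#'   similarity_mother, similarity_father, parental_similarity)`.
#' @export
stage2_resolve <- function(stage1, zygosity, contigs, parental_similarity,
                           sim_threshold = 0.5) {
  pairs <- allelic_pairs(zygosity, contigs)
  canon <- pairs[contig_id < partner]
  cat_map <- setNames(zygosity$category, zygosity$contig_id)
  offs <- unique(stage1$offspring_id)
  res_list <- vector("list", length(offs))
  for (i in seq_along(offs)) {
    off <- offs[i]
    s1 <- stage1[offspring_id == off]
    idx <- setNames(seq_len(nrow(s1)), s1$contig_id)
    cat_v <- cat_map[s1$contig_id]
    ps_v <- unname(parental_similarity[s1$contig_id])
    out_state <- character(nrow(s1)); out_basis <- character(nrow(s1))
    out_stage <- rep(2L, nrow(s1))
    # (a) homozygous contigs
    hom <- which(cat_v == "true_non_bubble")
    out_state[hom] <- "inherited"; out_basis[hom] <- "homozygous_always"
    # (e) uncertain contigs
    unc <- which(cat_v == "uncertain")
    hi <- unc[ps_v[unc] > sim_threshold]
    lo <- setdiff(unc, hi)
    out_state[hi] <- "unresolved"; out_basis[hi] <- "high_parental_similarity"
    out_state[lo] <- s1$state[lo]; out_basis[lo] <- s1$basis[lo]
    out_stage[lo] <- 1L
    # (b)-(d) allelic pairs
    paired <- cat_v %in% c("bubble", "bubble_like")
    in_set <- canon$contig_id %in% s1$contig_id & canon$partner %in% s1$contig_id
    missing_partner <- sum(paired) - 2L * sum(in_set)
    if (missing_partner != 0L)
      stop("inconsistent allelic pairing: ", missing_partner,
           " paired contig(s) lack a partner in the call set")
    for (r in which(in_set)) {
      ii <- c(idx[[canon$contig_id[r]]], idx[[canon$partner[r]]])
      res <- resolve_pair(s1$state[ii], ps_v[ii],
                          s1$basis[ii] == "low_depth", sim_threshold)
      out_state[ii] <- res$states
      out_basis[ii] <- res$bases
    }
    res_list[[i]] <- data.table::data.table(
      offspring_id = off, contig_id = s1$contig_id,
      state = out_state, stage = out_stage, basis = out_basis,
      similarity_mother = s1$similarity_mother,
      similarity_father = s1$similarity_father,
      parental_similarity = ps_v)
  }
  data.table::rbindlist(res_list)
}

# allelic pair table: assembler bubbles use partner_id, bubble-like pairs use
# the mutual RBH partner recorded by classification
allelic_pairs <- function(zygosity, contigs) {
  bub <- merge(zygosity[category == "bubble", list(contig_id)],
               contigs[, list(contig_id, partner_id)], by = "contig_id")
  data.table::setnames(bub, "partner_id", "partner")
  bl <- zygosity[category == "bubble_like",
                 list(contig_id, partner = rbh_partner)]
  data.table::rbindlist(list(bub, bl))
}

#' Offspring genome-wide mean depth
#'
#' Length-weighted mean of per-contig mean depths over all contigs of the
#' parental reference; the statistic behind the stage-1 low-depth cutoff and
#' the callable-genome depth cap.
#'
#' @param mean_depths `data.table(contig_id, mean_depth)` for the offspring.
#' @param contig_lengths Named vector of contig lengths.
#' @return Scalar mean depth.
#' @export
offspring_mean_depth <- function(mean_depths, contig_lengths) {
  len <- as.numeric(contig_lengths[mean_depths$contig_id])
  sum(mean_depths$mean_depth * len) / sum(len)
}

#' Full two-stage inheritance inference for a pedigree
#'
#' @param bins Nested list: `bins[[individual]][[contig]]` is the 50-bp bin
#'   vector of that individual's depth on that contig.  Must contain the two
#'   parents and every offspring.
#' @param contigs Contig table.
#' @param zygosity Zygosity table from [classify_contigs()] for the whole
#'   parental reference.
#' @param mother_id,father_id Parent individual IDs in `bins`.
#' @param offspring_ids Offspring individual IDs.
#' @param min_depth Stage-1 absolute depth floor.
#' @param sim_threshold Parental-similarity cutoff.
#' @return Stage-2 call table (see [stage2_resolve()]).
#' @export
infer_inheritance <- function(bins, contigs, zygosity, mother_id, father_id,
                              offspring_ids, min_depth = 10,
                              sim_threshold = 0.5) {
  cids <- contigs$contig_id
  lens <- setNames(as.numeric(contigs$length_bp), cids)
  origin <- setNames(contigs$parent_of_origin, cids)
  mb <- bins[[mother_id]]; fb <- bins[[father_id]]
  par_sim <- vapply(cids, function(cid)
    similarity_value(mb[[cid]], fb[[cid]]), numeric(1))
  s1_list <- vector("list", length(offspring_ids))
  for (k in seq_along(offspring_ids)) {
    off <- offspring_ids[k]
    ob <- bins[[off]]
    cmean <- vapply(cids, function(cid) mean(ob[[cid]]), numeric(1))
    omean <- sum(cmean * lens) / sum(lens)
    cut <- max(min_depth, omean / 4)
    sim_m <- numeric(length(cids)); sim_f <- numeric(length(cids))
    state <- character(length(cids)); basis <- character(length(cids))
    for (j in seq_along(cids)) {
      cid <- cids[j]
      sim_m[j] <- similarity_value(ob[[cid]], mb[[cid]])
      sim_f[j] <- similarity_value(ob[[cid]], fb[[cid]])
      if (cmean[j] < cut) {
        state[j] <- "not_inherited"; basis[j] <- "low_depth"
      } else {
        so <- if (origin[[cid]] == "maternal") sim_m[j] else sim_f[j]
        st <- if (origin[[cid]] == "maternal") sim_f[j] else sim_m[j]
        if (so > st) { state[j] <- "inherited"; basis[j] <- "similarity" }
        else if (so < st) { state[j] <- "not_inherited"; basis[j] <- "similarity" }
        else { state[j] <- "unresolved"; basis[j] <- "similarity" }
      }
    }
    s1_list[[k]] <- data.table::data.table(
      offspring_id = off, contig_id = cids, state = state, basis = basis,
      similarity_mother = sim_m, similarity_father = sim_f)
  }
  stage1 <- data.table::rbindlist(s1_list)
  stage2_resolve(stage1, zygosity, contigs, par_sim, sim_threshold)
}
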