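# Zygosity reclassification of assembler contigs.
#
# Allele-aware assemblers emit heterozygous regions as "bubble" contig pairs
# (primary + secondary allele) and homozygous regions as single "non-bubble"
# contigs, but in practice the non-bubble set is a mixture.  Two lines of
# evidence separate them: contig mean read depth (a heterozygous contig
# carries one of the parent's two haplotypes, so it sits at roughly half the
# individual's sequencing depth) and reciprocal-best-hit (RBH) self-alignment
# (a heterozygous contig has a high-coverage, high-identity partner -- its
# other allele -- somewhere in the assembly).

#' Mean read depth of one contig
#'
#' Arithmetic mean of per-base depth, computed from the run-length track
#' without expansion.
#'
#' @param track Depth `data.table` rows for a single contig
#'   (`contig_id, start, end, depth`).
#' @return Non-negative scalar.
#' @export
contig_mean_depth <- function(track) {
  len <- sum(track$end - track$start)
  if (!nrow(track) || len <= 0) stop("zero-length depth track")
  sum(track$depth * (track$end - track$start)) / len
}

#' Mean depth of every contig in a track
#' @param track Depth `data.table` (many contigs).
#' @return `data.table(contig_id, mean_depth)`.
#' @export
mean_depth_by_contig <- function(track) {
  track[, list(mean_depth = sum(depth * (end - start)) / sum(end - start)),
        by = contig_id]
}

# Aggregate PAF records between each unordered contig pair.  Fragmented
# alignments between the same two contigs are merged: identity is
# sum(matches)/sum(block length) over all blocks, coverage is the merged
# aligned span divided by contig length, taken on each side, and the pair
# coverage is the minimum of the two sides (a short contig contained in a
# long one must qualify on the long side too).
pair_alignment_stats <- function(paf, contig_lengths) {
  paf <- paf[qname != tname]
  if (!nrow(paf)) {
    return(data.table::data.table(
      contig_a = character(), contig_b = character(), coverage = numeric(),
      identity = numeric(), n_matches = numeric()))
  }
  p <- data.table::copy(paf)
  p[, `:=`(contig_a = pmin(qname, tname), contig_b = pmax(qname, tname))]
  span <- function(s, e) {
    o <- order(s); s <- s[o]; e <- cummax(e[o])
    grp <- cumsum(c(TRUE, s[-1] > e[-length(e)]))
    sum(tapply(e, grp, max) - tapply(s, grp, min))
  }
  p[, {
    # per-pair spans on each member, using whichever side the member appears
    a_s <- c(qstart[qname == contig_a], tstart[tname == contig_a])
    a_e <- c(qend[qname == contig_a], tend[tname == contig_a])
    b_s <- c(qstart[qname == contig_b], tstart[tname == contig_b])
    b_e <- c(qend[qname == contig_b], tend[tname == contig_b])
    cov_a <- span(a_s, a_e) / contig_lengths[[contig_a]]
    cov_b <- span(b_s, b_e) / contig_lengths[[contig_b]]
    list(coverage = min(cov_a, cov_b),
         identity = sum(n_matches) / sum(block_len),
         n_matches = sum(n_matches))
  }, by = list(contig_a, contig_b)]
}

#' Reciprocal best hits from all-vs-all contig self-alignment
#'
#' Alignment blocks between the same two contigs are aggregated
#' (coverage = merged aligned span / contig length, minimum over the two
#' members; identity = total matches / total block length), pairs failing
#' either threshold are discarded, each contig's best hit is the qualifying
#' pair maximizing total matches, and a pair is reported iff the two members
#' are each other's best hit.  A tie for best hit disqualifies the contig
#' (conservative reading of "reciprocal best").
#'
#' @param paf PAF `data.table` from all-vs-all self-alignment (self-hits with
#'   `qname == tname` are ignored).
#' @param contig_lengths Named vector of contig lengths.
#' @param min_coverage,min_identity Retention thresholds (default 0.7 both).
#' @return `data.table(contig_a, contig_b, coverage, identity, n_matches)`
#'   with `contig_a < contig_b`; one row per RBH pair.
#' @export
rbh_pairs <- function(paf, contig_lengths, min_coverage = 0.7,
                      min_identity = 0.7) {
  stats <- pair_alignment_stats(paf, contig_lengths)
  qual <- stats[coverage >= min_coverage & identity >= min_identity]
  if (!nrow(qual)) return(qual)
  long <- data.table::rbindlist(list(
    qual[, list(contig = contig_a, other = contig_b, n_matches)],
    qual[, list(contig = contig_b, other = contig_a, n_matches)]))
  best <- long[, {
    mx <- max(n_matches)
    hits <- other[n_matches == mx]
    list(best = if (length(hits) == 1L) hits else NA_character_)
  }, by = contig]
  bmap <- setNames(best$best, best$contig)
  qual[!is.na(bmap[contig_a]) & !is.na(bmap[contig_b]) &
       bmap[contig_a] == contig_b & bmap[contig_b] == contig_a]
}

#' Depth thresholds for zygosity classification
#'
#' Returns the heterozygous depth window `[het_low, het_high]` and the
#' homozygous upper bound `hom_high`, scaled linearly in the individual's
#' sequencing depth from the 80x calibration at which the fixed windows are
#' 10--50x (heterozygous) and >50--100x (homozygous).
#'
#' @param parent_mean_depth The parent's mean (diploid) sequencing depth.
#' @return List with `het_low`, `het_high`, `hom_high`.
#' @export
default_thresholds <- function(parent_mean_depth) {
  if (!is.numeric(parent_mean_depth) || parent_mean_depth <= 0)
    stop("parent_mean_depth must be positive")
  f <- parent_mean_depth / 80
  list(het_low = 10 * f, het_high = 50 * f, hom_high = 100 * f)
}

#' Classify contigs into zygosity categories
#'
#' Assembler bubble contigs keep category `bubble`.  Non-bubble contigs with
#' mean depth in `[het_low, het_high]` are candidate heterozygous; those in
#' `(het_high, hom_high]` candidate homozygous; others uncertain.  Candidate
#' heterozygous contigs that form an RBH pair with another candidate
#' heterozygous contig become `bubble_like` (mutually paired); candidate
#' homozygous contigs with *any* qualifying RBH to any contig are demoted to
#' `uncertain`, and only RBH-free candidates become `true_non_bubble`.
#' Everything else is `uncertain`.
#'
#' @param contigs Contig `data.table` (see [read_contig_table()]).
#' @param mean_depths `data.table(contig_id, mean_depth)` for the parent that
#'   owns the assembly.
#' @param rbh RBH pairs from [rbh_pairs()] computed over the full assembly.
#' @param thresholds List from [default_thresholds()].
#' @return `data.table(contig_id, category, mean_depth, rbh_partner,
#'   rbh_coverage, rbh_identity)`; `category` is one of `bubble`,
#'   `bubble_like`, `true_non_bubble`, `uncertain`.
#' @export
classify_contigs <- function(contigs, mean_depths, rbh, thresholds) {
  z <- merge(contigs[, list(contig_id, assembler_class, partner_id)],
             mean_depths, by = "contig_id", all.x = TRUE)
  if (anyNA(z$mean_depth))
    stop("contig(s) missing from depth table: ",
         paste(head(z[is.na(mean_depth), contig_id], 5), collapse = ", "))
  long <- if (nrow(rbh)) data.table::rbindlist(list(
    rbh[, list(contig_id = contig_a, rbh_partner = contig_b,
               rbh_coverage = coverage, rbh_identity = identity)],
    rbh[, list(contig_id = contig_b, rbh_partner = contig_a,
               rbh_coverage = coverage, rbh_identity = identity)]))
  else data.table::data.table(contig_id = character(),
                              rbh_partner = character(),
                              rbh_coverage = numeric(),
                              rbh_identity = numeric())
  z <- merge(z, long, by = "contig_id", all.x = TRUE)
  z[, category := "uncertain"]
  z[assembler_class != "non_bubble", category := "bubble"]
  nb <- z$assembler_class == "non_bubble"
  cand_het <- nb & z$mean_depth >= thresholds$het_low &
    z$mean_depth <= thresholds$het_high
  cand_hom <- nb & z$mean_depth > thresholds$het_high &
    z$mean_depth <= thresholds$hom_high
  het_set <- z$contig_id[cand_het]
  z[cand_het & !is.na(rbh_partner) & rbh_partner %in% het_set,
    category := "bubble_like"]
  # bubble_like must be mutual: partner itself classified bubble_like
  bl <- z[category == "bubble_like", contig_id]
  z[category == "bubble_like" & !(rbh_partner %in% bl),
    category := "uncertain"]
  z[cand_hom & is.na(rbh_partner), category := "true_non_bubble"]
  z[, list(contig_id, category, mean_depth, rbh_partner,
           rbh_coverage, rbh_identity)]
}

#' Positive-control fraction for bubble-like classification
#'
#' Re-runs assembler bubble contigs through the depth + RBH machinery as if
#' they were unlabeled non-bubble contigs and reports the fraction re-labeled
#' heterozygous (`bubble_like`).  Assembler bubbles are trusted heterozygous
#' sequence, so this fraction estimates the sensitivity of the bubble-like
#' classification.
#'
#' @inheritParams classify_contigs
#' @return Fraction in \[0, 1\] (NA if there are no bubble contigs).
#' @export
positive_control_fraction <- function(contigs, mean_depths, rbh, thresholds) {
  stripped <- data.table::copy(contigs)
  stripped[, `:=`(assembler_class = "non_bubble", partner_id = NA_character_)]
  res <- classify_contigs(stripped, mean_depths, rbh, thresholds)
  orig_bubble <- contigs[assembler_class != "non_bubble", contig_id]
  if (!length(orig_bubble)) return(NA_real_)
  mean(res[contig_id %in% orig_bubble, category] == "bubble_like")
}
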