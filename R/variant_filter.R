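# Candidate DNM and PZM filtering.
#
# Works on flattened trio observation tables: one row per site x caller with
# the focal offspring's and both parents' genotype fields side by side.
# Because variants are called against the parental contigs themselves, the
# parental origin of a retained mutation is simply the parent of origin of
# the contig it sits on.

#' Flatten a trio VCF into an observation table
#'
#' @param vcf List from [read_trio_vcf()].
#' @param offspring,mother,father Sample IDs of the trio roles.
#' @return `data.table` with one row per site: `contig_id, pos, ref, alt,
#'   qual, caller, is_indel`, plus `gt_off, dp_off, ad_off, gt_mo, dp_mo,
#'   ad_mo, gt_fa, dp_fa, ad_fa`.
#' @export
trio_observations <- function(vcf, offspring, mother, father) {
  g <- vcf$geno
  pick <- function(sample, suffix) {
    x <- g[sample_id == sample, list(site_id, gt, dp, ad)]
    data.table::setnames(x, c("gt", "dp", "ad"),
                         paste0(c("gt", "dp", "ad"), "_", suffix))
    x
  }
  out <- data.table::copy(vcf$sites)
  for (p in list(list(offspring, "off"), list(mother, "mo"),
                 list(father, "fa"))) {
    out <- merge(out, pick(p[[1]], p[[2]]), by = "site_id", all.x = TRUE)
  }
  out
}

#' Merge observations from the two variant callers
#'
#' On contigs with high sequence similarity between the parents only the
#' haplotype-caller calls are kept; elsewhere the union of both callers is
#' used, with duplicate sites retained once per caller tag.
#'
#' @param pileup_calls,haplotype_calls Flat observation tables (see
#'   [trio_observations()]) tagged `caller_pileup` / `caller_haplotype`.
#' @param high_similarity_contigs Character vector of contig IDs.
#' @return Combined observation table.
#' @export
merge_caller_calls <- function(pileup_calls, haplotype_calls,
                               high_similarity_contigs = character(0)) {
  keep_pileup <- pileup_calls[!(contig_id %in% high_similarity_contigs)]
  data.table::rbindlist(list(keep_pileup, haplotype_calls), use.names = TRUE)
}

# genotype helpers ----------------------------------------------------------

# vectorized diploid genotype parsing ("a/b" or "a|b"); anything else -> NA
parse_gt_pair <- function(gt) {
  m <- regmatches(gt, regexec("^([0-9]+)[/|]([0-9]+)$", gt))
  a <- vapply(m, function(x) if (length(x) == 3L) x[2] else NA_character_,
              character(1))
  b <- vapply(m, function(x) if (length(x) == 3L) x[3] else NA_character_,
              character(1))
  list(a = as.integer(a), b = as.integer(b))
}

gt_is_hom_alt <- function(gt) {
  p <- parse_gt_pair(gt)
  !is.na(p$a) & !is.na(p$b) & p$a == p$b & p$a > 0L
}

gt_is_het <- function(gt) {
  p <- parse_gt_pair(gt)
  !is.na(p$a) & !is.na(p$b) & p$a != p$b
}

gt_alt_index <- function(gt) {
  # the (single) non-reference allele index carried, else NA
  p <- parse_gt_pair(gt)
  out <- rep(NA_integer_, length(gt))
  both <- !is.na(p$a) & !is.na(p$b)
  one_alt <- both & ((p$a == p$b & p$a > 0L) |
                       (p$a == 0L & p$b > 0L) | (p$b == 0L & p$a > 0L))
  out[one_alt] <- pmax(p$a[one_alt], p$b[one_alt])
  mixed <- both & p$a > 0L & p$b > 0L & p$a != p$b
  out[mixed] <- NA_integer_
  out
}

nth_alt <- function(alt, idx) {
  # idx is the VCF allele index (1 = first ALT)
  alts <- strsplit(alt, ",", fixed = TRUE)
  vapply(seq_along(alts), function(i) {
    if (is.na(idx[i]) || idx[i] < 1L || idx[i] > length(alts[[i]]))
      NA_character_
    else alts[[i]][idx[i]]
  }, character(1))
}

n_alt_alleles_observed <- function(ad) {
  # number of alternative alleles with at least one supporting read
  vapply(strsplit(ad, ",", fixed = TRUE), function(x) {
    v <- suppressWarnings(as.numeric(x))
    if (anyNA(v) || length(v) < 2L) return(NA_integer_)
    sum(v[-1] >= 1)
  }, integer(1))
}

ad_for_allele <- function(ad, idx) {
  # read depth of allele index idx (0 = ref)
  vapply(seq_along(ad), function(i) {
    v <- suppressWarnings(as.numeric(strsplit(ad[i], ",", fixed = TRUE)[[1]]))
    j <- idx[i] + 1L
    if (anyNA(idx[i]) || anyNA(v) || j < 1L || j > length(v)) NA_real_
    else v[j]
  }, numeric(1))
}

near_indel <- function(contig, pos, indel_positions, flank) {
  if (is.null(indel_positions) || !nrow(indel_positions))
    return(rep(FALSE, length(pos)))
  dt <- data.table::data.table(contig_id = contig, lo = pos - flank,
                               hi = pos + flank, i = seq_along(pos))
  m <- indel_positions[dt, on = list(contig_id, pos >= lo, pos <= hi),
                       nomatch = 0L, allow.cartesian = TRUE]
  res <- rep(FALSE, length(pos))
  res[unique(m$i)] <- TRUE
  res
}

in_mask <- function(contig, pos, mask) {
  if (is.null(mask) || !nrow(mask)) return(rep(FALSE, length(pos)))
  dt <- data.table::data.table(contig_id = contig, pos = pos)
  !is.na(mask[dt, on = c("contig_id", "pos"), which = TRUE])
}

#' Extract INDEL positions from an observation table
#' @param obs Flat observation table.
#' @return `data.table(contig_id, pos)` of INDEL sites.
#' @export
indel_positions <- function(obs) {
  unique(obs[is_indel == TRUE, list(contig_id, pos)])
}

#' Candidate de novo mutation filter
#'
#' Retains a site iff all of: (i) it lies inside the offspring's callable
#' set; (ii) the offspring is homozygous for a single alternative allele with
#' `DP > offspring_dp_min` and the contig's parent of origin has
#' `DP > parent_dp_min` there; (iii) at most `max_parent_alt` alternative
#' alleles are observed (AD >= 1) in each parent; (iv) `QUAL >= qual_min`,
#' applied to pileup-caller records only; (v) no INDEL within
#' `indel_flank` bp (exclusive: distance > flank passes); (vi) the site is
#' not in the gene-conversion mask; (vii) no other offspring carries a
#' heterozygous genotype at the same contig position.  Sites retained by
#' several callers are reported once.  Contigs accumulating more than
#' `contig_cap` candidates in one offspring are sent to a review set instead
#' of the retained set (a stand-in for manual inspection of clustered calls).
#'
#' @param obs Flat (merged) observation table for the trio.
#' @param cs `callable_set` of the offspring.
#' @param contigs Contig table.
#' @param offspring Offspring ID (stored in the records).
#' @param cohort_geno `data.table(contig_id, pos, sample_id, gt)` of all
#'   offspring genotypes at candidate sites (criterion vii).
#' @param indels `data.table(contig_id, pos)` of INDEL sites.
#' @param conversion_mask `data.table(contig_id, pos)` or NULL.
#' @param qual_min,offspring_dp_min,parent_dp_min,indel_flank,max_parent_alt,
#'   contig_cap Filter thresholds (defaults 220, 10, 5, 20, 2, 2).
#' @return List with `dnms` (retained records: `offspring_id, contig_id,
#'   pos, ref_base, alt_base, origin, caller`), `review` (capped clusters)
#'   and `rejects` (`contig_id, pos, reason` -- first failing criterion).
#' @export
dnm_filter <- function(obs, cs, contigs, offspring, cohort_geno = NULL,
                       indels = NULL, conversion_mask = NULL,
                       qual_min = 220, offspring_dp_min = 10,
                       parent_dp_min = 5, indel_flank = 20,
                       max_parent_alt = 2, contig_cap = 2) {
  unknown <- setdiff(obs$contig_id, contigs$contig_id)
  if (length(unknown))
    stop("observation on contig absent from the contig table: ",
         paste(head(unknown, 5), collapse = ", "))
  o <- data.table::copy(obs)
  org <- setNames(contigs$parent_of_origin, contigs$contig_id)
  o[, reject := NA_character_]
  snv <- nchar(o$ref) == 1L
  o[!snv & is.na(reject), reject := "not_snv"]
  o[is_indel == TRUE & is.na(reject), reject := "not_snv"]
  o[is.na(reject) & !in_callable(cs, contig_id, pos), reject := "callable"]
  hom <- gt_is_hom_alt(o$gt_off)
  o[is.na(reject) & !hom, reject := "genotype"]
  o[is.na(reject) & !(dp_off > offspring_dp_min), reject := "offspring_depth"]
  pdp <- ifelse(org[o$contig_id] == "maternal", o$dp_mo, o$dp_fa)
  o[is.na(reject) & !(pdp > parent_dp_min & !is.na(pdp)),
    reject := "parent_depth"]
  nam <- n_alt_alleles_observed(o$ad_mo)
  naf <- n_alt_alleles_observed(o$ad_fa)
  o[is.na(reject) & (is.na(nam) | is.na(naf) | nam > max_parent_alt |
                       naf > max_parent_alt), reject := "parent_alt_alleles"]
  o[is.na(reject) & caller == "caller_pileup" &
      (is.na(qual) | qual < qual_min), reject := "qual"]
  o[is.na(reject) & near_indel(contig_id, pos, indels, indel_flank),
    reject := "indel_proximity"]
  o[is.na(reject) & in_mask(contig_id, pos, conversion_mask),
    reject := "conversion_mask"]
  # allele actually carried
  idx <- gt_alt_index(o$gt_off)
  ab <- nth_alt(o$alt, idx)
  o[, alt_base := ab]
  o[is.na(reject) & (is.na(alt_base) | nchar(alt_base) != 1L),
    reject := "not_snv"]
  # (vii) heterozygous carriers among the other offspring (restricted to
  # the candidate sites first; the cohort table can be large)
  if (!is.null(cohort_geno) && nrow(cohort_geno)) {
    cand <- unique(o[is.na(reject), list(contig_id, pos)])
    cg <- cohort_geno[cand, on = c("contig_id", "pos"), nomatch = 0L]
    hets <- cg[sample_id != offspring][gt_is_het(gt),
                                       list(contig_id, pos)]
    o[is.na(reject) & in_mask(contig_id, pos, unique(hets)),
      reject := "sibling_het"]
  }
  pass <- o[is.na(reject)]
  rejects <- o[!is.na(reject), list(contig_id, pos, caller, reason = reject)]
  dnms <- unique(pass[, list(offspring_id = offspring, contig_id, pos,
                             ref_base = ref, alt_base)],
                 by = c("contig_id", "pos", "alt_base"))
  dnms[, origin := ifelse(contig_id %in% cs$unphased_contigs, "unphased",
                          org[contig_id])]
  # clustered-candidate cap (manual-review proxy)
  cnt <- dnms[, .N, by = contig_id]
  crowded <- cnt[N > contig_cap, contig_id]
  review <- dnms[contig_id %in% crowded]
  dnms <- dnms[!(contig_id %in% crowded)]
  list(dnms = dnms[], review = review[], rejects = rejects[])
}

#' Group sibling-shared DNMs
#'
#' Records identical in (contig, position, alternative allele) across two or
#' more offspring receive a common `shared_group_id`; each sharing offspring
#' keeps its own record (shared DNMs count once per carrier).
#'
#' @param dnms Pooled DNM records from all offspring.
#' @return The records with a `shared_group_id` column (NA when unique).
#' @export
group_shared_dnms <- function(dnms) {
  d <- data.table::copy(dnms)
  if (!nrow(d)) { d[, shared_group_id := character(0)]; return(d[]) }
  d[, group_n := data.table::uniqueN(offspring_id),
    by = list(contig_id, pos, alt_base)]
  d[, shared_group_id := ifelse(group_n >= 2L,
                                paste0("ss", .GRP), NA_character_),
    by = list(contig_id, pos, alt_base)]
  d[group_n < 2L, shared_group_id := NA_character_]
  d[, group_n := NULL]
  d[]
}

#' One-sided proportion test of a VAF against a null fraction
#'
#' `stats::prop.test` with `alternative = "greater"` (chi-square score
#' statistic with continuity correction, one-tailed): the p-value for the
#' variant allele fraction exceeding `null_fraction`.  PZM candidates are
#' retained when `p > 0.05`, i.e. when the VAF is *not* significantly
#' greater than the null.
#'
#' @param alt_depth,total_depth Alternative-allele and total read depths
#'   (vectors allowed).
#' @param null_fraction Null VAF (default 0.25).
#' @return Vector of p-values.
#' @export
vaf_test <- function(alt_depth, total_depth, null_fraction = 0.25) {
  if (any(total_depth <= 0)) stop("total_depth must be positive")
  stopifnot(all(alt_depth >= 0), all(alt_depth <= total_depth))
  vapply(seq_along(alt_depth), function(i) {
    suppressWarnings(
      stats::prop.test(alt_depth[i], total_depth[i], p = null_fraction,
                       alternative = "greater")$p.value)
  }, numeric(1))
}

#' Candidate postzygotic mutation filter
#'
#' The DNM criteria with three changes: unphased regions are excluded
#' entirely; heterozygous offspring genotypes are retained (hom-ALT calls
#' are germline, not mosaic); and no *other* parental or offspring sample
#' may carry more than `max_other_alt_reads` alternative-allele reads at the
#' position.  The VAF denominator spans both inherited alleles: the focal
#' contig's depth plus the depth of the other parent's inherited allelic
#' contig at the same (collinear) position.  Candidates whose VAF is
#' significantly greater than `null_fraction` are dropped.
#'
#' @inheritParams dnm_filter
#' @param counterpart `data.table(contig_id, counterpart_id)`: for each
#'   focal contig, the other parent's allelic contig inherited by this
#'   offspring (NA when unknown -- such records are dropped and counted).
#' @param depth_track Offspring run-length depth table (for counterpart
#'   depth lookup).
#' @param cohort_ad `data.table(contig_id, pos, sample_id, alt_reads)` of
#'   alternative-read counts for every sample in the cohort.
#' @param max_other_alt_reads Carrier threshold for other samples (default 2).
#' @param null_fraction,p_min VAF test parameters (defaults 0.25, 0.05).
#' @return List with `pzms` (records incl. `alt_depth, total_depth, vaf,
#'   p_value_vs_quarter`), `rejects`, and `n_missing_counterpart`.
#' @export
pzm_filter <- function(obs, cs, contigs, offspring, counterpart, depth_track,
                       cohort_ad = NULL, indels = NULL,
                       conversion_mask = NULL, qual_min = 220,
                       offspring_dp_min = 10, parent_dp_min = 5,
                       indel_flank = 20, max_parent_alt = 2,
                       max_other_alt_reads = 2, null_fraction = 0.25,
                       p_min = 0.05) {
  o <- data.table::copy(obs)
  org <- setNames(contigs$parent_of_origin, contigs$contig_id)
  o[, reject := NA_character_]
  o[nchar(ref) != 1L | is_indel == TRUE, reject := "not_snv"]
  o[is.na(reject) & contig_id %in% cs$unphased_contigs, reject := "unphased"]
  o[is.na(reject) & !in_callable(cs, contig_id, pos, include_unphased = FALSE),
    reject := "callable"]
  het <- gt_is_het(o$gt_off)
  o[is.na(reject) & !het, reject := "genotype"]
  o[is.na(reject) & !(dp_off > offspring_dp_min), reject := "offspring_depth"]
  pdp <- ifelse(org[o$contig_id] == "maternal", o$dp_mo, o$dp_fa)
  o[is.na(reject) & !(pdp > parent_dp_min & !is.na(pdp)),
    reject := "parent_depth"]
  nam <- n_alt_alleles_observed(o$ad_mo)
  naf <- n_alt_alleles_observed(o$ad_fa)
  o[is.na(reject) & (is.na(nam) | is.na(naf) | nam > max_parent_alt |
                       naf > max_parent_alt), reject := "parent_alt_alleles"]
  o[is.na(reject) & caller == "caller_pileup" &
      (is.na(qual) | qual < qual_min), reject := "qual"]
  o[is.na(reject) & near_indel(contig_id, pos, indels, indel_flank),
    reject := "indel_proximity"]
  o[is.na(reject) & in_mask(contig_id, pos, conversion_mask),
    reject := "conversion_mask"]
  idx <- gt_alt_index(o$gt_off)
  o[, alt_base := nth_alt(alt, idx)]
  o[is.na(reject) & (is.na(alt_base) | nchar(alt_base) != 1L),
    reject := "not_snv"]
  # no other sample with alt support
  if (!is.null(cohort_ad) && nrow(cohort_ad)) {
    carriers <- cohort_ad[sample_id != offspring &
                            alt_reads > max_other_alt_reads,
                          list(contig_id, pos)]
    o[is.na(reject) & in_mask(contig_id, pos, unique(carriers)),
      reject := "other_carrier"]
  }
  pass <- o[is.na(reject)]
  pass <- unique(pass, by = c("contig_id", "pos", "alt_base"))
  n_missing <- 0L
  if (nrow(pass)) {
    cp <- setNames(counterpart$counterpart_id, counterpart$contig_id)
    pass[, other := unname(cp[contig_id])]
    n_missing <- sum(is.na(pass$other))
    if (n_missing)
      warning(n_missing,
              " PZM candidate(s) dropped: no allelic counterpart for VAF")
    pass <- pass[!is.na(other)]
  }
  if (nrow(pass)) {
    oth_depth <- vapply(seq_len(nrow(pass)), function(i) {
      tr <- depth_track[contig_id == pass$other[i] &
                          start <= pass$pos[i] & end > pass$pos[i]]
      if (nrow(tr)) tr$depth[1] else 0
    }, numeric(1))
    alt_dp <- ad_for_allele(pass$ad_off, gt_alt_index(pass$gt_off))
    pass[, `:=`(alt_depth = alt_dp,
                total_depth = dp_off + oth_depth)]
    pass <- pass[!is.na(alt_depth) & total_depth > 0]
    pass[, vaf := alt_depth / total_depth]
    pass[, p_value_vs_quarter := vaf_test(alt_depth, total_depth,
                                          null_fraction)]
    keep_vaf <- pass$p_value_vs_quarter > p_min
    vaf_rej <- pass[!keep_vaf, list(contig_id, pos,
                                    caller, reason = "vaf_above_null")]
    pass <- pass[keep_vaf]
  } else {
    vaf_rej <- data.table::data.table(contig_id = character(),
                                      pos = integer(), caller = character(),
                                      reason = character())
  }
  pzms <- if (nrow(pass)) {
    pass[, list(offspring_id = offspring, contig_id, pos,
                ref_base = ref, alt_base,
                origin = unname(org[contig_id]),
                alt_depth, total_depth, vaf, p_value_vs_quarter)]
  } else {
    data.table::data.table(
      offspring_id = character(), contig_id = character(), pos = integer(),
      ref_base = character(), alt_base = character(), origin = character(),
      alt_depth = numeric(), total_depth = numeric(), vaf = numeric(),
      p_value_vs_quarter = numeric())
  }
  rejects <- data.table::rbindlist(list(
    o[!is.na(reject), list(contig_id, pos, caller, reason = reject)],
    vaf_rej))
  list(pzms = pzms[], rejects = rejects[], n_missing_counterpart = n_missing)
}
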