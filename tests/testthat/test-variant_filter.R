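# A hand-built two-contig trio world for exercising each retention
# criterion in isolation.

vf_contigs <- data.table::data.table(
  contig_id = c("M", "P"), parent_of_origin = c("maternal", "paternal"),
  assembler_class = "non_bubble", partner_id = NA_character_,
  length_bp = 5000L)

vf_callable <- structure(list(
  offspring_id = "kid",
  phased_intervals = data.table::data.table(
    contig_id = c("M", "P"), start = 100L, end = 4900L),
  unphased_contigs = character(0),
  phased_bp = 9600, unphased_bp_contribution = 0, total_bp = 9600,
  phased_bp_by_parent = c(maternal = 4800, paternal = 4800),
  depth_mean = 40), class = "callable_set")

vf_obs <- function(pos = 2000L, contig = "M", qual = 250,
                   caller = "caller_pileup", gt_off = "1/1", dp_off = 40,
                   ad_off = "0,40", dp_mo = 40, ad_mo = "40,0",
                   dp_fa = 0, ad_fa = "0,0", ref = "A", alt = "G",
                   is_indel = FALSE) {
  data.table::data.table(
    site_id = 1L, contig_id = contig, pos = pos, ref = ref, alt = alt,
    qual = qual, caller = caller, is_indel = is_indel,
    gt_off = gt_off, dp_off = dp_off, ad_off = ad_off,
    gt_mo = "0/0", dp_mo = dp_mo, ad_mo = ad_mo,
    gt_fa = "0/0", dp_fa = dp_fa, ad_fa = ad_fa)
}

run_dnm <- function(obs, ...) {
  dnm_filter(obs, vf_callable, vf_contigs, "kid", ...)
}

test_that("a clean site passing all seven criteria is retained", {
  res <- run_dnm(vf_obs())
  expect_equal(nrow(res$dnms), 1)
  expect_equal(res$dnms$origin, "maternal")
  expect_equal(res$dnms$alt_base, "G")
  expect_equal(nrow(res$rejects), 0)
})

test_that("each criterion rejects with the first failing reason", {
  reason_of <- function(obs, ...) run_dnm(obs, ...)$rejects$reason
  expect_equal(reason_of(vf_obs(pos = 50L)), "callable")
  expect_equal(reason_of(vf_obs(gt_off = "0/1")), "genotype")
  expect_equal(reason_of(vf_obs(dp_off = 10)), "offspring_depth")
  expect_equal(reason_of(vf_obs(dp_mo = 5)), "parent_depth")
  expect_equal(reason_of(vf_obs(ad_mo = "30,1,1,1", alt = "G,C,T")),
               "parent_alt_alleles")
  expect_equal(reason_of(vf_obs(qual = 200)), "qual")
  expect_equal(reason_of(vf_obs(is_indel = TRUE)), "not_snv")
  msk <- data.table::data.table(contig_id = "M", pos = 2000L)
  expect_equal(reason_of(vf_obs(), conversion_mask = msk),
               "conversion_mask")
})

test_that("the QUAL threshold is scoped to the pileup caller", {
  expect_equal(nrow(run_dnm(vf_obs(qual = 200))$dnms), 0)
  expect_equal(nrow(run_dnm(vf_obs(qual = 200,
                                   caller = "caller_haplotype"))$dnms), 1)
})

test_that("the INDEL flank is exclusive at exactly 20 bp", {
  ind <- function(d) data.table::data.table(contig_id = "M",
                                            pos = 2000L + d)
  expect_equal(nrow(run_dnm(vf_obs(), indels = ind(15))$dnms), 0)
  expect_equal(nrow(run_dnm(vf_obs(), indels = ind(20))$dnms), 0)
  expect_equal(nrow(run_dnm(vf_obs(), indels = ind(21))$dnms), 1)
  expect_equal(nrow(run_dnm(vf_obs(), indels = ind(-21))$dnms), 1)
})

test_that("a heterozygous genotype in any other offspring rejects the site", {
  cg <- data.table::data.table(contig_id = "M", pos = 2000L,
                               sample_id = c("kid", "sib1", "sib2"),
                               gt = c("1/1", "0/0", "0/1"))
  expect_equal(run_dnm(vf_obs(), cohort_geno = cg)$rejects$reason,
               "sibling_het")
  # a hom-alt sibling (shared DNM) does not reject
  cg2 <- data.table::copy(cg)[3, gt := "1/1"]
  expect_equal(nrow(run_dnm(vf_obs(), cohort_geno = cg2)$dnms), 1)
})

test_that("filters are order-independent (pure conjunction)", {
  # a site failing several criteria is rejected regardless of which table
  # rows surround it, and passing sites are unaffected by rejected ones
  bad <- vf_obs(pos = 2500L, qual = 100, gt_off = "0/1")
  good <- vf_obs()
  both <- rbind(good, bad)
  r1 <- run_dnm(both)
  r2 <- run_dnm(both[c(2, 1)])
  expect_equal(r1$dnms$pos, 2000L)
  expect_equal(data.table::setorder(r1$dnms, pos),
               data.table::setorder(r2$dnms, pos))
})

test_that("clustered candidates beyond the per-contig cap go to review", {
  obs <- data.table::rbindlist(lapply(c(1000L, 2000L, 3000L), function(p)
    vf_obs(pos = p)))
  res <- run_dnm(obs, contig_cap = 2)
  expect_equal(nrow(res$dnms), 0)
  expect_equal(nrow(res$review), 3)
  res2 <- run_dnm(obs, contig_cap = Inf)
  expect_equal(nrow(res2$dnms), 3)
})

test_that("duplicate caller observations yield one DNM record", {
  obs <- rbind(vf_obs(), vf_obs(caller = "caller_haplotype"))
  expect_equal(nrow(run_dnm(obs)$dnms), 1)
})

test_that("caller merging keeps only haplotype calls on similar contigs", {
  pu <- rbind(vf_obs(), vf_obs(contig = "P"))
  hc <- vf_obs(caller = "caller_haplotype")
  merged <- merge_caller_calls(pu, hc, high_similarity_contigs = "M")
  expect_equal(nrow(merged), 2)
  expect_equal(merged[contig_id == "M", caller], "caller_haplotype")
  # no similar contigs: union with both tags kept
  merged2 <- merge_caller_calls(pu, hc, character(0))
  expect_equal(nrow(merged2), 3)
  expect_equal(sort(unique(merged2$caller)),
               c("caller_haplotype", "caller_pileup"))
})

test_that("sibling-shared DNMs are grouped and counted per carrier", {
  d <- data.table::data.table(
    offspring_id = c("o1", "o2", "o3", "o1"),
    contig_id = c("M", "M", "M", "P"),
    pos = c(10L, 10L, 10L, 99L), ref_base = "A",
    alt_base = c("G", "G", "G", "T"), origin = "maternal")
  g <- group_shared_dnms(d)
  expect_equal(sum(!is.na(g$shared_group_id)), 3)
  expect_equal(length(unique(g[!is.na(shared_group_id), shared_group_id])),
               1)
  expect_true(is.na(g[contig_id == "P", shared_group_id]))
  all_unique <- group_shared_dnms(d[c(1, 4)])
  expect_true(all(is.na(all_unique$shared_group_id)))
})

test_that("the VAF test retains fractions at or below 0.25", {
  expect_gt(vaf_test(25, 100), 0.4)           # VAF exactly at the null
  expect_lt(vaf_test(120, 200), 1e-4)         # VAF 0.6, clearly rejected
  expect_gt(vaf_test(10, 200), 0.999)         # VAF 0.05
  expect_error(vaf_test(5, 0), "positive")
  # decisions agree with the exact binomial oracle across realistic depths
  for (n in c(40, 80, 120)) {
    x <- 0:n
    p_imp <- vaf_test(x, rep(n, n + 1))
    p_bin <- vapply(x, function(k)
      binom.test(k, n, 0.25, alternative = "greater")$p.value, numeric(1))
    expect_equal(p_imp > 0.05, p_bin > 0.05)
  }
})

test_that("PZM filtering keeps moderate-VAF heterozygous candidates", {
  counterpart <- data.table::data.table(contig_id = c("M", "P"),
                                        counterpart_id = c("P", "M"))
  track <- data.table::data.table(contig_id = c("M", "P"), start = 0L,
                                  end = 5000L, depth = 40)
  run_pzm <- function(obs, ...) {
    pzm_filter(obs, vf_callable, vf_contigs, "kid", counterpart, track, ...)
  }
  cand <- vf_obs(gt_off = "0/1", ad_off = "28,12")     # VAF 12/80 = 0.15
  res <- run_pzm(cand)
  expect_equal(nrow(res$pzms), 1)
  expect_equal(res$pzms$vaf, 12 / 80)
  expect_equal(res$pzms$total_depth, 80)
  expect_gt(res$pzms$p_value_vs_quarter, 0.05)
  # hom-alt calls are germline, not mosaic
  expect_equal(nrow(run_pzm(vf_obs())$pzms), 0)
  # a VAF significantly above 0.25 is dropped
  hi <- vf_obs(gt_off = "0/1", dp_off = 60, ad_off = "20,40")
  res_hi <- run_pzm(hi)
  expect_equal(nrow(res_hi$pzms), 0)
  expect_true("vaf_above_null" %in% res_hi$rejects$reason)
  # another sample with >2 alt reads kills the candidate
  ad_tab <- data.table::data.table(contig_id = "M", pos = 2000L,
                                   sample_id = c("kid", "sib1"),
                                   alt_reads = c(12L, 3L))
  expect_equal(nrow(run_pzm(cand, cohort_ad = ad_tab)$pzms), 0)
  # unphased contigs are excluded entirely
  cs2 <- vf_callable
  cs2$unphased_contigs <- "M"
  cs2$phased_intervals <- cs2$phased_intervals[contig_id == "P"]
  res_un <- pzm_filter(cand, cs2, vf_contigs, "kid", counterpart, track)
  expect_equal(nrow(res_un$pzms), 0)
  # a missing counterpart drops the record with a warning
  cp_na <- data.table::data.table(contig_id = c("M", "P"),
                                  counterpart_id = NA_character_)
  expect_warning(
    res_na <- pzm_filter(cand, vf_callable, vf_contigs, "kid", cp_na,
                         track),
    "counterpart")
  expect_equal(nrow(res_na$pzms), 0)
  expect_equal(res_na$n_missing_counterpart, 1L)
})

test_that("retained DNMs sit inside the callable set and avoid sibling hets", {
  fxd <- fx_small_detect()
  fx <- fx_small()
  d <- fxd$det$dnms
  expect_gt(nrow(d), 0)
  for (off in unique(d$offspring_id)) {
    sub <- d[offspring_id == off]
    expect_true(all(in_callable(fx$state$callable[[off]],
                                sub$contig_id, sub$pos)))
  }
  # direct re-scan of the cohort genotypes
  cg <- fxd$bundle$cohort_geno
  hets <- cg[gt_is_het(gt)]
  viol <- d[hets, on = c("contig_id", "pos"), nomatch = 0L][
    offspring_id != sample_id]
  expect_equal(nrow(viol), 0)
})

test_that("retained PZM VAFs never reject against 0.25 under the exact test", {
  fxd <- fx_small_detect()
  z <- fxd$det$pzms
  expect_gt(nrow(z), 0)
  p_exact <- vapply(seq_len(nrow(z)), function(i)
    binom.test(z$alt_depth[i], z$total_depth[i], 0.25,
               alternative = "greater")$p.value, numeric(1))
  expect_true(all(p_exact > 0.05))
})
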