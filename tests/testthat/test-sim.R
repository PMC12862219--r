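test_that("the generator is fully deterministic under a fixed seed", {
  cfg <- sim_config(genome_length = 3e5, n_no_variant_intervals = 3,
                    no_variant_length = 8000, n_offspring = 2, seed = 33)
  s1 <- simulate_pedigree(cfg)
  s2 <- simulate_pedigree(cfg)
  expect_identical(s1$reference, s2$reference)
  expect_identical(s1$contigs, s2$contigs)
  expect_identical(s1$bins, s2$bins)
  expect_identical(s1$transmission, s2$transmission)
  expect_identical(s1$cross_paf, s2$cross_paf)
})

test_that("SNP placement respects weights and no-variant intervals", {
  cfg <- sim_config(genome_length = 1e6, seed = 5,
                    n_no_variant_intervals = 0, no_variant_length = 0)
  set.seed(5)
  nv <- data.table::data.table(start = c(100000L, 500000L),
                               end = c(140000L, 540000L))
  res <- simulate_snp_positions(cfg, nv)
  # nothing inside the excluded intervals
  expect_false(any((res$positions >= 100000 & res$positions < 140000) |
                     (res$positions >= 500000 & res$positions < 540000)))
  expect_false(anyDuplicated(res$positions) > 0)
  # zero-weight windows never receive SNPs
  w <- rep(1, 10); w[4] <- 0
  set.seed(6)
  res2 <- simulate_snp_positions(cfg, NULL, weights = w)
  expect_equal(res2$window_counts$n_snps[4], 0L)
  # total close to heterozygosity * length
  expect_equal(length(res$positions), 0.03 * 1e6, tolerance = 0.05)
})

test_that("per-window counts behave like independent Poisson draws", {
  cfg <- sim_config(genome_length = 1e6, window_size = 2e4, seed = 1,
                    n_no_variant_intervals = 0, no_variant_length = 0)
  lam <- 0.03 * 1e6 / 50
  pass <- 0
  n_seeds <- 60
  for (s in seq_len(n_seeds)) {
    set.seed(s)
    res <- simulate_snp_positions(cfg, NULL)
    x <- res$window_counts$n_snps
    # chi-square GOF against the Poisson expectation
    brk <- c(-Inf, qpois(seq(0.1, 0.9, by = 0.1), lam), Inf)
    obs <- table(cut(x, brk))
    pr <- diff(ppois(c(-Inf, qpois(seq(0.1, 0.9, by = 0.1), lam), Inf),
                     lam))
    p <- suppressWarnings(chisq.test(as.vector(obs), p = pr,
                                     rescale.p = TRUE)$p.value)
    if (p > 0.01) pass <- pass + 1
  }
  expect_gte(pass / n_seeds, 0.9)
})

test_that("parental haplotypes differ exactly at the recorded het SNPs", {
  cfg <- sim_config(genome_length = 3e5, n_no_variant_intervals = 2,
                    no_variant_length = 5000, n_offspring = 1, seed = 12)
  sim <- simulate_pedigree(cfg)
  ctg <- sim$contigs[parent_of_origin == "maternal" &
                       truth_zygosity == "heterozygous" &
                       haplotype == 1L][1:10]
  segs <- sim$segments[match(ctg$segment_id, segment_id)]
  het <- sim$parents$maternal$het_snps
  for (i in seq_len(nrow(ctg))) {
    a <- sim$sequences[[ctg$contig_id[i]]]
    b <- sim$sequences[[sub("_h1$", "_h2", ctg$contig_id[i])]]
    diffs <- which(charToRaw(a) != charToRaw(b))
    truth_pos <- het[pos >= segs$start[i] & pos < segs$end[i], pos] -
      segs$start[i] + 1L
    expect_setequal(diffs, truth_pos)
  }
  # zero heterozygosity leaves haplotypes identical to the reference
  p0 <- simulate_parent(strrep("ACGT", 100), cfg, integer(0))
  expect_equal(nrow(p0$het_snps), 0)
})

test_that("observed heterozygosity matches the configured rate", {
  cfg <- sim_config(genome_length = 5e5, n_no_variant_intervals = 0,
                    no_variant_length = 0, n_offspring = 1, seed = 13)
  sim <- simulate_pedigree(cfg)
  for (p in c("maternal", "paternal")) {
    n_het <- nrow(sim$parents[[p]]$het_snps)
    expect_equal(n_het / cfg$genome_length, 0.03, tolerance = 0.05)
  }
})

test_that("contigization emits bubble pairs, singles, and mislabels", {
  fx <- fx_small()
  ctg <- fx$sim$contigs
  # no-variant segments yield single homozygous contigs
  nv_segs <- fx$sim$segments[fx$sim$no_variant,
                             on = c(start = "start"), nomatch = 0L,
                             segment_id]
  expect_true(all(ctg[segment_id %in% nv_segs, truth_zygosity] ==
                    "homozygous"))
  # heterozygous segments always yield h1/h2 pairs
  het <- ctg[truth_zygosity == "heterozygous"]
  expect_true(all(sort(unique(het$haplotype)) == 1:2))
  # mislabel fraction recovered from emitted labels (pair level)
  pairs_m <- het[parent_of_origin == "maternal" & haplotype == 1]
  frac <- mean(ctg[match(pairs_m$contig_id, contig_id),
                   assembler_class] == "non_bubble")
  expect_equal(frac, fx$cfg$nonbubble_mislabel_fraction, tolerance = 0.25)
  # mislabel 0: assembler classes equal truth
  cfg0 <- sim_config(genome_length = 3e5, nonbubble_mislabel_fraction = 0,
                     n_offspring = 1, n_no_variant_intervals = 2,
                     no_variant_length = 5000, seed = 14)
  sim0 <- simulate_pedigree(cfg0)
  expect_true(all((sim0$contigs$assembler_class == "non_bubble") ==
                    (sim0$contigs$truth_zygosity == "homozygous")))
})

test_that("transmission picks one haplotype per segment with fair odds", {
  cfg <- sim_config(genome_length = 3e5, n_offspring = 40,
                    n_no_variant_intervals = 2, no_variant_length = 5000,
                    seed = 15)
  set.seed(15)
  tr <- transmit(data.table::data.table(segment_id = sprintf("s%02d", 1:50)),
                 sprintf("o%02d", 1:40))
  expect_true(all(tr$inherited_hap %in% 1:2))
  frac1 <- tr[, mean(inherited_hap == 1)]
  expect_equal(frac1, 0.5, tolerance = 0.05)
})

test_that("depth doses reflect inheritance and cross-mapping", {
  cfg0 <- sim_config(genome_length = 3e5, cross_mapping_rate = 0,
                     shared_ancestry_fraction = 0, n_offspring = 2,
                     n_no_variant_intervals = 2, no_variant_length = 5000,
                     seed = 16)
  sim0 <- simulate_pedigree(cfg0)
  truth <- truth_inheritance(sim0)
  d <- sim0$doses
  for (off in sim0$offspring_ids) {
    ni <- truth[offspring_id == off & truth_state == "not_inherited",
                contig_id]
    expect_true(all(d[ni, off] == 0))
    expect_true(all(unlist(sim0$bins[[off]][ni]) == 0))
  }
  # parent doses: 1 per bubble member, 2 for homozygous contigs
  hom <- sim0$contigs[truth_zygosity == "homozygous" &
                        parent_of_origin == "maternal", contig_id]
  het <- sim0$contigs[truth_zygosity == "heterozygous" &
                        parent_of_origin == "maternal", contig_id]
  expect_true(all(d[hom, "mother"] == 2))
  expect_true(all(d[het, "mother"] == 1))
  # realized depth close to dose * depth_mean / 2 at aggregate scale
  m_depth <- mean(unlist(sim0$bins[["mother"]][het]))
  expect_equal(m_depth, cfg0$depth_mean / 2, tolerance = 0.02)
})

test_that("every offspring base is of parental origin except spiked sites", {
  # Mendelian consistency at the dose level: each segment contributes
  # exactly one maternal and one paternal haplotype dose per offspring
  fx <- fx_small()
  truth <- truth_inheritance(fx$sim)
  counts <- merge(truth[truth_state == "inherited"],
                  fx$sim$contigs[, list(contig_id, segment_id,
                                        parent_of_origin)],
                  by = "contig_id")
  per_seg <- counts[, .N, by = list(offspring_id, segment_id,
                                    parent_of_origin)]
  expect_true(all(per_seg$N == 1))
})

test_that("spiked mutations land in callable regions with exact counts", {
  fx <- fx_small()
  set.seed(20)
  spikes <- spike_mutations(fx$sim, fx$state, dnm_per_offspring = 25,
                            pzm_per_offspring = 5, shared_groups = 2,
                            shared_k = 3)
  for (off in fx$sim$offspring_ids) {
    sp <- spikes[offspring_id == off & type == "dnm" &
                   is.na(shared_group)]
    expect_equal(nrow(sp), 25)
    expect_true(all(in_callable(fx$state$callable[[off]], sp$contig_id,
                                sp$pos, include_unphased = FALSE)))
  }
  sh <- spikes[!is.na(shared_group)]
  expect_equal(sh[, data.table::uniqueN(offspring_id), by = shared_group]$V1,
               rep(3L, 2))
  # same (contig, pos, alt) within a group
  expect_equal(sh[, data.table::uniqueN(paste(contig_id, pos, alt)),
                  by = shared_group]$V1, rep(1L, 2))
  # PZM truth VAFs live in the mosaic range
  pz <- spikes[type == "pzm"]
  expect_true(all(pz$true_vaf >= 0.03 & pz$true_vaf <= 0.45))
  # spiked ref bases match the contig sequence
  expect_equal(unname(substr(fx$sim$sequences[spikes$contig_id],
                             spikes$pos + 1, spikes$pos + 1)), spikes$ref)
  expect_true(all(spikes$ref != spikes$alt))
})

test_that("simulated observations carry truthful depths and genotypes", {
  fxd <- fx_small_detect()
  fx <- fx_small()
  obs <- fxd$bundle$obs[[fx$sim$offspring_ids[1]]]
  dn <- fxd$spikes[type == "dnm" &
                     offspring_id == fx$sim$offspring_ids[1]]
  hit <- obs[dn, on = c("contig_id", "pos"), nomatch = 0L]
  expect_true(all(hit$gt_off == "1/1"))
  # parents never carry the spiked allele beyond sequencing noise
  alt_frac_mo <- sapply(strsplit(hit$ad_mo, ","), function(x)
    as.numeric(x[2]) / max(1, sum(as.numeric(x))))
  expect_true(all(alt_frac_mo < 0.1))
})
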