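test_that("contig mean depth matches the expand-and-average oracle", {
  tr <- data.table::data.table(contig_id = "c", start = c(0, 4),
                               end = c(4, 8), depth = c(10, 10))
  expect_equal(contig_mean_depth(tr), 10)
  tr0 <- data.table::data.table(contig_id = "c", start = 0, end = 4,
                                depth = 0)
  expect_equal(contig_mean_depth(tr0), 0)
  set.seed(5)
  lens <- sample(1:30, 40, replace = TRUE)
  ends <- cumsum(lens)
  rnd <- data.table::data.table(contig_id = "c", start = ends - lens,
                                end = ends,
                                depth = sample(0:200, 40, replace = TRUE))
  expect_equal(contig_mean_depth(rnd), mean(expand_depth(rnd, "c")))
  expect_error(contig_mean_depth(rnd[0]), "zero-length")
})

paf_row <- function(q, t, qlen, tlen, qs, qe, ts, te, nm, bl) {
  data.table::data.table(qname = q, qlen = qlen, qstart = qs, qend = qe,
                         strand = "+", tname = t, tlen = tlen, tstart = ts,
                         tend = te, n_matches = nm, block_len = bl,
                         mapq = 60)
}

test_that("reciprocal best hits honor the coverage and identity cutoffs", {
  lens <- c(A = 1000, B = 1000)
  ok <- rbind(paf_row("A", "B", 1000, 1000, 0, 900, 0, 900, 864, 900),
              paf_row("B", "A", 1000, 1000, 0, 900, 0, 900, 864, 900))
  got <- rbh_pairs(ok, lens)
  expect_equal(nrow(got), 1)
  expect_equal(sort(c(got$contig_a, got$contig_b)), c("A", "B"))
  expect_equal(got$coverage, 0.9)
  expect_equal(got$identity, 0.96)

  # coverage 0.69 on one side is below threshold
  low <- paf_row("A", "B", 1000, 1000, 0, 690, 0, 690, 680, 690)
  expect_equal(nrow(rbh_pairs(low, lens)), 0)
})

test_that("RBH on a planted 20-contig set matches the brute-force oracle", {
  set.seed(6)
  n <- 20
  base_len <- sample(2000:8000, n)
  # allelic partners have near-equal lengths, unrelated contigs vary freely
  base_len[seq(2, 12, by = 2)] <-
    round(base_len[seq(1, 11, by = 2)] * runif(6, 0.95, 1.05))
  lens <- setNames(base_len, sprintf("c%02d", 1:n))
  ids <- names(lens)
  # planted allelic pairs among the first 12 contigs, identity ~0.97
  paf <- list()
  for (i in seq(1, 12, by = 2)) {
    a <- ids[i]; b <- ids[i + 1]
    l <- min(lens[a], lens[b])
    paf[[length(paf) + 1]] <-
      paf_row(a, b, lens[a], lens[b], 0, l, 0, l, round(0.97 * l), l)
  }
  # decoy partial hits at coverage 0.4
  for (k in 1:15) {
    a <- sample(ids, 1); b <- sample(setdiff(ids, a), 1)
    l <- floor(0.4 * min(lens[a], lens[b]))
    paf[[length(paf) + 1]] <-
      paf_row(a, b, lens[a], lens[b], 0, l, 0, l, round(0.9 * l), l)
  }
  paf <- data.table::rbindlist(paf)
  got <- rbh_pairs(paf, lens)
  oracle <- bf_rbh(as.data.frame(paf), lens)
  got_pairs <- sort(paste(got$contig_a, got$contig_b))
  bf_pairs <- sort(vapply(oracle, paste, character(1), collapse = " "))
  expect_equal(got_pairs, bf_pairs)
  # exactly the planted pairs survive
  expect_equal(nrow(got), 6)
})

test_that("fragmented alignments are aggregated per pair before filtering", {
  lens <- c(A = 1000, B = 1000)
  # two 400-bp blocks: merged coverage 0.8 passes, each alone would fail
  frag <- rbind(paf_row("A", "B", 1000, 1000, 0, 400, 0, 400, 390, 400),
                paf_row("A", "B", 1000, 1000, 500, 900, 500, 900, 390, 400))
  got <- rbh_pairs(frag, lens)
  expect_equal(nrow(got), 1)
  expect_equal(got$coverage, 0.8)
  expect_equal(got$identity, 780 / 800)
})

test_that("depth thresholds scale linearly from the 80x calibration", {
  expect_equal(default_thresholds(80),
               list(het_low = 10, het_high = 50, hom_high = 100))
  expect_equal(default_thresholds(40),
               list(het_low = 5, het_high = 25, hom_high = 50))
  expect_equal(default_thresholds(160),
               list(het_low = 20, het_high = 100, hom_high = 200))
  expect_error(default_thresholds(0), "positive")
})

mk_contigs <- function(ids, class = "non_bubble", partner = NA_character_) {
  data.table::data.table(contig_id = ids, parent_of_origin = "maternal",
                         assembler_class = class, partner_id = partner,
                         length_bp = 5000L)
}

test_that("classification applies the depth-window and RBH rules", {
  th <- default_thresholds(80)
  contigs <- mk_contigs(c("n1", "n2", "n3", "n4", "n5"))
  depths <- data.table::data.table(
    contig_id = c("n1", "n2", "n3", "n4", "n5"),
    mean_depth = c(30, 35, 80, 80, 120))
  rbh <- data.table::data.table(contig_a = c("n1", "n3"),
                                contig_b = c("n2", "n5"),
                                coverage = 0.9, identity = 0.97,
                                n_matches = 4000)
  z <- classify_contigs(contigs, depths, rbh, th)
  zl <- setNames(z$category, z$contig_id)
  expect_equal(unname(zl[c("n1", "n2")]), rep("bubble_like", 2))
  expect_equal(unname(zl["n3"]), "uncertain")  # candidate hom with an RBH
  expect_equal(unname(zl["n4"]), "true_non_bubble")
  expect_equal(unname(zl["n5"]), "uncertain")  # depth 120 above hom_high
  # mutual partner ids on the bubble-like pair
  expect_equal(z[contig_id == "n1", rbh_partner], "n2")
  expect_equal(z[contig_id == "n2", rbh_partner], "n1")
  # assembler bubbles keep their category
  bub <- mk_contigs(c("b1", "b2"), class = c("bubble_primary",
                                             "bubble_secondary"),
                    partner = c("b2", "b1"))
  zb <- classify_contigs(bub,
                         data.table::data.table(contig_id = c("b1", "b2"),
                                                mean_depth = c(40, 40)),
                         rbh[0], th)
  expect_equal(zb$category, c("bubble", "bubble"))
  # missing depth is an error
  expect_error(classify_contigs(contigs, depths[1:3], rbh, th), "missing")
})

test_that("every contig receives exactly one category on simulated data", {
  fx <- fx_small()
  expect_setequal(fx$state$zygosity$contig_id, fx$sim$contigs$contig_id)
  expect_true(all(fx$state$zygosity$category %in%
                    c("bubble", "bubble_like", "true_non_bubble",
                      "uncertain")))
  # bubble-like pairing is an involution
  bl <- fx$state$zygosity[category == "bubble_like"]
  pmap <- setNames(bl$rbh_partner, bl$contig_id)
  expect_identical(unname(pmap[pmap[bl$contig_id]]), bl$contig_id)
})

test_that("assembler bubbles re-enter the heterozygous class (positive control)", {
  fx <- fx_small()
  for (p in c("maternal", "paternal")) {
    ind <- if (p == "maternal") "mother" else "father"
    cc <- fx$sim$contigs[parent_of_origin == p]
    md <- contig_means_from_bins(fx$sim, ind)[contig_id %in% cc$contig_id]
    lens <- setNames(as.numeric(cc$length_bp), cc$contig_id)
    rbh <- rbh_pairs(fx$sim$self_paf[[p]], lens)
    frac <- positive_control_fraction(cc, md, rbh, default_thresholds(80))
    expect_gte(frac, 0.9)
  }
})
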