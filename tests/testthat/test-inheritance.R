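test_that("depth binning takes 50-bp means and drops the partial tail", {
  expect_equal(bin_depths(rep(20, 100), 50), c(20, 20))
  expect_length(bin_depths(rep(1, 149), 50), 2)  # trailing 49 bp discarded
  set.seed(8)
  v <- sample(0:80, 437, replace = TRUE)
  got <- bin_depths(v, 50)
  oracle <- vapply(seq_len(8), function(i)
    mean(v[((i - 1) * 50 + 1):(i * 50)]), numeric(1))
  expect_equal(got, oracle)
  expect_error(bin_depths(rep(1, 30), 50), "shorter")
})

test_that("depth similarity follows its weighted cosine/Jaccard definition", {
  s <- depth_similarity(c(5, 5, 5, 5), c(5, 5, 5, 5))
  expect_equal(s$value, 1)
  expect_equal(depth_similarity(c(0, 0, 0), c(0, 0, 0))$value, 1)
  # hand-computed mixed case
  s2 <- depth_similarity(c(4, 0, 4, 0), c(2, 0, 0, 4))
  expect_equal(s2$cosine_part, 1)
  expect_equal(s2$jaccard_part, 1 / 3)
  expect_equal(s2$weight_nonzero, 1 / 4)
  expect_equal(s2$value, 0.5)
  expect_error(depth_similarity(1:3, 1:4), "mismatch")
})

test_that("similarity is symmetric, bounded and matches the brute-force oracle", {
  set.seed(9)
  for (i in 1:1000) {
    b <- sample(1:30, 1)
    u <- ifelse(runif(b) < 0.3, 0, rpois(b, 40))
    v <- ifelse(runif(b) < 0.3, 0, rpois(b, 40))
    a <- depth_similarity(u, v)$value
    expect_equal(a, depth_similarity(v, u)$value)
    expect_gte(a, 0); expect_lte(a, 1)
    expect_equal(a, bf_similarity(u, v))
  }
})

test_that("parental similarity flags confounded contigs", {
  expect_equal(parental_similarity_score(rep(40, 10), rep(40, 10)), 1)
  expect_equal(parental_similarity_score(rep(0, 10), rep(40, 10)), 0)
  # simulated: shared-haplotype contigs score high, ordinary ones low
  fx <- fx_small()
  ps <- fx$state$parental_similarity
  shared_ids <- fx$sim$contigs[shared == TRUE, contig_id]
  plain <- fx$sim$contigs[shared == FALSE & truth_zygosity == "heterozygous",
                          contig_id]
  if (length(shared_ids)) expect_true(all(ps[shared_ids] > 0.5))
  expect_true(mean(ps[plain] <= 0.5) > 0.98)
})

test_that("stage 1 applies the low-depth rule then the similarity vote", {
  expect_equal(stage1_call(0.9, 0.4, 5, 80)$state, "not_inherited")
  expect_equal(stage1_call(0.9, 0.4, 5, 80)$basis, "low_depth")
  # threshold is max(10, mean/4)
  expect_equal(stage1_call(0.9, 0.4, 25, 120)$state, "not_inherited")
  expect_equal(stage1_call(0.9, 0.4, 40, 80)$state, "inherited")
  expect_equal(stage1_call(0.3, 0.8, 40, 80)$state, "not_inherited")
  expect_equal(stage1_call(0.5, 0.5, 40, 80)$state, "unresolved")
})

mk_stage1 <- function(states, bases, ids = c("A", "B")) {
  data.table::data.table(offspring_id = "o", contig_id = ids,
                         state = states, basis = bases,
                         similarity_mother = 0.8, similarity_father = 0.2)
}

mk_zyg <- function(cat, ids = c("A", "B")) {
  data.table::data.table(contig_id = ids, category = cat,
                         mean_depth = 40,
                         rbh_partner = if (cat[1] == "bubble_like")
                           rev(ids) else NA_character_,
                         rbh_coverage = NA_real_, rbh_identity = NA_real_)
}

mk_ctg <- function(ids = c("A", "B"), class = c("bubble_primary",
                                                "bubble_secondary")) {
  data.table::data.table(contig_id = ids, parent_of_origin = "maternal",
                         assembler_class = class,
                         partner_id = if (class[1] == "non_bubble")
                           NA_character_ else rev(ids),
                         length_bp = 5000L)
}

test_that("stage 2: a low-depth member forces its partner inherited", {
  s1 <- mk_stage1(c("not_inherited", "inherited"),
                  c("low_depth", "similarity"))
  out <- stage2_resolve(s1, mk_zyg(c("bubble", "bubble")), mk_ctg(),
                        c(A = 0.1, B = 0.1))
  expect_equal(out[contig_id == "A", state], "not_inherited")
  expect_equal(out[contig_id == "B", state], "inherited")
  expect_equal(out[contig_id == "B", basis], "partner_forced")
})

test_that("stage 2: both inherited resolves to the lower parental score", {
  s1 <- mk_stage1(c("inherited", "inherited"),
                  c("similarity", "similarity"))
  out <- stage2_resolve(s1, mk_zyg(c("bubble", "bubble")), mk_ctg(),
                        c(A = 0.2, B = 0.45))
  expect_equal(out[contig_id == "A", state], "inherited")
  expect_equal(out[contig_id == "B", state], "not_inherited")
  # both not inherited: force-inherit the lower score
  s1b <- mk_stage1(c("not_inherited", "not_inherited"),
                   c("similarity", "similarity"))
  out2 <- stage2_resolve(s1b, mk_zyg(c("bubble", "bubble")), mk_ctg(),
                         c(A = 0.45, B = 0.2))
  expect_equal(out2[contig_id == "B", state], "inherited")
  expect_equal(out2[contig_id == "A", state], "not_inherited")
})

test_that("stage 2: one separable member's stage-1 call wins", {
  # A separable and inherited at stage 1; B confounded
  s1 <- mk_stage1(c("inherited", "inherited"),
                  c("similarity", "similarity"))
  out <- stage2_resolve(s1, mk_zyg(c("bubble", "bubble")), mk_ctg(),
                        c(A = 0.3, B = 0.7))
  expect_equal(out[contig_id == "A", state], "inherited")
  expect_equal(out[contig_id == "B", state], "not_inherited")
  # consistent stage-1 calls are kept even if the not-inherited member has
  # the lower score
  s1c <- mk_stage1(c("inherited", "not_inherited"),
                   c("similarity", "similarity"))
  out2 <- stage2_resolve(s1c, mk_zyg(c("bubble", "bubble")), mk_ctg(),
                         c(A = 0.45, B = 0.2))
  expect_equal(out2[contig_id == "A", state], "inherited")
  expect_equal(out2[contig_id == "B", state], "not_inherited")
})

test_that("stage 2: doubly confounded pairs stay unresolved", {
  s1 <- mk_stage1(c("inherited", "inherited"),
                  c("similarity", "similarity"))
  out <- stage2_resolve(s1, mk_zyg(c("bubble", "bubble")), mk_ctg(),
                        c(A = 0.8, B = 0.8))
  expect_equal(out$state, c("unresolved", "unresolved"))
  expect_equal(out$basis, rep("high_parental_similarity", 2))
})

test_that("stage 2: homozygous contigs are always inherited, uncertain follow the score", {
  s1 <- mk_stage1(c("not_inherited", "inherited"),
                  c("low_depth", "similarity"))
  zyg <- mk_zyg(c("true_non_bubble", "uncertain"))
  ctg <- mk_ctg(class = c("non_bubble", "non_bubble"))
  out <- stage2_resolve(s1, zyg, ctg, c(A = 0.1, B = 0.1))
  expect_equal(out[contig_id == "A", state], "inherited")
  expect_equal(out[contig_id == "A", basis], "homozygous_always")
  expect_equal(out[contig_id == "B", state], "inherited")  # stage-1 kept
  expect_equal(out[contig_id == "B", stage], 1L)
  out2 <- stage2_resolve(s1, zyg, ctg, c(A = 0.1, B = 0.8))
  expect_equal(out2[contig_id == "B", state], "unresolved")
  # a paired contig whose partner is missing from the call set errors
  s1d <- mk_stage1("inherited", "similarity", ids = "A")
  expect_error(stage2_resolve(s1d, mk_zyg(c("bubble", "bubble")), mk_ctg(),
                              c(A = 0.1, B = 0.1)), "partner")
})

test_that("exactly one contig per pair is inherited after stage 2", {
  fx <- fx_small()
  pairs <- fx$sim$contigs[truth_zygosity == "heterozygous" &
                            haplotype == 1L,
                          list(a = contig_id,
                               b = sub("_h1$", "_h2", contig_id))]
  calls <- fx$state$calls
  for (off in fx$sim$offspring_ids) {
    st <- calls[offspring_id == off, setNames(state, contig_id)]
    n_inh <- (st[pairs$a] == "inherited") + (st[pairs$b] == "inherited")
    unres <- st[pairs$a] == "unresolved" | st[pairs$b] == "unresolved"
    expect_true(all(n_inh[!unres] == 1))
    # unresolved only ever happens pairwise, from high parental similarity
    expect_true(all((st[pairs$a] == "unresolved") ==
                      (st[pairs$b] == "unresolved")))
  }
})

test_that("inference recovers the simulated transmission almost perfectly", {
  fx <- fx_small()
  inh <- inheritance_error(fx$sim, fx$state)
  expect_lte(inh$error_rate, 0.03)
})
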