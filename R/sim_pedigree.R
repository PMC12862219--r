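# Pedigree-level simulation: haplotype transmission, read-depth doses with
# cross-mapping, binned depth profiles, and simulated contig alignments.
# The generator operates at the depth/observation level: read simulation,
# alignment and variant calling are replaced by parametric models of the
# quantities the downstream algorithms actually consume.

hamming <- function(a, b) sum(charToRaw(a) != charToRaw(b))

apply_subs <- function(chunk, local_pos, alts) {
  if (!length(local_pos)) return(chunk)
  r <- charToRaw(chunk)
  r[local_pos + 1L] <- charToRaw(paste(alts, collapse = ""))
  rawToChar(r)
}

# materialize every contig sequence for one parent
parent_contig_seqs <- function(reference, contigs, segments, truth) {
  segs <- segments[match(contigs$segment_id, segment_id)]
  out <- character(nrow(contigs))
  hom <- truth$hom_subs; het <- truth$het_snps
  for (i in seq_len(nrow(contigs))) {
    s <- segs$start[i]; e <- segs$end[i]
    chunk <- substr(reference, s + 1L, e)
    h <- hom[pos >= s & pos < e]
    chunk <- apply_subs(chunk, h$pos - s, h$alt)
    hp <- contigs$haplotype[i]
    if (hp > 0L) {
      v <- het[pos >= s & pos < e & hap == hp]
      chunk <- apply_subs(chunk, v$pos - s, v$alt)
    }
    out[i] <- chunk
  }
  setNames(out, contigs$contig_id)
}

#' Mendelian transmission of parental haplotypes
#'
#' For every offspring, segment and parent, one haplotype is chosen
#' uniformly and recorded as the transmitted one.
#'
#' @param segments Segment grid.
#' @param offspring_ids Offspring labels.
#' @return `data.table(offspring_id, segment_id, parent, inherited_hap)`.
#' @export
transmit <- function(segments, offspring_ids) {
  grid <- data.table::CJ(offspring_id = offspring_ids,
                         segment_id = segments$segment_id,
                         parent = c("maternal", "paternal"))
  grid[, inherited_hap := sample(1:2, .N, replace = TRUE)]
  grid
}

# dose matrix: expected haplotype copies of each individual's reads landing
# on each contig, after similar-allele splitting and bubble-pair
# cross-mapping
compute_doses <- function(cfg, contigs, transmission, shared_segments,
                          individuals) {
  D <- matrix(0, nrow = nrow(contigs), ncol = length(individuals),
              dimnames = list(contigs$contig_id, individuals))
  by_seg <- split(seq_len(nrow(contigs)),
                  list(contigs$segment_id, contigs$parent_of_origin),
                  drop = TRUE)
  key <- function(seg, par) paste(seg, par, sep = ".")
  tr <- data.table::dcast(transmission,
                          segment_id + parent ~ offspring_id,
                          value.var = "inherited_hap")
  offspring <- setdiff(individuals, c("mother", "father"))
  tr_key <- paste(tr$segment_id, tr$parent, sep = ".")
  tr_mat <- as.matrix(tr[, offspring, with = FALSE])
  rownames(tr_mat) <- tr_key
  segs <- unique(contigs$segment_id)
  cid_of <- function(seg, par, hap) {
    idx <- by_seg[[key(seg, par)]]
    ids <- contigs$contig_id[idx]
    hps <- contigs$haplotype[idx]
    if (length(idx) == 1L) ids else ids[hps == hap]
  }
  add <- function(cid, ind, x) D[cid, ind] <<- D[cid, ind] + x
  for (seg in segs) {
    m_idx <- by_seg[[key(seg, "maternal")]]
    p_idx <- by_seg[[key(seg, "paternal")]]
    m_het <- length(m_idx) == 2L
    p_het <- length(p_idx) == 2L
    shared <- seg %in% shared_segments && m_het && p_het
    # route one haplotype dose of reads from (parent, hap) to contigs
    route <- function(par, hap, ind, dose = 1) {
      own_het <- if (par == "maternal") m_het else p_het
      if (shared && hap == 1L) {
        add(cid_of(seg, "maternal", 1L), ind, dose / 2)
        add(cid_of(seg, "paternal", 1L), ind, dose / 2)
      } else if (own_het) {
        add(cid_of(seg, par, hap), ind, dose)
      } else {
        add(cid_of(seg, par, 0L), ind, dose)
      }
    }
    route("maternal", 1L, "mother"); route("maternal", 2L, "mother")
    route("paternal", 1L, "father"); route("paternal", 2L, "father")
    hk <- key(seg, "maternal")
    for (o in offspring) {
      route("maternal", tr_mat[key(seg, "maternal"), o], o)
      route("paternal", tr_mat[key(seg, "paternal"), o], o)
    }
    # bubble-pair cross-mapping bleed
    cm <- cfg$cross_mapping_rate
    if (cm > 0) {
      for (idx in list(m_idx, p_idx)) {
        if (length(idx) == 2L) {
          a <- contigs$contig_id[idx[1]]; b <- contigs$contig_id[idx[2]]
          da <- D[a, ]; db <- D[b, ]
          D[a, ] <- (1 - cm) * da + cm * db
          D[b, ] <- (1 - cm) * db + cm * da
        }
      }
    }
  }
  D
}

# negative-binomial per-bin depths for every individual
simulate_bins <- function(cfg, contigs, doses) {
  n_bins <- contigs$length_bp %/% cfg$bin_size
  idx <- rep(seq_len(nrow(contigs)), n_bins)
  fac <- factor(contigs$contig_id[idx], levels = contigs$contig_id)
  bins <- list()
  for (ind in colnames(doses)) {
    mu <- doses[, ind][idx] * cfg$depth_mean / 2
    v <- stats::rnbinom(length(mu), size = cfg$nb_size, mu = mu)
    bins[[ind]] <- split(as.numeric(v), fac)
  }
  bins
}

#' Run-length depth track of one individual
#'
#' Reconstructs a mosdepth-style per-base run-length table from the
#' simulated bin depths; the trailing sub-bin remainder of each contig
#' repeats the last bin's depth so the track tiles the contig.
#'
#' @param sim A `pedigree_sim` object.
#' @param individual Individual ID.
#' @return `data.table(contig_id, start, end, depth)`.
#' @export
make_depth_track <- function(sim, individual) {
  cfg <- sim$cfg
  b <- sim$bins[[individual]]
  if (is.null(b)) stop("unknown individual: ", individual)
  contigs <- sim$contigs
  n_bins <- contigs$length_bp %/% cfg$bin_size
  rem <- contigs$length_bp %% cfg$bin_size
  starts <- sequence(n_bins, from = 0L, by = cfg$bin_size)
  ends <- starts + cfg$bin_size
  depth <- unlist(b[contigs$contig_id], use.names = FALSE)
  dt <- data.table::data.table(
    contig_id = rep(contigs$contig_id, n_bins),
    start = starts, end = ends, depth = depth)
  extra <- contigs[rem > 0]
  if (nrow(extra)) {
    last_depth <- vapply(extra$contig_id,
                         function(cid) tail(b[[cid]], 1L), numeric(1))
    dt <- rbind(dt, data.table::data.table(
      contig_id = extra$contig_id,
      start = (extra$length_bp %/% cfg$bin_size) * cfg$bin_size,
      end = extra$length_bp, depth = last_depth))
  }
  data.table::setorder(dt, contig_id, start)
  dt[]
}

# per-contig mean depth of one individual, from bins + remainder rule
contig_means_from_bins <- function(sim, individual) {
  cfg <- sim$cfg
  b <- sim$bins[[individual]]
  contigs <- sim$contigs
  md <- vapply(seq_len(nrow(contigs)), function(i) {
    v <- b[[contigs$contig_id[i]]]
    len <- contigs$length_bp[i]
    rem <- len %% cfg$bin_size
    (sum(v) * cfg$bin_size + if (rem) tail(v, 1L) * rem else 0) / len
  }, numeric(1))
  data.table::data.table(contig_id = contigs$contig_id, mean_depth = md)
}

# simulated all-vs-all self-alignment of one parent's assembly
simulate_self_paf <- function(contigs, seqs, parent_label, cfg) {
  cc <- contigs[parent_of_origin == parent_label]
  het1 <- cc[haplotype == 1L & truth_zygosity == "heterozygous"]
  recs <- vector("list", nrow(het1))
  for (i in seq_len(nrow(het1))) {
    a <- het1$contig_id[i]
    b <- sub("_h1$", "_h2", a)
    len <- het1$length_bp[i]
    nm <- len - hamming(seqs[[a]], seqs[[b]])
    recs[[i]] <- data.table::data.table(
      qname = a, qlen = len, qstart = 0, qend = len, strand = "+",
      tname = b, tlen = len, tstart = 0, tend = len,
      n_matches = nm, block_len = len, mapq = 60)
  }
  paf <- data.table::rbindlist(recs)
  # spurious partial hits that must fail the coverage filter
  nd <- cfg$n_decoy_alignments
  if (nd > 0 && nrow(cc) >= 2) {
    i1 <- sample.int(nrow(cc), nd, replace = TRUE)
    i2 <- sample.int(nrow(cc), nd, replace = TRUE)
    keep <- i1 != i2
    i1 <- i1[keep]; i2 <- i2[keep]
    span <- floor(0.4 * pmin(cc$length_bp[i1], cc$length_bp[i2]))
    ok <- span >= 50
    decoys <- data.table::data.table(
      qname = cc$contig_id[i1][ok], qlen = cc$length_bp[i1][ok],
      qstart = 0, qend = span[ok], strand = "+",
      tname = cc$contig_id[i2][ok], tlen = cc$length_bp[i2][ok],
      tstart = 0, tend = span[ok],
      n_matches = round(0.9 * span[ok]), block_len = span[ok], mapq = 60)
    paf <- rbind(paf, decoys)
  }
  if (is.null(paf) || !nrow(paf)) empty_paf() else paf
}

# simulated cross-parent alignments (maternal assembly vs paternal)
simulate_cross_paf <- function(contigs, seqs) {
  segs <- unique(contigs$segment_id)
  recs <- list()
  k <- 0L
  for (seg in segs) {
    m <- contigs[segment_id == seg & parent_of_origin == "maternal"]
    p <- contigs[segment_id == seg & parent_of_origin == "paternal"]
    for (i in seq_len(nrow(m))) {
      for (j in seq_len(nrow(p))) {
        len <- m$length_bp[i]
        nm <- len - hamming(seqs[[m$contig_id[i]]], seqs[[p$contig_id[j]]])
        k <- k + 1L
        recs[[k]] <- data.table::data.table(
          qname = m$contig_id[i], qlen = len, qstart = 0, qend = len,
          strand = "+", tname = p$contig_id[j], tlen = p$length_bp[j],
          tstart = 0, tend = p$length_bp[j], n_matches = nm,
          block_len = len, mapq = 60)
      }
    }
  }
  data.table::rbindlist(recs)
}

#' Simulate a pedigree: parents, assemblies, transmission and depth
#'
#' Runs the whole generator (no mutations yet; see [spike_mutations()]):
#' random reference, no-variant intervals, window-based inhomogeneous
#' Poisson SNP placement per parent, haplotype construction, shared-ancestry
#' haplotype copying, segmentation and contigization with assembler-class
#' mislabeling, Mendelian transmission, dose computation with cross-mapping,
#' negative-binomial bin depths, and simulated self-/cross-alignment PAFs.
#'
#' @param cfg A [sim_config()].
#' @return List of class `pedigree_sim` with elements `cfg`, `reference`,
#'   `no_variant`, `segments`, `contigs` (incl. truth columns), `sequences`,
#'   `parents` (truth SNP tables), `transmission`, `shared_segments`,
#'   `doses`, `bins`, `self_paf` (list by parent), `cross_paf`,
#'   `individuals`, `offspring_ids`.
#' @export
simulate_pedigree <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  reference <- random_reference(cfg$genome_length)
  no_variant <- place_no_variant_intervals(cfg)
  snp_m <- simulate_snp_positions(cfg, no_variant)
  snp_p <- simulate_snp_positions(cfg, no_variant)
  mother <- simulate_parent(reference, cfg, snp_m$positions)
  father <- simulate_parent(reference, cfg, snp_p$positions)
  segments <- segment_genome(cfg, no_variant)
  contigs_m <- contigize("maternal", segments, mother$het_snps, cfg)
  contigs_p <- contigize("paternal", segments, father$het_snps, cfg)
  contigs <- rbind(contigs_m, contigs_p)
  # shared ancestry: in a fraction of doubly heterozygous segments the
  # father's haplotype 1 is replaced by the mother's haplotype 1
  het_both <- intersect(contigs_m[truth_zygosity == "heterozygous", segment_id],
                        contigs_p[truth_zygosity == "heterozygous", segment_id])
  n_shared <- round(cfg$shared_ancestry_fraction * length(het_both))
  shared_segments <- if (n_shared > 0) sample(het_both, n_shared)
  else character(0)
  seq_m <- parent_contig_seqs(reference, contigs_m, segments, mother)
  seq_p <- parent_contig_seqs(reference, contigs_p, segments, father)
  for (seg in shared_segments) {
    seq_p[[paste0("p_", seg, "_h1")]] <- seq_m[[paste0("m_", seg, "_h1")]]
  }
  seqs <- c(seq_m, seq_p)
  offspring_ids <- sprintf("o%02d", seq_len(cfg$n_offspring))
  individuals <- c("mother", "father", offspring_ids)
  transmission <- transmit(segments, offspring_ids)
  contigs[, shared := segment_id %in% shared_segments &
            truth_zygosity == "heterozygous" & haplotype == 1L]
  doses <- compute_doses(cfg, contigs, transmission, shared_segments,
                         individuals)
  bins <- simulate_bins(cfg, contigs, doses)
  self_paf <- list(
    maternal = simulate_self_paf(contigs, seqs, "maternal", cfg),
    paternal = simulate_self_paf(contigs, seqs, "paternal", cfg))
  cross_paf <- simulate_cross_paf(contigs, seqs)
  structure(list(cfg = cfg, reference = reference, no_variant = no_variant,
                 snp_windows = list(maternal = snp_m$window_counts,
                                    paternal = snp_p$window_counts),
                 parents = list(maternal = mother, paternal = father),
                 segments = segments, contigs = contigs, sequences = seqs,
                 transmission = transmission,
                 shared_segments = shared_segments, doses = doses,
                 bins = bins, self_paf = self_paf, cross_paf = cross_paf,
                 individuals = individuals, offspring_ids = offspring_ids),
            class = "pedigree_sim")
}

#' True inheritance state of every contig in every offspring
#'
#' @param sim A `pedigree_sim`.
#' @return `data.table(offspring_id, contig_id, truth_state)` with values
#'   `inherited` / `not_inherited`.
#' @export
truth_inheritance <- function(sim) {
  tr <- sim$transmission
  grid <- data.table::CJ(offspring_id = sim$offspring_ids,
                         contig_id = sim$contigs$contig_id, sorted = FALSE)
  meta <- sim$contigs[, list(contig_id, segment_id, parent_of_origin,
                             haplotype)]
  grid <- merge(grid, meta, by = "contig_id")
  grid <- merge(grid, tr,
                by.x = c("offspring_id", "segment_id", "parent_of_origin"),
                by.y = c("offspring_id", "segment_id", "parent"))
  grid[, truth_state := ifelse(haplotype == 0L | haplotype == inherited_hap,
                               "inherited", "not_inherited")]
  grid[, list(offspring_id, contig_id, truth_state)]
}
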