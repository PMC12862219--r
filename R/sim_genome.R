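# Genome-level simulation: reference, heterozygous SNP placement, parental
# haplotypes, segmentation into contigs, and simulated contig alignments.

#' Random reference sequence
#' @param length_bp Sequence length.
#' @return A single uppercase ACGT string.
#' @export
random_reference <- function(length_bp) {
  paste(sample(c("A", "C", "G", "T"), length_bp, replace = TRUE),
        collapse = "")
}

# non-overlapping no-variant intervals, uniformly placed
place_no_variant_intervals <- function(cfg) {
  n <- cfg$n_no_variant_intervals
  if (n == 0) {
    return(data.table::data.table(start = integer(), end = integer()))
  }
  len <- cfg$no_variant_length
  taken_s <- integer(0); taken_e <- integer(0)
  tries <- 0L
  while (length(taken_s) < n && tries < 10000L) {
    tries <- tries + 1L
    s <- sample.int(cfg$genome_length - len, 1L)
    if (!any(s < taken_e & s + len > taken_s)) {
      taken_s <- c(taken_s, s); taken_e <- c(taken_e, s + len)
    }
  }
  if (length(taken_s) < n)
    stop("could not place the requested no-variant intervals")
  o <- order(taken_s)
  data.table::data.table(start = taken_s[o], end = taken_e[o])
}

#' Window-based inhomogeneous Poisson SNP placement
#'
#' The genome is divided into non-overlapping windows with (uniform or
#' Gamma-drawn) weights; a target total of `round(heterozygosity *
#' genome_length)` SNPs is allocated to windows by independent Poisson
#' sampling with means proportional to the weights, and positions are drawn
#' uniformly within each window excluding the no-variant intervals.
#'
#' @param cfg A [sim_config()].
#' @param no_variant `data.table(start, end)` of excluded intervals.
#' @param weights Optional explicit per-window weights (recycled checks
#'   apply); by default drawn per `cfg$window_weight_shape`.
#' @return List with `positions` (sorted 0-based, unique), `window_counts`
#'   (`data.table(window, start, end, weight, n_snps)`).
#' @export
simulate_snp_positions <- function(cfg, no_variant = NULL, weights = NULL) {
  L <- cfg$genome_length
  ws <- seq(0L, L - 1L, by = cfg$window_size)
  we <- pmin(ws + cfg$window_size, L)
  nw <- length(ws)
  if (is.null(weights)) {
    weights <- if (is.null(cfg$window_weight_shape)) rep(1, nw)
    else stats::rgamma(nw, shape = cfg$window_weight_shape,
                       rate = cfg$window_weight_shape)
  }
  stopifnot(length(weights) == nw, all(weights >= 0), any(weights > 0))
  if (is.null(no_variant)) {
    no_variant <- data.table::data.table(start = integer(), end = integer())
  }
  # per-window eligible positions
  elig <- vector("list", nw)
  avail <- numeric(nw)
  for (i in seq_len(nw)) {
    mask <- rep(TRUE, we[i] - ws[i])
    nv <- no_variant[start < we[i] & end > ws[i]]
    if (nrow(nv)) {
      for (j in seq_len(nrow(nv))) {
        a <- max(nv$start[j], ws[i]) - ws[i] + 1L
        b <- min(nv$end[j], we[i]) - ws[i]
        mask[a:b] <- FALSE
      }
    }
    elig[[i]] <- ws[i] + which(mask) - 1L
    avail[i] <- sum(mask)
  }
  dead <- weights > 0 & avail == 0
  if (any(dead)) {
    warning(sum(dead), " window(s) fully covered by no-variant intervals; ",
            "weight renormalized to the remaining windows")
    weights[dead] <- 0
  }
  target <- round(cfg$heterozygosity * L)
  lam <- target * weights / sum(weights)
  counts <- stats::rpois(nw, lam)
  over <- counts > avail
  if (any(over)) {
    warning("SNP count capped at available positions in ",
            sum(over), " window(s)")
    counts[over] <- avail[over]
  }
  pos <- unlist(lapply(seq_len(nw), function(i) {
    if (counts[i] == 0L) integer(0)
    else sort(sample(elig[[i]], counts[i]))
  }))
  list(positions = as.integer(pos),
       window_counts = data.table::data.table(
         window = seq_len(nw), start = ws, end = we,
         weight = weights, n_snps = counts))
}

# random base different from `from` (vectorized)
other_base <- function(from) {
  bases <- c("A", "C", "G", "T")
  vapply(from, function(b) sample(setdiff(bases, b), 1L), character(1),
         USE.NAMES = FALSE)
}

#' Simulate one diploid parent
#'
#' Homozygous substitutions (both haplotypes) model the parent's divergence
#' from the reference; heterozygous SNPs are introduced at the supplied
#' positions by mutating one randomly chosen haplotype to a random different
#' base.
#'
#' @param reference Reference string.
#' @param cfg A [sim_config()].
#' @param snp_positions 0-based heterozygous SNP positions.
#' @return List with `hom_subs` (`data.table(pos, alt)`) and `het_snps`
#'   (`data.table(pos, hap, ref, alt)`), where `ref` is the base after
#'   homozygous substitution.
#' @export
simulate_parent <- function(reference, cfg, snp_positions) {
  L <- nchar(reference)
  n_hom <- stats::rpois(1L, cfg$hom_divergence * L)
  hom_pos <- if (n_hom > 0) sort(sample.int(L, min(n_hom, L)) - 1L)
  else integer(0)
  ref_at <- function(p) substring(reference, p + 1L, p + 1L)
  hom <- data.table::data.table(pos = hom_pos)
  if (nrow(hom)) hom[, alt := other_base(ref_at(pos))]
  else hom[, alt := character(0)]
  base_at <- setNames(hom$alt, hom$pos)
  het <- data.table::data.table(pos = as.integer(snp_positions))
  if (nrow(het)) {
    cur <- ref_at(het$pos)
    hb <- base_at[as.character(het$pos)]
    cur[!is.na(hb)] <- hb[!is.na(hb)]
    het[, `:=`(hap = sample(1:2, .N, replace = TRUE), ref = cur,
               alt = other_base(cur))]
  } else {
    het[, `:=`(hap = integer(0), ref = character(0), alt = character(0))]
  }
  list(hom_subs = hom, het_snps = het)
}

# Segment grid: no-variant intervals are their own segments; remaining
# spans are chopped into log-normal pieces.
segment_genome <- function(cfg, no_variant) {
  L <- cfg$genome_length
  bounds <- data.table::data.table(start = integer(), end = integer(),
                                   is_novar = logical())
  cuts_s <- c(no_variant$start, L); cuts_e <- c(no_variant$end, L)
  prev <- 0L
  segs <- list()
  add <- function(s, e, nv) {
    segs[[length(segs) + 1L]] <<- data.table::data.table(
      start = as.integer(s), end = as.integer(e), is_novar = nv)
  }
  chop <- function(a, b) {
    # split [a, b) into log-normal pieces of at least segment_min
    span <- b - a
    if (span <= 0) return(invisible())
    if (span < 2 * cfg$segment_min) { add(a, b, FALSE); return(invisible()) }
    meanlog <- log(cfg$segment_mean) - cfg$segment_sdlog^2 / 2
    pos <- a
    while (pos < b) {
      len <- max(cfg$segment_min,
                 round(stats::rlnorm(1, meanlog, cfg$segment_sdlog)))
      if (b - (pos + len) < cfg$segment_min) { add(pos, b, FALSE); break }
      add(pos, pos + len, FALSE)
      pos <- pos + len
    }
  }
  if (nrow(no_variant)) {
    for (j in seq_len(nrow(no_variant))) {
      chop(prev, no_variant$start[j])
      add(no_variant$start[j], no_variant$end[j], TRUE)
      prev <- no_variant$end[j]
    }
  }
  chop(prev, L)
  out <- data.table::rbindlist(segs)[order(start)]
  out[, segment_id := sprintf("s%05d", .I)]
  out[]
}

#' Contigize a parent's diploid genome
#'
#' Heterozygous segments (at least one het SNP) emit a bubble pair, one
#' contig per haplotype; segments without het SNPs emit a single non-bubble
#' contig.  A `nonbubble_mislabel_fraction` of bubble pairs is emitted with
#' assembler class `non_bubble` and no partner, emulating the assembler's
#' mixed non-bubble output that classification must fix.
#'
#' @param parent_label `"maternal"` or `"paternal"`.
#' @param segments Segment grid from the generator.
#' @param het_snps Parent's heterozygous SNP table.
#' @param cfg A [sim_config()].
#' @return `data.table` of contig records with truth columns `segment_id`,
#'   `haplotype` (0 = homozygous), `truth_zygosity`.
#' @export
contigize <- function(parent_label, segments, het_snps, cfg) {
  pfx <- if (parent_label == "maternal") "m" else "p"
  segs <- data.table::copy(segments)
  counts <- if (nrow(het_snps))
    het_snps[, list(n_snps = .N),
             by = list(segment_id = segment_of(pos, segments))]
  else data.table::data.table(segment_id = character(), n_snps = integer())
  segs <- merge(segs, counts, by = "segment_id", all.x = TRUE)
  segs[is.na(n_snps), n_snps := 0L]
  out <- vector("list", nrow(segs))
  for (i in seq_len(nrow(segs))) {
    s <- segs[i]
    len <- s$end - s$start
    if (s$is_novar || s$n_snps == 0L) {
      out[[i]] <- data.table::data.table(
        contig_id = sprintf("%s_%s_h0", pfx, s$segment_id),
        parent_of_origin = parent_label, assembler_class = "non_bubble",
        partner_id = NA_character_, length_bp = len,
        segment_id = s$segment_id, haplotype = 0L,
        truth_zygosity = "homozygous")
    } else {
      ids <- sprintf("%s_%s_h%d", pfx, s$segment_id, 1:2)
      mislabel <- stats::runif(1) < cfg$nonbubble_mislabel_fraction
      out[[i]] <- data.table::data.table(
        contig_id = ids, parent_of_origin = parent_label,
        assembler_class = if (mislabel) c("non_bubble", "non_bubble")
        else c("bubble_primary", "bubble_secondary"),
        partner_id = if (mislabel) c(NA_character_, NA_character_)
        else rev(ids),
        length_bp = len, segment_id = s$segment_id, haplotype = 1:2,
        truth_zygosity = "heterozygous")
    }
  }
  data.table::rbindlist(out)
}

# segment id of each genome position
segment_of <- function(pos, segments) {
  idx <- findInterval(pos, segments$start)
  segments$segment_id[idx]
}
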