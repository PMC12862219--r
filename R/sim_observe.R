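# Spiked mutations and observation-level simulation of variant calls.
# Replaces read simulation + alignment + calling: variant records are
# generated directly at truth sites (plus decoys exercising each filter),
# with depths taken from the simulated depth profiles.

sample_callable_positions <- function(cs, n) {
  iv <- cs$phased_intervals
  if (!nrow(iv) || n == 0) {
    return(data.table::data.table(contig_id = character(), pos = integer()))
  }
  w <- iv$end - iv$start
  out <- data.table::data.table(contig_id = character(0), pos = integer(0))
  tries <- 0L
  while (nrow(out) < n && tries < 50L) {
    tries <- tries + 1L
    need <- n - nrow(out)
    idx <- sample.int(nrow(iv), need, replace = TRUE, prob = w)
    pos <- iv$start[idx] + floor(stats::runif(need) * w[idx])
    out <- unique(rbind(out, data.table::data.table(
      contig_id = iv$contig_id[idx], pos = as.integer(pos))))
  }
  out[seq_len(min(n, nrow(out)))]
}

#' Spike DNMs and PZMs into a simulated pedigree
#'
#' DNMs are placed uniformly inside each offspring's phased callable
#' intervals (mirroring spike-in false-negative-rate experiments, which seed
#' mutations into callable regions); early-germline shared DNMs are placed
#' at a common position of a contig inherited by `shared_dnm_k` offspring;
#' PZMs get a true VAF drawn from the configured Beta.
#'
#' @param sim A `pedigree_sim`.
#' @param state A `haplodnm_pipeline` from [run_pipeline()].
#' @param dnm_per_offspring DNM spike count per offspring (default from the
#'   config); ignored when `dnm_rate` is given.
#' @param dnm_rate Optional per-base rate: each offspring's spike count is
#'   then Poisson with mean `dnm_rate * total callable bp`.
#' @param pzm_per_offspring PZM spike count per offspring.
#' @param shared_groups,shared_k Shared-DNM groups and carriers per group.
#' @return `data.table(type, offspring_id, contig_id, pos, ref, alt, origin,
#'   shared_group, true_vaf)`.
#' @export
spike_mutations <- function(sim, state,
                            dnm_per_offspring = sim$cfg$dnm_per_offspring,
                            dnm_rate = NULL,
                            pzm_per_offspring = sim$cfg$pzm_per_offspring,
                            shared_groups = sim$cfg$shared_dnm_groups,
                            shared_k = sim$cfg$shared_dnm_k,
                            offspring = sim$offspring_ids) {
  seqs <- sim$sequences
  org <- setNames(sim$contigs$parent_of_origin, sim$contigs$contig_id)
  base_at <- function(contig, pos) {
    substr(seqs[contig], pos + 1L, pos + 1L)
  }
  recs <- list()
  for (off in offspring) {
    cs <- state$callable[[off]]
    n_dnm <- if (!is.null(dnm_rate)) stats::rpois(1L, dnm_rate * cs$total_bp)
    else dnm_per_offspring
    p <- sample_callable_positions(cs, n_dnm)
    if (nrow(p) < n_dnm)
      stop("requested DNM spike count exceeds eligible positions")
    if (nrow(p)) {
      rb <- base_at(p$contig_id, p$pos)
      recs[[length(recs) + 1L]] <- data.table::data.table(
        type = "dnm", offspring_id = off, contig_id = p$contig_id,
        pos = p$pos, ref = rb, alt = other_base(rb),
        origin = unname(org[p$contig_id]), shared_group = NA_integer_,
        true_vaf = NA_real_)
    }
    q <- sample_callable_positions(cs, pzm_per_offspring)
    if (nrow(q)) {
      rb <- base_at(q$contig_id, q$pos)
      recs[[length(recs) + 1L]] <- data.table::data.table(
        type = "pzm", offspring_id = off, contig_id = q$contig_id,
        pos = q$pos, ref = rb, alt = other_base(rb),
        origin = unname(org[q$contig_id]), shared_group = NA_integer_,
        true_vaf = pmin(pmax(stats::rbeta(nrow(q), sim$cfg$pzm_vaf_shape1,
                                          sim$cfg$pzm_vaf_shape2),
                             0.03), 0.45))
    }
  }
  # early-germline shared DNMs: identical site in shared_k offspring
  if (shared_groups > 0 && shared_k >= 2 && length(offspring) >= shared_k) {
    for (g in seq_len(shared_groups)) {
      placed <- FALSE
      for (try in 1:100) {
        carriers <- sample(offspring, shared_k)
        common <- Reduce(intersect, lapply(carriers, function(o)
          unique(state$callable[[o]]$phased_intervals$contig_id)))
        if (!length(common)) next
        cid <- sample(common, 1L)
        ivs <- lapply(carriers, function(o) {
          a <- state$callable[[o]]$phased_intervals[contig_id == cid]
          IRanges::IRanges(a$start + 1L, a$end)
        })
        inter <- Reduce(IRanges::intersect, ivs)
        if (!length(inter)) next
        w <- IRanges::width(inter)
        k <- sample.int(length(inter), 1L, prob = w)
        pos <- IRanges::start(inter)[k] - 1L +
          floor(stats::runif(1) * w[k])
        rb <- base_at(cid, pos)
        ab <- other_base(rb)
        recs[[length(recs) + 1L]] <- data.table::data.table(
          type = "dnm", offspring_id = carriers, contig_id = cid,
          pos = as.integer(pos), ref = rb, alt = ab,
          origin = unname(org[cid]), shared_group = g, true_vaf = NA_real_)
        placed <- TRUE
        break
      }
      if (!placed)
        warning("could not place shared DNM group ", g)
    }
  }
  out <- data.table::rbindlist(recs)
  unique(out, by = c("type", "offspring_id", "contig_id", "pos"))
}

rnorm_qual <- function(n, mean, sd) {
  pmin(pmax(round(stats::rnorm(n, mean, sd)), 1), 255)
}

#' Simulate variant-call observations for every trio
#'
#' Generates flat observation tables from the spiked truth plus decoy
#' records exercising the INDEL-proximity, gene-conversion and
#' sibling-heterozygosity filters.  The pileup caller reports every site;
#' haplotype-caller records are emitted only on contigs in high
#' parental-similarity regions (where the pipeline discards pileup calls),
#' matching how such callers are deployed.
#'
#' @param sim A `pedigree_sim`.
#' @param state A `haplodnm_pipeline`.
#' @param spikes Truth table from [spike_mutations()].
#' @return List with `obs` (named list per offspring, flat tables),
#'   `cohort_geno`, `cohort_ad`, `conversion_mask`, and `indel_sites`.
#' @export
simulate_observations <- function(sim, state, spikes,
                                  offspring = sim$offspring_ids) {
  cfg <- sim$cfg
  seqs <- sim$sequences
  high_sim <- state$high_similarity_contigs
  obs <- list()
  conv_mask <- list()
  artifact <- list()
  cohort_ad <- list()
  for (off in offspring) {
    cs <- state$callable[[off]]
    sp <- spikes[offspring_id == off]
    rows <- list()
    mk_row <- function(contig, pos, ref, alt, gt, alt_reads = NULL,
                       is_indel = FALSE) {
      dpo <- depth_at(sim, off, contig, pos)
      dpm <- depth_at(sim, "mother", contig, pos)
      dpf <- depth_at(sim, "father", contig, pos)
      n <- length(contig)
      if (is.null(alt_reads)) {
        noise <- stats::rbinom(n, round(dpo), 0.01)
        alt_reads <- pmax(round(dpo) - noise, 0)
      }
      ref_reads <- pmax(round(dpo) - alt_reads, 0)
      alt_mo <- stats::rbinom(n, round(dpm), 0.002)
      alt_fa <- stats::rbinom(n, round(dpf), 0.002)
      data.table::data.table(
        contig_id = contig, pos = pos, ref = ref, alt = alt,
        qual = rnorm_qual(n, cfg$qual_mean, cfg$qual_sd),
        is_indel = is_indel, gt_off = gt, dp_off = round(dpo),
        ad_off = paste(ref_reads, alt_reads, sep = ","),
        gt_mo = "0/0", dp_mo = round(dpm),
        ad_mo = paste(pmax(round(dpm) - alt_mo, 0), alt_mo, sep = ","),
        gt_fa = "0/0", dp_fa = round(dpf),
        ad_fa = paste(pmax(round(dpf) - alt_fa, 0), alt_fa, sep = ","))
    }
    d <- sp[type == "dnm"]
    if (nrow(d)) rows$dnm <- mk_row(d$contig_id, d$pos, d$ref, d$alt, "1/1")
    z <- sp[type == "pzm"]
    if (nrow(z)) {
      dpo <- round(depth_at(sim, off, z$contig_id, z$pos))
      alt_reads <- stats::rbinom(nrow(z), dpo, pmin(2 * z$true_vaf, 1))
      keep <- alt_reads >= 2          # a caller would not report fewer
      if (any(keep)) {
        rows$pzm <- mk_row(z$contig_id[keep], z$pos[keep], z$ref[keep],
                           z$alt[keep], "0/1", alt_reads = alt_reads[keep])
      }
    }
    # INDEL decoys
    if (cfg$indel_decoys > 0) {
      p <- sample_callable_positions(cs, cfg$indel_decoys)
      p <- p[pos + 2L <= nchar(seqs[contig_id])]
      if (nrow(p)) {
        rr <- substr(seqs[p$contig_id], p$pos + 1L, p$pos + 2L)
        rows$indel <- mk_row(p$contig_id, p$pos, rr, substr(rr, 1, 1),
                             "0/1", is_indel = TRUE)
      }
    }
    # gene-conversion-like decoys (mask carries the positions)
    if (cfg$conversion_decoys > 0) {
      p <- sample_callable_positions(cs, cfg$conversion_decoys)
      if (nrow(p)) {
        rb <- substr(seqs[p$contig_id], p$pos + 1L, p$pos + 1L)
        rows$conv <- mk_row(p$contig_id, p$pos, rb, other_base(rb), "1/1")
        conv_mask[[off]] <- p
      }
    }
    # alignment-artifact sites: another offspring appears heterozygous
    if (cfg$artifact_het_sites > 0 && length(offspring) > 1) {
      p <- sample_callable_positions(cs, cfg$artifact_het_sites)
      if (nrow(p)) {
        rb <- substr(seqs[p$contig_id], p$pos + 1L, p$pos + 1L)
        rows$artifact <- mk_row(p$contig_id, p$pos, rb, other_base(rb),
                                "1/1")
        artifact[[off]] <- data.table::data.table(
          contig_id = p$contig_id, pos = p$pos,
          sample_id = sample(setdiff(offspring, off), nrow(p),
                             replace = TRUE))
      }
    }
    tab <- data.table::rbindlist(rows)
    if (!nrow(tab)) { obs[[off]] <- tab; next }
    pu <- data.table::copy(tab)[, caller := "caller_pileup"]
    hc <- data.table::copy(tab[contig_id %in% high_sim])
    hc[, caller := "caller_haplotype"]
    full <- data.table::rbindlist(list(pu, hc), use.names = TRUE)
    full[, site_id := .I]
    obs[[off]] <- full
    # cohort alternative-read support at this offspring's PZM sites
    if (nrow(z)) {
      others <- setdiff(sim$individuals, off)
      cohort_ad[[off]] <- data.table::rbindlist(lapply(others, function(s)
        data.table::data.table(contig_id = z$contig_id, pos = z$pos,
                               sample_id = s,
                               alt_reads = stats::rpois(nrow(z), 0.02))))
    }
  }
  # cohort genotypes at every candidate SNV site
  all_sites <- unique(data.table::rbindlist(lapply(
    offspring, function(o) {
      t <- obs[[o]]
      if (!nrow(t)) return(NULL)
      t[is_indel == FALSE, list(contig_id, pos)]
    })))
  geno <- list()
  if (nrow(all_sites)) {
    for (o in offspring) {
      g <- data.table::copy(all_sites)[, `:=`(sample_id = o, gt = "0/0")]
      own <- obs[[o]]
      if (nrow(own)) {
        # carriers show their own called genotype
        key <- paste(own$contig_id, own$pos)
        m <- match(paste(g$contig_id, g$pos), key)
        g[!is.na(m), gt := own$gt_off[m[!is.na(m)]]]
      }
      geno[[o]] <- g
    }
    geno <- data.table::rbindlist(geno)
    # artifact heterozygous carriers
    art <- data.table::rbindlist(artifact)
    if (length(artifact) && nrow(art)) {
      geno[art, on = c("contig_id", "pos", "sample_id"), gt := "0/1"]
    }
  } else {
    geno <- data.table::data.table(contig_id = character(), pos = integer(),
                                   sample_id = character(), gt = character())
  }
  mask <- if (length(conv_mask))
    unique(data.table::rbindlist(conv_mask))
  else data.table::data.table(contig_id = character(), pos = integer())
  list(obs = obs, cohort_geno = geno,
       cohort_ad = data.table::rbindlist(cohort_ad),
       conversion_mask = mask)
}

#' Run the DNM and PZM filters on simulated observations
#'
#' @param sim A `pedigree_sim`.
#' @param state A `haplodnm_pipeline`.
#' @param bundle Output of [simulate_observations()].
#' @param ... Threshold overrides passed to [dnm_filter()] / [pzm_filter()].
#' @return List with pooled `dnms` (shared groups annotated), `pzms`, and
#'   per-offspring `rejects`.
#' @export
detect_mutations <- function(sim, state, bundle, run_pzm = TRUE, ...) {
  contigs <- sim$contigs
  dnms <- list(); pzms <- list(); rejects <- list()
  for (off in names(bundle$obs)) {
    o <- bundle$obs[[off]]
    if (is.null(o) || !nrow(o)) next
    merged <- merge_caller_calls(o[caller == "caller_pileup"],
                                 o[caller == "caller_haplotype"],
                                 state$high_similarity_contigs)
    cs <- state$callable[[off]]
    ind <- indel_positions(merged)
    dn <- dnm_filter(merged, cs, contigs, off,
                     cohort_geno = bundle$cohort_geno,
                     indels = ind, conversion_mask = bundle$conversion_mask,
                     ...)
    if (run_pzm) {
      track <- make_depth_track(sim, off)
      pz <- pzm_filter(merged, cs, contigs, off,
                       counterpart = state$counterpart[[off]],
                       depth_track = track,
                       cohort_ad = bundle$cohort_ad,
                       indels = ind, conversion_mask = bundle$conversion_mask)
      pzms[[off]] <- pz$pzms
    }
    dnms[[off]] <- dn$dnms
    rejects[[off]] <- dn$rejects
  }
  list(dnms = group_shared_dnms(data.table::rbindlist(dnms)),
       pzms = data.table::rbindlist(pzms),
       rejects = rejects)
}
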