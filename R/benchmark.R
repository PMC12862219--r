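# Benchmark harnesses: classification accuracy, inheritance error, spike-in
# false-negative rate, and mutation-rate recovery, all scored against the
# generator's truth records.

#' Spike-in false-negative rate of the DNM detection pipeline
#'
#' Spikes a known number of DNMs into the callable regions of a few
#' offspring, regenerates observations, reruns the filters, and reports
#' `FNR = 1 - detected/spiked`.
#'
#' @param sim A `pedigree_sim`.
#' @param state A `haplodnm_pipeline`.
#' @param n_per_offspring Spiked DNMs per selected offspring (default 200).
#' @param offspring Offspring used (default: up to the first three).
#' @return List with `fnr`, `n_detected`, `n_spiked`, and `per_offspring`.
#' @export
fnr_harness <- function(sim, state, n_per_offspring = 200,
                        offspring = head(sim$offspring_ids, 3)) {
  spikes <- spike_mutations(sim, state,
                            dnm_per_offspring = n_per_offspring,
                            pzm_per_offspring = 0, shared_groups = 0,
                            offspring = offspring)
  bundle <- simulate_observations(sim, state, spikes, offspring = offspring)
  # spike densities are far above realistic per-contig mutation counts, so
  # the clustered-candidate review cap is disabled in the harness
  det <- detect_mutations(sim, state, bundle, run_pzm = FALSE,
                          contig_cap = Inf)
  truth <- spikes[type == "dnm"]
  hit <- det$dnms[truth,
                  on = c("offspring_id", "contig_id", "pos",
                         alt_base = "alt"), nomatch = 0L]
  per <- truth[, list(n_spiked = .N), by = offspring_id]
  per_hit <- hit[, list(n_detected = .N), by = offspring_id]
  per <- merge(per, per_hit, by = "offspring_id", all.x = TRUE)
  per[is.na(n_detected), n_detected := 0L]
  list(fnr = false_negative_rate(nrow(hit), nrow(truth)),
       n_detected = nrow(hit), n_spiked = nrow(truth),
       per_offspring = per[])
}

#' Closed-form expectation of each offspring's callable size
#'
#' Conditional on the realized transmission and truth labels: a homozygous
#' segment contributes one trimmed contig per parent; a heterozygous
#' non-shared segment contributes the trimmed inherited allele per parent;
#' shared-haplotype segments follow the similar-pair rules (both shared
#' alleles inherited: dropped; one: half-length unphased plus the other
#' parent's trimmed allele; neither: two trimmed alleles).  Depth-cap and
#' classification-noise losses are not modeled, so realized values sit
#' slightly below (within a couple of percent of) this expectation.
#'
#' @param sim A `pedigree_sim`.
#' @param end_trim Trim used by the callable computation (default 100).
#' @return `data.table(offspring_id, expected_bp)`.
#' @export
callable_expectation <- function(sim, end_trim = 100) {
  segs <- data.table::copy(sim$segments)
  segs[, len := end - start]
  het_m <- sim$contigs[parent_of_origin == "maternal" &
                         truth_zygosity == "heterozygous",
                       unique(segment_id)]
  het_p <- sim$contigs[parent_of_origin == "paternal" &
                         truth_zygosity == "heterozygous",
                       unique(segment_id)]
  tr <- data.table::dcast(sim$transmission,
                          offspring_id + segment_id ~ parent,
                          value.var = "inherited_hap")
  tr <- merge(tr, segs[, list(segment_id, len)], by = "segment_id")
  tr[, `:=`(m_het = segment_id %in% het_m, p_het = segment_id %in% het_p,
            shared = segment_id %in% sim$shared_segments)]
  trim2 <- 2 * end_trim
  tr[, bp := {
    t_len <- pmax(len - trim2, 0)
    no_shared <- 2 * t_len
    sh <- ifelse(maternal == 1 & paternal == 1, 0,
          ifelse(maternal == 2 & paternal == 2, 2 * t_len,
                 floor(len / 2) + t_len))
    ifelse(shared & m_het & p_het, sh, no_shared)
  }]
  tr[, list(expected_bp = sum(bp)), by = offspring_id]
}

#' Score zygosity classification against generator truth
#'
#' Accuracy over the assembler's non-bubble contigs: truth-heterozygous
#' contigs should be classified `bubble_like`, truth-homozygous ones
#' `true_non_bubble`; anything else (including `uncertain`) counts as an
#' error.
#'
#' @param sim A `pedigree_sim`.
#' @param state A `haplodnm_pipeline`.
#' @return Fraction in \[0, 1\].
#' @export
classification_accuracy <- function(sim, state) {
  nb <- sim$contigs[assembler_class == "non_bubble"]
  zc <- state$zygosity[match(nb$contig_id, contig_id)]
  expect_cat <- ifelse(nb$truth_zygosity == "heterozygous", "bubble_like",
                       "true_non_bubble")
  mean(zc$category == expect_cat)
}

#' Score inheritance inference against generator truth
#'
#' @param sim A `pedigree_sim`.
#' @param state A `haplodnm_pipeline`.
#' @return List with `error_rate` (fraction of resolved calls whose
#'   inherited/not-inherited state disagrees with the transmission truth)
#'   and `unresolved_fraction`.
#' @export
inheritance_error <- function(sim, state) {
  truth <- truth_inheritance(sim)
  cmp <- merge(state$calls, truth, by = c("offspring_id", "contig_id"))
  resolved <- cmp[state %in% c("inherited", "not_inherited")]
  list(error_rate = mean(resolved$state != resolved$truth_state),
       unresolved_fraction = mean(cmp$state == "unresolved"))
}

#' End-to-end benchmark of the pipeline against generator truth
#'
#' Generates a pedigree, runs classification, inheritance, callable-genome
#' determination, the spike-in FNR harness, and mutation detection, scoring
#' each stage against the truth records.
#'
#' @param cfg A [sim_config()].
#' @param fnr_spikes Spiked DNMs per offspring in the FNR harness.
#' @return List of class `haplodnm_benchmark`; key fields:
#'   `classification_accuracy` (non-bubble contigs vs truth zygosity),
#'   `positive_control` (fraction of assembler bubbles re-labeled
#'   heterozygous), `inheritance_error_rate` (resolved calls vs truth),
#'   `unresolved_fraction`, `callable_fraction` (of the diploid genome),
#'   `fnr`, `dnm_detection`, `pzm_detection`, plus the underlying `sim`,
#'   `state`, `spikes` and `detected` objects.
#' @export
run_benchmarks <- function(cfg, fnr_spikes = 200) {
  sim <- simulate_pedigree(cfg)
  state <- run_pipeline(sim)
  cls_acc <- classification_accuracy(sim, state)
  # internal positive control, per parent
  pc <- vapply(c("maternal", "paternal"), function(p) {
    ind <- if (p == "maternal") "mother" else "father"
    cc <- sim$contigs[parent_of_origin == p]
    md <- contig_means_from_bins(sim, ind)[contig_id %in% cc$contig_id]
    lens <- setNames(as.numeric(cc$length_bp), cc$contig_id)
    rbh <- rbh_pairs(sim$self_paf[[p]], lens)
    positive_control_fraction(cc, md, rbh,
                              default_thresholds(sim$cfg$depth_mean))
  }, numeric(1))
  inh <- inheritance_error(sim, state)
  # callable
  csum <- callable_summary(state$callable)
  callable_fraction <- mean(csum$total_bp) / (2 * cfg$genome_length)
  # spike-in FNR
  fnr <- fnr_harness(sim, state, n_per_offspring = fnr_spikes)
  # default mutation spiking + detection
  spikes <- spike_mutations(sim, state)
  bundle <- simulate_observations(sim, state, spikes)
  detected <- detect_mutations(sim, state, bundle, contig_cap = Inf)
  td <- spikes[type == "dnm"]
  hit_d <- detected$dnms[td, on = c("offspring_id", "contig_id", "pos",
                                    alt_base = "alt"), nomatch = 0L]
  tz <- spikes[type == "pzm"]
  hit_z <- detected$pzms[tz, on = c("offspring_id", "contig_id", "pos",
                                    alt_base = "alt"), nomatch = 0L]
  structure(list(
    seed = cfg$seed,
    classification_accuracy = cls_acc,
    positive_control = pc,
    inheritance_error_rate = inh$error_rate,
    unresolved_fraction = inh$unresolved_fraction,
    callable = csum, callable_fraction = callable_fraction,
    fnr = fnr$fnr, fnr_detail = fnr,
    dnm_detection = list(n_spiked = nrow(td), n_detected = nrow(hit_d),
                         fraction = if (nrow(td)) nrow(hit_d) / nrow(td)
                         else NA_real_),
    pzm_detection = list(
      n_spiked = nrow(tz), n_detected = nrow(hit_z),
      fraction = if (nrow(tz)) nrow(hit_z) / nrow(tz) else NA_real_,
      mean_abs_vaf_error = if (nrow(hit_z))
        mean(abs(hit_z$vaf - hit_z$true_vaf)) else NA_real_),
    sim = sim, state = state, spikes = spikes, detected = detected),
    class = "haplodnm_benchmark")
}

#' @export
print.haplodnm_benchmark <- function(x, ...) {
  cat("pedigree benchmark (seed ", x$seed, ")\n", sep = "")
  cat(sprintf("  non-bubble classification accuracy: %.3f\n",
              x$classification_accuracy))
  cat(sprintf("  positive control (bubble re-het):   %.3f / %.3f\n",
              x$positive_control[1], x$positive_control[2]))
  cat(sprintf("  inheritance error rate:             %.4f\n",
              x$inheritance_error_rate))
  cat(sprintf("  unresolved contig fraction:         %.4f\n",
              x$unresolved_fraction))
  cat(sprintf("  mean callable / diploid genome:     %.3f\n",
              x$callable_fraction))
  cat(sprintf("  spike-in FNR:                       %.4f\n", x$fnr))
  cat(sprintf("  DNM detection: %d/%d   PZM detection: %d/%d\n",
              x$dnm_detection$n_detected, x$dnm_detection$n_spiked,
              x$pzm_detection$n_detected, x$pzm_detection$n_spiked))
  invisible(x)
}

#' Mutation-rate recovery across repeated spike replicates
#'
#' Holds the pedigree, inheritance and callable sets fixed and replicates
#' the mutation layer: each replicate spikes DNMs at true rate `mu_star`
#' (Poisson per offspring over callable size), regenerates observations,
#' reruns detection, and estimates the rate with [mutation_rate()] using a
#' fixed FNR estimated once by the spike-in harness.  Reports per-replicate
#' estimates and the fraction of replicates whose CI covers `mu_star`.
#'
#' @param sim,state Pedigree and pipeline state.
#' @param mu_star True spiking rate (per base per generation).
#' @param n_reps Number of replicates (default 100).
#' @param fnr Optional fixed FNR; estimated via [fnr_harness()] when NULL.
#' @return List with `coverage`, `fnr`, and `replicates`
#'   (`data.table(rep, n_detected, mu_hat, ci_low, ci_high, covered)`).
#' @export
mu_recovery <- function(sim, state, mu_star = 1e-6, n_reps = 100,
                        fnr = NULL) {
  if (is.null(fnr)) fnr <- fnr_harness(sim, state)$fnr
  total_bp <- sum(callable_summary(state$callable)$total_bp)
  out <- vector("list", n_reps)
  for (r in seq_len(n_reps)) {
    spikes <- spike_mutations(sim, state, dnm_rate = mu_star,
                              pzm_per_offspring = 0, shared_groups = 0)
    bundle <- simulate_observations(sim, state, spikes)
    det <- detect_mutations(sim, state, bundle, run_pzm = FALSE,
                            contig_cap = Inf)
    n_det <- nrow(det$dnms)
    est <- mutation_rate(n_det, total_bp, fnr)
    out[[r]] <- data.table::data.table(
      rep = r, n_detected = n_det, mu_hat = est$mu,
      ci_low = est$ci_low, ci_high = est$ci_high,
      covered = est$ci_low <= mu_star && mu_star <= est$ci_high)
  }
  reps <- data.table::rbindlist(out)
  list(coverage = mean(reps$covered), fnr = fnr, mu_star = mu_star,
       replicates = reps)
}
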