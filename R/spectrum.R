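# Folded mutation spectrum, CpG handling, and annotation-context rates.

COMP <- c(A = "T", C = "G", G = "C", T = "A")
SPECTRUM_CLASSES <- c("A>C", "A>T", "A>G", "C>A", "C>G", "C>T", "CpG>TpG")

#' Folded substitution class of a single-base mutation
#'
#' Classes are folded to an A- or C-reference convention (e.g. `T>G` is
#' reported as `A>C`).  A `C>T` change whose right neighbor is `G` -- or the
#' folded equivalent, `G>A` with left neighbor `C` -- is the special class
#' `CpG>TpG`.
#'
#' @param ref,alt Reference and alternative bases.
#' @param left_base,right_base Flanking bases from the contig sequence (use
#'   `"N"` at contig ends).
#' @return Character vector of class labels (one of
#'   `A>C, A>T, A>G, C>A, C>G, C>T, CpG>TpG`).
#' @export
substitution_class <- function(ref, alt, left_base, right_base) {
  n <- length(ref)
  stopifnot(length(alt) == n, length(left_base) == n, length(right_base) == n)
  ref <- toupper(ref); alt <- toupper(alt)
  left_base <- toupper(left_base); right_base <- toupper(right_base)
  if (!all(ref %in% names(COMP)) || !all(alt %in% names(COMP)))
    stop("non-ACGT base in ref/alt")
  if (any(ref == alt)) stop("ref and alt must differ")
  fold <- ref %in% c("G", "T")
  fr <- ifelse(fold, COMP[ref], ref)
  fa <- ifelse(fold, COMP[alt], alt)
  cls <- paste0(fr, ">", fa)
  cpg <- (ref == "C" & alt == "T" & right_base == "G") |
    (ref == "G" & alt == "A" & left_base == "C")
  cls[cls == "C>T" & cpg] <- "CpG>TpG"
  unname(cls)
}

#' Annotate DNM/PZM records with substitution classes
#'
#' Looks up the flanking bases in the contig sequences.
#'
#' @param records DNM or PZM table with `contig_id, pos, ref_base, alt_base`.
#' @param sequences Named character vector of contig sequences.
#' @return The records with a `substitution_class` column.
#' @export
annotate_substitution_class <- function(records, sequences) {
  r <- data.table::copy(records)
  if (!nrow(r)) { r[, substitution_class := character(0)]; return(r[]) }
  p1 <- r$pos + 1L  # 1-based within the sequence
  seq_at <- function(off) {
    s <- substr(sequences[r$contig_id], p1 + off, p1 + off)
    ifelse(is.na(s) | s == "", "N", s)
  }
  left <- seq_at(-1L); right <- seq_at(1L)
  left[left == ""] <- "N"; right[right == ""] <- "N"
  # unknown flanks cannot form a CpG; substitute a non-G/C placeholder
  left[!left %in% names(COMP)] <- "N"
  right[!right %in% names(COMP)] <- "N"
  left[left == "N"] <- "A"; right[right == "N"] <- "A"
  r[, substitution_class := substitution_class(ref_base, alt_base,
                                               left, right)]
  r[]
}

#' Mutation spectrum table
#'
#' Counts and proportions over the seven folded classes, with
#' Clopper-Pearson CIs on the proportions.
#'
#' @param records Records carrying a `substitution_class` column.
#' @param conf_level Confidence level for the proportion CIs.
#' @return `data.table(substitution_class, n, proportion, ci_low, ci_high)`
#'   covering all seven classes (zero rows included).
#' @export
spectrum_table <- function(records, conf_level = 0.95) {
  counts <- as.integer(table(factor(records$substitution_class,
                                    levels = SPECTRUM_CLASSES)))
  total <- sum(counts)
  a <- 1 - conf_level
  out <- data.table::data.table(substitution_class = SPECTRUM_CLASSES,
                                n = counts)
  if (total > 0) {
    out$proportion <- counts / total
    out$ci_low <- ifelse(counts == 0, 0,
                         stats::qbeta(a / 2, counts, total - counts + 1))
    out$ci_high <- ifelse(counts == total, 1,
                          stats::qbeta(1 - a / 2, counts + 1, total - counts))
  } else {
    out[, `:=`(proportion = NA_real_, ci_low = NA_real_, ci_high = NA_real_)]
  }
  out[]
}

#' Project reference annotation contexts onto contigs through PAF alignments
#'
#' Block-wise linear coordinate transfer: each PAF record maps its target
#' (reference) span onto its query (contig) span; reference context
#' intervals (exonic/intronic/intergenic, non-overlapping) are intersected
#' with the target span and carried over.  Contig spans with no alignment
#' stay `unannotated`.
#'
#' @param paf Contig-to-reference PAF (primary alignments only).
#' @param ref_contexts `data.table(contig_id, start, end, context)` on the
#'   reference, non-overlapping (checked).
#' @param contig_lengths Named vector of contig lengths.
#' @return `data.table(contig_id, start, end, context)` on contig
#'   coordinates, tiling each contig (gaps filled with `unannotated`).
#' @export
project_annotation <- function(paf, ref_contexts, contig_lengths) {
  # overlapping reference contexts are a configuration error
  ov <- ref_contexts[order(contig_id, start),
                     list(bad = any(start[-1] < end[-.N])), by = contig_id]
  if (nrow(ov) && any(ov$bad)) stop("overlapping reference context intervals")
  pieces <- vector("list", nrow(paf))
  for (i in seq_len(nrow(paf))) {
    rec <- paf[i]
    ctx <- ref_contexts[contig_id == rec$tname & start < rec$tend &
                          end > rec$tstart]
    if (!nrow(ctx)) next
    s <- pmax(ctx$start, rec$tstart); e <- pmin(ctx$end, rec$tend)
    if (rec$strand == "+") {
      qs <- rec$qstart + (s - rec$tstart)
      qe <- rec$qstart + (e - rec$tstart)
    } else {
      qs <- rec$qend - (e - rec$tstart)
      qe <- rec$qend - (s - rec$tstart)
    }
    pieces[[i]] <- data.table::data.table(contig_id = rec$qname, start = qs,
                                          end = qe, context = ctx$context)
  }
  mapped <- data.table::rbindlist(pieces)
  fill_unannotated(mapped, contig_lengths)
}

fill_unannotated <- function(mapped, contig_lengths) {
  out <- vector("list", length(contig_lengths))
  for (i in seq_along(contig_lengths)) {
    cid <- names(contig_lengths)[i]
    len <- contig_lengths[[i]]
    m <- if (nrow(mapped)) mapped[contig_id == cid][order(start)]
    else mapped
    if (!nrow(m)) {
      out[[i]] <- data.table::data.table(contig_id = cid, start = 0,
                                         end = len, context = "unannotated")
      next
    }
    gaps_s <- c(0, m$end); gaps_e <- c(m$start, len)
    g <- data.table::data.table(contig_id = cid, start = gaps_s,
                                end = gaps_e, context = "unannotated")
    g <- g[end > start]
    out[[i]] <- rbind(m, g)[order(start)]
  }
  data.table::rbindlist(out)
}

#' Context of single positions under a projected annotation
#' @param context_map Output of [project_annotation()].
#' @param contig,pos Position vectors (0-based).
#' @return Character vector of contexts (`unannotated` when unmapped).
#' @export
context_at <- function(context_map, contig, pos) {
  dt <- data.table::data.table(contig_id = contig, pos = pos,
                               i = seq_along(contig))
  m <- context_map[dt, on = list(contig_id, start <= pos, end > pos),
                   nomatch = NA, mult = "first"]
  res <- m$context[order(m$i)]
  res[is.na(res)] <- "unannotated"
  res
}

#' Per-context mutation rates
#'
#' Rate per context = DNMs in context / (callable bp in context * (1 - FNR)),
#' with a chi-square test of homogeneity of counts against callable-bp
#' expectations.
#'
#' @param dnms DNM records.
#' @param callable_list List of per-offspring `callable_set` objects.
#' @param context_map Output of [project_annotation()].
#' @param fnr False-negative rate applied to every context.
#' @return List with `table` (`context, n_dnm, callable_bp, rate`) and
#'   `chisq_p` (NA when untestable).
#' @export
context_rates <- function(dnms, callable_list, context_map, fnr = 0) {
  ctx_of_dnm <- context_at(context_map, dnms$contig_id, dnms$pos)
  cnt <- data.table::data.table(context = ctx_of_dnm)[, .N, by = context]
  bp <- callable_context_bp(callable_list, context_map)
  tab <- merge(bp, cnt, by = "context", all.x = TRUE)
  tab[is.na(N), N := 0L]
  data.table::setnames(tab, "N", "n_dnm")
  tab[, rate := ifelse(bp > 0, n_dnm / (bp * (1 - fnr)), NA_real_)]
  testable <- tab[bp > 0]
  chisq_p <- if (nrow(testable) >= 2 && sum(testable$n_dnm) > 0) {
    suppressWarnings(stats::chisq.test(
      testable$n_dnm, p = testable$bp / sum(testable$bp))$p.value)
  } else NA_real_
  list(table = tab[, list(context, n_dnm, callable_bp = bp, rate)],
       chisq_p = chisq_p)
}

# callable bp per context, summed over offspring (phased intervals only;
# unphased contigs have no resolved haplotype and are left out of
# context-specific denominators)
callable_context_bp <- function(callable_list, context_map) {
  acc <- list()
  for (cs in callable_list) {
    iv <- cs$phased_intervals
    if (!nrow(iv)) next
    for (cid in unique(iv$contig_id)) {
      a <- iv[contig_id == cid]
      b <- context_map[contig_id == cid]
      ra <- IRanges::IRanges(a$start + 1L, a$end)
      for (ctx in unique(b$context)) {
        rb <- IRanges::reduce(IRanges::IRanges(b[context == ctx]$start + 1L,
                                               b[context == ctx]$end))
        w <- sum(IRanges::width(IRanges::intersect(ra, rb)))
        if (w > 0) {
          key <- ctx
          acc[[key]] <- (if (is.null(acc[[key]])) 0 else acc[[key]]) + w
        }
      }
    }
  }
  if (!length(acc)) {
    return(data.table::data.table(context = character(), bp = numeric()))
  }
  data.table::data.table(context = names(acc), bp = unlist(acc))
}
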