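# Independent oracles used across tests; deliberately literal/brute-force
# implementations, kept separate from the package's code paths.

# literal transcription of the weighted cosine/Jaccard definition
bf_similarity <- function(u, v) {
  b <- length(u)
  nz_idx <- which(u > 0 & v > 0)
  z_idx <- setdiff(seq_len(b), nz_idx)
  cos_p <- if (length(nz_idx) > 0) {
    num <- 0; du <- 0; dv <- 0
    for (i in nz_idx) {
      num <- num + u[i] * v[i]; du <- du + u[i]^2; dv <- dv + v[i]^2
    }
    num / (sqrt(du) * sqrt(dv))
  } else 1
  jac_p <- if (length(z_idx) > 0) {
    both0 <- sum(u[z_idx] == 0 & v[z_idx] == 0)
    both0 / length(z_idx)
  } else 1
  (length(nz_idx) / b) * cos_p + (length(z_idx) / b) * jac_p
}

# brute-force RBH: per unordered pair aggregate blocks, filter, take best
# hits by total matches, keep mutual ones
bf_rbh <- function(paf, lens, min_cov = 0.7, min_id = 0.7) {
  paf <- paf[paf$qname != paf$tname, ]
  if (!nrow(paf)) return(list())
  key <- ifelse(paf$qname < paf$tname,
                paste(paf$qname, paf$tname), paste(paf$tname, paf$qname))
  stats <- list()
  for (k in unique(key)) {
    rows <- paf[key == k, ]
    ids <- sort(c(rows$qname[1], rows$tname[1]))
    span_of <- function(cid) {
      s <- c(rows$qstart[rows$qname == cid], rows$tstart[rows$tname == cid])
      e <- c(rows$qend[rows$qname == cid], rows$tend[rows$tname == cid])
      cov <- rep(FALSE, lens[[cid]])
      for (i in seq_along(s)) cov[(s[i] + 1):e[i]] <- TRUE
      sum(cov)
    }
    cov <- min(span_of(ids[1]) / lens[[ids[1]]],
               span_of(ids[2]) / lens[[ids[2]]])
    idy <- sum(rows$n_matches) / sum(rows$block_len)
    stats[[k]] <- list(ids = ids, cov = cov, idy = idy,
                       nm = sum(rows$n_matches))
  }
  qual <- Filter(function(x) x$cov >= min_cov && x$idy >= min_id, stats)
  if (!length(qual)) return(list())
  all_ids <- unique(unlist(lapply(qual, `[[`, "ids")))
  best <- setNames(rep(NA_character_, length(all_ids)), all_ids)
  for (cid in all_ids) {
    mine <- Filter(function(x) cid %in% x$ids, qual)
    nm <- vapply(mine, `[[`, numeric(1), "nm")
    if (sum(nm == max(nm)) == 1L) {
      pair <- mine[[which.max(nm)]]
      best[cid] <- setdiff(pair$ids, cid)
    }
  }
  out <- list()
  for (cid in all_ids) {
    p <- best[[cid]]
    if (!is.na(p) && !is.na(best[[p]]) && best[[p]] == cid && cid < p)
      out[[length(out) + 1L]] <- c(cid, p)
  }
  out
}

# exact hypergeometric two-sided p for a 2x2 table (fisher oracle)
bf_fisher_p <- function(tab) {
  m <- sum(tab[1, ]); n <- sum(tab[2, ]); k <- sum(tab[, 1])
  x <- tab[1, 1]
  supp <- max(0, k - n):min(k, m)
  d <- dhyper(supp, m, n, k)
  sum(d[d <= dhyper(x, m, n, k) * (1 + 1e-7)])
}

# per-base annotation liftover oracle
bf_context_at <- function(paf, ref_ctx, contig, pos) {
  for (i in seq_len(nrow(paf))) {
    r <- paf[i, ]
    if (r$qname != contig) next
    if (pos < r$qstart || pos >= r$qend) next
    tp <- if (r$strand == "+") r$tstart + (pos - r$qstart)
    else r$tend - 1 - (pos - r$qstart)
    hit <- ref_ctx[ref_ctx$contig_id == r$tname & ref_ctx$start <= tp &
                     ref_ctx$end > tp, ]
    if (nrow(hit)) return(hit$context[1])
  }
  "unannotated"
}
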