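# Readers and writers for the plain-text formats the pipeline touches.
# Internal coordinates are 0-based half-open; VCF (1-based) is converted on
# read and write, and is the only 1-based surface.

#' Read a FASTA file into a named character vector
#'
#' Thin wrapper over [Biostrings::readDNAStringSet()] that returns plain
#' uppercase character strings keyed by the first whitespace-delimited token
#' of each header.
#'
#' @param path Path to a FASTA file.
#' @return Named character vector of uppercase sequences.  An empty file
#'   yields an empty vector with a warning.  Duplicate IDs are an error.
#' @export
read_fasta <- function(path) {
  stopifnot(file.exists(path))
  if (file.size(path) == 0L) {
    warning("empty FASTA file: ", path)
    return(setNames(character(0), character(0)))
  }
  ss <- Biostrings::readDNAStringSet(path)
  ids <- sub("\\s.*$", "", names(ss))
  if (anyDuplicated(ids))
    stop("duplicate FASTA IDs in ", path, ": ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  setNames(toupper(as.character(ss)), ids)
}

#' Write sequences to a FASTA file
#'
#' @param seqs Named character vector of sequences.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_fasta <- function(seqs, path) {
  ss <- Biostrings::DNAStringSet(seqs)
  names(ss) <- names(seqs)
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}

#' Read a PAF alignment file
#'
#' Parses the 12 mandatory minimap2 PAF columns; optional SAM-style tags are
#' ignored.  Coordinates stay 0-based half-open as in the file.
#'
#' @param path Path to a PAF file (plain text).
#' @param min_mapq Records with mapping quality below this are dropped.
#' @return `data.table` with columns `qname, qlen, qstart, qend, strand,
#'   tname, tlen, tstart, tend, n_matches, block_len, mapq`.
#' @export
read_paf <- function(path, min_mapq = 0) {
  stopifnot(file.exists(path))
  cols <- c("qname", "qlen", "qstart", "qend", "strand", "tname", "tlen",
            "tstart", "tend", "n_matches", "block_len", "mapq")
  if (file.size(path) == 0L) return(empty_paf())
  dt <- data.table::fread(path, header = FALSE, sep = "\t", fill = TRUE,
                          colClasses = list(character = c(1, 5, 6)))
  if (ncol(dt) < 12L)
    stop("PAF file ", path, " has fewer than 12 columns")
  dt <- dt[, 1:12]
  data.table::setnames(dt, cols)
  num <- setdiff(cols, c("qname", "strand", "tname"))
  for (cn in num) {
    v <- suppressWarnings(as.numeric(dt[[cn]]))
    if (anyNA(v))
      stop("malformed PAF line ", which(is.na(v))[1], " in ", path,
           " (non-numeric ", cn, ")")
    data.table::set(dt, j = cn, value = v)
  }
  bad <- dt[!(qstart >= 0 & qstart < qend & qend <= qlen &
              tstart >= 0 & tstart < tend & tend <= tlen &
              n_matches <= block_len), which = TRUE]
  if (length(bad))
    stop("malformed PAF line ", bad[1], " in ", path, " (coordinate check)")
  dt[mapq >= min_mapq]
}

empty_paf <- function() {
  data.table::data.table(
    qname = character(), qlen = numeric(), qstart = numeric(),
    qend = numeric(), strand = character(), tname = character(),
    tlen = numeric(), tstart = numeric(), tend = numeric(),
    n_matches = numeric(), block_len = numeric(), mapq = numeric())
}

#' Write PAF records
#' @param paf `data.table` as returned by [read_paf()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_paf <- function(paf, path) {
  data.table::fwrite(paf, path, sep = "\t", col.names = FALSE)
  invisible(path)
}

#' Read a per-base depth BED (mosdepth-style)
#'
#' Four columns: contig, start, end, depth; 0-based half-open run-length
#' intervals.  Intervals per contig must be sorted, non-overlapping, and --
#' when `contig_lengths` is supplied -- tile the contig exactly.
#'
#' @param path Path to the BED file.
#' @param contig_lengths Optional named vector of contig lengths used to
#'   verify that the runs tile each contig; a gap or overlap is an error
#'   naming the contig.
#' @param individual_id Optional label stored in an `individual_id` column.
#' @return `data.table(contig_id, start, end, depth)` (run-length encoded).
#' @export
read_depth_bed <- function(path, contig_lengths = NULL, individual_id = NULL) {
  stopifnot(file.exists(path))
  dt <- data.table::fread(path, header = FALSE, sep = "\t",
                          col.names = c("contig_id", "start", "end", "depth"),
                          colClasses = list(character = 1))
  validate_depth_track(dt, contig_lengths)
  if (!is.null(individual_id)) dt[, individual_id := individual_id]
  dt[]
}

validate_depth_track <- function(dt, contig_lengths = NULL) {
  if (any(dt$depth < 0)) stop("negative depth values")
  bad <- dt[, {
    o <- order(start)
    s <- start[o]; e <- end[o]
    gap <- length(s) && (any(s[-1] != e[-length(e)]))
    list(ok = !gap && all(e > s))
  }, by = contig_id][ok == FALSE, contig_id]
  if (length(bad))
    stop("depth intervals do not tile contig(s): ",
         paste(head(bad, 5), collapse = ", "))
  if (!is.null(contig_lengths)) {
    cov <- dt[, list(lo = min(start), hi = max(end)), by = contig_id]
    cov[, len := as.numeric(contig_lengths[contig_id])]
    bad <- cov[is.na(len) | lo != 0 | hi != len, contig_id]
    if (length(bad))
      stop("depth track does not span contig(s): ",
           paste(head(bad, 5), collapse = ", "))
  }
  invisible(TRUE)
}

#' Write a depth track as a 4-column BED
#' @param track `data.table(contig_id, start, end, depth)`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_depth_bed <- function(track, path) {
  data.table::fwrite(track[, list(contig_id, start, end, depth)], path,
                     sep = "\t", col.names = FALSE)
  invisible(path)
}

#' Expand a run-length depth track to per-base values
#'
#' @param track Depth `data.table` (one or more contigs).
#' @param contig Contig to expand.
#' @param len Optional expected length (checked).
#' @return Numeric vector of per-base depths.
#' @export
expand_depth <- function(track, contig, len = NULL) {
  tr <- track[contig_id == contig][order(start)]
  if (!nrow(tr)) stop("no depth runs for contig ", contig)
  v <- rep(tr$depth, tr$end - tr$start)
  if (!is.null(len) && length(v) != len)
    stop("depth track for ", contig, " covers ", length(v),
         " bp, expected ", len)
  v
}

#' Read a trio (or cohort) VCF
#'
#' Uses [vcfR::read.vcfR()] and returns a site table plus a long genotype
#' table.  Positions are converted to 0-based.  Multi-allelic sites are kept
#' unsplit (comma-separated ALT).  Missing DP/AD are returned as `NA` so that
#' downstream filters can reject the records.
#'
#' @param path Path to a plain-text VCF 4.x file.
#' @param caller_tag Label recorded in the `caller` column, e.g.
#'   `"caller_pileup"` (bcftools-style) or `"caller_haplotype"`
#'   (haplotype/freebayes-style).
#' @return List with elements `sites` (`site_id, contig_id, pos, ref, alt,
#'   qual, caller, is_indel`) and `geno` (`site_id, sample_id, gt, dp, ad`);
#'   `ad` is the comma-joined per-allele depth string.
#' @export
read_trio_vcf <- function(path, caller_tag) {
  stopifnot(file.exists(path))
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  n <- nrow(fix)
  sites <- data.table::data.table(
    site_id = seq_len(max(n, 0L)),
    contig_id = fix$CHROM,
    pos = as.integer(fix$POS) - 1L,
    ref = fix$REF,
    alt = fix$ALT,
    qual = suppressWarnings(as.numeric(fix$QUAL)),
    caller = caller_tag)
  sites[, is_indel := is_indel_site(ref, alt)]
  samples <- colnames(v@gt)[-1]
  gt <- vcfR::extract.gt(v, element = "GT")
  dp <- suppressWarnings(vcfR::extract.gt(v, element = "DP", as.numeric = TRUE))
  adm <- tryCatch(vcfR::extract.gt(v, element = "AD"),
                  error = function(e) matrix(NA_character_, n, length(samples)))
  geno <- data.table::rbindlist(lapply(seq_along(samples), function(j) {
    data.table::data.table(
      site_id = seq_len(n), sample_id = samples[j],
      gt = as.character(gt[, j]), dp = as.numeric(dp[, j]),
      ad = as.character(adm[, j]))
  }))
  list(sites = sites, geno = geno)
}

is_indel_site <- function(ref, alt) {
  alts <- strsplit(alt, ",", fixed = TRUE)
  nchar(ref) != 1L |
    vapply(alts, function(a) any(nchar(a) != 1L), logical(1))
}

#' Write a site/genotype pair of tables as a VCF 4.2 file
#'
#' Inverse of [read_trio_vcf()]; positions are written 1-based.
#'
#' @param sites,geno Tables as returned by [read_trio_vcf()].
#' @param path Output path.
#' @param sample_order Optional explicit sample column order.
#' @return Invisibly, `path`.
#' @export
write_trio_vcf <- function(sites, geno, path, sample_order = NULL) {
  if (is.null(sample_order)) sample_order <- unique(geno$sample_id)
  hdr <- c("##fileformat=VCFv4.2",
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
           "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
           "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allele depths\">",
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", sample_order), collapse = "\t"))
  contigs <- unique(sites$contig_id)
  hdr <- c(hdr[1],
           sprintf("##contig=<ID=%s>", contigs),
           hdr[-1])
  g <- data.table::copy(geno)
  g[, gt := ifelse(is.na(gt), "./.", gt)]
  g[, dp := ifelse(is.na(dp), ".", as.character(dp))]
  g[, ad := ifelse(is.na(ad), ".", ad)]
  g[, value := paste(gt, dp, ad, sep = ":")]
  wide <- data.table::dcast(g, site_id ~ sample_id, value.var = "value",
                            fill = "./.:.:.")
  wide <- wide[match(sites$site_id, wide$site_id)]
  body <- paste(sites$contig_id, sites$pos + 1L, ".", sites$ref, sites$alt,
                ifelse(is.na(sites$qual), ".", format(sites$qual, trim = TRUE,
                                                      scientific = FALSE)),
                "PASS", ".", "GT:DP:AD", sep = "\t")
  for (s in sample_order) body <- paste(body, wide[[s]], sep = "\t")
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read a gene-conversion site mask
#'
#' Two-column TSV (`contig_id`, `pos`); positions 0-based to match the
#' internal convention (the writer emits the same).
#'
#' @param path Path to the TSV.
#' @return `data.table(contig_id, pos)`.
#' @export
read_conversion_mask <- function(path) {
  stopifnot(file.exists(path))
  if (file.size(path) == 0L)
    return(data.table::data.table(contig_id = character(), pos = integer()))
  dt <- data.table::fread(path, header = FALSE, sep = "\t",
                          col.names = c("contig_id", "pos"),
                          colClasses = list(character = 1))
  dt
}

#' Write a gene-conversion site mask
#' @param mask `data.table(contig_id, pos)`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_conversion_mask <- function(mask, path) {
  data.table::fwrite(mask[, list(contig_id, pos)], path, sep = "\t",
                     col.names = FALSE)
  invisible(path)
}

#' Read a contig table
#'
#' TSV with columns `contig_id, parent_of_origin, assembler_class,
#' partner_id, length_bp` (header required).  `partner_id` may be empty for
#' non-bubble contigs.
#'
#' @param path Path to the TSV.
#' @return `data.table` of contig records.
#' @export
read_contig_table <- function(path) {
  dt <- data.table::fread(path, header = TRUE, sep = "\t",
                          colClasses = list(character = 1:4))
  dt[partner_id == "", partner_id := NA_character_]
  validate_contigs(dt)
  dt
}

#' Write a contig table
#' @param contigs Contig `data.table`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_contig_table <- function(contigs, path) {
  out <- contigs[, list(contig_id, parent_of_origin, assembler_class,
                        partner_id, length_bp)]
  data.table::fwrite(out, path, sep = "\t", na = "")
  invisible(path)
}

validate_contigs <- function(contigs) {
  stopifnot(all(c("contig_id", "parent_of_origin", "assembler_class",
                  "length_bp") %in% names(contigs)))
  if (anyDuplicated(contigs$contig_id)) stop("duplicate contig IDs")
  if (any(contigs$length_bp < 150))
    stop("contigs shorter than 150 bp must be filtered before analysis")
  if (!all(contigs$assembler_class %in%
           c("bubble_primary", "bubble_secondary", "non_bubble")))
    stop("unknown assembler_class value")
  bub <- contigs[assembler_class != "non_bubble"]
  if (nrow(bub)) {
    if (anyNA(bub$partner_id)) stop("bubble contigs must carry a partner_id")
    m <- setNames(bub$partner_id, bub$contig_id)
    if (!identical(unname(m[m[bub$contig_id]]), bub$contig_id))
      stop("bubble partnership is not symmetric")
  }
  invisible(TRUE)
}
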