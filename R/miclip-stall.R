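# Reverse-transcription stall scoring from miCLIP-style alignments and
# motif/methylation-stratified binding-site lists.

#' Reverse-transcription truncation profile at candidate sites
#'
#' Counts read 5' ends per offset in -`window`..+`window` around each site
#' and scores RT stalling as the 5'-end count at offset +1 (the canonical
#' truncation position, one nucleotide 3' of the modified base on the cDNA
#' sense; configurable) divided by the mean per-base coverage over the
#' window. Sites with zero window coverage get an NA score and are flagged.
#'
#' @param alignments SAM or BAM path.
#' @param sites data.frame with `ref`, `pos0` (and optionally `strand`; minus
#'   strand reads 5' ends at alignment ends).
#' @param window half-width (nt) of the profile.
#' @param stall_offset offset whose 5'-end count defines the score.
#' @param collapse_duplicates collapse reads sharing (start, strand) before
#'   counting.
#' @return data.frame `ref`, `pos0`, `stall_score`, `mean_coverage`,
#'   `defined`; the per-site offset count matrix is attached as attribute
#'   `"profiles"` (sites x offsets).
#' @export
truncation_profile <- function(alignments, sites, window = 10L,
                               stall_offset = 1L, collapse_duplicates = FALSE) {
  bam <- .as_bam(alignments)
  aln <- Rsamtools::scanBam(bam,
    param = Rsamtools::ScanBamParam(what = c("rname", "pos", "strand", "cigar")))[[1]]
  keep <- !is.na(aln$pos)
  rname <- as.character(aln$rname)[keep]
  pos <- aln$pos[keep]
  strand <- as.character(aln$strand)[keep]
  width <- vapply(aln$cigar[keep], function(cg) {
    sum(as.integer(regmatches(cg, gregexpr("[0-9]+(?=[MDN=X])", cg, perl = TRUE))[[1]]))
  }, numeric(1))
  end <- pos + width - 1
  five_prime <- ifelse(strand == "-", end, pos)
  if (collapse_duplicates) {
    k <- !duplicated(paste(rname, five_prime, strand))
    rname <- rname[k]; pos <- pos[k]; end <- end[k]; five_prime <- five_prime[k]
  }
  offs <- -window:window
  cov_gr <- GenomicRanges::GRanges(rname, IRanges::IRanges(pos, end))
  covlist <- GenomicRanges::coverage(cov_gr)
  prof <- matrix(0L, nrow = nrow(sites), ncol = length(offs),
                 dimnames = list(NULL, offs))
  meancov <- numeric(nrow(sites))
  for (i in seq_len(nrow(sites))) {
    tx <- as.character(sites$ref[i]); p1 <- sites$pos0[i] + 1L
    sel <- rname == tx & five_prime >= p1 - window & five_prime <= p1 + window
    if (any(sel))
      prof[i, ] <- tabulate(five_prime[sel] - p1 + window + 1L,
                            nbins = length(offs))
    if (tx %in% names(covlist)) {
      rl <- covlist[[tx]]
      lo <- max(1L, p1 - window); hi <- min(length(rl), p1 + window)
      v <- as.integer(S4Vectors::window(rl, lo, hi))
      meancov[i] <- sum(v) / (2 * window + 1)
    }
  }
  score <- ifelse(meancov > 0, prof[, as.character(stall_offset)] / meancov,
                  NA_real_)
  out <- data.frame(ref = sites$ref, pos0 = sites$pos0, stall_score = score,
                    mean_coverage = meancov, defined = meancov > 0,
                    stringsAsFactors = FALSE)
  attr(out, "profiles") <- prof
  out
}

#' Select and stratify binding sites by motif and methylation
#'
#' Keeps binding sites whose sequence context is a cytosine followed by UCCA
#' and stratifies them into the no/low/high methylation groups of
#' [group_sites_by_methylation()]. Also reports the fraction of all binding
#' sites carrying the downstream UCCA motif and, when an annotation is
#' supplied, the fraction of binding sites falling in exonic regions.
#'
#' @param bed BED path or `GRanges` of binding sites (0-based half-open on
#'   disk; imported 1-based).
#' @param transcriptome FASTA path, `DNAStringSet` or named character vector.
#' @param levels data.frame with `ref`, `pos0`, `level` giving methylation
#'   levels; sites without a level are treated as unmethylated.
#' @param gtf optional annotation for the exonic fraction.
#' @return list with `sites` (kept UCCA sites with `level` and `meth_group`),
#'   `groups` (split by group), `fraction_ucca`, `fraction_exonic` (NA
#'   without `gtf`), `n_total`.
#' @export
select_binding_sites <- function(bed, transcriptome, levels = NULL, gtf = NULL) {
  if (is.character(bed) && length(bed) == 1 && file.exists(bed))
    bed <- rtracklayer::import(bed, format = "bed")
  stopifnot(methods::is(bed, "GRanges"))
  seqs <- .load_fasta(transcriptome)
  df <- data.frame(ref = as.character(GenomicRanges::seqnames(bed)),
                   pos0 = IRanges::start(GenomicRanges::ranges(bed)) - 1L,
                   stringsAsFactors = FALSE)
  n_total <- nrow(df)
  has_ucca <- vapply(seq_len(n_total), function(i) {
    if (!df$ref[i] %in% names(seqs)) return(FALSE)
    s <- seqs[[df$ref[i]]]
    p1 <- df$pos0[i] + 1L
    p1 + 4L <= nchar(s) && substr(s, p1, p1 + 4L) == "CTCCA"
  }, logical(1))
  kept <- df[has_ucca, , drop = FALSE]
  kept$level <- 0
  if (!is.null(levels)) {
    m <- match(paste(kept$ref, kept$pos0), paste(levels$ref, levels$pos0))
    kept$level[!is.na(m)] <- levels$level[m[!is.na(m)]]
  }
  kept <- group_sites_by_methylation(kept)
  frac_exonic <- NA_real_
  if (!is.null(gtf)) {
    loc <- annotate_genic_location(df, gtf, mode = "genome")
    frac_exonic <- mean(loc %in% c("5'UTR", "CDS", "3'UTR", "exon"))
  }
  list(sites = kept,
       groups = split(kept, kept$meth_group),
       fraction_ucca = if (n_total) mean(has_ucca) else NA_real_,
       fraction_exonic = frac_exonic,
       n_total = n_total)
}
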