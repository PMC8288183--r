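# Sequence-context extraction, Type I / Type II typing, genic annotation,
# metagene density and per-sample proportions.

#' Extract the RNA sequence context around sites
#'
#' Returns the strand-correct +/- `k` nt RNA context centred on each site
#' (2k + 1 characters, C at the centre). Windows extending past the
#' transcript ends are padded with N. Sites whose centre base is not C raise
#' an error (stale coordinates).
#'
#' @param sites data.frame with `ref`, `pos0` and optionally `strand`
#'   (defaults to `+`).
#' @param transcriptome FASTA path, `DNAStringSet` or named character vector.
#' @param k context half-width (nt).
#' @return character vector of RNA contexts, one per site.
#' @export
extract_context <- function(sites, transcriptome, k = 10L) {
  stopifnot(is.data.frame(sites), all(c("ref", "pos0") %in% names(sites)))
  seqs <- .load_fasta(transcriptome)
  strand <- if ("strand" %in% names(sites)) as.character(sites$strand) else
    rep("+", nrow(sites))
  ctx <- vapply(seq_len(nrow(sites)), function(i) {
    tx <- as.character(sites$ref[i])
    if (!tx %in% names(seqs)) stop("transcript not in FASTA: ", tx)
    s <- seqs[[tx]]; len <- nchar(s)
    pos1 <- sites$pos0[i] + 1L
    lo <- pos1 - k; hi <- pos1 + k
    core <- substr(s, max(1L, lo), min(len, hi))
    core <- paste0(strrep("N", max(0L, 1L - lo)), core,
                   strrep("N", max(0L, hi - len)))
    core <- dna2rna(toupper(core))
    if (strand[i] == "-") core <- .revcomp_rna(core)
    core
  }, character(1))
  centre <- substr(ctx, k + 1L, k + 1L)
  if (any(centre != "C"))
    stop("centre base is not C for ", sum(centre != "C"),
         " site(s): stale coordinates?")
  ctx
}

#' Classify site type from sequence context
#'
#' Type II iff the four bases immediately downstream (+1..+4) are UCCA;
#' otherwise Type I iff a G-rich triplet (`g_pattern`) occurs within the
#' `g_window` downstream offsets; otherwise `other`. Type II takes precedence
#' on the rare double match, since the UCCA motif is the robust Type II
#' signature. The G-rich definition is an operational default and can be
#' overridden.
#'
#' @param context character vector of RNA contexts with the site C at the
#'   centre (odd length).
#' @param g_pattern G-rich triplet pattern for Type I.
#' @param g_window downstream offset window (inclusive) searched for
#'   `g_pattern`.
#' @return character vector with values `TypeII`, `TypeI`, `other`.
#' @examples
#' classify_type("AACUCCAGG")  # "TypeII"
#' @export
classify_type <- function(context, g_pattern = "GGG", g_window = c(2L, 6L)) {
  n <- nchar(context)
  if (any(n %% 2 != 1)) stop("contexts must have odd length (site at centre)")
  centre <- (n + 1L) %/% 2L
  if (any(substr(context, centre, centre) != "C"))
    stop("centre base must be C")
  down4 <- substr(context, centre + 1L, centre + 4L)
  gwin <- substr(context, centre + g_window[1], centre + g_window[2])
  ifelse(down4 == "UCCA", "TypeII",
         ifelse(grepl(g_pattern, gwin, fixed = TRUE), "TypeI", "other"))
}

# Internal: per-transcript CDS bounds (1-based, transcript coordinates) from
# an imported or generated GTF table.
.cds_table <- function(gtf) {
  if (methods::is(gtf, "GRanges")) {
    df <- data.frame(seqid = as.character(GenomicRanges::seqnames(gtf)),
                     type = as.character(gtf$type),
                     start = IRanges::start(GenomicRanges::ranges(gtf)),
                     end = IRanges::end(GenomicRanges::ranges(gtf)),
                     transcript_id = if (!is.null(gtf$transcript_id))
                       as.character(gtf$transcript_id) else
                         as.character(GenomicRanges::seqnames(gtf)),
                     stringsAsFactors = FALSE)
  } else df <- gtf
  cds <- df[df$type == "CDS", , drop = FALSE]
  if (!nrow(cds)) return(NULL)
  agg_min <- tapply(cds$start, cds$seqid, min)
  agg_max <- tapply(cds$end, cds$seqid, max)
  data.frame(seqid = names(agg_min), cds_start = as.integer(agg_min),
             cds_end = as.integer(agg_max), stringsAsFactors = FALSE)
}

#' Annotate the genic compartment of sites
#'
#' Transcript mode (`mode = "transcript"`): labels each site 5'UTR, CDS or
#' 3'UTR from the transcript's CDS bounds in the GTF; transcripts without a
#' CDS are `noncoding`. Genome mode (`mode = "genome"`): sites overlapping a
#' CDS/exon are labelled by compartment, sites inside a gene but outside all
#' exons are `intron`, and sites outside genes are `noncoding` (exonic and
#' intronic sites can then be analysed separately).
#'
#' @param sites data.frame with `ref` and `pos0` (transcript or genome
#'   coordinates according to `mode`).
#' @param gtf GTF path, `GRanges` (as from `rtracklayer::import`), or the
#'   data.frame emitted by [make_transcriptome()].
#' @param mode `"transcript"` or `"genome"`.
#' @return character vector of compartments (`5'UTR`, `CDS`, `3'UTR`,
#'   `intron`, `noncoding`).
#' @export
annotate_genic_location <- function(sites, gtf, mode = c("transcript", "genome")) {
  mode <- match.arg(mode)
  if (is.character(gtf) && length(gtf) == 1 && file.exists(gtf))
    gtf <- rtracklayer::import(gtf, format = "gtf")
  if (mode == "transcript") {
    cds <- .cds_table(gtf)
    pos1 <- sites$pos0 + 1L
    if (is.null(cds)) return(rep("noncoding", nrow(sites)))
    m <- match(as.character(sites$ref), cds$seqid)
    out <- rep("noncoding", nrow(sites))
    has <- !is.na(m)
    out[has & pos1 < cds$cds_start[m]] <- "5'UTR"
    out[has & pos1 >= cds$cds_start[m] & pos1 <= cds$cds_end[m]] <- "CDS"
    out[has & pos1 > cds$cds_end[m]] <- "3'UTR"
    return(out)
  }
  # genome mode: interval overlap against gene/exon/CDS features
  if (!methods::is(gtf, "GRanges"))
    gtf <- GenomicRanges::makeGRangesFromDataFrame(gtf, keep.extra.columns = TRUE,
                                                   seqnames.field = "seqid")
  gr <- GenomicRanges::GRanges(sites$ref,
                               IRanges::IRanges(sites$pos0 + 1L, sites$pos0 + 1L))
  ov <- function(type) {
    sub <- gtf[as.character(gtf$type) == type]
    IRanges::overlapsAny(gr, sub, ignore.strand = TRUE)
  }
  in_gene <- ov("gene"); in_exon <- ov("exon"); in_cds <- ov("CDS")
  out <- rep("noncoding", nrow(sites))
  out[in_gene & !in_exon] <- "intron"
  out[in_exon] <- "exon"
  out[in_cds] <- "CDS"
  # refine exonic non-CDS into UTRs where CDS bounds are known
  cds <- .cds_table(gtf)
  if (!is.null(cds)) {
    m <- match(as.character(sites$ref), cds$seqid)
    pos1 <- sites$pos0 + 1L
    sel <- out == "exon" & !is.na(m)
    out[sel & pos1 < cds$cds_start[m]] <- "5'UTR"
    out[sel & pos1 > cds$cds_end[m]] <- "3'UTR"
  }
  out
}

#' Metagene density of sites along the transcript model
#'
#' Maps each exonic site to a scaled bin within its compartment (5'UTR, CDS,
#' 3'UTR widths fixed at `bins`), and returns per-type bin densities
#' normalised to unit sum, the standard metagene representation.
#'
#' @param sites data.frame with `ref`, `pos0` and a `type` column.
#' @param gtf annotation, as in [annotate_genic_location()].
#' @param bins integer vector of bin counts for (5'UTR, CDS, 3'UTR).
#' @return data.frame `type`, `bin` (1..sum(bins)), `compartment`, `density`;
#'   densities sum to 1 within each type.
#' @export
metagene_density <- function(sites, gtf, bins = c(20L, 40L, 20L)) {
  stopifnot(length(bins) == 3)
  if (is.character(gtf) && length(gtf) == 1 && file.exists(gtf))
    gtf <- rtracklayer::import(gtf, format = "gtf")
  cds <- .cds_table(gtf)
  if (methods::is(gtf, "GRanges")) {
    tx_len <- tapply(IRanges::end(GenomicRanges::ranges(gtf)),
                     as.character(GenomicRanges::seqnames(gtf)), max)
  } else tx_len <- tapply(gtf$end, gtf$seqid, max)
  pos1 <- sites$pos0 + 1L
  m <- match(as.character(sites$ref), cds$seqid)
  if (anyNA(m)) stop("site transcript(s) missing CDS annotation")
  cs <- cds$cds_start[m]; ce <- cds$cds_end[m]
  tl <- as.integer(tx_len[as.character(sites$ref)])
  # relative position within compartment, then global bin
  comp <- ifelse(pos1 < cs, "5'UTR", ifelse(pos1 <= ce, "CDS", "3'UTR"))
  relpos <- ifelse(comp == "5'UTR", (pos1 - 0.5) / pmax(cs - 1L, 1L),
            ifelse(comp == "CDS", (pos1 - cs + 0.5) / (ce - cs + 1L),
                   (pos1 - ce - 0.5) / pmax(tl - ce, 1L)))
  base <- c("5'UTR" = 0L, "CDS" = bins[1], "3'UTR" = bins[1] + bins[2])
  width <- c("5'UTR" = bins[1], "CDS" = bins[2], "3'UTR" = bins[3])
  bin <- base[comp] + pmin(width[comp], pmax(1L, ceiling(relpos * width[comp])))
  all_bins <- seq_len(sum(bins))
  comp_of_bin <- rep(c("5'UTR", "CDS", "3'UTR"), bins)
  out <- do.call(rbind, lapply(unique(as.character(sites$type)), function(ty) {
    cnt <- tabulate(bin[sites$type == ty], nbins = sum(bins))
    data.frame(type = ty, bin = all_bins, compartment = comp_of_bin,
               density = if (sum(cnt)) cnt / sum(cnt) else cnt,
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Per-sample Type II site counts and proportions
#'
#' The proportion is the number of Type II sites divided by the total number
#' of m5C sites in the sample; samples without sites get NA.
#'
#' @param callsets named list of data.frames, one per sample, each with a
#'   `type` column (as from [classify_type()]).
#' @return data.frame `sample`, `n_typeII`, `n_total`, `proportion`.
#' @export
type_proportions <- function(callsets) {
  stopifnot(length(callsets) >= 1)
  if (is.null(names(callsets)))
    names(callsets) <- sprintf("sample%d", seq_along(callsets))
  out <- do.call(rbind, lapply(names(callsets), function(s) {
    df <- callsets[[s]]
    n2 <- sum(df$type == "TypeII"); nt <- nrow(df)
    data.frame(sample = s, n_typeII = n2, n_total = nt,
               proportion = if (nt > 0) n2 / nt else NA_real_,
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}
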