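# Synthetic-data generators. Every input the pipeline consumes can be
# produced here with known ground truth: a transcriptome FASTA + GTF with
# planted Type II / Type I / motif-less m5C sites, pre-aligned bisulfite
# reads (SAM), a methyltransferase expression matrix with one planted writer,
# barcoded reporter reads, and translation/polysome tables.
#
# Sequence architecture: transcripts are concatenations of closed hairpin
# cassettes (mixed G/C stems, A-only loops). Because every G in a transcript
# is consumed by a designed stem, the base-pair-maximizing fold recovers the
# designed structures (re-pairing a stem base elsewhere never gains pairs and
# always loses stacking), which keeps planted loops unpaired and makes
# metaprofiles analyzable. This trades sequence realism for exact,
# verifiable structural ground truth; see the methods vignette.

# ---- cassette builders (DNA alphabet) --------------------------------------

.sample_range <- function(rng) {
  if (rng[1] == rng[2]) rng[1] else sample(rng[1]:rng[2], 1L)
}

.sample_gc_arm <- function(len) {
  stopifnot(len >= 2)
  need <- if (len >= 4) 2L else 1L   # mixed composition, so no pure-G/C runs
  repeat {
    arm <- sample(c("G", "C"), len, replace = TRUE)
    if (sum(arm == "G") >= need && sum(arm == "C") >= need)
      return(paste(arm, collapse = ""))
  }
}

.revcomp_dna <- function(s) {
  paste(rev(strsplit(chartr("ACGT", "TGCA", s), "")[[1]]), collapse = "")
}

# Unpairable spacer separating cassettes; A cannot pair A, and every U in a
# transcript is buried in a designed stem, so spacers stay single-stranded.
.a_spacer <- function(min_len = 15L, max_len = 30L) {
  strrep("A", sample(min_len:max_len, 1))
}

# Type II cassette: hairpin with the site in the loop. Loop (length L >= 5) is
# C^(L-5) C TCCA in DNA, so the site C sits at loop position L-4 with UCCA at
# +1..+4 and the loop cannot pair internally. L == 4 drops the pad and pairs
# the motif A into the stem. The hairpin is insulated by A-only spacers wider
# than the fold window half-width minus the hairpin, so the +/-50 nt window
# around the site contains only the designed hairpin plus unpairable As and
# the base-pair-maximizing fold provably recovers the planted structure.
.type2_cassette <- function(stem_len, loop_len, pad = 40L) {
  arm <- .sample_gc_arm(stem_len)
  if (loop_len >= 5) {
    loop <- paste0(strrep("C", loop_len - 5), "CTCCA")
    core <- paste0(arm, loop, .revcomp_dna(arm))
    site_core <- stem_len + loop_len - 5L          # 0-based within core
  } else if (loop_len == 4) {
    # loop CTCC closed by an extra T..A pair; the motif A sits in the stem
    core <- paste0(arm, "TCTCCA", .revcomp_dna(arm))
    site_core <- stem_len + 1L
  } else stop("Type II hairpin loop must be >= 4 nt")
  list(seq = paste0(strrep("A", pad), core, strrep("A", pad)),
       site_off = pad + site_core)
}

# Type I cassette: site C just 5' of a hairpin whose stem starts with GGGG,
# giving the downstream G-rich triplet at +2..+4 (and never UCCA at +1..+4).
.type1_cassette <- function(stem_len) {
  arm <- paste0("GGGG", .sample_gc_arm(max(stem_len - 4L, 4L)))
  list(seq = paste0("CA", arm, "AAA", .revcomp_dna(arm)), site_off = 0L)
}

# Motif-less methylated site: C followed by AAAA.
.none_cassette <- function() list(seq = "AACAAAA", site_off = 2L)

# Background cassette: an unmethylated C-UCCA motif embedded in a tiling of
# hairpin units whose geometry (arm length, motif depth, 5'/3' arm choice,
# occasional stem-loop boundary placement) is randomized per cassette.
# Pairing around background cytosines is then high and, crucially, flat:
# every offset carries the same small probability of hitting one of the
# randomly phased hairpin loops.
.bg_unit <- function(arm_rng = c(12L, 16L)) {
  arm <- .sample_gc_arm(sample(arm_rng[1]:arm_rng[2], 1))
  paste0(arm, "AAA", .revcomp_dna(arm))
}

.background_cassette <- function() {
  variant <- sample(c("stem5", "stem3", "bulge", "edge2", "edge1"), 1,
                    prob = c(0.38, 0.38, 0.12, 0.06, 0.06))
  a <- sample(8:20, 1)
  mot <- c("C", "T", "C", "C", "A")
  if (variant == "stem5") {          # motif in the 5' arm, loop downstream
    q <- sample.int(a - 4L, 1)
    arm <- strsplit(.sample_gc_arm(a), "")[[1]]
    arm[q:(q + 4L)] <- mot
    arm <- paste(arm, collapse = "")
    core <- paste0(arm, "AAA", .revcomp_dna(arm)); off <- q - 1L
  } else if (variant == "stem3") {   # motif in the 3' arm, loop upstream
    r <- sample.int(a - 4L, 1)
    arm2 <- strsplit(.sample_gc_arm(a), "")[[1]]
    arm2[r:(r + 4L)] <- mot
    arm2 <- paste(arm2, collapse = "")
    core <- paste0(.revcomp_dna(arm2), "AAA", arm2)
    off <- a + 3L + r - 1L
  } else if (variant == "bulge") {   # site C bulged out, UCCA in the stem
    armA <- .sample_gc_arm(sample(8:12, 1))
    armB <- paste0("TCCA", .sample_gc_arm(sample(6:10, 1)))
    core <- paste0(armA, "C", armB, "AAA", .revcomp_dna(armB),
                   .revcomp_dna(armA))
    off <- nchar(armA)
  } else if (variant == "edge2") {   # C,U paired, CCA in the loop
    arm <- paste0(.sample_gc_arm(a - 2L), "CT")
    core <- paste0(arm, "CCA", .revcomp_dna(arm)); off <- a - 2L
  } else {                           # C paired, UCCA forms the loop
    arm <- paste0(.sample_gc_arm(a - 1L), "C")
    core <- paste0(arm, "TCCA", .revcomp_dna(arm)); off <- a - 1L
  }
  left <- paste0(.bg_unit(c(12L, 16L)), .bg_unit(c(5L, 16L)))
  right <- paste0(.bg_unit(c(5L, 16L)), .bg_unit(c(12L, 16L)))
  list(seq = paste0(left, core, right),
       site_off = nchar(left) + off)
}

# ---- transcriptome ----------------------------------------------------------

#' Generate a synthetic transcriptome with planted m5C sites
#'
#' Builds `n_transcripts` transcript sequences (DNA alphabet on disk) carrying
#' planted Type II sites (m5C in a designed hairpin loop, UCCA at +1..+4),
#' Type I sites (downstream G-rich triplet at the 5' side of a hairpin), and
#' motif-less methylated sites, plus unmethylated background C-UCCA motifs
#' for null resampling. Each transcript gets a single-exon gene model with
#' 5'UTR/CDS/3'UTR boundaries. All randomness is governed by `seed`:
#' identical seed and configuration give byte-identical outputs.
#'
#' @param n_transcripts number of transcripts.
#' @param sites_per_type total number of planted sites of each type
#'   (Type II, Type I, none), distributed round-robin over transcripts.
#' @param hairpin_spec list with `loop` and `stem` length ranges
#'   (2-vectors); Type II hairpins sample within them. Loop must be >= 4 and
#'   stem >= 3.
#' @param seed integer seed.
#' @param background_per_transcript unmethylated C-UCCA background motifs per
#'   transcript.
#' @param level_range range of true methylation levels for planted sites.
#' @param conversion per-sample bisulfite conversion rate stored in the truth
#'   table (fraction in (0.9, 1]).
#' @param transcript_length optional target transcript length; transcripts are
#'   padded with structural filler to approximately this length. An error is
#'   raised if one hairpin cannot fit.
#' @param outdir optional directory; when given, writes `transcriptome.fa`,
#'   `annotation.gtf` and the truth table files there.
#' @return list with `sequences` (named DNA character vector), `gtf`
#'   (data.frame of gene/transcript/exon/CDS features), `truth` (see
#'   [write_truth_table()]), and `paths` when `outdir` was used.
#' @export
make_transcriptome <- function(n_transcripts = 10L, sites_per_type = 5L,
                               hairpin_spec = list(loop = c(7L, 7L),
                                                   stem = c(11L, 11L)),
                               seed = NULL,
                               background_per_transcript = 4L,
                               level_range = c(0.1, 0.9),
                               conversion = 0.995,
                               transcript_length = NULL,
                               outdir = NULL) {
  stopifnot(n_transcripts >= 1, sites_per_type >= 0)
  loop_rng <- as.integer(hairpin_spec$loop); stem_rng <- as.integer(hairpin_spec$stem)
  if (length(loop_rng) == 1) loop_rng <- rep(loop_rng, 2)
  if (length(stem_rng) == 1) stem_rng <- rep(stem_rng, 2)
  if (min(loop_rng) < 4) stop("hairpin loop length must be >= 4")
  if (min(stem_rng) < 3) stop("hairpin stem length must be >= 3")
  if (conversion <= 0.9 || conversion > 1)
    stop("conversion rate must lie in (0.9, 1]")
  if (!is.null(transcript_length) &&
      2 * max(stem_rng) + max(loop_rng) + 46 > transcript_length)
    stop("hairpin spec cannot embed: stem+loop exceeds transcript length")
  .set_seed(seed)

  tx_of <- function(total) if (total > 0) rep(seq_len(n_transcripts), length.out = total) else integer(0)
  plan <- data.frame(
    tx = c(tx_of(sites_per_type), tx_of(sites_per_type), tx_of(sites_per_type),
           rep(seq_len(n_transcripts), each = background_per_transcript)),
    type = c(rep("TypeII", sites_per_type), rep("TypeI", sites_per_type),
             rep("none", sites_per_type),
             rep("background", n_transcripts * background_per_transcript)),
    stringsAsFactors = FALSE)

  seqs <- character(n_transcripts)
  names(seqs) <- sprintf("TX%04d", seq_len(n_transcripts))
  sites <- list(); bg <- list()
  for (t in seq_len(n_transcripts)) {
    # terminal spacers exceed typical read length so planted sites sit in the
    # uniform-coverage plateau, away from transcript-end ramp-down
    parts <- .a_spacer(110L, 130L)
    cass <- plan[plan$tx == t, , drop = FALSE]
    cass <- cass[sample.int(nrow(cass)), , drop = FALSE]   # shuffle order
    for (r in seq_len(nrow(cass))) {
      cs <- switch(cass$type[r],
        TypeII = .type2_cassette(.sample_range(stem_rng), .sample_range(loop_rng)),
        TypeI = .type1_cassette(.sample_range(stem_rng)),
        none = .none_cassette(),
        background = .background_cassette())
      pos0 <- sum(nchar(parts)) + cs$site_off
      rec <- data.frame(ref = names(seqs)[t], pos0 = pos0, strand = "+",
                        type = cass$type[r], stringsAsFactors = FALSE)
      if (cass$type[r] == "background") bg[[length(bg) + 1]] <- rec
      else sites[[length(sites) + 1]] <- rec
      parts <- c(parts, cs$seq, .a_spacer())
    }
    parts <- c(parts, .a_spacer(110L, 130L))
    s <- paste(parts, collapse = "")
    if (!is.null(transcript_length) && nchar(s) < transcript_length) {
      extra <- replicate(ceiling((transcript_length - nchar(s)) / 70),
                         paste0(.background_cassette()$seq, .a_spacer()))
      s <- paste0(s, paste(extra, collapse = ""))
    }
    seqs[t] <- s
  }
  sites <- if (length(sites)) do.call(rbind, sites) else
    data.frame(ref = character(), pos0 = integer(), strand = character(),
               type = character(), stringsAsFactors = FALSE)
  bg <- if (length(bg)) do.call(rbind, bg) else
    data.frame(ref = character(), pos0 = integer(), strand = character(),
               type = character(), stringsAsFactors = FALSE)
  sites$level <- runif(nrow(sites), level_range[1], level_range[2])

  # single-exon gene models; CDS spans the middle half, codon-rounded
  gtf <- do.call(rbind, lapply(seq_len(n_transcripts), function(t) {
    len <- nchar(seqs[t]); id <- names(seqs)[t]
    cds_start <- floor(len * 0.25) + 1L
    cds_len <- (floor(len * 0.5) %/% 3L) * 3L
    cds_end <- cds_start + cds_len - 1L
    data.frame(seqid = id, source = "m5Ctools",
               type = c("gene", "transcript", "exon", "CDS"),
               start = c(1L, 1L, 1L, cds_start),
               end = c(len, len, len, cds_end),
               strand = "+",
               gene_id = paste0("G_", id), transcript_id = id,
               stringsAsFactors = FALSE)
  }))

  truth <- list(sites = sites, background = bg[, c("ref", "pos0", "strand")],
                conversion = conversion, writer = NA_character_)
  out <- list(sequences = seqs, gtf = gtf, truth = truth)
  if (!is.null(outdir)) {
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    fa <- file.path(outdir, "transcriptome.fa")
    Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs), fa)
    gtf_path <- file.path(outdir, "annotation.gtf")
    .write_gtf(gtf, gtf_path)
    tp <- write_truth_table(truth, outdir)
    out$paths <- c(fasta = fa, gtf = gtf_path, tp)
  }
  out
}

# GTF emission: nine-column text with gene_id/transcript_id attributes,
# readable by rtracklayer::import.
.write_gtf <- function(gtf, path) {
  attrs <- sprintf('gene_id "%s"; transcript_id "%s";', gtf$gene_id, gtf$transcript_id)
  lines <- paste(gtf$seqid, gtf$source, gtf$type, gtf$start, gtf$end, ".",
                 gtf$strand, ".", attrs, sep = "\t")
  writeLines(lines, path)
  invisible(path)
}

#' Write / read a ground-truth table
#'
#' The truth table records every planted site (transcript, 0-based position,
#' strand, true level, type label), the unmethylated background motif
#' positions, the per-sample conversion rate and the planted writer enzyme.
#' Stored as three plain TSV files so that written-then-read truth equals the
#' in-memory object.
#'
#' @param truth truth list as produced by [make_transcriptome()].
#' @param dir directory to write into (created if needed).
#' @return named vector of file paths ([write_truth_table()]) or the truth
#'   list ([read_truth_table()]).
#' @export
write_truth_table <- function(truth, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p1 <- file.path(dir, "truth_sites.tsv")
  p2 <- file.path(dir, "truth_background.tsv")
  p3 <- file.path(dir, "truth_meta.tsv")
  .write_tsv(truth$sites, p1)
  .write_tsv(truth$background, p2)
  .write_tsv(data.frame(key = c("conversion", "writer"),
                        value = c(format(truth$conversion, digits = 17),
                                  as.character(truth$writer)),
                        stringsAsFactors = FALSE), p3)
  c(truth_sites = p1, truth_background = p2, truth_meta = p3)
}

#' @rdname write_truth_table
#' @export
read_truth_table <- function(dir) {
  sites <- read.delim(file.path(dir, "truth_sites.tsv"), stringsAsFactors = FALSE)
  bg <- read.delim(file.path(dir, "truth_background.tsv"), stringsAsFactors = FALSE)
  meta <- read.delim(file.path(dir, "truth_meta.tsv"), stringsAsFactors = FALSE)
  writer <- meta$value[meta$key == "writer"]
  list(sites = sites, background = bg,
       conversion = as.numeric(meta$value[meta$key == "conversion"]),
       writer = if (identical(writer, "NA")) NA_character_ else writer)
}

# ---- bisulfite reads --------------------------------------------------------

#' Simulate pre-aligned bisulfite-sequencing reads
#'
#' Emits aligned SAM records against the supplied transcriptome under the
#' standard bisulfite observation model: at a planted site with true level m
#' and conversion rate c, a read shows C with probability m + (1 - m)(1 - c);
#' every other reference C converts to T with probability c. Reads are
#' emitted pre-aligned (correct POS/CIGAR by construction) because alignment
#' is outside the scope of the pipeline.
#'
#' @param transcriptome FASTA path, `DNAStringSet` or named character vector.
#' @param truth truth list (uses `sites` levels and `conversion`).
#' @param depth target mean per-base coverage.
#' @param read_len read length (nt); transcripts shorter than this yield
#'   full-length reads.
#' @param seed integer seed.
#' @param out_sam output SAM path (default: tempfile).
#' @param out_fasta optional path for a copy of the reference FASTA.
#' @param conversion overrides the truth conversion rate when given.
#' @return list with `sam`, `fasta` (or NULL), `n_reads`.
#' @export
simulate_bs_reads <- function(transcriptome, truth, depth = 50, read_len = 100L,
                              seed = NULL, out_sam = tempfile(fileext = ".sam"),
                              out_fasta = NULL, conversion = NULL) {
  stopifnot(depth > 0)
  seqs <- .load_fasta(transcriptome)
  conv <- if (is.null(conversion)) truth$conversion else conversion
  .stopifnot_prob(conv, "conversion")
  .set_seed(seed)
  qn <- rn <- sq <- character(0); ps <- integer(0)
  n_total <- 0L
  for (tx in names(seqs)) {
    ref <- strsplit(seqs[[tx]], "")[[1]]
    len <- length(ref)
    rl <- min(read_len, len)
    n_reads <- ceiling(depth * len / rl)
    # per-position probability that a C survives as C
    p_c <- rep(NA_real_, len)
    p_c[ref == "C"] <- 1 - conv
    st <- truth$sites[truth$sites$ref == tx, , drop = FALSE]
    if (nrow(st)) {
      m <- st$level
      p_c[st$pos0 + 1L] <- m + (1 - m) * (1 - conv)
    }
    starts <- if (len == rl) rep(1L, n_reads) else
      sample.int(len - rl + 1L, n_reads, replace = TRUE)
    reads <- vapply(starts, function(s) {
      b <- ref[s:(s + rl - 1L)]
      pc <- p_c[s:(s + rl - 1L)]
      ic <- which(!is.na(pc))
      if (length(ic)) b[ic] <- ifelse(runif(length(ic)) < pc[ic], "C", "T")
      paste(b, collapse = "")
    }, character(1))
    qn <- c(qn, sprintf("%s_r%06d", tx, seq_len(n_reads)))
    rn <- c(rn, rep(tx, n_reads)); ps <- c(ps, starts); sq <- c(sq, reads)
    n_total <- n_total + n_reads
  }
  .write_sam(out_sam, names(seqs), nchar(seqs), qn, rn, ps, sq)
  if (!is.null(out_fasta))
    Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs), out_fasta)
  list(sam = out_sam, fasta = out_fasta, n_reads = n_total)
}

# ---- expression matrix with planted writer ---------------------------------

# Permutation of 1..n whose squared rank distance to the identity matches the
# Spearman target; found by a seeded stochastic search.
.perm_for_spearman <- function(n, rho, iters = 4000L) {
  target <- (1 - rho) * (n^3 - n) / 6
  perm <- seq_len(n)
  d2 <- function(p) sum((p - seq_len(n))^2)
  cur <- d2(perm)
  for (it in seq_len(iters)) {
    if (cur == round(target)) break
    ij <- sample.int(n, 2)
    cand <- perm; cand[ij] <- cand[rev(ij)]
    cd <- d2(cand)
    if (abs(cd - target) < abs(cur - target)) { perm <- cand; cur <- cd }
  }
  perm
}

#' Simulate a methyltransferase expression screen with one planted writer
#'
#' Emits an expression matrix (`n_enzymes` rows x `n_samples` columns) and a
#' per-sample Type II site count vector. Exactly one enzyme (the planted
#' writer) has expression whose sample Spearman correlation with the count
#' vector matches `writer_corr` as closely as the rank lattice allows; all
#' other enzymes are drawn independently.
#'
#' @param n_enzymes number of candidate enzymes (the screen uses 125).
#' @param n_samples number of samples (>= 3).
#' @param writer_corr target Spearman correlation in `[-1, 1]`.
#' @param seed integer seed.
#' @param counts optional Type II count vector; by default drawn uniformly
#'   from 5..169 sites per sample (the observed cross-sample range).
#' @param outdir optional directory for `expression.tsv` / `type2_counts.tsv`.
#' @return list with `expression` matrix, `type2_counts`, `writer` (planted
#'   enzyme id), `achieved_spearman`.
#' @export
simulate_expression <- function(n_enzymes = 125L, n_samples = 9L,
                                writer_corr = 0.9, seed = NULL,
                                counts = NULL, outdir = NULL) {
  if (n_samples < 3) stop("need at least 3 samples")
  if (abs(writer_corr) > 1) stop("|writer_corr| must be <= 1")
  .set_seed(seed)
  samples <- sprintf("S%02d", seq_len(n_samples))
  enzymes <- sprintf("MTase%03d", seq_len(n_enzymes))
  if (is.null(counts))
    counts <- sample(5:169, n_samples, replace = n_samples > 165)
  counts <- setNames(as.numeric(counts), samples)
  expr <- matrix(rlnorm(n_enzymes * n_samples, meanlog = 3, sdlog = 1),
                 nrow = n_enzymes, dimnames = list(enzymes, samples))
  writer <- sample(enzymes, 1)
  perm <- .perm_for_spearman(n_samples, writer_corr)
  count_rank <- rank(counts, ties.method = "first")
  expr_rank <- perm[count_rank]
  expr[writer, ] <- sort(rlnorm(n_samples, meanlog = 3, sdlog = 1))[expr_rank]
  achieved <- suppressWarnings(cor(expr[writer, ], counts, method = "spearman"))
  if (!is.null(outdir)) {
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    .write_tsv(data.frame(enzyme = rownames(expr), expr,
                          check.names = FALSE, stringsAsFactors = FALSE),
               file.path(outdir, "expression.tsv"))
    .write_tsv(data.frame(sample = samples, type2_count = counts,
                          stringsAsFactors = FALSE),
               file.path(outdir, "type2_counts.tsv"))
  }
  list(expression = expr, type2_counts = counts, writer = writer,
       achieved_spearman = achieved)
}

# ---- reporter reads ---------------------------------------------------------

#' Simulate barcoded targeted-bisulfite reporter reads
#'
#' For each variant in an oligo design table, emits `depth_per_variant`
#' reads consisting of the (conversion-proof, C-free) barcode followed by the
#' bisulfite-converted insert: the target cytosine resists conversion with
#' probability equal to the variant's rule-assigned true level, all other
#' insert cytosines convert at the conversion rate.
#'
#' @param designs oligo design data.frame from [design_variant_library()].
#' @param effect_rules data.frame mapping variants to true levels: either
#'   per-variant (`variant_id`, `true_level`) or per-category (`category`,
#'   `true_level`).
#' @param depth_per_variant reads per variant (scalar or per-variant vector);
#'   variants with depth 0 are absent from the output.
#' @param seed integer seed.
#' @param conversion bisulfite conversion rate.
#' @param out_fastq output FASTQ path (default: tempfile).
#' @return list with `fastq`, `truth` (variant_id, true_level, n_reads).
#' @export
simulate_reporter_reads <- function(designs, effect_rules,
                                    depth_per_variant = 200L, seed = NULL,
                                    conversion = 0.995,
                                    out_fastq = tempfile(fileext = ".fastq")) {
  stopifnot(is.data.frame(designs),
            all(c("variant_id", "barcode", "sequence", "target_offset") %in% names(designs)))
  if (anyDuplicated(designs$barcode)) stop("duplicate barcodes in design table")
  .stopifnot_prob(conversion, "conversion")
  if ("variant_id" %in% names(effect_rules)) {
    lv <- effect_rules$true_level[match(designs$variant_id, effect_rules$variant_id)]
  } else if ("category" %in% names(effect_rules)) {
    lv <- effect_rules$true_level[match(designs$category, effect_rules$category)]
  } else stop("effect_rules needs a variant_id or category column")
  if (anyNA(lv)) stop("effect_rules does not cover every design variant")
  .stopifnot_prob(lv, "true_level")
  depth <- rep_len(as.integer(depth_per_variant), nrow(designs))
  .set_seed(seed)
  ids <- seqs <- character(0)
  for (k in seq_len(nrow(designs))) {
    if (depth[k] <= 0) next
    ins <- strsplit(designs$sequence[k], "")[[1]]
    cpos <- which(ins == "C")
    toff <- designs$target_offset[k] + 1L            # 0-based -> 1-based
    reads <- vapply(seq_len(depth[k]), function(i) {
      b <- ins
      for (p in cpos) {
        pr <- if (p == toff) lv[k] + (1 - lv[k]) * (1 - conversion) else 1 - conversion
        if (runif(1) >= pr) b[p] <- "T"
      }
      paste0(designs$barcode[k], paste(b, collapse = ""))
    }, character(1))
    ids <- c(ids, sprintf("%s_r%05d", designs$variant_id[k], seq_len(depth[k])))
    seqs <- c(seqs, reads)
  }
  con <- file(out_fastq, "w")
  if (length(ids))
    writeLines(paste0("@", ids, "\n", seqs, "\n+\n",
                      vapply(nchar(seqs), function(n) strrep("I", n), character(1))),
               con)
  close(con)
  list(fastq = out_fastq,
       truth = data.frame(variant_id = designs$variant_id, true_level = lv,
                          n_reads = depth, stringsAsFactors = FALSE))
}

# ---- translation / polysome data -------------------------------------------

#' Simulate ribosome-profiling counts and a polysome-fraction table
#'
#' Plants a translation-efficiency effect: `genes` m5C genes whose TE is
#' multiplied by `planted_te_shift` relative to `genes` control genes, with
#' log-normal biological TE variation and Poisson count noise for mRNA and
#' ribosome-protected-fragment (RPF) libraries. Also emits a site x fraction
#' polysome methylation table where each site follows a planted monotone
#' trend across fractions (most sites decreasing, i.e. highest methylation in
#' ribosome-free fractions).
#'
#' @param genes genes per group (m5C and control).
#' @param planted_te_shift TE multiplier applied to m5C genes (> 0; 1 = null).
#' @param seed integer seed.
#' @param te_sdlog log-normal SD of gene-level TE variation.
#' @param n_fraction_sites,n_fractions size of the polysome table.
#' @param frac_depth mean read count per site/fraction cell.
#' @return list with `mrna_counts`, `rpf_counts`, `gene_lengths` (named
#'   vectors), `m5c_genes`, `polysome` (site, type, fraction, level, reads),
#'   `truth` (per-gene TE multiplier and per-site trend direction).
#' @export
simulate_translation_data <- function(genes = 500L, planted_te_shift = 0.7,
                                      seed = NULL, te_sdlog = 0.5,
                                      n_fraction_sites = 60L, n_fractions = 8L,
                                      frac_depth = 40) {
  if (planted_te_shift <= 0) stop("planted_te_shift must be > 0")
  .set_seed(seed)
  n <- 2L * genes
  ids <- sprintf("GENE%05d", seq_len(n))
  m5c <- ids[seq_len(genes)]
  len <- sample(500:3000, n, replace = TRUE)
  abun <- rlnorm(n, meanlog = log(100), sdlog = 1)
  te <- rlnorm(n, meanlog = 0, sdlog = te_sdlog) *
    ifelse(ids %in% m5c, planted_te_shift, 1)
  mrna <- rpois(n, abun * len / 1000)
  rpf <- rpois(n, abun * len / 1000 * te)
  frac_sites <- sprintf("SITE%04d", seq_len(n_fraction_sites))
  direction <- sample(c("down", "up"), n_fraction_sites, replace = TRUE,
                      prob = c(0.8, 0.2))
  poly <- do.call(rbind, lapply(seq_len(n_fraction_sites), function(k) {
    hi <- runif(1, 0.5, 0.9); lo <- runif(1, 0.02, 0.2)
    lev <- seq(hi, lo, length.out = n_fractions)
    if (direction[k] == "up") lev <- rev(lev)
    data.frame(site = frac_sites[k],
               type = sample(c("TypeI", "TypeII"), 1),
               fraction = seq_len(n_fractions),
               level = lev,
               reads = rpois(n_fractions, frac_depth),
               stringsAsFactors = FALSE)
  }))
  list(mrna_counts = setNames(mrna, ids),
       rpf_counts = setNames(rpf, ids),
       gene_lengths = setNames(len, ids),
       m5c_genes = m5c,
       polysome = poly,
       truth = list(te_multiplier = setNames(ifelse(ids %in% m5c,
                                                    planted_te_shift, 1), ids),
                    fraction_trend = setNames(direction, frac_sites)))
}
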