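# Reporter mutagenesis: systematic variant library design around a Type II
# site, barcode demultiplexing of targeted bisulfite reads, and per-variant
# methylation quantification.

# Conversion-proof barcodes: alphabet {A,G,T} (no C, so bisulfite conversion
# cannot alter them), pairwise Hamming distance >= min_dist.
.make_barcodes <- function(n, len = 10L, min_dist = 3L) {
  out <- character(0)
  mat <- matrix(character(0), nrow = 0, ncol = len)
  tries <- 0L
  while (length(out) < n) {
    cand <- sample(c("A", "G", "T"), len, replace = TRUE)
    ok <- TRUE
    if (nrow(mat))
      ok <- all(rowSums(mat != matrix(cand, nrow(mat), len, byrow = TRUE)) >= min_dist)
    if (ok) {
      out <- c(out, paste(cand, collapse = ""))
      mat <- rbind(mat, cand)
    }
    tries <- tries + 1L
    if (tries > 200000L) stop("cannot generate ", n, " barcodes at distance ",
                              min_dist, "; increase length")
  }
  out
}

.apply_subs <- function(chars, pos1, base) {
  chars[pos1] <- base
  chars
}

#' Design a systematic reporter variant library
#'
#' Enumerates sequence variants of a Type II site insert, mirroring the
#' high-throughput mutagenesis schemes: `core_motif` substitutes all 4^4
#' combinations at +1..+4 (256 variants, the original among them); `flank`
#' substitutes single bases at -3 and the full 4 x 4 grid at (-2, +5);
#' `loop` produces the truncation (deleting the -2 and +5 bases of the loop)
#' and the A1..A4 extensions (one to four As added at both ends of the loop);
#' `stem` breaks base pairs by replacing the C/G base of designated stem
#' pairs with A on one side. Each variant receives a fresh conversion-proof
#' barcode (alphabet A/G/T, pairwise Hamming distance >= 3).
#'
#' @param insert DNA insert sequence carrying exactly one target cytosine.
#' @param site_offset 0-based offset of the target C within `insert`.
#' @param scheme one of `"all"`, `"core_motif"`, `"flank"`, `"loop"`,
#'   `"stem"`, `"original"`.
#' @param loop 0-based (start, end) interval of the hairpin loop within the
#'   insert; required for the loop scheme.
#' @param stem_pairs data.frame with 0-based columns `pos5`, `pos3` listing
#'   the stem's base-pair positions (innermost first); required for the stem
#'   scheme.
#' @param disrupt_sets list of integer vectors indexing rows of `stem_pairs`;
#'   each vector yields one variant with those pairs broken.
#' @param disrupt_side which side of each pair is replaced by A (`"5p"` or
#'   `"3p"`).
#' @param barcode_len barcode length.
#' @param seed integer seed for barcode generation.
#' @return data.frame `variant_id`, `barcode`, `sequence`, `category`,
#'   `descriptor`, `target_offset` (0-based position of the target C in
#'   `sequence`).
#' @export
design_variant_library <- function(insert, site_offset,
                                   scheme = c("all", "core_motif", "flank",
                                              "loop", "stem", "original"),
                                   loop = NULL, stem_pairs = NULL,
                                   disrupt_sets = NULL, disrupt_side = "5p",
                                   barcode_len = 10L, seed = NULL) {
  scheme <- match.arg(scheme)
  insert <- toupper(rna2dna(insert))
  chars <- strsplit(insert, "")[[1]]
  s1 <- site_offset + 1L                       # 1-based site position
  stopifnot(s1 >= 1, s1 <= length(chars))
  if (chars[s1] != "C") stop("target offset does not point at a C")
  .set_seed(seed)
  bases <- c("A", "C", "G", "T")

  rows <- list()
  add <- function(category, descriptor, seq_chars, target1) {
    rows[[length(rows) + 1L]] <<- data.frame(
      category = category, descriptor = descriptor,
      sequence = paste(seq_chars, collapse = ""),
      target_offset = target1 - 1L, stringsAsFactors = FALSE)
  }
  if (scheme %in% c("all", "original", "flank", "loop", "stem"))
    add("original", "original", chars, s1)

  if (scheme %in% c("all", "core_motif")) {
    if (s1 + 4L > length(chars)) stop("insert too short for the core motif scheme")
    grid <- expand.grid(b1 = bases, b2 = bases, b3 = bases, b4 = bases,
                        stringsAsFactors = FALSE)
    for (r in seq_len(nrow(grid))) {
      v <- chars
      v[(s1 + 1L):(s1 + 4L)] <- unlist(grid[r, ])
      add("core_motif", paste0("core:", dna2rna(paste(unlist(grid[r, ]), collapse = ""))),
          v, s1)
    }
  }
  if (scheme %in% c("all", "flank")) {
    if (s1 - 3L < 1 || s1 + 5L > length(chars))
      stop("insert too short for the flank scheme")
    for (b in setdiff(bases, chars[s1 - 3L]))
      add("flank_sub", sprintf("p-3:%s>%s", dna2rna(chars[s1 - 3L]), dna2rna(b)),
          .apply_subs(chars, s1 - 3L, b), s1)
    for (b2 in bases) for (b5 in bases) {
      if (b2 == chars[s1 - 2L] && b5 == chars[s1 + 5L]) next
      toks <- c(if (b2 != chars[s1 - 2L])
                  sprintf("p-2:%s>%s", dna2rna(chars[s1 - 2L]), dna2rna(b2)),
                if (b5 != chars[s1 + 5L])
                  sprintf("p+5:%s>%s", dna2rna(chars[s1 + 5L]), dna2rna(b5)))
      v <- .apply_subs(.apply_subs(chars, s1 - 2L, b2), s1 + 5L, b5)
      add("flank_sub", paste(toks, collapse = ";"), v, s1)
    }
  }
  if (scheme %in% c("all", "loop")) {
    if (is.null(loop)) stop("loop interval required for the loop scheme")
    del <- c(s1 - 2L, s1 + 5L)
    if (any(del == s1)) stop("perturbation would delete the target C")
    v <- chars[-del]
    add("loop_trunc", "trunc:-2,+5", v, s1 - sum(del < s1))
    l1 <- loop[1] + 1L; l2 <- loop[2] + 1L
    for (nA in 1:4) {
      v <- append(chars, rep("A", nA), after = l2)     # downstream of loop end
      v <- append(v, rep("A", nA), after = l1 - 1L)    # upstream of loop start
      t1 <- s1 + if (s1 >= l1) nA else 0L
      add("loop_ext", sprintf("ext:A%d", nA), v, t1)
    }
  }
  if (scheme %in% c("all", "stem")) {
    if (is.null(stem_pairs)) stop("stem_pairs required for the stem scheme")
    if (is.null(disrupt_sets))
      disrupt_sets <- lapply(seq_len(nrow(stem_pairs)), seq_len)  # 1, 1:2, ...
    for (set in disrupt_sets) {
      v <- chars
      pos <- if (disrupt_side == "5p") stem_pairs$pos5[set] else stem_pairs$pos3[set]
      pos1 <- pos + 1L
      if (any(pos1 == s1)) stop("perturbation would delete the target C")
      if (!all(v[pos1] %in% c("C", "G")))
        stop("stem disruption targets a non-C/G base")
      v[pos1] <- "A"
      add("stem_disrupt", sprintf("stem:%s@%s", paste(set, collapse = ","),
                                  disrupt_side), v, s1)
    }
  }
  out <- do.call(rbind, rows)
  if (scheme == "all" || scheme == "original") {
    # keep a single 'original' row; schemes may re-create the original sequence
  }
  out$variant_id <- sprintf("V%04d", seq_len(nrow(out)))
  out$barcode <- .make_barcodes(nrow(out), len = barcode_len)
  out[, c("variant_id", "barcode", "sequence", "category", "descriptor",
          "target_offset")]
}

#' Rule table mapping perturbation classes to true methylation levels
#'
#' Encodes the qualitative mutagenesis findings as generator ground truth:
#' the intact NmCUCCA motif in its intact hairpin methylates at
#' `original_level`; +3 tolerates C and U (reduced level) while +3 purines
#' abolish methylation, as do other core-motif substitutions; +5 A-to-G/C and
#' -3 A-to-C/U replacements are strongly deleterious while -2 substitutions
#' are tolerated; loop truncation, progressive loop extension and increasing
#' stem disruption tune methylation down.
#'
#' @param designs design table from [design_variant_library()].
#' @param original_level true level of the unperturbed insert.
#' @return data.frame `variant_id`, `true_level`.
#' @export
default_reporter_rules <- function(designs, original_level = 0.8) {
  lvl <- vapply(seq_len(nrow(designs)), function(k) {
    cat <- designs$category[k]; d <- designs$descriptor[k]
    if (d == "original") return(1.0)
    if (cat == "core_motif") {
      motif <- sub("^core:", "", d)
      if (motif == "UCCA") return(1.0)
      m <- strsplit(motif, "")[[1]]
      if (m[1] == "U" && m[2] == "C" && m[4] == "A" && m[3] %in% c("C", "U"))
        return(0.6)                                   # +3 favours C and U
      return(0.0)
    }
    if (cat == "flank_sub") {
      toks <- strsplit(d, ";", fixed = TRUE)[[1]]
      f <- 1.0
      for (tk in toks) {
        pos <- sub("^p([+-]\\d+):.*$", "\\1", tk)
        alt <- sub("^.*>", "", tk)
        f <- f * switch(pos,
          "-3" = if (alt %in% c("C", "U")) 0.15 else 0.7,
          "-2" = 0.8,
          "+5" = if (alt %in% c("G", "C")) 0.12 else 0.7,
          1.0)
      }
      return(f)
    }
    if (cat == "loop_trunc") return(0.12)
    if (cat == "loop_ext") {
      nA <- as.integer(sub("^ext:A", "", d))
      return(c(0.75, 0.5, 0.3, 0.15)[nA])
    }
    if (cat == "stem_disrupt") {
      nb <- length(strsplit(sub("^stem:([^@]*)@.*$", "\\1", d), ",")[[1]])
      return(if (nb <= 1) 0.6 else if (nb == 2) 0.45 else 0.08)
    }
    1.0
  }, numeric(1))
  data.frame(variant_id = designs$variant_id,
             true_level = pmin(1, lvl * original_level),
             stringsAsFactors = FALSE)
}

#' Demultiplex barcoded reporter reads
#'
#' Assigns each read to a variant by its barcode prefix. Barcodes are C-free,
#' so bisulfite conversion cannot break the match; the default is exact
#' matching, with an optional Hamming tolerance (assignments must be unique
#' at the minimal distance).
#'
#' @param reads FASTQ path, `DNAStringSet`, or character vector of read
#'   sequences.
#' @param designs design table from [design_variant_library()].
#' @param max_mismatch maximum barcode Hamming distance (default 0 = exact).
#' @return list with `groups` (named list, per variant, of insert sequences
#'   with the barcode stripped), `n_assigned`, `n_unassigned`.
#' @export
demultiplex <- function(reads, designs, max_mismatch = 0L) {
  if (anyDuplicated(designs$barcode))
    stop("ambiguous design table: duplicate barcodes")
  if (is.character(reads) && length(reads) == 1 && file.exists(reads))
    reads <- Biostrings::readDNAStringSet(reads, format = "fastq")
  if (methods::is(reads, "XStringSet")) reads <- as.character(reads)
  blen <- unique(nchar(designs$barcode))
  stopifnot(length(blen) == 1)
  prefix <- substr(reads, 1L, blen)
  idx <- match(prefix, designs$barcode)
  if (max_mismatch > 0L && anyNA(idx)) {
    bc_mat <- do.call(rbind, strsplit(designs$barcode, ""))
    for (i in which(is.na(idx))) {
      d <- rowSums(bc_mat != matrix(strsplit(prefix[i], "")[[1]],
                                    nrow(bc_mat), blen, byrow = TRUE))
      best <- min(d)
      if (best <= max_mismatch && sum(d == best) == 1L) idx[i] <- which.min(d)
    }
  }
  inserts <- substr(reads, blen + 1L, nchar(reads))
  groups <- split(inserts[!is.na(idx)], designs$variant_id[idx[!is.na(idx)]])
  # keep every variant key, empty where no reads
  groups <- setNames(lapply(designs$variant_id, function(v)
    if (v %in% names(groups)) groups[[v]] else character(0)), designs$variant_id)
  list(groups = groups, n_assigned = sum(!is.na(idx)),
       n_unassigned = sum(is.na(idx)))
}

#' Quantify per-variant methylation from demultiplexed reads
#'
#' The level is the fraction of assigned reads showing C at the variant's
#' target cytosine (reads showing neither C nor T there are excluded).
#' Variants with fewer than `min_reads` assigned reads are flagged
#' unreported (their level is set to NA). Variants whose reads disagree with
#' the design at more than `contamination_threshold` of non-cytosine
#' positions are flagged contaminated.
#'
#' @param groups demultiplexed read groups from [demultiplex()].
#' @param designs design table.
#' @param min_reads minimum read count for a variant to be reported.
#' @param contamination_threshold tolerated mismatch fraction at non-C
#'   positions.
#' @return data.frame `variant_id`, `category`, `descriptor`, `n_reads`,
#'   `unconverted`, `level`, `reported`, `contaminated`.
#' @export
quantify_variants <- function(groups, designs, min_reads = 20L,
                              contamination_threshold = 0.2) {
  out <- lapply(seq_len(nrow(designs)), function(k) {
    v <- designs$variant_id[k]
    rd <- groups[[v]]
    ins <- strsplit(designs$sequence[k], "")[[1]]
    t1 <- designs$target_offset[k] + 1L
    n <- length(rd)
    if (n == 0) {
      return(data.frame(variant_id = v, category = designs$category[k],
                        descriptor = designs$descriptor[k], n_reads = 0L,
                        unconverted = NA_integer_, level = NA_real_,
                        reported = FALSE, contaminated = FALSE,
                        stringsAsFactors = FALSE))
    }
    tb <- substr(rd, t1, t1)
    un <- sum(tb == "C"); cv <- sum(tb %in% c("C", "T"))
    noncpos <- which(ins != "C")
    mm <- if (length(noncpos)) {
      mean(vapply(noncpos, function(p) {
        mean(substr(rd, p, p) != ins[p])
      }, numeric(1)))
    } else 0
    reported <- n >= min_reads
    data.frame(variant_id = v, category = designs$category[k],
               descriptor = designs$descriptor[k], n_reads = n,
               unconverted = as.integer(un),
               level = if (reported && cv > 0) un / cv else NA_real_,
               reported = reported,
               contaminated = mm > contamination_threshold,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Per-position, per-base maximum methylation over core-motif variants
#'
#' For each core-motif position (+1..+4) and each base, reports the maximum
#' level among reported variants carrying that base at that position — the
#' position-wise summary of the motif requirements.
#'
#' @param results quantification table from [quantify_variants()].
#' @param designs design table (for the motif descriptors).
#' @return data.frame `position` (+1..+4), `base` (RNA), `max_level`.
#' @export
position_max_profile <- function(results, designs) {
  core <- results[results$category == "core_motif" & results$reported &
                    !is.na(results$level), , drop = FALSE]
  if (!nrow(core)) stop("no reported core_motif variants")
  motifs <- sub("^core:", "", core$descriptor)
  out <- expand.grid(position = 1:4, base = c("A", "C", "G", "U"),
                     stringsAsFactors = FALSE)
  out$max_level <- vapply(seq_len(nrow(out)), function(r) {
    sel <- substr(motifs, out$position[r], out$position[r]) == out$base[r]
    if (!any(sel)) return(NA_real_)
    max(core$level[sel])
  }, numeric(1))
  out <- out[order(out$position, out$base), ]
  rownames(out) <- NULL
  out
}
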