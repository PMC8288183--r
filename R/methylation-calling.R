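# Conversion-aware per-cytosine counting and m5C site calling.

#' Count bisulfite conversion events per reference cytosine
#'
#' Tallies, for every covered reference cytosine, the number of aligned reads
#' showing C (unconverted) and the coverage (reads showing C or T; reads
#' showing any other base at a C position are excluded from both counts).
#' Counting is strand-aware: on the plus strand C/T are counted at reference
#' Cs; with `both_strands = TRUE`, reference Gs are additionally counted as
#' minus-strand cytosines via G/A.
#'
#' @param alignments path to a SAM or BAM file of pre-aligned reads.
#' @param reference FASTA path, `DNAStringSet` or named character vector the
#'   reads were aligned to.
#' @param both_strands also count minus-strand cytosines (genome mode).
#' @param max_depth pileup depth cap.
#' @return data.frame with `ref`, `pos0` (0-based), `strand`, `coverage`,
#'   `unconverted`, `level` for every covered cytosine.
#' @export
count_conversions <- function(alignments, reference, both_strands = FALSE,
                              max_depth = 1e6L) {
  seqs <- .load_fasta(reference)
  bam <- .as_bam(alignments)
  hdr <- Rsamtools::scanBamHeader(bam)[[1]]$targets
  missing <- setdiff(names(hdr), names(seqs))
  if (length(missing))
    stop("alignment target(s) not in reference FASTA: ",
         paste(missing, collapse = ", "))
  pp <- Rsamtools::PileupParam(max_depth = as.integer(max_depth),
                               min_base_quality = 0L, min_mapq = 0L,
                               min_nucleotide_depth = 1L,
                               distinguish_strands = FALSE,
                               distinguish_nucleotides = TRUE,
                               include_deletions = FALSE,
                               include_insertions = FALSE)
  pu <- Rsamtools::pileup(bam, pileupParam = pp)
  if (!nrow(pu))
    return(data.frame(ref = character(), pos0 = integer(), strand = character(),
                      coverage = integer(), unconverted = integer(),
                      level = numeric(), stringsAsFactors = FALSE))
  pu$seqnames <- as.character(pu$seqnames)
  key <- paste(pu$seqnames, pu$pos)
  nuc_count <- function(nuc) {
    sel <- pu$nucleotide == nuc
    setNames(pu$count[sel], key[sel])
  }
  cnt <- lapply(c(A = "A", C = "C", G = "G", T = "T"), nuc_count)

  per_strand <- function(base, un_nuc, conv_nuc, strand) {
    out <- lapply(names(hdr), function(tx) {
      refc <- strsplit(seqs[[tx]], "")[[1]]
      pos1 <- which(refc == base)
      if (!length(pos1)) return(NULL)
      k <- paste(tx, pos1)
      un <- cnt[[un_nuc]][k]; un[is.na(un)] <- 0L
      cv <- cnt[[conv_nuc]][k]; cv[is.na(cv)] <- 0L
      cov <- as.integer(un + cv)
      keep <- cov > 0L
      if (!any(keep)) return(NULL)
      data.frame(ref = tx, pos0 = pos1[keep] - 1L, strand = strand,
                 coverage = cov[keep], unconverted = as.integer(un[keep]),
                 stringsAsFactors = FALSE)
    })
    do.call(rbind, out)
  }
  res <- per_strand("C", "C", "T", "+")
  if (both_strands) res <- rbind(res, per_strand("G", "G", "A", "-"))
  if (is.null(res))
    return(data.frame(ref = character(), pos0 = integer(), strand = character(),
                      coverage = integer(), unconverted = integer(),
                      level = numeric(), stringsAsFactors = FALSE))
  res$level <- res$unconverted / res$coverage
  res[order(res$ref, res$pos0), , drop = FALSE]
}

#' Estimate the bisulfite conversion rate
#'
#' One-iteration trimmed estimate: cytosines with an apparent level >=
#' `trim_level` (putative methylated sites) are excluded in a first pass, and
#' the rate is 1 - sum(unconverted) / sum(coverage) over the remainder.
#'
#' @param counts per-cytosine table from [count_conversions()].
#' @param trim_level level at or above which a cytosine is excluded.
#' @return conversion rate (fraction).
#' @export
estimate_conversion_rate <- function(counts, trim_level = 0.1) {
  stopifnot(is.data.frame(counts),
            all(c("coverage", "unconverted") %in% names(counts)))
  if (!nrow(counts) || sum(counts$coverage) == 0)
    stop("zero total coverage: cannot estimate conversion rate")
  lev <- counts$unconverted / counts$coverage
  keep <- lev < trim_level
  if (!any(keep)) keep <- rep(TRUE, nrow(counts))
  1 - sum(counts$unconverted[keep]) / sum(counts$coverage[keep])
}

#' Call m5C sites in one sample
#'
#' A cytosine is called iff coverage >= `min_cov`, level >= `min_level`,
#' unconverted reads >= `min_unconverted`, and the Benjamini-Hochberg adjusted
#' one-sided binomial p-value (unconverted ~ Binomial(coverage,
#' 1 - conversion_rate)) is <= `fdr`. The BH adjustment is computed over all
#' cytosines passing the coverage filter (the tested universe). tRNA-style
#' calling reuses this with `min_cov = 10`.
#'
#' @param counts per-cytosine table from [count_conversions()].
#' @param conversion_rate sample conversion rate in (0, 1].
#' @param min_cov minimum coverage (default 20 reads; 10 for tRNA analyses).
#' @param min_level minimum methylation level.
#' @param min_unconverted minimum unconverted read count.
#' @param fdr BH-adjusted p-value cutoff.
#' @param sample_id label stored in the result.
#' @return object of class `SampleCallSet`: list with `sample`,
#'   `conversion_rate`, `calls` (called sites with p/q values) and `tested`
#'   (all cytosines passing the coverage filter, with level and p/q).
#' @export
call_sites <- function(counts, conversion_rate, min_cov = 20L,
                       min_level = 0.1, min_unconverted = 3L, fdr = 0.05,
                       sample_id = "sample") {
  stopifnot(conversion_rate > 0, conversion_rate <= 1)
  tested <- counts[counts$coverage >= min_cov, , drop = FALSE]
  if (nrow(tested)) {
    p0 <- 1 - conversion_rate
    tested$p <- pbinom(tested$unconverted - 1L, tested$coverage, p0,
                       lower.tail = FALSE)
    tested$q <- p.adjust(tested$p, method = "BH")
    called <- tested$level >= min_level &
      tested$unconverted >= min_unconverted &
      tested$q <= fdr
  } else {
    tested$p <- tested$q <- numeric(0)
    called <- logical(0)
  }
  structure(list(sample = sample_id,
                 conversion_rate = conversion_rate,
                 calls = tested[called, , drop = FALSE],
                 tested = tested,
                 filters = list(min_cov = min_cov, min_level = min_level,
                                min_unconverted = min_unconverted, fdr = fdr)),
            class = "SampleCallSet")
}

#' @export
print.SampleCallSet <- function(x, ...) {
  cat("SampleCallSet '", x$sample, "': ", nrow(x$calls), " called / ",
      nrow(x$tested), " tested cytosines; conversion ",
      format(x$conversion_rate, digits = 4), "\n", sep = "")
  invisible(x)
}

.site_key <- function(df) paste(df$ref, df$pos0, df$strand)

#' Classify writer dependency of called sites
#'
#' Compares wild-type calls with knockout (and optionally rescue) levels.
#' Sites called in the wild type and covered (>= `min_cov`) in the knockout
#' are `dependent` when the knockout level is < `threshold`, otherwise
#' `independent`; `dependent` sites additionally covered in the rescue sample
#' with level >= `threshold` become `rescued`. Sites lacking coverage in a
#' required sample are `unresolved`.
#'
#' @param wt,ko,rescue `SampleCallSet` objects (`rescue` optional).
#' @param min_cov coverage required in each compared sample.
#' @param threshold methylation-level cutoff separating methylated from
#'   unmethylated (0.05).
#' @return data.frame with site key columns, `status`, and the levels in each
#'   available sample.
#' @export
classify_dependency <- function(wt, ko, rescue = NULL, min_cov = 20L,
                                threshold = 0.05) {
  stopifnot(inherits(wt, "SampleCallSet"), inherits(ko, "SampleCallSet"))
  sites <- wt$calls
  if (!nrow(sites))
    return(data.frame(ref = character(), pos0 = integer(), strand = character(),
                      wt_level = numeric(), ko_level = numeric(),
                      rescue_level = numeric(), status = character(),
                      stringsAsFactors = FALSE))
  ko_ok <- ko$tested[ko$tested$coverage >= min_cov, , drop = FALSE]
  ko_lev <- ko_ok$level[match(.site_key(sites), .site_key(ko_ok))]
  res_lev <- rep(NA_real_, nrow(sites))
  if (!is.null(rescue)) {
    r_ok <- rescue$tested[rescue$tested$coverage >= min_cov, , drop = FALSE]
    res_lev <- r_ok$level[match(.site_key(sites), .site_key(r_ok))]
  }
  status <- ifelse(is.na(ko_lev), "unresolved",
                   ifelse(ko_lev < threshold, "dependent", "independent"))
  if (!is.null(rescue))
    status[status == "dependent" & !is.na(res_lev) & res_lev >= threshold] <- "rescued"
  data.frame(ref = sites$ref, pos0 = sites$pos0, strand = sites$strand,
             wt_level = sites$level, ko_level = ko_lev, rescue_level = res_lev,
             status = status, stringsAsFactors = FALSE)
}

#' Pairwise comparison of methylation levels between two samples
#'
#' Returns sites covered by at least `min_cov` reads in both samples and with
#' level >= `min_level` in at least one of them, with both levels side by
#' side (the scatter behind pairwise sample comparisons).
#'
#' @param a,b `SampleCallSet` objects.
#' @param min_cov coverage required in both samples.
#' @param min_level level required in at least one sample.
#' @return data.frame `ref`, `pos0`, `strand`, `level_a`, `level_b`.
#' @export
compare_pairwise <- function(a, b, min_cov = 20L, min_level = 0.1) {
  stopifnot(inherits(a, "SampleCallSet"), inherits(b, "SampleCallSet"))
  ta <- a$tested[a$tested$coverage >= min_cov, , drop = FALSE]
  tb <- b$tested[b$tested$coverage >= min_cov, , drop = FALSE]
  m <- match(.site_key(ta), .site_key(tb))
  keep <- !is.na(m)
  ta <- ta[keep, , drop = FALSE]
  lb <- tb$level[m[keep]]
  sel <- ta$level >= min_level | lb >= min_level
  data.frame(ref = ta$ref[sel], pos0 = ta$pos0[sel], strand = ta$strand[sel],
             level_a = ta$level[sel], level_b = lb[sel],
             stringsAsFactors = FALSE)
}
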