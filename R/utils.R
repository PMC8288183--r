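# Internal helpers shared across modules. DNA is used on disk (T not U);
# RNA logic (UCCA etc.) is applied after T->U mapping at the analysis layer.

dna2rna <- function(x) chartr("Tt", "Uu", x)
rna2dna <- function(x) chartr("Uu", "Tt", x)

.revcomp_rna <- function(x) {
  vapply(x, function(s) {
    paste(rev(strsplit(chartr("ACGUN", "UGCAN", s), "")[[1]]), collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

# Load a reference as a named character vector of DNA strings, accepting a
# file path, a DNAStringSet, or an already-converted character vector.
.load_fasta <- function(x) {
  if (is.character(x) && length(x) == 1 && file.exists(x)) {
    x <- Biostrings::readDNAStringSet(x)
  }
  if (methods::is(x, "XStringSet")) {
    out <- as.character(x)
    names(out) <- sub("\\s.*$", "", names(x))
    return(out)
  }
  if (is.character(x) && !is.null(names(x))) return(x)
  stop("expected a FASTA path, DNAStringSet, or named character vector")
}

.set_seed <- function(seed) {
  if (!is.null(seed)) {
    stopifnot(is.numeric(seed), length(seed) == 1)
    set.seed(as.integer(seed))
  }
  invisible(NULL)
}

# Minimal SAM emitter for generator output: reads are created pre-aligned so
# positions/CIGARs are correct by construction; reading always goes through
# Rsamtools.
.write_sam <- function(path, ref_names, ref_lengths, qname, rname, pos1, seq,
                       flag = 0L, mapq = 60L) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("@HD\tVN:1.6\tSO:unknown", con)
  writeLines(sprintf("@SQ\tSN:%s\tLN:%d", ref_names, as.integer(ref_lengths)), con)
  if (length(qname)) {
    cigar <- sprintf("%dM", nchar(seq))
    qual <- vapply(nchar(seq), function(n) strrep("I", n), character(1))
    writeLines(paste(qname, flag, rname, as.integer(pos1), mapq, cigar,
                     "*", 0L, 0L, seq, qual, sep = "\t"), con)
  }
  invisible(path)
}

# Convert SAM to a sorted+indexed BAM in tempdir when needed; BAM passes through.
.as_bam <- function(path) {
  stopifnot(file.exists(path))
  if (grepl("\\.bam$", path, ignore.case = TRUE)) return(path)
  dest <- tempfile(fileext = "")
  Rsamtools::asBam(path, destination = dest, overwrite = TRUE,
                   indexDestination = TRUE)
}

.write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

.stopifnot_prob <- function(x, name) {
  if (any(!is.finite(x)) || any(x < 0) || any(x > 1))
    stop(sprintf("%s must lie in [0, 1]", name))
  invisible(x)
}
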