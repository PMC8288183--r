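# Independent oracles and shared fixtures for the test suite.

# Brute-force maximum base-pair count by exhaustive recursion over all nested
# structures (no memoisation, different decomposition from the package's DP).
bf_max_pairs <- function(seq) {
  ch <- strsplit(toupper(chartr("Tt", "Uu", seq)), "")[[1]]
  pairable <- function(a, b)
    paste0(a, b) %in% c("GC", "CG", "AU", "UA", "GU", "UG")
  rec <- function(i, j) {
    if (j - i < 4) return(0L)
    best <- rec(i + 1L, j)                      # i unpaired
    for (k in (i + 4L):j) {
      if (pairable(ch[i], ch[k]))
        best <- max(best, 1L + rec(i + 1L, k - 1L) + rec(k + 1L, j))
    }
    best
  }
  n <- length(ch)
  if (n < 5) 0L else rec(1L, n)
}

# Exact one-sided binomial tail by direct summation of the mass function.
bf_binom_tail <- function(q, n, p) {
  if (q > n) return(0)
  sum(vapply(q:n, function(k) choose(n, k) * p^k * (1 - p)^(n - k), numeric(1)))
}

# Random RNA string.
rand_rna <- function(n) paste(sample(c("A", "C", "G", "U"), n, TRUE), collapse = "")

site_key <- function(d) paste(d$ref, d$pos0)

# Small shared transcriptome built once per test run.
fixture_env <- new.env()
small_world <- function() {
  if (is.null(fixture_env$world)) {
    tg <- make_transcriptome(n_transcripts = 6, sites_per_type = 12, seed = 4242)
    fixture_env$world <- tg
  }
  fixture_env$world
}

# Hand-written SAM fixture: reads with given bases at a single position of a
# one-transcript reference; returns the SAM path and the reference.
pileup_fixture <- function(bases, ref_base = "C", pos = 50L, ref_len = 120L) {
  ref <- strsplit(strrep("A", ref_len), "")[[1]]
  ref[pos] <- ref_base
  ref[80] <- "C"                          # second cytosine for context
  refseq <- c(TX = paste(ref, collapse = ""))
  reads <- vapply(bases, function(b) {
    r <- strsplit(strrep("A", 21L), "")[[1]]
    r[11] <- b
    paste(r, collapse = "")
  }, character(1))
  sam <- tempfile(fileext = ".sam")
  m5Ctools:::.write_sam(sam, names(refseq), nchar(refseq),
                        sprintf("r%03d", seq_along(reads)),
                        rep("TX", length(reads)), rep(pos - 10L, length(reads)),
                        reads)
  list(sam = sam, ref = refseq, pos0 = pos - 1L)
}
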