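# Base-pairing metaprofiles around m5C sites and their bootstrap background.

# Internal: pairing indicator rows (offsets -show..+show) for given positions.
# Windows that would be truncated at the transcript ends are dropped.
.pairing_rows <- function(positions, refs, seqs, flank, show, folder) {
  offs <- -show:show
  keep <- logical(length(positions))
  rows <- matrix(NA, nrow = length(positions), ncol = length(offs))
  for (k in seq_along(positions)) {
    tx <- refs[k]
    pos1 <- positions[k] + 1L           # 0-based -> 1-based
    len <- nchar(seqs[[tx]])
    if (pos1 - flank < 1 || pos1 + flank > len) next
    win <- substr(seqs[[tx]], pos1 - flank, pos1 + flank)
    fr <- folder(win, site_index = flank + 1L)
    keep[k] <- TRUE
    rows[k, ] <- fr$paired[(flank + 1L) + offs]
  }
  list(rows = rows[keep, , drop = FALSE], n_dropped = sum(!keep), offsets = offs)
}

#' Base-pairing metaprofile around a set of sites
#'
#' For each site, extracts the +/- `flank` nt window from the transcriptome,
#' folds it with [fold_window()] (or a supplied folder), and reports, for each
#' offset in -`show`..+`show` (0 = the m5C site), the fraction of sites whose
#' base at that offset is paired. Sites whose window would run off the
#' transcript are dropped and counted.
#'
#' @param sites data.frame with columns `ref` (transcript id) and `pos0`
#'   (0-based site position).
#' @param transcriptome FASTA path, `DNAStringSet`, or named character vector.
#' @param flank window half-width folded (nt).
#' @param show half-width of the reported profile (nt).
#' @param folder function (sequence, site_index) -> `FoldResult`; replace to
#'   inject externally computed structures.
#' @return list of class `Metaprofile`: `offset`, `fraction`, `n_sites`,
#'   `n_dropped`.
#' @export
pairing_metaprofile <- function(sites, transcriptome, flank = 50L, show = 25L,
                                folder = fold_window) {
  stopifnot(is.data.frame(sites), all(c("ref", "pos0") %in% names(sites)))
  seqs <- .load_fasta(transcriptome)
  missing <- setdiff(unique(sites$ref), names(seqs))
  if (length(missing))
    stop("transcripts absent from FASTA: ", paste(missing, collapse = ", "))
  pr <- .pairing_rows(sites$pos0, as.character(sites$ref), seqs, flank, show, folder)
  if (nrow(pr$rows) == 0) stop("no site has a full +/-", flank, " nt window")
  structure(list(offset = pr$offsets,
                 fraction = colMeans(pr$rows),
                 n_sites = nrow(pr$rows),
                 n_dropped = pr$n_dropped),
            class = "Metaprofile")
}

#' Bootstrap background metaprofile from motif-matched cytosines
#'
#' Builds the null expectation for [pairing_metaprofile()]: the pool is every
#' cytosine followed by UCCA on m5C-containing transcripts (transcripts
#' carrying at least one queried site), excluding the called sites themselves.
#' `n_resamples` draws of |sites| pool members without replacement each give a
#' metaprofile; the pointwise median and quartiles over resamples are
#' returned.
#'
#' @inheritParams pairing_metaprofile
#' @param n_resamples number of resamples (the analysis uses 100).
#' @param seed integer seed for reproducible resampling.
#' @param exclude optional additional data.frame of sites (`ref`, `pos0`) to
#'   drop from the pool, e.g. the full call set.
#' @return list of class `BootstrapNull`: `offset`, `median`, `lower`,
#'   `upper` (quartile curves), `n_resamples`, `pool_size`.
#' @export
sample_background <- function(sites, transcriptome, n_resamples = 100L,
                              seed = NULL, flank = 50L, show = 25L,
                              folder = fold_window, exclude = NULL) {
  stopifnot(is.data.frame(sites), all(c("ref", "pos0") %in% names(sites)))
  seqs <- .load_fasta(transcriptome)
  txs <- intersect(unique(as.character(sites$ref)), names(seqs))
  # pool: Cs followed by UCCA (DNA: CTCCA) on m5C-containing transcripts
  pool <- do.call(rbind, lapply(txs, function(tx) {
    m <- Biostrings::matchPattern("CTCCA", Biostrings::DNAString(seqs[[tx]]))
    if (!length(m)) return(NULL)
    data.frame(ref = tx, pos0 = IRanges::start(m) - 1L,
               stringsAsFactors = FALSE)
  }))
  drop <- rbind(sites[, c("ref", "pos0")],
                if (!is.null(exclude)) exclude[, c("ref", "pos0")])
  if (!is.null(pool)) {
    key <- paste(pool$ref, pool$pos0)
    pool <- pool[!key %in% paste(drop$ref, drop$pos0), , drop = FALSE]
  }
  n_sites <- nrow(sites)
  if (is.null(pool) || nrow(pool) < n_sites)
    stop(sprintf("background pool too small: %d motif cytosines for %d sites",
                 if (is.null(pool)) 0L else nrow(pool), n_sites))
  pr <- .pairing_rows(pool$pos0, as.character(pool$ref), seqs, flank, show, folder)
  if (nrow(pr$rows) < n_sites)
    stop("background pool too small after dropping truncated windows: ",
         nrow(pr$rows))
  .set_seed(seed)
  profs <- t(vapply(seq_len(n_resamples), function(i) {
    colMeans(pr$rows[sample.int(nrow(pr$rows), n_sites), , drop = FALSE])
  }, numeric(length(pr$offsets))))
  structure(list(offset = pr$offsets,
                 median = apply(profs, 2, median),
                 lower = apply(profs, 2, quantile, 0.25, names = FALSE),
                 upper = apply(profs, 2, quantile, 0.75, names = FALSE),
                 n_resamples = as.integer(n_resamples),
                 pool_size = nrow(pr$rows)),
            class = "BootstrapNull")
}

#' Group sites by methylation level
#'
#' Standard binning used for miCLIP binding-site analyses: no methylation
#' (level < 1\%), low (1\%-10\%) and high (>= 10\%, boundary inclusive).
#'
#' @param sites data.frame with a `level` column (fractions in 0..1).
#' @return the input with an added `meth_group` factor
#'   (`none`/`low`/`high`).
#' @export
group_sites_by_methylation <- function(sites) {
  stopifnot(is.data.frame(sites), "level" %in% names(sites))
  .stopifnot_prob(sites$level, "level")
  sites$meth_group <- cut(sites$level, breaks = c(-Inf, 0.01, 0.10, Inf),
                          labels = c("none", "low", "high"), right = FALSE)
  sites
}

#' Stem/loop geometry table for a set of sites
#'
#' Convenience wrapper producing the loop-length/stem-length table behind the
#' 2D geometry plots: folds each site window and applies [hairpin_geometry()].
#'
#' @inheritParams pairing_metaprofile
#' @param bulge_tol passed to [hairpin_geometry()].
#' @return data.frame `ref`, `pos0`, `loop_len`, `stem_len`, `site_in_loop`.
#' @export
stem_loop_table <- function(sites, transcriptome, flank = 50L,
                            folder = fold_window, bulge_tol = 2L) {
  seqs <- .load_fasta(transcriptome)
  out <- lapply(seq_len(nrow(sites)), function(k) {
    tx <- as.character(sites$ref[k]); pos1 <- sites$pos0[k] + 1L
    len <- nchar(seqs[[tx]])
    lo <- max(1L, pos1 - flank); hi <- min(len, pos1 + flank)
    fr <- folder(substr(seqs[[tx]], lo, hi), site_index = pos1 - lo + 1L)
    g <- hairpin_geometry(fr, bulge_tol = bulge_tol)
    data.frame(ref = tx, pos0 = sites$pos0[k], loop_len = g$loop_len,
               stem_len = g$stem_len, site_in_loop = g$site_in_loop,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
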