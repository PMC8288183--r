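# Polysome-fraction normalization/filtering, translation efficiency, and
# group comparisons.

#' Min-max normalize a site x fraction methylation matrix
#'
#' Per row, L_norm = (L - L_min) / (L_max - L_min), mapping each site's
#' levels across polysome fractions onto [0, 1]. Rows with no dynamic range
#' (L_max = L_min) are set to 0 and flagged.
#'
#' @param mat numeric matrix (rows = sites, columns = ordered fractions);
#'   NAs are ignored per row.
#' @return matrix of the same shape with attributes `l_min`, `l_max`,
#'   `constant` (logical per row).
#' @examples
#' minmax_normalize(matrix(c(0.2, 0.5, 0.8), nrow = 1))  # 0, 0.5, 1
#' @export
minmax_normalize <- function(mat) {
  mat <- as.matrix(mat)
  lmin <- apply(mat, 1, min, na.rm = TRUE)
  lmax <- apply(mat, 1, max, na.rm = TRUE)
  rng <- lmax - lmin
  const <- rng == 0
  out <- (mat - lmin) / ifelse(const, 1, rng)
  out[const, ] <- 0
  attr(out, "l_min") <- lmin
  attr(out, "l_max") <- lmax
  attr(out, "constant") <- const
  out
}

#' Filter polysome-fraction sites by read support
#'
#' Keeps sites (rows) with at least `min_reads` reads in at least
#' `min_fractions` fractions.
#'
#' @param levels numeric site x fraction level matrix.
#' @param reads integer site x fraction read-count matrix (same shape).
#' @param min_reads minimum reads per cell.
#' @param min_fractions minimum number of qualifying fractions.
#' @return the filtered `levels` matrix.
#' @export
filter_fraction_sites <- function(levels, reads, min_reads = 20L,
                                  min_fractions = 5L) {
  levels <- as.matrix(levels); reads <- as.matrix(reads)
  stopifnot(all(dim(levels) == dim(reads)))
  if (!nrow(levels)) return(levels)
  keep <- rowSums(reads >= min_reads, na.rm = TRUE) >= min_fractions
  levels[keep, , drop = FALSE]
}

#' Per-gene translation efficiency from mRNA and RPF counts
#'
#' RPKM = 1e9 * count / (library size * gene length); TE = RPF RPKM / mRNA
#' RPKM. The `pass` flag marks genes whose mRNA and RPF RPKM both exceed
#' `min_rpkm` (the comparison set is further restricted by the caller to
#' genes passing in every condition).
#'
#' @param mrna_counts,rpf_counts named integer vectors over shared gene ids.
#' @param gene_lengths named vector of gene lengths (nt, > 0).
#' @param min_rpkm abundance threshold for the `pass` flag.
#' @return data.frame `gene`, `mrna_rpkm`, `rpf_rpkm`, `te`, `pass`.
#' @export
compute_te <- function(mrna_counts, rpf_counts, gene_lengths, min_rpkm = 2) {
  genes <- intersect(names(mrna_counts), names(rpf_counts))
  genes <- intersect(genes, names(gene_lengths))
  if (!length(genes)) stop("no shared gene ids")
  len <- gene_lengths[genes]
  if (any(len <= 0)) stop("zero-length gene(s): ",
                          paste(genes[len <= 0], collapse = ", "))
  lib_m <- sum(mrna_counts); lib_r <- sum(rpf_counts)
  if (lib_m <= 0 || lib_r <= 0) stop("library sizes must be > 0")
  mr <- 1e9 * mrna_counts[genes] / (lib_m * len)
  rr <- 1e9 * rpf_counts[genes] / (lib_r * len)
  data.frame(gene = genes, mrna_rpkm = as.numeric(mr), rpf_rpkm = as.numeric(rr),
             te = as.numeric(rr / mr),
             pass = as.numeric(mr) > min_rpkm & as.numeric(rr) > min_rpkm,
             stringsAsFactors = FALSE)
}

#' One-sided Kolmogorov-Smirnov comparison of TE distributions
#'
#' Compares log-TE of m5C genes (`te_a`) against control genes (`te_b`) with
#' a one-sided two-sample KS test; the default direction tests whether m5C
#' genes have stochastically lower TE. Groups smaller than 5 raise a
#' warning.
#'
#' @param te_a TE values of the m5C gene group.
#' @param te_b TE values of the control group.
#' @param direction `"a_lower"` (default) or `"a_higher"`.
#' @param log compare on the log scale (default TRUE).
#' @return list with `statistic`, `p_value`, `n_a`, `n_b`, `direction`.
#' @export
compare_te_groups <- function(te_a, te_b, direction = c("a_lower", "a_higher"),
                              log = TRUE) {
  direction <- match.arg(direction)
  te_a <- te_a[is.finite(te_a) & te_a > 0]
  te_b <- te_b[is.finite(te_b) & te_b > 0]
  if (!length(te_a) || !length(te_b)) stop("both groups must be non-empty")
  if (length(te_a) < 5 || length(te_b) < 5)
    warning("group size < 5: KS comparison is underpowered")
  x <- if (log) base::log(te_a) else te_a
  y <- if (log) base::log(te_b) else te_b
  # 'greater' tests whether the CDF of x lies above that of y (x smaller)
  alt <- if (direction == "a_lower") "greater" else "less"
  kt <- suppressWarnings(ks.test(x, y, alternative = alt))
  list(statistic = unname(kt$statistic), p_value = kt$p.value,
       n_a = length(te_a), n_b = length(te_b), direction = direction)
}

#' Subcellular localization enrichment test between gene groups
#'
#' For each subcellular compartment, compares the enrichment values
#' (log2 fold change over negative controls) of genes containing Type II
#' sites against genes containing Type I sites with a two-sided
#' Mann-Whitney U test (normal approximation with tie correction on
#' tie-heavy data, as in `stats::wilcox.test`).
#'
#' @param enrichment data.frame with a `gene` column and one numeric column
#'   per compartment.
#' @param genes_typeII,genes_typeI character vectors of gene ids.
#' @param compartments compartments to test; default all numeric columns.
#' @return data.frame `compartment`, `n_typeII`, `n_typeI`, `statistic`
#'   (Mann-Whitney U), `p_value`.
#' @export
localization_enrichment_test <- function(enrichment, genes_typeII, genes_typeI,
                                         compartments = NULL) {
  stopifnot("gene" %in% names(enrichment))
  if (is.null(compartments))
    compartments <- setdiff(names(enrichment)[vapply(enrichment, is.numeric,
                                                     logical(1))], "gene")
  if (!length(compartments)) stop("no compartment columns found")
  missing <- setdiff(compartments, names(enrichment))
  if (length(missing)) stop("missing compartment column(s): ",
                            paste(missing, collapse = ", "))
  out <- do.call(rbind, lapply(compartments, function(cp) {
    a <- enrichment[[cp]][enrichment$gene %in% genes_typeII]
    b <- enrichment[[cp]][enrichment$gene %in% genes_typeI]
    a <- a[is.finite(a)]; b <- b[is.finite(b)]
    if (length(a) < 5 || length(b) < 5)
      warning("fewer than 5 genes per group in compartment ", cp)
    wt <- suppressWarnings(wilcox.test(a, b, alternative = "two.sided"))
    data.frame(compartment = cp, n_typeII = length(a), n_typeI = length(b),
               statistic = unname(wt$statistic), p_value = wt$p.value,
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}
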