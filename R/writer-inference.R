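# Writer-enzyme inference: correlation between methyltransferase expression
# and per-sample Type II site counts.

#' Rank candidate writer enzymes by expression correlation
#'
#' Computes, for each enzyme, the correlation between its expression across
#' samples and the per-sample Type II m5C site counts, and ranks enzymes by
#' descending coefficient. Enzymes with zero expression variance have an
#' undefined coefficient and rank below all defined ones; ties are broken by
#' enzyme id so ranking is deterministic.
#'
#' @param expression numeric matrix or data.frame, enzymes x samples, with
#'   row and column names.
#' @param type2_counts named numeric vector of per-sample Type II counts.
#' @param method correlation flavour, `"spearman"` (default, robust to
#'   expression scale) or `"pearson"`.
#' @return data.frame `enzyme`, `coefficient`, `rank`, `n_samples`, sorted by
#'   rank.
#' @export
rank_writers <- function(expression, type2_counts,
                         method = c("spearman", "pearson")) {
  method <- match.arg(method)
  if (is.data.frame(expression)) {
    if (is.character(expression[[1]])) {
      rn <- expression[[1]]
      expression <- as.matrix(expression[, -1, drop = FALSE])
      rownames(expression) <- rn
    } else expression <- as.matrix(expression)
  }
  shared <- intersect(colnames(expression), names(type2_counts))
  if (length(shared) < 3)
    stop("need at least 3 shared samples; got ", length(shared))
  ex <- expression[, shared, drop = FALSE]
  cts <- type2_counts[shared]
  coefs <- apply(ex, 1, function(x) {
    if (length(unique(x)) < 2) return(NA_real_)
    suppressWarnings(cor(x, cts, method = method))
  })
  ids <- rownames(ex)
  ord <- order(-ifelse(is.na(coefs), -Inf, coefs), is.na(coefs), ids)
  out <- data.frame(enzyme = ids[ord], coefficient = coefs[ord],
                    rank = seq_along(ord), n_samples = length(shared),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}
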