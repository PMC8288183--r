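#' Fold an RNA window by base-pair maximization
#'
#' Predicts a nested secondary structure for a short RNA window (typically the
#' site +/- 50 nt context) with a Nussinov-style dynamic program over
#' Watson-Crick and G-U wobble pairs, minimum hairpin loop 3 nt. Among
#' structures with the maximal number of pairs, the one maximizing the number
#' of stacked pairs is chosen; the traceback is deterministic, so the same
#' sequence always yields the same dot-bracket. An externally computed
#' dot-bracket string (e.g. RNAfold output) can be supplied instead via
#' `dotbracket`, in which case the engine is bypassed and the string is only
#' validated.
#'
#' @param sequence single RNA (or DNA; T is mapped to U) string.
#' @param site_index optional 1-based index of the focal cytosine within the
#'   window, carried through to [hairpin_geometry()].
#' @param dotbracket optional externally computed dot-bracket string of the
#'   same length as `sequence`.
#' @return An object of class `FoldResult`: a list with `sequence` (RNA),
#'   `dotbracket`, `paired` (logical vector), `partner` (1-based pairing
#'   partner, 0 = unpaired), `n_pairs`, `n_stacks`, `site_index`.
#' @examples
#' fold_window("GGGGAAAACCCC")$dotbracket  # "((((....))))"
#' @export
fold_window <- function(sequence, site_index = NA_integer_, dotbracket = NULL) {
  stopifnot(is.character(sequence), length(sequence) == 1, nchar(sequence) >= 1)
  rna <- toupper(dna2rna(sequence))
  if (grepl("[^ACGU]", rna))
    stop("invalid characters in sequence: RNA alphabet (ACGU/T) required")
  if (is.null(dotbracket)) {
    res <- .nussinov_fold(rna)
  } else {
    res <- .parse_dotbracket(dotbracket, nchar(rna))
  }
  structure(list(sequence = rna,
                 dotbracket = res$dotbracket,
                 paired = strsplit(res$dotbracket, "")[[1]] != ".",
                 partner = as.integer(res$partner),
                 n_pairs = res$n_pairs,
                 n_stacks = res$n_stacks,
                 site_index = as.integer(site_index)),
            class = "FoldResult")
}

# Validate a dot-bracket string and derive the partner vector.
.parse_dotbracket <- function(db, n) {
  stopifnot(is.character(db), length(db) == 1)
  if (nchar(db) != n)
    stop("dot-bracket length does not match sequence length")
  ch <- strsplit(db, "")[[1]]
  if (any(!ch %in% c("(", ")", ".")))
    stop("dot-bracket may contain only '(', ')' and '.'")
  partner <- integer(n)
  open <- integer(0)
  for (i in seq_len(n)) {
    if (ch[i] == "(") open <- c(open, i)
    else if (ch[i] == ")") {
      if (!length(open)) stop("unbalanced dot-bracket")
      j <- open[length(open)]
      open <- open[-length(open)]
      partner[i] <- j; partner[j] <- i
    }
  }
  if (length(open)) stop("unbalanced dot-bracket")
  npairs <- sum(partner > 0) / 2
  nstacks <- sum(vapply(which(partner > seq_along(partner)), function(i) {
    j <- partner[i]
    i + 1 <= n && partner[i + 1] == j - 1
  }, logical(1)))
  list(dotbracket = db, partner = partner, n_pairs = npairs, n_stacks = nstacks)
}

#' @export
print.FoldResult <- function(x, ...) {
  cat("FoldResult:", nchar(x$sequence), "nt,", x$n_pairs, "pairs,",
      x$n_stacks, "stacks\n")
  cat(x$sequence, "\n", x$dotbracket, "\n", sep = "")
  invisible(x)
}

#' Stem/loop geometry of a folded window around a site
#'
#' Reads the hairpin geometry off a [fold_window()] result: the innermost base
#' pair (i, j) enclosing the site with no pairs between them defines a hairpin
#' loop of length j - i - 1 with the site in the loop; the stem length is the
#' number of pairs in the enclosing helix, walking outward and tolerating
#' bulges/internal loops up to `bulge_tol` nt per side. If the site itself is
#' paired or not enclosed by any pair, `site_in_loop` is FALSE and loop/stem
#' are reported from the nearest enclosing helix, or 0 if there is none.
#'
#' @param fold a `FoldResult`.
#' @param site_index 1-based site position in the window; defaults to the one
#'   stored in `fold`.
#' @param bulge_tol maximum bulge/internal-loop width (nt, per side) across
#'   which a helix is still counted as one stem.
#' @return list of class `HairpinGeometry` with `loop_len`, `stem_len`,
#'   `site_in_loop`.
#' @export
hairpin_geometry <- function(fold, site_index = fold$site_index, bulge_tol = 2L) {
  stopifnot(inherits(fold, "FoldResult"))
  s <- as.integer(site_index)
  partner <- fold$partner
  n <- length(partner)
  stopifnot(!is.na(s), s >= 1, s <= n)
  # innermost enclosing pair: i < s < j with partner[i] == j, minimal span
  enc <- NULL
  ii <- which(partner > seq_len(n))          # 5' members of pairs
  if (length(ii)) {
    jj <- partner[ii]
    keep <- ii < s & jj > s
    if (any(keep)) {
      ii <- ii[keep]; jj <- jj[keep]
      k <- which.min(jj - ii)
      enc <- c(ii[k], jj[k])
    }
  }
  if (is.null(enc)) {
    return(structure(list(loop_len = 0L, stem_len = 0L, site_in_loop = FALSE),
                     class = "HairpinGeometry"))
  }
  i <- enc[1]; j <- enc[2]
  inner <- if (j - i > 1) partner[(i + 1):(j - 1)] else integer(0)
  in_loop <- partner[s] == 0 && all(inner == 0)
  # walk the helix outward from (i, j)
  stem <- 1L
  a <- i; b <- j
  repeat {
    nxt <- NULL
    if (a > 1) {
      for (a2 in seq(a - 1, max(1, a - 1 - bulge_tol), by = -1)) {
        p <- partner[a2]
        if (p == 0) next               # unpaired: inside-tolerance bulge
        if (p > b) {
          if ((a - a2 - 1) <= bulge_tol && (p - b - 1) <= bulge_tol) nxt <- c(a2, p)
        }
        break                          # first paired base decides either way
      }
    }
    if (is.null(nxt)) break
    stem <- stem + 1L
    a <- nxt[1]; b <- nxt[2]
  }
  structure(list(loop_len = as.integer(j - i - 1), stem_len = stem,
                 site_in_loop = in_loop),
            class = "HairpinGeometry")
}
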