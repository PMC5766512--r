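#' Fold an RNA (or DNA) sequence into its minimum-energy nested structure
#'
#' Computes a pseudoknot-free secondary structure by an energy-minimizing
#' Nussinov-style dynamic program with per-pair energies G:C = -3, A:U = -2,
#' G:U = -1 (kcal/mol by convention) and a minimum hairpin loop of
#' `min_loop` unpaired bases. `T` is treated as `U`, so DNA-alphabet input
#' folds identically. The model is deliberately simple: it is deterministic,
#' exhaustively verifiable against structure enumeration at small lengths,
#' and adequate for hairpin topology and MFEI screening at desk scale. A
#' thermodynamic folding engine can be substituted through `backend`.
#'
#' @param sequence Single nucleotide string (length 1--1000 nt, `N` allowed
#'   and never paired).
#' @param min_loop Minimum number of unpaired bases enclosed by a pair.
#' @param backend Optional replacement folding engine: a function taking the
#'   sequence and returning `list(structure =, mfe =)` under the same
#'   contract (dot-bracket string of equal length; MFE <= 0).
#' @return A list with elements `structure` (dot-bracket string), `mfe`
#'   (kcal/mol, <= 0) and `pairs` (integer vector: 1-based partner of each
#'   position, 0 if unpaired).
#' @examples
#' fold_rna("GGGGAAAACCCC")
#' @export
fold_rna <- function(sequence, min_loop = 3, backend = NULL) {
  stopifnot(is.character(sequence), length(sequence) == 1)
  if (nchar(sequence) == 0) stop("cannot fold an empty sequence")
  if (!is.null(backend)) {
    res <- backend(sequence)
  } else {
    res <- .c_nussinov(norm_seq(sequence), as.integer(min_loop))
  }
  if (nchar(res$structure) != nchar(sequence))
    stop("folding backend returned a structure of the wrong length")
  res$pairs <- pair_table(res$structure)
  res
}

#' Partner table of a dot-bracket structure
#'
#' @param structure Dot-bracket string (balanced `(`/`)`, `.` unpaired).
#' @return Integer vector: 1-based position of each base's partner, 0 if
#'   unpaired.
#' @export
pair_table <- function(structure) {
  ch <- strsplit(structure, "")[[1]]
  pt <- integer(length(ch))
  stack <- integer(0)
  for (i in seq_along(ch)) {
    if (ch[i] == "(") {
      stack <- c(stack, i)
    } else if (ch[i] == ")") {
      if (!length(stack)) stop("unbalanced dot-bracket structure")
      j <- stack[length(stack)]
      stack <- stack[-length(stack)]
      pt[i] <- j
      pt[j] <- i
    }
  }
  if (length(stack)) stop("unbalanced dot-bracket structure")
  pt
}

#' GC content of a sequence, in percent
#'
#' @param sequence Nucleotide string.
#' @return GC percentage in `[0, 100]`.
#' @export
gc_percent <- function(sequence) {
  s <- strsplit(norm_seq(sequence), "")[[1]]
  100 * sum(s %in% c("G", "C")) / length(s)
}

#' Minimum free energy index (MFEI)
#'
#' MFEI = (MFE / length x 100) / GC%, the standard normalization of hairpin
#' free energy by length and base composition; genuine miRNA precursors are
#' strongly negative (commonly below -0.85).
#'
#' @param mfe Minimum free energy (kcal/mol, <= 0).
#' @param length Sequence length in nt.
#' @param gc GC content in percent.
#' @return The (negative) index; `NaN` when `gc` is 0.
#' @export
mfei <- function(mfe, length, gc) {
  (mfe / length * 100) / gc
}

# Number of terminal (hairpin) loops in a structure, counting only helices
# with at least `min_helix` stacked pairs; isolated pairs are spurious under
# a max-pairing model and are ignored for topology calls.
n_hairpin_loops <- function(pairs, min_helix = 2) {
  n <- length(pairs)
  keep <- logical(n)
  for (i in seq_len(n)) {
    j <- pairs[i]
    if (j <= i) next
    # helix run length through stacked pairs (i+k, j-k)
    run <- 1
    k <- 1
    while (i + k <= n && pairs[i + k] == j - k && j - k > i + k) {
      run <- run + 1
      k <- k + 1
    }
    k <- 1
    while (i - k >= 1 && pairs[i - k] == j + k) {
      run <- run + 1
      k <- k + 1
    }
    if (run >= min_helix) keep[i] <- keep[j] <- TRUE
  }
  p2 <- ifelse(keep, pairs, 0L)
  loops <- 0
  for (i in seq_len(n)) {
    j <- p2[i]
    if (j <= i) next
    if (j - i >= 1 && all(p2[seq(i + 1, length.out = j - i - 1)] == 0))
      loops <- loops + 1
  }
  loops
}
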