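#' Scoring scheme for miRNA:target duplex alignment
#'
#' Defaults follow published miRanda conventions: match +5, G:U wobble +2,
#' mismatch -3, gap open -9, gap extend -4, with the substitution scores of
#' the seed-proximal miRNA positions (`weight_range`, default 1-11)
#' multiplied by `weight` (default 4). Reported sites must reach
#' `score_min` (default 172) and a duplex energy at or below `energy_max`
#' (default -20 kcal/mol under the package's simplified pair-energy table:
#' G:C -3, A:U -2, G:U -1). The seed is miRNA positions 2-8,
#' Watson-Crick only; `seed_min` of 7 requires the full seed match.
#'
#' @param match,gu,mismatch Substitution scores.
#' @param gap_open,gap_extend Affine gap penalties (negative).
#' @param weight Multiplier on substitution scores within `weight_range`.
#' @param weight_range miRNA positions (5' based) receiving `weight`.
#' @param score_min Minimum alignment score of a reported site.
#' @param energy_max Maximum (most positive) duplex energy, kcal/mol.
#' @param seed_min Minimum contiguous Watson-Crick seed pairing (>= 2).
#' @return A `duplex_scoring_scheme` list.
#' @export
duplex_scoring_scheme <- function(match = 5, gu = 2, mismatch = -3,
                                  gap_open = -9, gap_extend = -4,
                                  weight = 4, weight_range = c(1, 11),
                                  score_min = 172, energy_max = -20,
                                  seed_min = 7) {
  if (seed_min < 2) stop("seed_min must be at least 2")
  stopifnot(is.finite(score_min), is.finite(energy_max))
  structure(list(match = match, gu = gu, mismatch = mismatch,
                 gap_open = gap_open, gap_extend = gap_extend,
                 weight = weight, weight_range = weight_range,
                 score_min = score_min, energy_max = energy_max,
                 seed_min = seed_min),
            class = "duplex_scoring_scheme")
}

# Pair classification between a miRNA base and a target base (both given
# 5'->3' in their own strands; pairing is antiparallel complementarity).
.pair_class <- function(mb, tb) {
  wc <- (mb == "A" & tb == "T") | (mb == "T" & tb == "A") |
    (mb == "G" & tb == "C") | (mb == "C" & tb == "G")
  gu <- (mb == "G" & tb == "T") | (mb == "T" & tb == "G")
  ifelse(wc, "wc", ifelse(gu, "gu", "mm"))
}

.pair_energy_r <- function(mb, tb) {
  cls <- .pair_class(mb, tb)
  gc <- (mb %in% c("G", "C")) & cls == "wc"
  ifelse(cls == "wc", ifelse(gc, -3, -2), ifelse(cls == "gu", -1, 0))
}

# Gotoh alignment of the full miRNA (read 3'->5', i.e. reversed) against a
# target window (5'->3'), global in the miRNA, free end gaps in the target.
# Returns score, per-position pairing and target span used.
.align_duplex <- function(mirna, window, scheme) {
  m <- rev(strsplit(mirna, "")[[1]]) # index i: miRNA position len-i+1
  t <- strsplit(window, "")[[1]]
  nm <- length(m)
  nt <- length(t)
  mir_pos <- nm:1 # miRNA 5'-based position for each row
  wts <- ifelse(mir_pos >= scheme$weight_range[1] &
                  mir_pos <= scheme$weight_range[2], scheme$weight, 1)
  sub <- function(i, j) {
    cls <- .pair_class(m[i], t[j])
    s <- switch(cls, wc = scheme$match, gu = scheme$gu, scheme$mismatch)
    s * wts[i]
  }
  NEG <- -1e9
  M <- matrix(NEG, nm + 1, nt + 1)  # m[i] aligned to t[j]
  Ix <- matrix(NEG, nm + 1, nt + 1) # gap in target (miRNA base unpaired)
  Iy <- matrix(NEG, nm + 1, nt + 1) # gap in miRNA (target base bulged)
  M[1, ] <- 0 # free leading target gap
  Ix[1, ] <- 0
  for (i in seq_len(nm)) {
    for (j in seq_len(nt)) {
      s <- sub(i, j)
      M[i + 1, j + 1] <- s + max(M[i, j], Ix[i, j], Iy[i, j])
      Ix[i + 1, j + 1] <- max(M[i, j + 1] + scheme$gap_open,
                              Ix[i, j + 1] + scheme$gap_extend)
      Iy[i + 1, j + 1] <- max(M[i + 1, j] + scheme$gap_open,
                              Iy[i + 1, j] + scheme$gap_extend)
    }
  }
  ends <- pmax(M[nm + 1, ], Ix[nm + 1, ]) # free trailing target gap
  jend <- which.max(ends)
  score <- ends[jend]
  # traceback for the pairing rendering and energy
  i <- nm + 1
  j <- jend
  state <- if (M[nm + 1, jend] >= Ix[nm + 1, jend]) "M" else "Ix"
  pairs_m <- character(0)
  pairs_t <- character(0)
  bond <- character(0)
  mirpos_of_pair <- integer(0)
  jmin <- j
  while (i > 1) {
    if (state == "M") {
      s <- sub(i - 1, j - 1)
      prev <- c(M[i - 1, j - 1], Ix[i - 1, j - 1], Iy[i - 1, j - 1])
      cls <- .pair_class(m[i - 1], t[j - 1])
      pairs_m <- c(m[i - 1], pairs_m)
      pairs_t <- c(t[j - 1], pairs_t)
      bond <- c(switch(cls, wc = "|", gu = ":", " "), bond)
      mirpos_of_pair <- c(mir_pos[i - 1], mirpos_of_pair)
      i <- i - 1
      j <- j - 1
      jmin <- j
      state <- c("M", "Ix", "Iy")[which.max(prev)]
    } else if (state == "Ix") {
      up_m <- M[i - 1, j] + scheme$gap_open
      up_x <- Ix[i - 1, j] + scheme$gap_extend
      pairs_m <- c(m[i - 1], pairs_m)
      pairs_t <- c("-", pairs_t)
      bond <- c(" ", bond)
      mirpos_of_pair <- c(mir_pos[i - 1], mirpos_of_pair)
      i <- i - 1
      state <- if (up_m >= up_x) "M" else "Ix"
    } else { # Iy
      left_m <- M[i, j - 1] + scheme$gap_open
      left_y <- Iy[i, j - 1] + scheme$gap_extend
      pairs_m <- c("-", pairs_m)
      pairs_t <- c(t[j - 1], pairs_t)
      bond <- c(" ", bond)
      j <- j - 1
      jmin <- j
      state <- if (left_m >= left_y) "M" else "Iy"
    }
  }
  energy <- sum(ifelse(bond == " ", 0,
                       .pair_energy_r(pairs_m, pairs_t)))
  list(score = score, energy = energy,
       t_start = jmin, t_end = jend - 1,
       duplex = paste0("miRNA 3'-", paste(rev(pairs_m), collapse = ""),
                       "-5'\n         ", paste(rev(bond), collapse = ""),
                       "\nUTR   5'-", paste(rev(pairs_t), collapse = ""),
                       "-3'"),
       bond = bond, mirpos = mirpos_of_pair)
}

#' Scan a 3'-UTR for miRNA target sites
#'
#' Candidate sites are anchored at exact Watson-Crick reverse-complement
#' matches of the miRNA seed (positions 2-8). Each anchor is extended by an
#' affine-gap duplex alignment of the full miRNA against the surrounding
#' UTR window with seed-proximally weighted scoring; the duplex energy is
#' the sum of pair energies (G:C -3, A:U -2, G:U -1) over aligned pairs.
#' Sites reaching `scheme$score_min` with energy at most
#' `scheme$energy_max` are reported; overlapping sites are resolved to the
#' best-scoring one.
#'
#' @param mirna miRNA sequence, 5'->3' (18-25 nt).
#' @param utr 3'-UTR sequence (named value or use `transcript`).
#' @param scheme A [duplex_scoring_scheme()].
#' @param transcript Optional transcript id for the report.
#' @return Data frame of sites: `mirna`, `transcript`, `start`, `end`
#'   (0-based half-open in the UTR), `score`, `energy`, `seed_length`,
#'   `duplex` (three-line rendering).
#' @export
scan_targets <- function(mirna, utr, scheme = duplex_scoring_scheme(),
                         transcript = NA_character_) {
  mir <- norm_seq(mirna)
  u <- norm_seq(utr)
  if (nchar(mir) < 18 || nchar(mir) > 25)
    stop("miRNA must be 18-25 nt")
  empty <- data.frame(mirna = character(0), transcript = character(0),
                      start = integer(0), end = integer(0),
                      score = numeric(0), energy = numeric(0),
                      seed_length = integer(0), duplex = character(0),
                      stringsAsFactors = FALSE)
  seed <- substr(mir, 2, 8)
  anchor <- revcomp(seed)
  hits <- gregexpr(anchor, u, fixed = TRUE)[[1]]
  if (hits[1] == -1) return(empty)
  nm <- nchar(mir)
  sites <- list()
  for (h in as.integer(hits)) {
    # the seed complement spans [h, h+6]; miRNA 3' end pairs upstream
    ws <- max(1, h - (nm - 8) - 4)
    we <- min(nchar(u), h + 8 + 4)
    aln <- .align_duplex(mir, substr(u, ws, we), scheme)
    # contiguous Watson-Crick run within the seed-proximal region
    wc_run <- 0
    run <- 0
    for (k in seq_along(aln$bond)) {
      if (aln$bond[k] == "|") run <- run + 1 else run <- 0
      wc_run <- max(wc_run, run)
    }
    if (wc_run < scheme$seed_min) next
    if (aln$score < scheme$score_min) next
    if (aln$energy > scheme$energy_max) next
    sites[[length(sites) + 1L]] <- data.frame(
      mirna = if (!is.null(names(mirna))) names(mirna) else "miRNA",
      transcript = transcript %||% NA_character_,
      start = ws + aln$t_start - 2L, end = ws + aln$t_end - 1L,
      score = aln$score, energy = aln$energy,
      seed_length = wc_run, duplex = aln$duplex,
      stringsAsFactors = FALSE)
  }
  if (!length(sites)) return(empty)
  out <- do.call(rbind, sites)
  out <- out[order(-out$score, out$start), , drop = FALSE]
  keep <- rep(TRUE, nrow(out))
  for (i in seq_len(nrow(out))) {
    if (!keep[i]) next
    later <- which(keep & seq_len(nrow(out)) > i)
    ov <- out$start[later] < out$end[i] & out$end[later] > out$start[i]
    keep[later[ov]] <- FALSE
  }
  out <- out[keep, , drop = FALSE]
  out <- out[order(out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Scan a UTR collection for sites of a set of miRNAs
#'
#' @param mirnas Named character vector of miRNA sequences.
#' @param utrs Named character vector or `DNAStringSet` of 3'-UTRs.
#' @param scheme A [duplex_scoring_scheme()].
#' @return Data frame of all passing sites across the collection.
#' @export
scan_target_set <- function(mirnas, utrs,
                            scheme = duplex_scoring_scheme()) {
  utrs <- as.character(Biostrings::DNAStringSet(utrs))
  out <- list()
  for (mi in seq_along(mirnas)) {
    mir <- mirnas[mi]
    for (ti in seq_along(utrs)) {
      s <- scan_targets(mir, utrs[ti], scheme,
                        transcript = names(utrs)[ti] %||%
                          as.character(ti))
      if (nrow(s)) out[[length(out) + 1L]] <- s
    }
  }
  if (!length(out)) {
    return(scan_targets(paste(rep("A", 20), collapse = ""),
                        "CCCC", scheme)) # empty frame of right shape
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Number of transcripts targeted by a miRNA
#'
#' Counts transcripts (not sites) with at least one passing target site.
#'
#' @param mirna miRNA sequence (named).
#' @param utrs Named character vector or `DNAStringSet` of 3'-UTRs.
#' @param scheme A [duplex_scoring_scheme()].
#' @return Integer count of targeted transcripts.
#' @export
count_genomic_targets <- function(mirna, utrs,
                                  scheme = duplex_scoring_scheme()) {
  sites <- scan_target_set(setNames(as.character(mirna), "m"), utrs, scheme)
  length(unique(sites$transcript))
}
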