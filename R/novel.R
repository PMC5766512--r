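#' Map tags to exact genomic loci on both strands
#'
#' Exact (ungapped, mismatch-free) matching of each tag against every contig
#' of the genome, on both strands. Coordinates are 0-based half-open on the
#' forward strand; a minus-strand locus means the reverse complement of the
#' tag occupies `[start, end)`. Tags hitting more than `max_hits` loci are
#' treated as repetitive and dropped.
#'
#' @param sequences Character vector of tag sequences (or `srna_tags`).
#' @param genome A `DNAStringSet` of contigs.
#' @param max_hits Repetitive-tag cutoff (default 15).
#' @return Data frame: `sequence`, `contig`, `start`, `end`, `strand`.
#' @export
map_tags <- function(sequences, genome, max_hits = 15) {
  if (inherits(sequences, "srna_tags")) sequences <- sequences$sequence
  sequences <- norm_seq(sequences)
  genome <- Biostrings::DNAStringSet(genome)
  out <- list()
  lens <- nchar(sequences)
  for (len in sort(unique(lens))) {
    sel <- which(lens == len)
    pd <- Biostrings::PDict(sequences[sel])
    for (ci in seq_along(genome)) {
      contig <- genome[[ci]]
      L <- length(contig)
      for (strand in c("+", "-")) {
        subj <- if (strand == "+") contig else
          Biostrings::reverseComplement(contig)
        m <- Biostrings::matchPDict(pd, subj)
        starts <- BiocGenerics::start(m)
        for (pi in which(lengths(starts) > 0)) {
          s <- starts[[pi]]
          if (strand == "+") {
            st <- s - 1L
          } else {
            st <- L - (s - 1L) - len
          }
          out[[length(out) + 1L]] <- data.frame(
            sequence = sequences[sel[pi]],
            contig = names(genome)[ci] %||% as.character(ci),
            start = st, end = st + len, strand = strand,
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  if (!length(out)) {
    return(data.frame(sequence = character(0), contig = character(0),
                      start = integer(0), end = integer(0),
                      strand = character(0), stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  nhits <- table(res$sequence)
  res <- res[res$sequence %in% names(nhits)[nhits <= max_hits], ,
             drop = FALSE]
  rownames(res) <- NULL
  res
}

# The two precursor excision windows for a tag locus (0-based half-open
# genomic coords), in tag orientation: tag at the 5' arm (window extends
# `flank` nt beyond the tag's 3' end) and tag at the 3' arm (extends
# `flank` nt beyond its 5' end). Returns a list of
# list(seq, tag_start, ws, we) with ws/we 1-based genomic and seq already
# reverse-complemented for minus-strand loci.
excise_windows <- function(contig, start, end, strand, flank) {
  contig <- as.character(contig)
  L <- nchar(contig)
  tlen <- end - start
  mk <- function(ws, we) {
    seq <- substr(contig, ws, we)
    if (strand == "+") {
      tag <- start + 2L - ws
    } else {
      seq <- revcomp(seq)
      tag <- we - end + 1L
    }
    list(seq = seq, tag_start = tag, ws = ws, we = we)
  }
  if (strand == "+") {
    list(five = mk(start + 1L, min(L, end + flank)),
         three = mk(max(1L, start + 1L - flank), end))
  } else {
    list(five = mk(max(1L, start + 1L - flank), end),
         three = mk(start + 1L, min(L, end + flank)))
  }
}

# Assess whether a tag embedded in an excised genomic window sits on one arm
# of a clean hairpin. Coordinates are 1-based within `window`. Returns a
# list with `ok`, a failure `reason`, and on success the excised precursor
# (span within the window), its re-folded structure, MFE, MFEI, the arm side
# and the star span.
assess_hairpin <- function(window, tag_start, tag_len,
                           mfei_max = -0.85, min_paired_fraction = 0.6,
                           max_loop = 60, pad = 5, backend = NULL) {
  fail <- function(reason) list(ok = FALSE, reason = reason)
  n <- nchar(window)
  ti <- tag_start
  tj <- tag_start + tag_len - 1
  if (ti < 1 || tj > n) return(fail("tag_outside_window"))

  arm_geometry <- function(pairs) {
    partners <- pairs[ti:tj]
    paired <- partners > 0
    if (mean(paired) < min_paired_fraction) return(NULL)
    pp <- partners[paired]
    down <- pp > tj
    up <- pp < ti
    side <- if (sum(down) >= sum(up)) "down" else "up"
    onside <- if (side == "down") down else up
    # the arm must pair coherently with a single opposite region
    if (mean(onside) < 0.9) return(NULL)
    star <- range(pp[onside])
    list(side = side, star = star)
  }

  f1 <- fold_rna(window, backend = backend)
  g <- arm_geometry(f1$pairs)
  if (is.null(g)) return(fail("arm_not_paired"))
  loop_gap <- if (g$side == "down") g$star[1] - tj - 1 else ti - g$star[2] - 1
  if (loop_gap < 3 || loop_gap > max_loop) return(fail("loop_geometry"))

  p_start <- max(1L, min(ti, g$star[1]) - pad)
  p_end <- min(n, max(tj, g$star[2]) + pad)
  if (p_end - p_start + 1 < 50) return(fail("precursor_too_short"))
  if (p_end - p_start + 1 > 150) return(fail("precursor_too_long"))
  precursor <- substr(window, p_start, p_end)

  f2 <- fold_rna(precursor, backend = backend)
  if (f2$mfe >= 0) return(fail("no_structure"))
  if (n_hairpin_loops(f2$pairs) != 1) return(fail("not_single_hairpin"))
  ti2 <- ti - p_start + 1
  tj2 <- tj - p_start + 1
  partners2 <- f2$pairs[ti2:tj2]
  paired2 <- partners2 > 0
  if (mean(paired2) < min_paired_fraction) return(fail("arm_not_paired"))
  pp2 <- partners2[paired2]
  onside2 <- if (g$side == "down") pp2 > tj2 else pp2 < ti2
  if (mean(onside2) < 0.9) return(fail("arm_not_paired"))
  star2 <- range(pp2[onside2])

  x <- mfei(f2$mfe, nchar(precursor), gc_percent(precursor))
  if (!is.finite(x) || x > mfei_max) return(fail("mfei"))

  list(ok = TRUE, reason = "ok",
       precursor = precursor, precursor_start = p_start,
       precursor_end = p_end, structure = f2$structure, mfe = f2$mfe,
       mfei = x, arm = if (g$side == "down") "5p" else "3p",
       star_start = star2[1] + p_start - 1,
       star_end = star2[2] + p_start - 1)
}

#' Call novel miRNA hairpin candidates from genome-mapped tags
#'
#' For each mapped locus, two precursor windows are excised (tag at the 5'
#' arm, extending `flank` nt downstream; tag at the 3' arm, extending
#' `flank` nt upstream), folded, and kept when (a) the excised precursor
#' folds into a single hairpin with the tag on one arm, (b) at least
#' `min_paired_fraction` of the tag bases pair with a single opposite
#' region, (c) MFEI = (MFE / length x 100) / GC% is at most `mfei_max`, and
#' (d) the count-weighted fraction of supporting tags sharing the modal 5'
#' end (Dicer-cleavage homogeneity) is at least `min_homogeneity`.
#' Candidates are merged by precursor sequence identity and named
#' `{species}-novel-miR-{serial}`.
#'
#' @param mapped Locus data frame from [map_tags()].
#' @param genome `DNAStringSet` of contigs.
#' @param tags Optional `srna_tags` data frame supplying per-tag counts for
#'   homogeneity and support (defaults to count 1 per tag).
#' @param flank Window extension in nt (default 70).
#' @param mfei_max MFEI acceptance threshold (default -0.85).
#' @param min_paired_fraction Minimum fraction of mature-arm bases paired.
#' @param min_homogeneity Minimum 5'-end homogeneity of supporting reads.
#' @param species Name prefix for candidates.
#' @param backend Optional folding backend (see [fold_rna()]).
#' @return Data frame of candidates: name, locus, precursor and mature
#'   sequences, structure, MFE, MFEI, arm, homogeneity, supporting read
#'   count.
#' @export
call_candidates <- function(mapped, genome, tags = NULL, flank = 70,
                            mfei_max = -0.85, min_paired_fraction = 0.6,
                            min_homogeneity = 0.8, species = "bta",
                            backend = NULL) {
  genome <- Biostrings::DNAStringSet(genome)
  counts <- if (!is.null(tags))
    setNames(tags$total, tags$sequence) else
      setNames(rep(1L, length(unique(mapped$sequence))),
               unique(mapped$sequence))
  res <- list()
  for (i in seq_len(nrow(mapped))) {
    row <- mapped[i, ]
    contig <- genome[[row$contig]]
    L <- length(contig)
    tlen <- row$end - row$start
    wins <- excise_windows(contig, row$start, row$end, row$strand, flank)
    for (wd in wins) {
      ws <- wd$ws
      we <- wd$we
      if (we - ws + 1 < 50) next # clipped window too short
      a <- assess_hairpin(wd$seq, wd$tag_start, tlen, mfei_max = mfei_max,
                          min_paired_fraction = min_paired_fraction,
                          backend = backend)
      if (!a$ok) next
      # precursor genomic span
      if (row$strand == "+") {
        ps <- ws + a$precursor_start - 1L
        pe <- ws + a$precursor_end - 1L
      } else {
        pe <- we - a$precursor_start + 1L
        ps <- we - a$precursor_end + 1L
      }
      # supporting tags: mapped tags on the same strand overlapping the
      # mature arm by at least half their length (a shifted 5' end still
      # counts as — inhomogeneous — support)
      sup <- mapped[mapped$contig == row$contig &
                      mapped$strand == row$strand, , drop = FALSE]
      ov_len <- pmin(sup$end, row$end) - pmax(sup$start, row$start)
      minlen <- pmin(sup$end - sup$start, row$end - row$start)
      sup <- sup[ov_len >= 0.5 * minlen, , drop = FALSE]
      w <- counts[sup$sequence]
      w[is.na(w)] <- 1L
      five_end <- if (row$strand == "+") sup$start else sup$end
      wt <- tapply(w, five_end, sum)
      homog <- if (length(wt)) max(wt) / sum(wt) else 0
      if (homog < min_homogeneity) next
      res[[length(res) + 1L]] <- data.frame(
        contig = row$contig, start = ps - 1L, end = pe, strand = row$strand,
        precursor = a$precursor, structure = a$structure,
        mfe = a$mfe, mfei = a$mfei, arm = a$arm,
        mature = row$sequence, homogeneity = unname(homog),
        support = sum(w), stringsAsFactors = FALSE)
    }
  }
  if (!length(res)) {
    return(data.frame(name = character(0), contig = character(0),
                      start = integer(0), end = integer(0),
                      strand = character(0), precursor = character(0),
                      structure = character(0), mfe = numeric(0),
                      mfei = numeric(0), arm = character(0),
                      mature = character(0), homogeneity = numeric(0),
                      support = integer(0), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, res)
  # merge candidates sharing the same precursor sequence, then collapse
  # overlapping loci on the same strand to the best-supported window
  out <- out[order(-out$support, out$contig, out$start), , drop = FALSE]
  out <- out[!duplicated(out$precursor), , drop = FALSE]
  keep <- rep(TRUE, nrow(out))
  for (i in seq_len(nrow(out))) {
    if (!keep[i]) next
    j <- which(keep & seq_len(nrow(out)) > i &
                 out$contig == out$contig[i] & out$strand == out$strand[i])
    ov <- out$start[j] < out$end[i] & out$end[j] > out$start[i]
    keep[j[ov]] <- FALSE
  }
  out <- out[keep, , drop = FALSE]
  out$name <- sprintf("%s-novel-miR-%d", species, seq_len(nrow(out)))
  rownames(out) <- NULL
  out[, c("name", setdiff(names(out), "name"))]
}

#' Export hairpin candidates as GFF3
#'
#' Writes 1-based inclusive coordinates with the strand column, one
#' `pre_miRNA` feature per candidate.
#'
#' @param candidates Data frame from [call_candidates()].
#' @param path Output GFF3 path.
#' @export
write_candidates_gff3 <- function(candidates, path) {
  gr <- GenomicRanges::GRanges(
    seqnames = candidates$contig,
    ranges = IRanges::IRanges(start = candidates$start + 1L,
                              end = candidates$end),
    strand = candidates$strand)
  gr$type <- "pre_miRNA"
  gr$ID <- candidates$name
  gr$mfe <- candidates$mfe
  gr$mfei <- round(candidates$mfei, 4)
  rtracklayer::export(gr, path, format = "GFF3")
  invisible(path)
}

#' Dinucleotide-preserving sequence shuffle
#'
#' Altschul-Erickson shuffle: permutes a sequence while preserving its exact
#' dinucleotide composition (an Eulerian-path shuffle of the transition
#' multigraph). Used to estimate the hairpin-filter false-positive rate on
#' composition-matched decoys.
#'
#' @param sequence Nucleotide string (length >= 2).
#' @return A shuffled sequence with identical dinucleotide counts.
#' @export
shuffle_dinucleotide <- function(sequence) {
  s <- strsplit(norm_seq(sequence), "")[[1]]
  n <- length(s)
  if (n < 3) return(paste(s, collapse = ""))
  letters_ <- unique(s)
  # edge lists: for each vertex, the multiset of successors
  edges <- split(s[-1], factor(s[-n], levels = letters_))
  last <- s[n]
  repeat {
    # pick a random final edge into `last` for every other vertex, check the
    # chosen "last edges" form a tree toward `last` (Eulerian-path condition)
    pick <- list()
    ok <- TRUE
    for (v in letters_) {
      if (v == last) next
      succ <- edges[[v]]
      if (!length(succ)) { pick[[v]] <- NA_character_; next }
      pick[[v]] <- sample(succ, 1)
    }
    reach <- function(v) {
      seen <- character(0)
      while (!is.na(v) && v != last && !(v %in% seen)) {
        seen <- c(seen, v)
        v <- if (v %in% names(pick)) pick[[v]] else NA_character_
      }
      identical(v, last)
    }
    for (v in letters_) {
      if (v == last) next
      if (length(edges[[v]]) && !reach(v)) { ok <- FALSE; break }
    }
    if (ok) break
  }
  # shuffle the remaining edges, append the picked last edge
  for (v in letters_) {
    succ <- edges[[v]]
    if (v != last && length(succ)) {
      drop1 <- match(pick[[v]], succ)
      rest <- succ[-drop1]
      edges[[v]] <- c(sample(rest), pick[[v]])
    } else {
      edges[[v]] <- sample(succ)
    }
  }
  # walk the Eulerian path
  out <- character(n)
  out[1] <- s[1]
  ptr <- setNames(rep(1L, length(letters_)), letters_)
  v <- s[1]
  for (i in 2:n) {
    nxt <- edges[[v]][ptr[[v]]]
    ptr[[v]] <- ptr[[v]] + 1L
    out[i] <- nxt
    v <- nxt
  }
  paste(out, collapse = "")
}
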