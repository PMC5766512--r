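#' Construct a small-RNA read library
#'
#' A light container for one sequencing library: sample id, condition label
#' (e.g. `"CY"`/`"YK"`), reads and per-read quality strings (Phred+33).
#'
#' @param sample Sample identifier (e.g. `"CY1"`).
#' @param condition Condition label.
#' @param reads Character vector of read sequences over `{A,C,G,T,N}`.
#' @param quality Optional character vector of quality strings (same lengths
#'   as `reads`); defaults to constant Phred 40 (`"I"`).
#' @return An object of class `srna_library`.
#' @export
srna_library <- function(sample, condition, reads, quality = NULL) {
  reads <- norm_seq(reads)
  if (is.null(quality))
    quality <- vapply(nchar(reads), function(n) strrep("I", n), character(1))
  if (length(quality) != length(reads))
    stop("quality must have one entry per read")
  structure(list(sample = sample, condition = condition,
                 reads = reads, quality = quality),
            class = "srna_library")
}

#' @export
print.srna_library <- function(x, ...) {
  cat(sprintf("<srna_library> %s (%s): %d reads\n",
              x$sample, x$condition, length(x$reads)))
  invisible(x)
}

#' Read a 4-line FASTQ file into an `srna_library`
#'
#' @param path FASTQ file (Phred+33).
#' @param sample,condition Labels attached to the library; `sample` defaults
#'   to the file stem.
#' @return An `srna_library`.
#' @export
read_fastq <- function(path, sample = NULL,
                       condition = NA_character_) {
  x <- Biostrings::readDNAStringSet(path, format = "fastq",
                                    with.qualities = TRUE)
  srna_library(sample %||% sub("\\.(fastq|fq)$", "", basename(path)),
               condition, unname(as.character(x)),
               unname(as.character(S4Vectors::mcols(x)$qualities)))
}

#' Write an `srna_library` as 4-line FASTQ (Phred+33)
#'
#' @param library An `srna_library`.
#' @param path Output path.
#' @export
write_fastq <- function(library, path) {
  n <- length(library$reads)
  ids <- sprintf("%s_read%d", library$sample, seq_len(n))
  lines <- character(4 * n)
  if (n) {
    lines[seq(1, 4 * n, 4)] <- paste0("@", ids)
    lines[seq(2, 4 * n, 4)] <- library$reads
    lines[seq(3, 4 * n, 4)] <- "+"
    lines[seq(4, 4 * n, 4)] <- library$quality
  }
  writeLines(lines, path)
  invisible(path)
}

# 3' adapter trimming: rightmost position where a prefix of the adapter
# (>= min_overlap nt) matches the read suffix with <= 1 mismatch per 10
# adapter bases. Returns trimmed reads ("" when the insert is empty).
trim_adapter <- function(reads, adapter, min_overlap = 8) {
  adapter <- norm_seq(adapter)
  if (nchar(adapter) == 0) stop("adapter must be non-empty")
  if (!length(reads)) return(reads)
  ach <- strsplit(adapter, "")[[1]]
  out <- reads
  lens <- nchar(reads)
  for (len in sort(unique(lens))) {
    sel <- which(lens == len)
    if (len < min_overlap) next
    m <- matrix(unlist(strsplit(reads[sel], "")), ncol = len, byrow = TRUE)
    best <- rep(NA_integer_, length(sel))
    for (p in seq_len(len - min_overlap + 1)) {
      L <- min(length(ach), len - p + 1)
      if (L < min_overlap) next
      mm <- rowSums(m[, p:(p + L - 1), drop = FALSE] !=
                      matrix(ach[seq_len(L)], length(sel), L, byrow = TRUE))
      hit <- mm <= floor(L / 10)
      best[hit] <- p # later p overwrites: rightmost occurrence wins
    }
    found <- !is.na(best)
    out[sel[found]] <- substr(reads[sel[found]], 1L, best[found] - 1L)
  }
  out
}

#' Clean a raw small-RNA library
#'
#' Drops low-quality reads (mean Phred below `min_mean_quality`), removes
#' the 3' sequencing adapter (rightmost match of an adapter prefix of at
#' least 8 nt with at most 1 mismatch per 10 adapter bases), and discards
#' reads outside `[min_len, max_len]` nt or containing more than `max_n`
#' ambiguous bases.
#'
#' @param library An `srna_library` of raw reads.
#' @param adapter 3' adapter sequence (non-empty).
#' @param min_len,max_len Retained post-trim length range (nt).
#' @param max_n Maximum number of `N` bases per retained read.
#' @param min_mean_quality Minimum mean Phred score.
#' @return A list with `library` (the cleaned `srna_library`) and `stats`
#'   (one-row data frame: raw, low-quality, trimmed, dropped-by-length/N and
#'   clean read counts).
#' @export
clean_reads <- function(library, adapter, min_len = 10, max_len = 50,
                        max_n = 0, min_mean_quality = 20) {
  stopifnot(inherits(library, "srna_library"))
  if (nchar(adapter) == 0) stop("adapter must be non-empty")
  reads <- library$reads
  qual <- library$quality
  raw_n <- length(reads)

  if (raw_n) {
    mq <- vapply(qual, function(q) mean(utf8ToInt(q)) - 33, numeric(1),
                 USE.NAMES = FALSE)
    ok_q <- mq >= min_mean_quality
  } else ok_q <- logical(0)
  reads <- reads[ok_q]
  qual <- qual[ok_q]

  trimmed <- trim_adapter(reads, adapter)
  qual <- substr(qual, 1L, nchar(trimmed))

  len <- nchar(trimmed)
  n_count <- nchar(trimmed) - nchar(gsub("N", "", trimmed, fixed = TRUE))
  keep <- len >= min_len & len <= max_len & n_count <= max_n
  clean <- srna_library(library$sample, library$condition,
                        trimmed[keep], qual[keep])
  stats <- data.frame(
    sample = library$sample, condition = library$condition,
    raw_reads = raw_n, low_quality = raw_n - sum(ok_q),
    adapter_trimmed = sum(trimmed != reads),
    dropped_short = sum(len < min_len), dropped_long = sum(len > max_len),
    dropped_n = sum(len >= min_len & len <= max_len & n_count > max_n),
    clean_reads = length(clean$reads), stringsAsFactors = FALSE)
  list(library = clean, stats = stats)
}

#' Collapse cleaned libraries to unique tags with per-sample counts
#'
#' A tag is a distinct small-RNA sequence; its count in each sample is the
#' number of reads with exactly that sequence (the "small RNAs" vs "reads"
#' distinction of library statistics tables). Per sample, tag counts sum to
#' the clean-read total by construction.
#'
#' @param libraries List of cleaned `srna_library` objects.
#' @return A data frame of class `srna_tags`: `sequence`, one integer count
#'   column per sample, and `total`; sample conditions are kept in
#'   `attr(, "conditions")`.
#' @export
collapse_tags <- function(libraries) {
  stopifnot(all(vapply(libraries, inherits, TRUE, "srna_library")))
  samples <- vapply(libraries, `[[`, "", "sample")
  conditions <- setNames(vapply(libraries, `[[`, "", "condition"), samples)
  seqs <- unlist(lapply(libraries, `[[`, "reads"), use.names = FALSE)
  if (!length(seqs)) {
    out <- data.frame(sequence = character(0))
    for (s in samples) out[[s]] <- integer(0)
    out$total <- integer(0)
  } else {
    src <- rep(samples, vapply(libraries, function(l) length(l$reads), 0L))
    tab <- table(factor(seqs), factor(src, levels = samples))
    out <- data.frame(sequence = rownames(tab), stringsAsFactors = FALSE)
    for (s in samples) out[[s]] <- as.integer(tab[, s])
    out$total <- as.integer(rowSums(tab))
    out <- out[order(-out$total, out$sequence), , drop = FALSE]
    rownames(out) <- NULL
  }
  attr(out, "conditions") <- conditions
  class(out) <- c("srna_tags", "data.frame")
  out
}

#' Per-length read counts per sample
#'
#' @param libraries List of cleaned `srna_library` objects.
#' @param range Length range to tabulate.
#' @return A data frame with `length` and one read-count column per sample;
#'   column sums equal clean-read totals.
#' @export
length_histogram <- function(libraries, range = c(10, 50)) {
  lens <- seq(range[1], range[2])
  out <- data.frame(length = lens)
  for (lib in libraries) {
    out[[lib$sample]] <-
      as.integer(table(factor(nchar(lib$reads), levels = lens)))
  }
  out
}

#' Write collapsed tags as FASTA with `tag{serial}_x{count}` headers
#'
#' @param tags An `srna_tags` data frame.
#' @param path Output FASTA path.
#' @export
write_tags_fasta <- function(tags, path) {
  x <- Biostrings::DNAStringSet(tags$sequence)
  names(x) <- sprintf("tag%d_x%d", seq_len(nrow(tags)), tags$total)
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}
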