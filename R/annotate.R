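#' Build an annotation catalog
#'
#' A catalog is an ordered list of RNA categories (known miRNA, precursor,
#' tRNA, rRNA, misc-RNA, mRNA, snoRNA/snRNA, lincRNA, ...), each holding a
#' set of named, strand-resolved reference sequences. The category order is
#' used only for reporting; ties between categories are never broken by
#' precedence (they become `AMBIGUOUS`).
#'
#' @param x Named list: one element per category, each a named character
#'   vector or `DNAStringSet` of reference sequences.
#' @return An `annotation_catalog` (list of `DNAStringSet`).
#' @export
annotation_catalog <- function(x) {
  stopifnot(is.list(x), !is.null(names(x)), !anyDuplicated(names(x)))
  out <- lapply(x, function(s) {
    nm <- names(s)
    s <- Biostrings::DNAStringSet(norm_seq(as.character(s)))
    names(s) <- nm %||% sprintf("ref%d", seq_along(s))
    if (any(Biostrings::width(s) == 0)) stop("empty reference sequence")
    s
  })
  structure(out, class = "annotation_catalog")
}

#' Read a catalog from a directory of per-category FASTA files
#'
#' Each `<category>.fa`/`.fasta` file becomes one category, named from the
#' file stem.
#'
#' @param dir Directory containing the FASTA files.
#' @return An `annotation_catalog`.
#' @export
read_catalog_dir <- function(dir) {
  files <- list.files(dir, pattern = "\\.(fa|fasta)$", full.names = TRUE)
  if (!length(files)) stop("no FASTA files found in ", dir)
  x <- lapply(files, Biostrings::readDNAStringSet)
  names(x) <- sub("\\.(fa|fasta)$", "", basename(files))
  annotation_catalog(x)
}

# Per-tag best (fewest-mismatch) hit against one category: ungapped
# substring Hamming matching of every tag against every reference.
# Returns list(dist = integer (NA if no hit within tolerance),
# ref = name of the first reference achieving it).
.category_best <- function(seqs, refs, max_mismatch) {
  n <- length(seqs)
  best <- rep(NA_integer_, n)
  bref <- rep(NA_character_, n)
  for (ri in seq_along(refs)) {
    d <- .c_min_hamming(seqs, as.character(refs[[ri]]), max_mismatch)
    upd <- !is.na(d) & (is.na(best) | d < best)
    best[upd] <- d[upd]
    bref[upd] <- names(refs)[ri]
  }
  list(dist = best, ref = bref)
}

#' Assign tags to RNA categories by catalog matching
#'
#' Each tag is compared as an ungapped substring of every reference (sense
#' strand, Hamming distance, no indels). The fewest-mismatch hit within
#' `max_mismatch` wins; equal-best hits in two or more categories yield
#' `AMBIGUOUS`; no hit (or a tag outside the `window` length range used for
#' category classification) yields `UNANNOTATED`.
#'
#' @param sequences Character vector of tag sequences (or an `srna_tags`
#'   data frame).
#' @param catalog An `annotation_catalog`.
#' @param max_mismatch Mismatch tolerance (default 2).
#' @param window Length range (nt) eligible for classification; tags outside
#'   it stay unannotated.
#' @return Data frame: `sequence`, `category`, `best_ref`, `mismatches`
#'   (NA when unannotated).
#' @export
match_tags <- function(sequences, catalog, max_mismatch = 2,
                       window = c(18, 35)) {
  if (inherits(sequences, "srna_tags")) sequences <- sequences$sequence
  sequences <- norm_seq(sequences)
  n <- length(sequences)
  category <- rep("UNANNOTATED", n)
  best_ref <- rep(NA_character_, n)
  mismatches <- rep(NA_integer_, n)
  if (!n || !length(catalog)) {
    return(data.frame(sequence = sequences, category = category,
                      best_ref = best_ref, mismatches = mismatches,
                      stringsAsFactors = FALSE))
  }
  lens <- nchar(sequences)
  todo <- which(lens >= window[1] & lens <= window[2])
  if (length(todo)) {
    sub <- sequences[todo]
    dist <- matrix(NA_integer_, length(todo), length(catalog),
                   dimnames = list(NULL, names(catalog)))
    refm <- matrix(NA_character_, length(todo), length(catalog))
    for (ci in seq_along(catalog)) {
      b <- .category_best(sub, catalog[[ci]], max_mismatch)
      dist[, ci] <- b$dist
      refm[, ci] <- b$ref
    }
    bestk <- suppressWarnings(apply(dist, 1, min, na.rm = TRUE))
    for (ti in which(is.finite(bestk))) {
      at <- which(dist[ti, ] == bestk[ti])
      i <- todo[ti]
      mismatches[i] <- bestk[ti]
      if (length(at) == 1) {
        category[i] <- names(catalog)[at]
        best_ref[i] <- refm[ti, at]
      } else {
        category[i] <- "AMBIGUOUS"
        best_ref[i] <- paste(refm[ti, at], collapse = ";")
      }
    }
  }
  data.frame(sequence = sequences, category = category, best_ref = best_ref,
             mismatches = mismatches, stringsAsFactors = FALSE)
}

#' Classify collapsed tags and tabulate per-category counts
#'
#' Produces the per-sample category count table (for reads and for unique
#' tags) and the annotated / ambiguously-annotated percentages reported in
#' library statistics tables.
#'
#' @param tags An `srna_tags` data frame from [collapse_tags()].
#' @param catalog An `annotation_catalog`.
#' @param max_mismatch,window Passed to [match_tags()].
#' @return List with `assignments` (per-tag), `category_reads` and
#'   `category_tags` (category x sample data frames), and `stats`
#'   (per-sample totals with annotated/ambiguous counts and percentages).
#' @export
classify_libraries <- function(tags, catalog, max_mismatch = 2,
                               window = c(18, 35)) {
  stopifnot(inherits(tags, "srna_tags"))
  samples <- setdiff(names(tags), c("sequence", "total"))
  asg <- match_tags(tags$sequence, catalog, max_mismatch, window)
  cats <- c(names(catalog), "AMBIGUOUS", "UNANNOTATED")
  f <- factor(asg$category, levels = cats)
  category_reads <- data.frame(category = cats)
  category_tags <- data.frame(category = cats)
  for (s in samples) {
    category_reads[[s]] <- as.integer(
      tapply(tags[[s]], f, sum, default = 0L))
    category_tags[[s]] <- as.integer(
      tapply(as.integer(tags[[s]] > 0), f, sum, default = 0L))
  }
  ann <- !(asg$category %in% c("AMBIGUOUS", "UNANNOTATED"))
  amb <- asg$category == "AMBIGUOUS"
  stats <- do.call(rbind, lapply(samples, function(s) {
    cnt <- tags[[s]]
    tr <- sum(cnt)
    tt <- sum(cnt > 0)
    data.frame(sample = s,
               tags = tt, annotated_tags = sum(cnt[ann] > 0),
               ambiguous_tags = sum(cnt[amb] > 0),
               reads = tr, annotated_reads = sum(cnt[ann]),
               ambiguous_reads = sum(cnt[amb]),
               stringsAsFactors = FALSE)
  }))
  stats$annotated_tags_pct <- 100 * stats$annotated_tags / pmax(stats$tags, 1)
  stats$ambiguous_tags_pct <- 100 * stats$ambiguous_tags / pmax(stats$tags, 1)
  stats$annotated_reads_pct <-
    100 * stats$annotated_reads / pmax(stats$reads, 1)
  stats$ambiguous_reads_pct <-
    100 * stats$ambiguous_reads / pmax(stats$reads, 1)
  list(assignments = asg, category_reads = category_reads,
       category_tags = category_tags, stats = stats)
}
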