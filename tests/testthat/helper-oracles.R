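# Independent oracles and small fixture builders shared across tests.

rand_seq <- function(n, len) {
  vapply(seq_len(n), function(i)
    paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = ""),
    character(1))
}

# per-pair energy of the package's folding model, re-stated independently
oracle_pair_energy <- function(a, b) {
  k <- paste0(a, b)
  if (k %in% c("GC", "CG")) -3
  else if (k %in% c("AT", "TA")) -2
  else if (k %in% c("GT", "TG")) -1
  else 0
}

# exhaustive recursive minimization over all nested structures
oracle_fold_energy <- function(s, min_loop = 3) {
  ch <- strsplit(s, "")[[1]]
  rec <- function(i, j) {
    if (j - i < min_loop + 1) return(0)
    best <- rec(i + 1, j)
    for (k in (i + min_loop + 1):j) {
      e <- oracle_pair_energy(ch[i], ch[k])
      if (e < 0) {
        cand <- e + (if (k - i - 1 > min_loop) rec(i + 1, k - 1) else 0) +
          (if (k + 1 <= j) rec(k + 1, j) else 0)
        if (cand < best) best <- cand
      }
    }
    best
  }
  rec(1, length(ch))
}

# energy of a reported dot-bracket structure under the model
structure_energy <- function(s, structure) {
  pt <- pair_table(structure)
  sum(vapply(which(pt > seq_along(pt)), function(i)
    oracle_pair_energy(substr(s, i, i), substr(s, pt[i], pt[i])),
    numeric(1)))
}

# Audic-Claverie tails through the negative-binomial identity:
# y | x ~ NB(size = x + 1, prob = n1 / (n1 + n2))
oracle_ac_test <- function(x, y, n1, n2) {
  C <- pnbinom(y, size = x + 1, prob = n1 / (n1 + n2))
  D <- 1 - pnbinom(y - 1, size = x + 1, prob = n1 / (n1 + n2))
  pmin(1, 2 * pmin(C, D))
}

# all-substring Hamming scan of one tag against a set of references
oracle_min_hamming <- function(tag, refs, max_mm = 2) {
  tl <- nchar(tag)
  tch <- strsplit(tag, "")[[1]]
  best <- NA_integer_
  for (r in refs) {
    rch <- strsplit(r, "")[[1]]
    if (length(rch) < tl) next
    for (o in seq_len(length(rch) - tl + 1)) {
      mm <- sum(tch != rch[o:(o + tl - 1)])
      if (mm <= max_mm && (is.na(best) || mm < best)) best <- mm
    }
  }
  best
}

# exhaustive urn enumeration of the upper-tail hypergeometric for one (N, n)
# via all C(N, n) draws; returns P(X >= m) when the first M indices are the
# term-annotated genes
oracle_hyper_enum <- function(N, n, M, m) {
  if (m == 0) return(1)
  draws <- combn(N, n)
  cnt <- colSums(draws <= M)
  mean(cnt >= m)
}

dinucleotide_counts <- function(x) {
  ch <- strsplit(x, "")[[1]]
  sort(table(paste0(ch[-length(ch)], ch[-1])))
}

# small default generator config used throughout the unit tests
small_config <- function(seed = 1, ...) {
  simulation_config(seed = seed, n_known_mirnas = 12, n_novel_mirnas = 4,
                    n_background_tags = 150, library_depths = 4000, ...)
}

printed_de_tables <- function() {
  list(
    known = read.delim(system.file("extdata", "known_de_table.tsv",
                                   package = "mirtestis")),
    novel = read.delim(system.file("extdata", "novel_de_table.tsv",
                                   package = "mirtestis")))
}

# half-unit-in-last-printed-digit tolerance of a printed decimal value
printed_tol <- function(x) {
  dec <- ifelse(grepl("\\.", x), nchar(sub("^[^.]*\\.", "", x)), 0)
  0.5 * 10^(-dec) + 1e-12
}
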