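#' Configuration for the synthetic small-RNA study generator
#'
#' The defaults emulate the structure of the six-library testis study the
#' package targets: 3 cattleyak (CY) + 3 yak (YK) libraries, reads 10-50 nt
#' with two length-density peaks (~22 nt miRNAs, ~30 nt piRNA-like
#' background), planted known and novel miRNAs with known per-group fold
#' changes, and unannotated background tags.
#'
#' @param seed Integer RNG seed; all generator randomness flows from it.
#' @param n_replicates_per_group Libraries per condition (default 3).
#' @param n_known_mirnas Planted known (catalog) miRNAs.
#' @param n_novel_mirnas Planted novel precursors in the toy genome.
#' @param n_background_tags Unannotated background tags.
#' @param planted_fold_changes Named numeric vector of CY/YK expression
#'   ratios keyed by miRNA id (`syn-miR-{i}` / `syn-novel-{i}`); `NULL`
#'   lets the generator assign a default DE design (a mix of ratios 4-8,
#'   their reciprocals, and 1).
#' @param library_depths Reads per library (default 20000).
#' @param adapter_sequence 3' adapter ligated to every read.
#' @param length_peaks The two target modes of the read-length histogram.
#' @param dispersion Negative-binomial dispersion of replicate counts
#'   (default 0.1, the standard RNA-seq scale).
#' @param utr_count Number of 3'-UTR fixtures.
#' @param term_count Number of annotation terms in the term table.
#' @return A validated `simulation_config`.
#' @export
simulation_config <- function(seed = 1, n_replicates_per_group = 3,
                              n_known_mirnas = 60, n_novel_mirnas = 12,
                              n_background_tags = 2000,
                              planted_fold_changes = NULL,
                              library_depths = 20000,
                              adapter_sequence = "TGGAATTCTCGGGTGCCAAGG",
                              length_peaks = c(22, 30),
                              dispersion = 0.1,
                              utr_count = 40, term_count = 12) {
  chk <- function(ok, field, msg) {
    if (!ok) stop("invalid configuration field '", field, "': ", msg)
  }
  chk(is.numeric(seed) && length(seed) == 1, "seed", "one integer required")
  chk(n_replicates_per_group >= 1, "n_replicates_per_group", "must be >= 1")
  chk(n_known_mirnas >= 0, "n_known_mirnas", "must be >= 0")
  chk(n_novel_mirnas >= 0, "n_novel_mirnas", "must be >= 0")
  chk(n_background_tags >= 0, "n_background_tags", "must be >= 0")
  chk(library_depths > 0, "library_depths", "must be > 0")
  chk(nchar(adapter_sequence) > 0, "adapter_sequence", "must be non-empty")
  chk(length(length_peaks) == 2 && all(length_peaks >= 10) &&
        all(length_peaks <= 50), "length_peaks",
      "two peaks within [10, 50] required")
  chk(is.null(planted_fold_changes) ||
        (is.numeric(planted_fold_changes) &&
           all(planted_fold_changes > 0) &&
           !is.null(names(planted_fold_changes))),
      "planted_fold_changes", "named positive ratios required")
  chk(dispersion >= 0, "dispersion", "must be >= 0")
  chk(utr_count >= 0, "utr_count", "must be >= 0")
  chk(term_count >= 1, "term_count", "must be >= 1")
  structure(list(seed = seed,
                 n_replicates_per_group = n_replicates_per_group,
                 n_known_mirnas = n_known_mirnas,
                 n_novel_mirnas = n_novel_mirnas,
                 n_background_tags = n_background_tags,
                 planted_fold_changes = planted_fold_changes,
                 library_depths = library_depths,
                 adapter_sequence = norm_seq(adapter_sequence),
                 length_peaks = sort(length_peaks),
                 dispersion = dispersion,
                 utr_count = utr_count, term_count = term_count),
            class = "simulation_config")
}

# miRNA-length sampler: mode at the first configured peak
.mirna_lengths <- function(n, peak) {
  sample(c(peak - 2, peak - 1, peak, peak + 1), n, replace = TRUE,
         prob = c(0.10, 0.20, 0.50, 0.20))
}

# Draw one planted hairpin precursor core (mature + loop + star) and its
# arm; the star is the reverse complement of the mature with a few
# mutations so 60-80% of arm bases remain pairable.
.draw_precursor <- function(peak) {
  mlen <- .mirna_lengths(1, peak)
  mature <- rand_dna(1, mlen)
  loop <- rand_dna(1, sample(14:17, 1))
  star <- strsplit(revcomp(mature), "")[[1]]
  nmut <- sample(2:4, 1)
  pos <- sample(seq(3, mlen - 2), nmut)
  for (p in pos) star[p] <- sample(setdiff(c("A", "C", "G", "T"), star[p]), 1)
  star <- paste(star, collapse = "")
  arm <- sample(c("5p", "3p"), 1)
  core <- if (arm == "5p") paste0(mature, loop, star) else
    paste0(star, loop, mature)
  list(mature = mature, core = core, arm = arm, mlen = mlen)
}

# Deterministic full-world construction; both exported simulate_* functions
# slice this. Everything is drawn inside one with_seed(config$seed).
sim_world <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  cfg <- config
  with_seed(cfg$seed, {
    peak1 <- cfg$length_peaks[1]
    peak2 <- cfg$length_peaks[2]
    nk <- cfg$n_known_mirnas
    nn <- cfg$n_novel_mirnas
    nb <- cfg$n_background_tags

    # --- known miRNAs -----------------------------------------------------
    known <- unique(rand_dna(max(nk * 2, 1), .mirna_lengths(max(nk * 2, 1),
                                                            peak1)))
    known <- known[seq_len(min(nk, length(known)))]
    known_ids <- if (nk) sprintf("syn-miR-%d", seq_along(known)) else
      character(0)

    # --- toy genome with planted novel precursors -------------------------
    slot_gap <- 260
    glen <- max(3000, nn * slot_gap + 1000)
    genome_chars <- strsplit(rand_dna(1, glen), "")[[1]]
    novel <- data.frame(id = character(0), mature = character(0),
                        precursor = character(0), arm = character(0),
                        contig = character(0), start = integer(0),
                        end = integer(0), strand = character(0),
                        stringsAsFactors = FALSE)
    if (nn > 0) {
      for (i in seq_len(nn)) {
        slot <- 200 + (i - 1) * slot_gap
        strand <- sample(c("+", "-"), 1)
        ok <- FALSE
        for (try in 1:60) {
          pc <- .draw_precursor(peak1)
          clen <- nchar(pc$core)
          embedded <- if (strand == "+") pc$core else revcomp(pc$core)
          genome_chars[slot:(slot + clen - 1)] <-
            strsplit(embedded, "")[[1]]
          # genomic coordinates of the mature arm (0-based half-open)
          off <- if (pc$arm == "5p") 0L else clen - pc$mlen
          if (strand == "+") {
            ms <- slot - 1L + off
          } else {
            ms <- slot - 1L + clen - off - pc$mlen
          }
          # run the pipeline's own window assessment at this locus
          contig_now <- paste(genome_chars, collapse = "")
          tlen <- pc$mlen
          wins <- excise_windows(contig_now, ms, ms + tlen, strand, 70)
          a5 <- assess_hairpin(wins$five$seq, wins$five$tag_start, tlen)
          a3 <- assess_hairpin(wins$three$seq, wins$three$tag_start, tlen)
          if (a5$ok || a3$ok) {
            novel <- rbind(novel, data.frame(
              id = sprintf("syn-novel-%d", i), mature = pc$mature,
              precursor = pc$core, arm = pc$arm, contig = "chr1",
              start = slot - 1L, end = slot - 1L + clen,
              strand = strand, stringsAsFactors = FALSE))
            ok <- TRUE
            break
          }
        }
        if (!ok) stop("failed to plant a foldable novel precursor")
      }
    }
    genome <- Biostrings::DNAStringSet(paste(genome_chars, collapse = ""))
    names(genome) <- "chr1"

    # --- background tags (piRNA-like, second length peak) -----------------
    bg_len <- pmin(50, pmax(10, round(rnorm(max(nb, 1), peak2, 1.8))))
    background <- if (nb) unique(rand_dna(nb, bg_len[seq_len(nb)])) else
      character(0)

    # --- expression design ------------------------------------------------
    ids <- c(known_ids, novel$id)
    seqs <- c(known, novel$mature)
    fc <- setNames(rep(1, length(ids)), ids)
    if (is.null(cfg$planted_fold_changes)) {
      ratios <- c(4, 5, 6, 8)
      nup <- min(8, floor(length(known_ids) / 4))
      if (nup >= 1) {
        fc[known_ids[seq_len(nup)]] <- rep_len(ratios, nup)
        fc[known_ids[nup + seq_len(nup)]] <- 1 / rep_len(ratios, nup)
      }
      nup_n <- min(4, floor(nrow(novel) / 3))
      ndn_n <- min(2, max(0, nrow(novel) - nup_n - 1))
      if (nup_n >= 1)
        fc[novel$id[seq_len(nup_n)]] <- rep_len(c(4, 6), nup_n)
      if (ndn_n >= 1)
        fc[novel$id[nup_n + seq_len(ndn_n)]] <- rep_len(c(0.2, 0.25), ndn_n)
    } else {
      hit <- intersect(names(cfg$planted_fold_changes), ids)
      fc[hit] <- cfg$planted_fold_changes[hit]
    }
    w_mirna <- rlnorm(length(ids), meanlog = 0, sdlog = 0.8)
    mass <- c(rep(0.35 / max(length(known_ids), 1), length(known_ids)),
              rep(0.05 / max(nrow(novel), 1), nrow(novel)))
    w_mirna <- w_mirna * mass
    w_bg <- rlnorm(length(background), meanlog = 0, sdlog = 1)
    w_bg <- 0.60 * w_bg / max(sum(w_bg), 1e-12)

    all_ids <- c(ids, sprintf("bg%d", seq_along(background)))
    all_seqs <- c(seqs, background)
    all_fc <- c(fc, setNames(rep(1, length(background)),
                             sprintf("bg%d", seq_along(background))))
    w <- c(w_mirna, w_bg)

    nrep <- cfg$n_replicates_per_group
    samples <- data.frame(
      sample = c(sprintf("CY%d", seq_len(nrep)),
                 sprintf("YK%d", seq_len(nrep))),
      condition = rep(c("CY", "YK"), each = nrep),
      stringsAsFactors = FALSE)
    counts <- matrix(0L, length(all_ids), nrow(samples),
                     dimnames = list(all_ids, samples$sample))
    mu <- matrix(0, length(all_ids), 2, dimnames = list(all_ids,
                                                        c("CY", "YK")))
    if (length(all_ids)) {
      for (g in c("CY", "YK")) {
        f <- if (g == "CY") all_fc else rep(1, length(all_fc))
        p <- w * f
        p <- p / sum(p)
        mu[, g] <- cfg$library_depths * p
      }
      for (si in seq_len(nrow(samples))) {
        m <- mu[, samples$condition[si]]
        counts[, si] <- if (cfg$dispersion > 0)
          rnbinom(length(m), mu = m, size = 1 / cfg$dispersion)
        else rpois(length(m), m)
      }
    }

    # --- reads ------------------------------------------------------------
    libraries <- lapply(seq_len(nrow(samples)), function(si) {
      cnt <- counts[, si]
      reads <- if (length(all_seqs))
        rep(substr(paste0(all_seqs, cfg$adapter_sequence), 1, 50), cnt)
      else character(0)
      if (length(reads)) reads <- sample(reads)
      srna_library(samples$sample[si], samples$condition[si], reads)
    })

    # --- annotation catalogs ---------------------------------------------
    catalogs <- list(
      miRNA = setNames(known, known_ids),
      precursor = setNames(
        vapply(1:6, function(i) .draw_precursor(peak1)$core, ""),
        sprintf("syn-pre-%d", 1:6)),
      tRNA = setNames(rand_dna(8, 72), sprintf("syn-tRNA-%d", 1:8)),
      rRNA = setNames(rand_dna(5, 115), sprintf("syn-rRNA-%d", 1:5)),
      misc_RNA = setNames(rand_dna(5, 80), sprintf("syn-misc-%d", 1:5)),
      mRNA = setNames(rand_dna(6, 150), sprintf("syn-mRNA-%d", 1:6)),
      snoRNA_snRNA = setNames(rand_dna(6, 100), sprintf("syn-sno-%d", 1:6)),
      lincRNA = setNames(rand_dna(4, 200), sprintf("syn-linc-%d", 1:4)))
    if (!length(known)) catalogs$miRNA <- setNames(rand_dna(1, peak1), "syn-miR-pad")
    catalog <- annotation_catalog(catalogs)

    # --- 3'-UTR fixtures with planted target sites ------------------------
    utr_n <- cfg$utr_count
    utrs <- if (utr_n) setNames(rand_dna(utr_n, sample(200:350, utr_n,
                                                       replace = TRUE)),
                                sprintf("gene%d", seq_len(utr_n)))
    else setNames(character(0), character(0))
    de_ids <- names(fc)[fc >= 4 | fc <= 0.25]
    target_mirnas <- intersect(de_ids, known_ids)
    target_mirnas <- head(target_mirnas, 6)
    plants <- list()
    if (length(target_mirnas) && utr_n >= 10) {
      for (mid in target_mirnas) {
        mir <- known[match(mid, known_ids)]
        n_genes <- sample(2:4, 1)
        genes <- sample(names(utrs)[seq_len(min(utr_n, 25))], n_genes)
        for (gn in genes) {
          site <- strsplit(revcomp(mir), "")[[1]]
          # degrade ~30% of the 3'-compensatory part, keep seed pairing
          mlen <- nchar(mir)
          deg_pos <- which(rev(seq_len(mlen)) >= 12) # miRNA positions >= 12
          nmut <- max(1, round(0.3 * length(deg_pos)))
          for (p in sample(deg_pos, nmut))
            site[p] <- sample(setdiff(c("A", "C", "G", "T"), site[p]), 1)
          site <- paste(site, collapse = "")
          u <- utrs[[gn]]
          at <- sample(seq(20, nchar(u) - nchar(site) - 20), 1)
          substr(u, at, at + nchar(site) - 1) <- site
          utrs[[gn]] <- u
          plants[[length(plants) + 1L]] <- data.frame(
            mirna = mid, gene = gn, start = at - 1L,
            end = at - 1L + nchar(site), stringsAsFactors = FALSE)
        }
      }
    }
    target_plants <- if (length(plants)) do.call(rbind, plants) else
      data.frame(mirna = character(0), gene = character(0),
                 start = integer(0), end = integer(0),
                 stringsAsFactors = FALSE)

    # --- term table with one deliberately enriched term -------------------
    extra_genes <- sprintf("xgene%d", 1:30)
    gene_universe <- c(names(utrs), extra_genes)
    tt <- list()
    planted_genes <- unique(target_plants$gene)
    for (ti in seq_len(cfg$term_count)) {
      tid <- sprintf("TERM%03d", ti)
      genes <- if (ti == 1 && length(planted_genes) >= 3) {
        unique(c(planted_genes,
                 sample(gene_universe, max(0, 3))))
      } else {
        sample(gene_universe, sample(8:25, 1))
      }
      tt[[ti]] <- data.frame(term_id = tid, gene_id = genes,
                             stringsAsFactors = FALSE)
    }
    term_table <- do.call(rbind, tt)
    enriched_term <- if (length(planted_genes) >= 3) "TERM001" else
      NA_character_

    # --- Ct table encoding planted relative expressions exactly -----------
    qpcr_genes <- head(names(fc)[fc != 1], 4)
    rel <- setNames(fc[qpcr_genes], qpcr_genes)
    mrna_rel <- c(TGT_A = 2, TGT_B = 0.5, TGT_C = 1)
    ct <- list()
    add_ct <- function(gene, ref, ref_ct, ctrl_ct, rel_val) {
      for (si in seq_len(nrow(samples))) {
        s <- samples$sample[si]
        g <- samples$condition[si]
        tgt_ct <- if (g == "YK") ctrl_ct else ctrl_ct - log2(rel_val)
        for (r in 1:3) {
          ct[[length(ct) + 1L]] <<- data.frame(
            sample = s, condition = g, gene = c(gene, ref),
            replicate = r, ct = c(tgt_ct, ref_ct),
            stringsAsFactors = FALSE)
        }
      }
    }
    for (g in qpcr_genes) add_ct(g, "RPS18", 20, 24, rel[[g]])
    for (g in names(mrna_rel)) add_ct(g, "ACTB", 19, 25, mrna_rel[[g]])
    ct_table <- if (length(ct)) do.call(rbind, ct) else
      data.frame(sample = character(0), condition = character(0),
                 gene = character(0), replicate = integer(0),
                 ct = numeric(0), stringsAsFactors = FALSE)

    truth <- list(
      mirnas = data.frame(id = ids, sequence = seqs,
                          type = c(rep("known", length(known_ids)),
                                   rep("novel", nrow(novel))),
                          fold_change = unname(fc[ids]),
                          cy_mean = if (length(ids)) mu[ids, "CY"] else
                            numeric(0),
                          yk_mean = if (length(ids)) mu[ids, "YK"] else
                            numeric(0),
                          stringsAsFactors = FALSE),
      novel_loci = novel,
      background = background,
      target_plants = target_plants,
      enriched_term = enriched_term,
      qpcr = data.frame(gene = c(qpcr_genes, names(mrna_rel)),
                        reference = c(rep("RPS18", length(qpcr_genes)),
                                      rep("ACTB", length(mrna_rel))),
                        relative_expression = c(unname(rel),
                                                unname(mrna_rel)),
                        stringsAsFactors = FALSE))

    list(config = cfg, samples = samples, counts = counts,
         libraries = libraries, genome = genome, catalog = catalog,
         utrs = utrs, term_table = term_table, ct_table = ct_table,
         truth = truth)
  })
}

#' Simulate the six small-RNA read libraries with ground truth
#'
#' Reads are adapter-ligated planted miRNA and background tag sequences
#' truncated to 50 nt, with per-replicate counts drawn from a negative
#' binomial around group means scaled by the planted CY/YK fold changes.
#' Byte-identical output for identical seeds.
#'
#' @param config A [simulation_config()].
#' @return List with `libraries` (list of [srna_library()] objects) and
#'   `truth` (planted miRNAs with group means and fold changes, novel loci,
#'   background tags, target plants, enriched term, qPCR plants).
#' @export
simulate_libraries <- function(config = simulation_config()) {
  w <- sim_world(config)
  list(libraries = w$libraries, truth = w$truth)
}

#' Simulate the pipeline's reference fixtures
#'
#' Produces the toy genome embedding the planted novel precursors, the
#' per-category annotation catalogs, 3'-UTRs carrying planted target sites,
#' the term-to-gene annotation table (with one deliberately enriched term),
#' and a Ct table that encodes planted relative expressions exactly under
#' the 2^-ddCt model.
#'
#' @param config A [simulation_config()].
#' @return List with `genome`, `catalog`, `utrs`, `term_table`, `ct_table`
#'   and `truth` (as in [simulate_libraries()]).
#' @export
simulate_fixtures <- function(config = simulation_config()) {
  w <- sim_world(config)
  list(genome = w$genome, catalog = w$catalog, utrs = w$utrs,
       term_table = w$term_table, ct_table = w$ct_table, truth = w$truth)
}
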