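#' Run the full small-RNA analysis workflow on synthetic data
#'
#' Chains every stage on generator output: simulate -> clean ->
#' collapse -> annotate -> novel discovery -> differential expression
#' (known and novel) -> target scan -> enrichment -> qPCR, writing the
#' per-stage report files (library statistics, classification table, novel
#' candidates GFF3 + FASTA, DE tables, target sites, enrichment table,
#' relative-expression table) and a JSON run manifest into `outdir`.
#' Deterministic given `config$seed`.
#'
#' @param config A [simulation_config()].
#' @param outdir Output directory (created if needed).
#' @param max_mismatch Annotation mismatch tolerance.
#' @param flank,mfei_max,min_paired_fraction,min_homogeneity Novel-discovery
#'   thresholds (see [call_candidates()]).
#' @param alpha,fc_high,fc_low DE thresholds (see [call_de()]).
#' @param scheme Target-scan [duplex_scoring_scheme()].
#' @return Invisibly, a list with every stage's in-memory result.
#' @export
run_pipeline <- function(config = simulation_config(), outdir = tempdir(),
                         max_mismatch = 2, flank = 70, mfei_max = -0.85,
                         min_paired_fraction = 0.6, min_homogeneity = 0.8,
                         alpha = 0.05, fc_high = 2, fc_low = 0.5,
                         scheme = duplex_scoring_scheme()) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  world <- sim_world(config)
  tsv <- function(d, f) {
    write.table(d, file.path(outdir, f), sep = "\t", quote = FALSE,
                row.names = FALSE)
  }

  # preprocess
  cleaned <- lapply(world$libraries, clean_reads,
                    adapter = config$adapter_sequence)
  libs <- lapply(cleaned, `[[`, "library")
  clean_stats <- do.call(rbind, lapply(cleaned, `[[`, "stats"))
  tags <- collapse_tags(libs)
  hist <- length_histogram(libs)
  tsv(hist, "length_histogram.tsv")

  # annotate
  cls <- classify_libraries(tags, world$catalog, max_mismatch = max_mismatch)
  stats <- merge(clean_stats, cls$stats, by = "sample")
  tsv(stats, "library_stats.tsv")
  tsv(cls$category_reads, "category_reads.tsv")
  tsv(cls$category_tags, "category_tags.tsv")

  # novel discovery from unannotated tags
  unann <- tags$sequence[cls$assignments$category == "UNANNOTATED"]
  mapped <- map_tags(unann, world$genome)
  cands <- call_candidates(mapped, world$genome, tags, flank = flank,
                           mfei_max = mfei_max,
                           min_paired_fraction = min_paired_fraction,
                           min_homogeneity = min_homogeneity)
  if (nrow(cands)) {
    write_candidates_gff3(cands, file.path(outdir, "novel_candidates.gff3"))
    pre <- Biostrings::DNAStringSet(setNames(cands$precursor, cands$name))
    Biostrings::writeXStringSet(pre, file.path(outdir,
                                               "novel_precursors.fa"))
    mat <- Biostrings::DNAStringSet(setNames(cands$mature, cands$name))
    Biostrings::writeXStringSet(mat, file.path(outdir, "novel_mature.fa"))
  }

  # counts per known miRNA and per novel candidate
  samples <- world$samples
  samples$clean_total <- vapply(libs, function(l) length(l$reads), 0L)[
    match(samples$sample, vapply(libs, `[[`, "", "sample"))]
  known_idx <- cls$assignments$category == "miRNA"
  count_rows <- function(sel, ids) {
    m <- matrix(0L, length(unique(ids)), nrow(samples),
                dimnames = list(unique(ids), samples$sample))
    for (s in samples$sample) {
      v <- tapply(tags[[s]][sel], ids, sum)
      m[names(v), s] <- as.integer(v)
    }
    m
  }
  de_known <- NULL
  if (any(known_idx)) {
    km <- count_rows(known_idx, cls$assignments$best_ref[known_idx])
    de_known <- call_de(km, samples, case = "CY", control = "YK",
                        alpha = alpha, fc_high = fc_high, fc_low = fc_low)
    write_de_table(de_known, file.path(outdir, "de_known.tsv"))
  }
  de_novel <- NULL
  if (nrow(cands)) {
    sel <- tags$sequence %in% cands$mature
    ids <- cands$name[match(tags$sequence[sel], cands$mature)]
    nm <- count_rows(sel, ids)
    de_novel <- call_de(nm, samples, case = "CY", control = "YK",
                        alpha = alpha, fc_high = fc_high, fc_low = fc_low)
    write_de_table(de_novel, file.path(outdir, "de_novel.tsv"))
  }

  # target prediction for DE known miRNAs
  sites <- NULL
  if (!is.null(de_known) && length(world$utrs)) {
    de_ids <- de_known$mirna[de_known$direction %in% c("UP", "DOWN")]
    mirseqs <- setNames(
      world$truth$mirnas$sequence[match(de_ids, world$truth$mirnas$id)],
      de_ids)
    mirseqs <- mirseqs[!is.na(mirseqs)]
    sites <- scan_target_set(mirseqs, world$utrs, scheme)
    tsv(sites[, setdiff(names(sites), "duplex")], "target_sites.tsv")
  }

  # enrichment of target genes
  enr <- NULL
  if (!is.null(sites) && nrow(sites)) {
    enr <- enrich(unique(sites$transcript), world$term_table)
    tsv(enr, "enrichment.tsv")
  }

  # qPCR validation table
  qp <- NULL
  if (nrow(world$ct_table)) {
    qp <- do.call(rbind, lapply(seq_len(nrow(world$truth$qpcr)), function(i) {
      g <- world$truth$qpcr$gene[i]
      r <- ddct(world$ct_table, g, world$truth$qpcr$reference[i],
                case = "CY", control = "YK")
      data.frame(gene = g, reference = r$reference, fold = r$fold,
                 ddct = r$ddct, sem = r$sem, stringsAsFactors = FALSE)
    }))
    tsv(qp, "qpcr_relative_expression.tsv")
  }

  manifest <- list(
    package = "mirtestis",
    version = as.character(utils::packageVersion("mirtestis")),
    seed = config$seed,
    thresholds = list(max_mismatch = max_mismatch,
                      annotation_window = c(18, 35), flank = flank,
                      mfei_max = mfei_max,
                      min_paired_fraction = min_paired_fraction,
                      min_homogeneity = min_homogeneity, alpha = alpha,
                      fc_high = fc_high, fc_low = fc_low,
                      score_min = scheme$score_min,
                      energy_max = scheme$energy_max,
                      seed_min = scheme$seed_min))
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)

  invisible(list(world = world, clean_stats = clean_stats, tags = tags,
                 classification = cls, candidates = cands,
                 de_known = de_known, de_novel = de_novel, sites = sites,
                 enrichment = enr, qpcr = qp, stats = stats,
                 samples = samples))
}
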