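test_that("invalid configuration fields are rejected by name", {
  expect_error(simulation_config(library_depths = 0), "library_depths")
  expect_error(simulation_config(length_peaks = c(5, 30)), "length_peaks")
  expect_error(simulation_config(n_replicates_per_group = 0),
               "n_replicates_per_group")
  expect_error(simulation_config(adapter_sequence = ""), "adapter_sequence")
  expect_error(simulation_config(planted_fold_changes = c(1, -2)),
               "planted_fold_changes")
  expect_error(simulation_config(dispersion = -1), "dispersion")
})

test_that("a degenerate configuration yields empty libraries and truth", {
  cfg <- simulation_config(n_known_mirnas = 0, n_novel_mirnas = 0,
                           n_background_tags = 0)
  sim <- simulate_libraries(cfg)
  expect_true(all(vapply(sim$libraries, function(l) length(l$reads), 0L)
                  == 0))
  expect_equal(nrow(sim$truth$mirnas), 0)
  expect_equal(nrow(sim$truth$novel_loci), 0)
})

test_that("identical seeds give byte-identical output, different seeds differ", {
  cfg <- small_config(seed = 19)
  a <- simulate_libraries(cfg)
  b <- simulate_libraries(cfg)
  expect_identical(a, b)
  d <- simulate_libraries(small_config(seed = 20))
  expect_false(identical(a$libraries[[1]]$reads, d$libraries[[1]]$reads))
  # reading/writing does not disturb determinism either
  p1 <- tempfile(fileext = ".fastq")
  p2 <- tempfile(fileext = ".fastq")
  write_fastq(a$libraries[[1]], p1)
  write_fastq(b$libraries[[1]], p2)
  expect_identical(readLines(p1), readLines(p2))
})

test_that("every planted mature sequence appears in every library", {
  sim <- simulate_libraries(small_config(seed = 25))
  planted <- sim$truth$mirnas$sequence
  adapter <- "TGGAATTCTCGGGTGCCAAGG"
  for (lib in sim$libraries) {
    inserts <- unique(substr(lib$reads, 1, 50))
    found <- vapply(planted, function(s)
      any(startsWith(inserts, s)), logical(1))
    expect_true(all(found), info = lib$sample)
  }
})

test_that("read lengths peak at the two configured modes", {
  sim <- simulate_libraries(simulation_config(seed = 33,
                                              library_depths = 20000))
  cleaned <- lapply(sim$libraries, clean_reads,
                    adapter = "TGGAATTCTCGGGTGCCAAGG")
  libs <- lapply(cleaned, `[[`, "library")
  h <- length_histogram(libs)
  total <- rowSums(h[, -1])
  expect_gte(sum(total), 1e4)
  peaks <- simulation_config()$length_peaks
  for (p in peaks) {
    at <- total[h$length == p]
    expect_gt(at, total[h$length == p - 2])
    expect_gt(at, total[h$length == p + 2])
  }
})

test_that("the empirical count ratio tracks a planted fold change of 4", {
  cfg <- simulation_config(seed = 37, n_known_mirnas = 20,
                           n_novel_mirnas = 0, n_background_tags = 300,
                           planted_fold_changes = c(`syn-miR-1` = 4),
                           library_depths = 100000)
  sim <- simulate_libraries(cfg)
  m1 <- sim$truth$mirnas$sequence[sim$truth$mirnas$id == "syn-miR-1"]
  cnt <- vapply(sim$libraries, function(l)
    sum(startsWith(l$reads, m1)), numeric(1))
  cond <- vapply(sim$libraries, `[[`, "", "condition")
  ratio <- mean(cnt[cond == "CY"]) / mean(cnt[cond == "YK"])
  expect_gt(ratio, 2.5)
  expect_lt(ratio, 6.4)
})

test_that("the genome embeds each planted precursor on its recorded strand", {
  fx <- simulate_fixtures(small_config(seed = 43))
  contig <- as.character(fx$genome[["chr1"]])
  for (i in seq_len(nrow(fx$truth$novel_loci))) {
    row <- fx$truth$novel_loci[i, ]
    span <- substr(contig, row$start + 1, row$end)
    want <- if (row$strand == "+") row$precursor else
      as.character(Biostrings::reverseComplement(
        Biostrings::DNAString(row$precursor)))
    expect_equal(span, want)
    # the mature arm is recoverable from the genome in tag orientation
    expect_true(grepl(row$mature, if (row$strand == "+") span else
      as.character(Biostrings::reverseComplement(
        Biostrings::DNAString(span))), fixed = TRUE))
  }
})

test_that("catalog categories and UTR fixtures have the advertised shape", {
  cfg <- small_config(seed = 47)
  fx <- simulate_fixtures(cfg)
  expect_setequal(
    names(fx$catalog),
    c("miRNA", "precursor", "tRNA", "rRNA", "misc_RNA", "mRNA",
      "snoRNA_snRNA", "lincRNA"))
  expect_length(fx$utrs, cfg$utr_count)
  expect_equal(length(unique(fx$term_table$term_id)), cfg$term_count)
  # planted target genes live inside the deliberately enriched term
  enr_genes <- fx$term_table$gene_id[
    fx$term_table$term_id == fx$truth$enriched_term]
  expect_true(all(unique(fx$truth$target_plants$gene) %in% enr_genes))
})
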