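adapter <- "TGGAATTCTCGGGTGCCAAGG"

test_that("adapter trimming keeps the insert and enforces the length window", {
  lib <- srna_library("s1", "CY", c(
    paste0("ACGTACGTAC", adapter),          # exact adapter suffix
    paste0("ACGTACGTA", adapter),           # post-trim length 9: dropped
    strrep("ACGTA", 6)))                    # no adapter, length 30: kept
  out <- clean_reads(lib, adapter)
  expect_equal(out$library$reads, c("ACGTACGTAC", strrep("ACGTA", 6)))
  expect_equal(out$stats$raw_reads, 3)
  expect_equal(out$stats$clean_reads, 2)
  expect_equal(out$stats$dropped_short, 1)
})

test_that("a partial 3' adapter prefix (>= 8 nt) is trimmed, shorter is not", {
  insert <- "ACGTACGTACGTACGTACGTAC"
  lib <- srna_library("s1", "CY", c(
    paste0(insert, substr(adapter, 1, 10)),
    paste0(insert, substr(adapter, 1, 5))))
  out <- clean_reads(lib, adapter)
  expect_equal(out$library$reads[1], insert)
  expect_equal(out$library$reads[2], paste0(insert, substr(adapter, 1, 5)))
})

test_that("low-quality and N-containing reads are dropped", {
  lib <- srna_library("s1", "CY",
                      c("ACGTACGTACGTACGTACGT", "ACGTACGTACNTACGTACGT",
                        "ACGTACGTACGTACGTACGT"),
                      quality = c(strrep("I", 20), strrep("I", 20),
                                  strrep("#", 20)))
  out <- clean_reads(lib, adapter)
  expect_equal(out$stats$clean_reads, 1)
  expect_equal(out$stats$low_quality, 1)
  expect_equal(out$stats$dropped_n, 1)
})

test_that("cleaning is idempotent on already-clean reads", {
  set.seed(11)
  lib <- srna_library("s1", "CY", rand_seq(50, 22))
  once <- clean_reads(lib, adapter)
  twice <- clean_reads(once$library, adapter)
  expect_identical(once$library$reads, twice$library$reads)
})

test_that("an empty library yields empty output with zeroed stats", {
  out <- clean_reads(srna_library("s1", "CY", character(0)), adapter)
  expect_length(out$library$reads, 0)
  expect_equal(out$stats$raw_reads, 0)
  expect_equal(out$stats$clean_reads, 0)
})

test_that("collapsing preserves counts per sample and pools across samples", {
  l1 <- srna_library("s1", "CY", c("ACGTACGTAC", "ACGTACGTAC", "TTTTTTTTTT"))
  l2 <- srna_library("s2", "YK", c("ACGTACGTAC"))
  tags <- collapse_tags(list(l1, l2))
  expect_equal(nrow(tags), 2)
  row <- tags[tags$sequence == "ACGTACGTAC", ]
  expect_equal(row$s1, 2)
  expect_equal(row$s2, 1)
  expect_equal(row$total, 3)
  expect_equal(sum(tags$s1), 3)
  expect_equal(sum(tags$s2), 1)
})

test_that("tag counts and length histogram both conserve clean reads at scale", {
  sim <- simulate_libraries(small_config(seed = 5))
  cleaned <- lapply(sim$libraries, clean_reads,
                    adapter = "TGGAATTCTCGGGTGCCAAGG")
  libs <- lapply(cleaned, `[[`, "library")
  tags <- collapse_tags(libs)
  hist <- length_histogram(libs)
  for (lib in libs) {
    n <- length(lib$reads)
    expect_gt(n, 1000)
    expect_equal(sum(tags[[lib$sample]]), n)
    expect_equal(sum(hist[[lib$sample]]), n)
  }
})

test_that("a single 22-nt read gives histogram {22: 1}", {
  h <- length_histogram(list(srna_library("s1", "CY", rand_seq(1, 22))))
  expect_equal(h$s1[h$length == 22], 1)
  expect_equal(sum(h$s1), 1)
})

test_that("FASTQ round trip preserves reads and qualities", {
  set.seed(2)
  lib <- srna_library("rt", "CY", rand_seq(25, 30))
  path <- tempfile(fileext = ".fastq")
  write_fastq(lib, path)
  back <- read_fastq(path, sample = "rt", condition = "CY")
  expect_equal(back$reads, lib$reads)
  expect_equal(back$quality, lib$quality)
})

test_that("collapsed tags export as tag{serial}_x{count} FASTA", {
  tags <- collapse_tags(list(srna_library("s1", "CY",
                                          c("ACGTACGTAC", "ACGTACGTAC"))))
  path <- tempfile(fileext = ".fa")
  write_tags_fasta(tags, path)
  fa <- Biostrings::readDNAStringSet(path)
  expect_equal(names(fa), "tag1_x2")
  expect_equal(as.character(fa[[1]]), "ACGTACGTAC")
})
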