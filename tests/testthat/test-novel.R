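test_that("tags map to exact genomic loci on both strands", {
  set.seed(41)
  g <- Biostrings::DNAStringSet(c(chr1 = paste(rand_seq(1, 500),
                                               collapse = "")))
  tag <- substr(as.character(g[[1]]), 101, 122)
  hits <- map_tags(tag, g)
  expect_equal(hits$start, 100)
  expect_equal(hits$end, 122)
  expect_equal(hits$strand, "+")
  rc <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(tag)))
  hits_rc <- map_tags(rc, g)
  expect_equal(hits_rc$start, 100)
  expect_equal(hits_rc$end, 122)
  expect_equal(hits_rc$strand, "-")
})

test_that("repetitive tags beyond the locus cap are discarded", {
  unit <- "ACGTACGTACGTACGTACGTGG"
  g <- Biostrings::DNAStringSet(c(chr1 = strrep(paste0(unit, "TTTT"), 20)))
  hits <- map_tags(unit, g, max_hits = 15)
  expect_equal(nrow(hits), 0)
  hits2 <- map_tags(unit, g, max_hits = 25)
  expect_equal(nrow(hits2), 20)
})

test_that("planted hairpins are called and reported candidates are coherent", {
  cfg <- small_config(seed = 3)
  fx <- simulate_fixtures(cfg)
  nl <- fx$truth$novel_loci
  mapped <- map_tags(nl$mature, fx$genome)
  cands <- call_candidates(mapped, fx$genome)
  expect_gte(sum(nl$mature %in% cands$mature), nrow(nl) - 1)
  for (i in seq_len(nrow(cands))) {
    expect_true(grepl(cands$mature[i], cands$precursor[i], fixed = TRUE) ||
                  grepl(cands$mature[i], cands$precursor[i]))
    expect_equal(nchar(cands$structure[i]), nchar(cands$precursor[i]))
    expect_lt(cands$mfe[i], 0)
    expect_lte(cands$mfei[i], -0.85)
    expect_gte(nchar(cands$precursor[i]), 50)
    expect_true(cands$arm[i] %in% c("5p", "3p"))
  }
})

test_that("split 5' ends halve homogeneity and reject the candidate", {
  # hand-built clean hairpin: mature + loop + perfect star
  set.seed(55)
  mature <- "TGAGGTAGTAGGTTGTATAGTT"
  loop <- "AACCAATTCCAAGG"
  star <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(mature)))
  pre <- paste0(mature, loop, star)
  g <- Biostrings::DNAStringSet(c(chr1 = paste0(
    rand_seq(1, 100), pre, rand_seq(1, 100))))
  tag2 <- substr(as.character(g[[1]]), 104, 104 + 21) # 5' end shifted by 3
  mapped <- map_tags(c(mature, tag2), g)
  tags <- collapse_tags(list(
    srna_library("s1", "CY", c(rep(mature, 5), rep(tag2, 5)))))
  cands <- call_candidates(mapped, g, tags, min_homogeneity = 0.8)
  expect_equal(nrow(cands), 0)
  cands2 <- call_candidates(mapped, g, tags, min_homogeneity = 0.5)
  expect_gte(nrow(cands2), 1)
  expect_equal(cands2$homogeneity[1], 0.5)
})

test_that("dinucleotide shuffling preserves composition and start base", {
  set.seed(8)
  for (r in 1:15) {
    s <- rand_seq(1, sample(40:90, 1))
    sh <- shuffle_dinucleotide(s)
    expect_equal(nchar(sh), nchar(s))
    expect_equal(dinucleotide_counts(sh), dinucleotide_counts(s))
    expect_equal(substr(sh, 1, 1), substr(s, 1, 1))
  }
})

test_that("candidate GFF3 export round-trips coordinates 1-based inclusive", {
  cands <- data.frame(name = "bta-novel-miR-1", contig = "chr1",
                      start = 99, end = 160, strand = "-",
                      mfe = -40, mfei = -1.2, stringsAsFactors = FALSE)
  path <- tempfile(fileext = ".gff3")
  write_candidates_gff3(cands, path)
  gr <- rtracklayer::import(path)
  expect_equal(BiocGenerics::start(gr), 100)
  expect_equal(BiocGenerics::end(gr), 160)
  expect_equal(as.character(BiocGenerics::strand(gr)), "-")
})
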