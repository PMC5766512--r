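mk_catalog <- function() {
  annotation_catalog(list(
    miRNA = c(m1 = "TGAGGTAGTAGGTTGTATAGTT", m2 = "ACTGGCCTTGGAGTCAGAAGGC"),
    tRNA = c(t1 = paste0("GGGGGTATAGCTCAGTTGGTAGAGC",
                         "GCGTGCTTAGCATGCACGAGGTCCTGGGTTCGATCCCCAGT")),
    rRNA = c(r1 = paste0("GTTGGTGGAGCGATTTGTCTGGTTAATTCCGATAACGAACG",
                         "AGACTCTGGCATGCTAACTAGTTACGCG"))))
}

test_that("a tag identical to a catalog mature miRNA is assigned at 0 mismatches", {
  asg <- match_tags("TGAGGTAGTAGGTTGTATAGTT", mk_catalog())
  expect_equal(asg$category, "miRNA")
  expect_equal(asg$best_ref, "m1")
  expect_equal(asg$mismatches, 0L)
})

test_that("equal-best hits in two categories are AMBIGUOUS, never precedence-broken", {
  cat2 <- annotation_catalog(list(
    tRNA = c(t1 = "AACCGGTTAACCGGTTAACCGGTT"),
    rRNA = c(r1 = "AACCGGTTAACCGGTTAACCGGAA")))
  # tag at 1 mismatch from both references
  tag <- "AACCGGTTAACCGGTTAACCGGTA"
  asg <- match_tags(tag, cat2)
  expect_equal(asg$category, "AMBIGUOUS")
  expect_equal(asg$mismatches, 1L)
  expect_true(grepl("t1", asg$best_ref) && grepl("r1", asg$best_ref))
})

test_that("tags with no hit within tolerance, or outside 18-35 nt, stay unannotated", {
  cat <- mk_catalog()
  expect_equal(match_tags(strrep("AT", 11), cat)$category, "UNANNOTATED")
  # 17-nt prefix of a real reference: outside the classification window
  short <- substr("TGAGGTAGTAGGTTGTATAGTT", 1, 17)
  expect_equal(match_tags(short, cat)$category, "UNANNOTATED")
})

test_that("an empty catalog leaves everything unannotated", {
  asg <- match_tags(c("TGAGGTAGTAGGTTGTATAGTT"), annotation_catalog(
    list(miRNA = character(0))))
  expect_equal(asg$category, "UNANNOTATED")
})

test_that("assignment equals a brute-force all-substrings Hamming scan", {
  set.seed(21)
  refs <- list(miRNA = setNames(rand_seq(6, 22), paste0("m", 1:6)),
               tRNA = setNames(rand_seq(4, 70), paste0("t", 1:4)),
               mRNA = setNames(rand_seq(5, 40), paste0("g", 1:5)))
  cat <- annotation_catalog(refs)
  # tags: some planted from references (with mutations), some random
  tags <- character(0)
  for (r in 1:25) {
    src <- sample(unlist(refs), 1)
    at <- sample(nchar(src) - 21, 1)
    t <- strsplit(substr(src, at, at + 21), "")[[1]]
    for (p in sample(22, sample(0:3, 1)))
      t[p] <- sample(c("A", "C", "G", "T"), 1)
    tags <- c(tags, paste(t, collapse = ""))
  }
  tags <- unique(c(tags, rand_seq(15, 22)))
  asg <- match_tags(tags, cat)
  for (i in seq_along(tags)) {
    d <- vapply(refs, function(r) {
      v <- oracle_min_hamming(tags[i], r)
      if (is.null(v) || is.na(v)) NA_integer_ else v
    }, integer(1))
    if (all(is.na(d))) {
      expect_equal(asg$category[i], "UNANNOTATED")
    } else {
      best <- min(d, na.rm = TRUE)
      hits <- names(d)[!is.na(d) & d == best]
      expect_equal(asg$mismatches[i], best)
      if (length(hits) == 1) expect_equal(asg$category[i], hits)
      else expect_equal(asg$category[i], "AMBIGUOUS")
    }
  }
})

test_that("raising the mismatch tolerance never decreases annotated tags", {
  set.seed(31)
  cat <- annotation_catalog(list(miRNA = setNames(rand_seq(8, 22),
                                                  paste0("m", 1:8))))
  refs <- as.character(cat$miRNA)
  tags <- c(rand_seq(30, 22), vapply(1:10, function(i) {
    t <- strsplit(sample(refs, 1), "")[[1]]
    t[sample(22, 2)] <- "A"
    paste(t, collapse = "")
  }, ""))
  n_ann <- vapply(0:3, function(k)
    sum(!match_tags(tags, cat, max_mismatch = k)$category %in%
          c("UNANNOTATED")), integer(1))
  expect_true(all(diff(n_ann) >= 0))
})

test_that("classification partitions reads and tags and percentages recompute", {
  sim <- simulate_libraries(small_config(seed = 9))
  fx <- simulate_fixtures(small_config(seed = 9))
  cleaned <- lapply(sim$libraries, clean_reads,
                    adapter = "TGGAATTCTCGGGTGCCAAGG")
  libs <- lapply(cleaned, `[[`, "library")
  tags <- collapse_tags(libs)
  cls <- classify_libraries(tags, fx$catalog)
  for (i in seq_len(nrow(cls$stats))) {
    st <- cls$stats[i, ]
    s <- st$sample
    expect_equal(sum(cls$category_reads[[s]]), st$reads)
    expect_equal(sum(cls$category_tags[[s]]), st$tags)
    expect_equal(st$annotated_reads_pct,
                 100 * st$annotated_reads / st$reads)
    expect_equal(st$ambiguous_tags_pct,
                 100 * st$ambiguous_tags / st$tags)
  }
  # every planted known miRNA tag is annotated as miRNA
  planted <- sim$truth$mirnas$sequence[sim$truth$mirnas$type == "known"]
  asg <- cls$assignments
  expect_true(all(asg$category[asg$sequence %in% planted] == "miRNA"))
})
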