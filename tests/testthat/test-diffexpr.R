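test_that("TPM normalization follows count / total x 1e6 and its sum identity", {
  expect_equal(tpm(100, 1e6), 100)
  expect_equal(tpm(0, 12345), 0)
  expect_error(tpm(5, 0), "positive")
  expect_error(tpm(-1, 10), "non-negative")
  set.seed(1)
  counts <- rpois(50, 40)
  total <- 1e5
  expect_equal(sum(tpm(counts, total)), 1e6 * sum(counts) / total)
})

test_that("fold change reproduces printed table rows and the identity case", {
  expect_equal(fold_change(40.5238, 3.391165), 11.94982,
               tolerance = 5e-5)
  expect_equal(fold_change(1443.226, 653.6905), 2.207813,
               tolerance = 5e-5)
  expect_equal(fold_change(21.90231, 10.62615), 2.061171,
               tolerance = 5e-5)
  expect_equal(fold_change(7.25, 7.25), 1)
  expect_true(is.nan(fold_change(0, 0)))
})

test_that("the exact test is symmetric, sharp, and internally consistent", {
  expect_equal(ac_exact_test(5, 5, 1e6, 1e6), c(p = 1), tolerance = 1e-9)
  expect_equal(ac_exact_test(120, 120, 1e3, 1e3), c(p = 1),
               tolerance = 1e-9)
  expect_lt(ac_exact_test(5, 50, 1e6, 1e6), 1e-6)
  # C + D - p(Y|X) = 1: the tails overlap exactly at the observed count
  pmf <- function(y, x, n1, n2)
    exp(y * log(n2 / n1) + lgamma(x + y + 1) - lgamma(x + 1) -
          lgamma(y + 1) - (x + y + 1) * log1p(n2 / n1))
  set.seed(4)
  for (r in 1:25) {
    x <- sample(0:200, 1)
    y <- sample(0:200, 1)
    nn <- sample(c(1e3, 1e6), 2, replace = TRUE)
    t <- ac_exact_test(x, y, nn[1], nn[2], tails = TRUE)
    expect_equal(t$C + t$D - pmf(y, x, nn[1], nn[2]), 1, tolerance = 1e-9)
  }
  expect_error(ac_exact_test(-1, 3, 10, 10), "non-negative")
  expect_error(ac_exact_test(1.5, 3, 10, 10), "integers")
})

test_that("the exact test matches the independent tail oracle on a subgrid", {
  for (nn in list(c(1e3, 1e6), c(1e6, 1e3), c(1e6, 1e6))) {
    x <- rep(seq(0, 200, by = 8), each = 26)
    y <- rep(seq(0, 200, by = 8), times = 26)
    expect_equal(ac_exact_test(x, y, nn[1], nn[2]),
                 oracle_ac_test(x, y, nn[1], nn[2]), tolerance = 1e-9)
  }
})

test_that("call_de pools replicates, classifies direction, and reports BH FDR", {
  counts <- rbind(up = c(120, 110, 130, 28, 33, 30),
                  dn = c(25, 30, 28, 120, 115, 125),
                  ns = c(80, 90, 85, 84, 88, 80),
                  zero = c(0, 0, 0, 0, 0, 0))
  colnames(counts) <- c("CY1", "CY2", "CY3", "YK1", "YK2", "YK3")
  samples <- data.frame(sample = colnames(counts),
                        condition = rep(c("CY", "YK"), each = 3),
                        clean_total = rep(1e5, 6))
  de <- call_de(counts, samples, case = "CY", control = "YK")
  expect_s3_class(de, "mirna_de")
  expect_equal(de$direction[de$mirna == "up"], "UP")
  expect_equal(de$direction[de$mirna == "dn"], "DOWN")
  expect_equal(de$direction[de$mirna == "ns"], "NS")
  expect_equal(de$direction[de$mirna == "zero"], "NA")
  expect_equal(de$CY_tpm[de$mirna == "up"], 360 / 3e5 * 1e6)
  # BH-adjusted values are monotone in the p-value ranking
  o <- order(de$p_value)
  expect_true(all(diff(de$fdr[o]) >= -1e-12))
  expect_error(call_de(counts, within(samples, clean_total <- 0)),
               "zero|positive")
})

test_that("planted null miRNAs at matched depths are not called", {
  set.seed(12)
  n <- 40
  counts <- cbind(matrix(rpois(n * 3, 60), n), matrix(rpois(n * 3, 60), n))
  rownames(counts) <- paste0("m", seq_len(n))
  colnames(counts) <- c("CY1", "CY2", "CY3", "YK1", "YK2", "YK3")
  samples <- data.frame(sample = colnames(counts),
                        condition = rep(c("CY", "YK"), each = 3),
                        clean_total = rep(2e5, 6))
  de <- call_de(counts, samples)
  expect_lt(mean(de$direction != "NS"), 0.15)
})
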