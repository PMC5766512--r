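#' Transcripts-per-million normalization
#'
#' `count / total_clean_reads * 1e6`: a tag's count scaled to the clean-read
#' depth of its library.
#'
#' @param count Non-negative count(s).
#' @param total_clean_reads Positive clean-read total(s).
#' @return TPM value(s).
#' @export
tpm <- function(count, total_clean_reads) {
  if (any(total_clean_reads <= 0)) stop("total_clean_reads must be positive")
  if (any(count < 0)) stop("count must be non-negative")
  count / total_clean_reads * 1e6
}

#' Fold change between group TPMs
#'
#' The plain ratio `(cy + pseudo) / (yk + pseudo)`, matching how fold
#' changes are reported in the study's tables (the ratio, not its log);
#' `log2` of the ratio is reported alongside by downstream callers.
#'
#' @param cy_tpm,yk_tpm Group TPM values.
#' @param pseudo Optional pseudo-count added to both (default 0).
#' @return The ratio; `NaN` when both inputs (plus pseudo) are zero.
#' @export
fold_change <- function(cy_tpm, yk_tpm, pseudo = 0) {
  (cy_tpm + pseudo) / (yk_tpm + pseudo)
}

# log pmf of the Audic-Claverie conditional distribution:
# p(y | x) = (N2/N1)^y (x+y)! / (x! y! (1 + N2/N1)^(x+y+1))
.ac_log_pmf <- function(y, x, n1, n2) {
  lr <- log(n2) - log(n1)
  y * lr + lgamma(x + y + 1) - lgamma(x + 1) - lgamma(y + 1) -
    (x + y + 1) * log1p(n2 / n1)
}

.logsumexp <- function(lx) {
  m <- max(lx)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(lx - m)))
}

#' Audic-Claverie exact test for a count observed in two libraries
#'
#' Tests whether count `y` (pooled clean-read total `n2`) is consistent with
#' count `x` (total `n1`) under the conditional distribution
#' `p(y | x) = (N2/N1)^y (x+y)! / (x! y! (1+N2/N1)^(x+y+1))`. The lower tail
#' `C` sums `p(y'|x)` for `y' <= y`, the upper tail `D` for `y' >= y`
#' (summed in log space; the infinite tail is truncated once terms fall
#' below 1e-16 of the running sum past the distribution mode), and the
#' two-sided p-value is `min(1, 2 min(C, D))`. `C + D - p(y|x) = 1` holds to
#' numerical accuracy since the tails overlap at the observed count.
#'
#' @param x,y Observed (pooled) integer counts in the two groups.
#' @param n1,n2 Pooled clean-read totals of the two groups.
#' @param tails Set to `TRUE` to return `C`, `D` and `p` instead of `p` only.
#' @return Two-sided p-value(s), vectorized over `x`/`y`.
#' @export
ac_exact_test <- function(x, y, n1, n2, tails = FALSE) {
  if (any(x < 0) || any(y < 0)) stop("counts must be non-negative")
  if (any(n1 <= 0) || any(n2 <= 0)) stop("totals must be positive")
  if (any(x != floor(x)) || any(y != floor(y)))
    stop("counts must be integers")
  k <- max(length(x), length(y), length(n1), length(n2))
  x <- rep_len(x, k); y <- rep_len(y, k)
  n1 <- rep_len(n1, k); n2 <- rep_len(n2, k)
  one <- function(x, y, n1, n2) {
    mode_y <- (x + 1) * n2 / n1 # mean of the conditional distribution
    p_obs <- exp(.ac_log_pmf(y, x, n1, n2))
    if (y <= mode_y) {
      # lower tail is the short one: sum it directly
      C <- exp(.logsumexp(.ac_log_pmf(0:y, x, n1, n2)))
      D <- 1 - C + p_obs
    } else {
      # upper tail short: chunked log-space summation with truncation
      acc <- -Inf
      from <- y
      repeat {
        ys <- seq(from, from + 4095)
        lp <- .ac_log_pmf(ys, x, n1, n2)
        acc <- .logsumexp(c(acc, lp))
        from <- from + 4096
        if (from > mode_y && max(lp) < acc + log(1e-16)) break
      }
      D <- exp(acc)
      C <- 1 - D + p_obs
    }
    c(C = min(1, C), D = min(1, D),
      p = min(1, 2 * min(C, D)))
  }
  res <- vapply(seq_len(k), function(i) one(x[i], y[i], n1[i], n2[i]),
                numeric(3))
  if (tails) {
    data.frame(C = res["C", ], D = res["D", ], p = res["p", ])
  } else res["p", ]
}

#' Call differential expression from a count matrix
#'
#' Replicates are pooled per condition; group TPMs are pooled counts over
#' pooled clean-read totals times 1e6; the fold change is the TPM ratio
#' (case over control); p-values come from [ac_exact_test()] on the pooled
#' integer counts; FDR is Benjamini-Hochberg across all tested miRNAs.
#' Direction is `UP` when the ratio exceeds `fc_high` and `p < alpha`,
#' `DOWN` when below `fc_low` and `p < alpha`, otherwise `NS`.
#'
#' @param counts Integer matrix, miRNAs x samples.
#' @param samples Data frame with columns `sample`, `condition`,
#'   `clean_total` (per-sample clean-read totals); exactly two conditions.
#' @param case,control Condition labels of the numerator and denominator
#'   group; default the first and second condition in `samples`.
#' @param alpha Significance gate on the raw p-value (default 0.05).
#' @param fc_high,fc_low Ratio thresholds for UP / DOWN (defaults 2, 0.5).
#' @return A data frame of class `mirna_de` with columns `mirna`, the two
#'   group TPMs, `fold_change`, `log2_fold_change`, `p_value`, `fdr`,
#'   `direction`.
#' @export
call_de <- function(counts, samples, case = NULL, control = NULL,
                    alpha = 0.05, fc_high = 2, fc_low = 0.5) {
  counts <- as.matrix(counts)
  stopifnot(all(c("sample", "condition", "clean_total") %in% names(samples)))
  conds <- unique(samples$condition)
  if (length(conds) != 2) stop("exactly two conditions are required")
  case <- case %||% conds[1]
  control <- control %||% conds[2]
  s1 <- samples$sample[samples$condition == case]
  s2 <- samples$sample[samples$condition == control]
  n1 <- sum(samples$clean_total[samples$condition == case])
  n2 <- sum(samples$clean_total[samples$condition == control])
  if (n1 <= 0 || n2 <= 0) stop("a group has zero clean-read total")
  x <- as.integer(round(rowSums(counts[, s1, drop = FALSE])))
  y <- as.integer(round(rowSums(counts[, s2, drop = FALSE])))
  cy_tpm <- tpm(x, n1)
  yk_tpm <- tpm(y, n2)
  fc <- fold_change(cy_tpm, yk_tpm)
  p <- ac_exact_test(x, y, n1, n2)
  fdr <- p.adjust(p, method = "BH")
  dir <- ifelse(!is.finite(fc), "NA",
                ifelse(p < alpha & fc > fc_high, "UP",
                       ifelse(p < alpha & fc < fc_low, "DOWN", "NS")))
  out <- data.frame(mirna = rownames(counts) %||%
                      sprintf("mir%d", seq_along(x)),
                    case_tpm = cy_tpm, control_tpm = yk_tpm,
                    fold_change = fc, log2_fold_change = log2(fc),
                    p_value = p, fdr = fdr, direction = dir,
                    stringsAsFactors = FALSE)
  names(out)[2:3] <- paste0(c(case, control), "_tpm")
  rownames(out) <- NULL
  attr(out, "groups") <- c(case = case, control = control)
  attr(out, "totals") <- c(n1, n2)
  attr(out, "thresholds") <- c(alpha = alpha, fc_high = fc_high,
                               fc_low = fc_low)
  class(out) <- c("mirna_de", "data.frame")
  out
}

#' @export
print.mirna_de <- function(x, ...) {
  g <- attr(x, "groups")
  th <- attr(x, "thresholds")
  cat(sprintf(
    "Differential miRNA expression: %s vs %s (%d miRNAs)\n",
    g["case"], g["control"], nrow(x)))
  cat(sprintf(
    "  ratio > %g or < %g and p < %g:  %d UP, %d DOWN, %d NS\n",
    th["fc_high"], th["fc_low"], th["alpha"],
    sum(x$direction == "UP"), sum(x$direction == "DOWN"),
    sum(x$direction == "NS")))
  print.data.frame(head(as.data.frame(x), 10), digits = 5)
  if (nrow(x) > 10) cat(sprintf("  ... %d more rows\n", nrow(x) - 10))
  invisible(x)
}

#' @method summary mirna_de
#' @export
summary.mirna_de <- function(object, ...) {
  table(factor(object$direction, levels = c("UP", "DOWN", "NS")))
}

#' Write a `mirna_de` table as TSV
#'
#' @param de A `mirna_de` data frame.
#' @param path Output path.
#' @export
write_de_table <- function(de, path) {
  write.table(as.data.frame(de), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
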