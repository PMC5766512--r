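#' Relative expression by the 2^-ddCt method
#'
#' Technical replicates are averaged (arithmetic mean of Ct) per sample and
#' gene; dCt = Ct(target) - Ct(reference) per sample; ddCt = mean dCt(case)
#' - mean dCt(control); fold = 2^-ddCt. The amplification efficiency is
#' fixed at 2, the standard ddCt assumption. The dispersion reported is the
#' SEM across case biological replicates of per-sample fold values
#' 2^-(dCt - mean dCt(control)).
#'
#' @param ct_table Data frame with columns `sample`, `condition`, `gene`,
#'   `replicate`, `ct` (cycles, > 0).
#' @param target Target gene id.
#' @param reference Reference gene id (e.g. RPS18 for miRNA assays,
#'   beta-actin for mRNA assays).
#' @param case,control Condition labels (fold is case relative to control).
#' @return A list of class `relative_expression`: `gene`, `fold`, `ddct`,
#'   `sem`, and per-sample `dct` values.
#' @export
ddct <- function(ct_table, target, reference, case, control) {
  need <- c("sample", "condition", "gene", "ct")
  stopifnot(all(need %in% names(ct_table)))
  if (any(ct_table$ct <= 0)) stop("Ct values must be positive")
  tab <- ct_table[ct_table$condition %in% c(case, control), , drop = FALSE]
  mean_ct <- aggregate(ct ~ sample + condition + gene, tab, mean)
  samples <- unique(tab$sample)
  dct <- setNames(numeric(0), character(0))
  cond_of <- character(0)
  for (s in samples) {
    tct <- mean_ct$ct[mean_ct$sample == s & mean_ct$gene == target]
    rct <- mean_ct$ct[mean_ct$sample == s & mean_ct$gene == reference]
    if (!length(rct))
      stop("reference gene '", reference, "' missing in sample ", s)
    if (!length(tct)) next
    dct[s] <- tct - rct
    cond_of[s] <- unique(tab$condition[tab$sample == s])
  }
  if (!any(cond_of == case) || !any(cond_of == control))
    stop("target gene '", target, "' missing in one of the conditions")
  ddct_val <- mean(dct[cond_of == case]) - mean(dct[cond_of == control])
  fold <- 2^(-ddct_val)
  rel_case <- 2^(-(dct[cond_of == case] - mean(dct[cond_of == control])))
  sem <- if (length(rel_case) > 1)
    sd(rel_case) / sqrt(length(rel_case)) else NA_real_
  structure(list(gene = target, reference = reference,
                 case = case, control = control,
                 fold = fold, ddct = ddct_val, sem = sem, dct = dct,
                 condition = cond_of),
            class = "relative_expression")
}

#' @export
print.relative_expression <- function(x, ...) {
  cat(sprintf(
    "%s (ref %s): %s vs %s fold = %.4g (ddCt = %.3f, SEM %.3g)\n",
    x$gene, x$reference, x$case, x$control, x$fold, x$ddct,
    x$sem), sep = "")
  invisible(x)
}

#' Read a Ct table from TSV
#'
#' Expected columns: `sample`, `condition`, `gene`, `replicate`, `ct`.
#'
#' @param path TSV path.
#' @return Data frame.
#' @export
read_ct_table <- function(path) {
  read.delim(path, stringsAsFactors = FALSE)
}
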