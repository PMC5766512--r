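#' Upper-tail hypergeometric enrichment p-value
#'
#' `P = 1 - sum_{i=0}^{m-1} C(M,i) C(N-M, n-i) / C(N,n)`: the probability of
#' drawing at least `m` term-annotated genes when `n` target genes are drawn
#' from a background of `N` annotated genes of which `M` carry the term.
#' Evaluated in log-gamma arithmetic via `lchoose`.
#'
#' @param N Number of annotated genes in the background.
#' @param n Number of target genes in the background.
#' @param M Genes annotated to the term.
#' @param m Target genes annotated to the term.
#' @return The upper-tail p-value in `[0, 1]`.
#' @export
hypergeom_p <- function(N, n, M, m) {
  if (any(c(N, n, M, m) < 0)) stop("invariant violated: non-negative counts")
  if (any(M > N)) stop("invariant violated: M <= N")
  if (any(n > N)) stop("invariant violated: n <= N")
  if (any(m > pmin(n, M))) stop("invariant violated: m <= min(n, M)")
  k <- max(length(N), length(n), length(M), length(m))
  N <- rep_len(N, k); n <- rep_len(n, k)
  M <- rep_len(M, k); m <- rep_len(m, k)
  vapply(seq_len(k), function(idx) {
    if (m[idx] == 0) return(1)
    # the complement 1 - sum_{i < m} loses precision when P is small;
    # summing the tail terms i = m .. min(n, M) is algebraically identical
    i <- m[idx]:min(n[idx], M[idx])
    lt <- lchoose(M[idx], i) + lchoose(N[idx] - M[idx], n[idx] - i) -
      lchoose(N[idx], n[idx])
    min(max(sum(exp(lt)), 0), 1)
  }, numeric(1))
}

#' Term enrichment of a target-gene set with Bonferroni correction
#'
#' One hypergeometric test per term with at least one annotated background
#' gene; the Bonferroni divisor is the number of tested terms. Target genes
#' absent from the background are dropped (and counted in the attributes).
#'
#' @param targets Character vector of target gene ids.
#' @param term_table Data frame with columns `term_id` and `gene_id` (one
#'   row per term-gene pair; an optional `term_name` column is carried
#'   through).
#' @param background Character vector of annotated background gene ids;
#'   defaults to all genes in `term_table`.
#' @param alpha Corrected-p threshold for the `enriched` flag (default 0.05).
#' @return Data frame sorted by raw p: `term_id`, `N`, `n`, `M`, `m`,
#'   `p_value`, `p_bonferroni`, `enriched`.
#' @export
enrich <- function(targets, term_table, background = NULL, alpha = 0.05) {
  stopifnot(all(c("term_id", "gene_id") %in% names(term_table)))
  background <- unique(background %||% term_table$gene_id)
  if (!length(background)) stop("background gene set is empty")
  targets <- unique(targets)
  dropped <- sum(!(targets %in% background))
  targets <- intersect(targets, background)
  tt <- term_table[term_table$gene_id %in% background, , drop = FALSE]
  terms <- split(unique(tt[, c("term_id", "gene_id")])$gene_id,
                 unique(tt[, c("term_id", "gene_id")])$term_id)
  terms <- terms[lengths(terms) >= 1]
  N <- length(background)
  n <- length(targets)
  out <- do.call(rbind, lapply(names(terms), function(tid) {
    genes <- terms[[tid]]
    M <- length(genes)
    m <- length(intersect(genes, targets))
    data.frame(term_id = tid, N = N, n = n, M = M, m = m,
               p_value = hypergeom_p(N, n, M, m),
               stringsAsFactors = FALSE)
  }))
  out$p_bonferroni <- pmin(1, out$p_value * nrow(out))
  out$enriched <- out$p_bonferroni <= alpha
  if ("term_name" %in% names(term_table)) {
    nm <- term_table$term_name[match(out$term_id, term_table$term_id)]
    out <- cbind(out[, 1, drop = FALSE], term_name = nm,
                 out[, -1, drop = FALSE])
  }
  out <- out[order(out$p_value, out$term_id), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "dropped_targets") <- dropped
  out
}
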