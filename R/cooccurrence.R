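#' Mutual exclusivity / co-occurrence of gene pairs
#'
#' For each pair of genes, builds the 2x2 table of patient counts (both
#' mutated, first only, second only, neither) and tests association with
#' the two-sided Fisher exact test (hypergeometric). Effect direction and
#' size are summarized by the log odds ratio with the Haldane-Anscombe 0.5
#' correction, `LR = log(((a+0.5)(d+0.5)) / ((b+0.5)(c+0.5)))` (natural
#' log), which stays finite when a cell is empty. A pair is called
#' `exclusive` when `LR < 0` and `p < alpha`, `co-occurring` when `LR > 0`
#' and `p < alpha`, otherwise `neutral`. Pairs with a degenerate margin (a
#' gene mutated in no or all patients) are marked `untestable`. No
#' multiple-testing correction is applied; raw p-values are reported.
#'
#' @param status Binary patient-by-gene matrix (1 = gene mutated in
#'   patient), with gene column names.
#' @param pairs Optional 2-column character matrix / data.frame of gene
#'   pairs to test; default all unordered pairs.
#' @param alpha Significance level for the call (default 0.05).
#' @return `data.frame` with columns `gene_a`, `gene_b`, `n_both`,
#'   `n_a_only`, `n_b_only`, `n_neither`, `log_odds_ratio`, `p_value`,
#'   `call`.
#' @export
pairwise_fisher <- function(status, pairs = NULL, alpha = 0.05) {
  stopifnot(is.matrix(status), !is.null(colnames(status)))
  genes <- colnames(status)
  if (is.null(pairs)) {
    if (length(genes) < 2L) stop("need at least two genes")
    pairs <- t(utils::combn(genes, 2L))
  } else {
    pairs <- as.matrix(pairs)
  }
  n <- nrow(status)
  out <- vector("list", nrow(pairs))
  for (i in seq_len(nrow(pairs))) {
    ga <- pairs[i, 1]; gb <- pairs[i, 2]
    xa <- status[, ga] != 0; xb <- status[, gb] != 0
    a <- sum(xa & xb); b <- sum(xa & !xb)
    c_ <- sum(!xa & xb); d <- sum(!xa & !xb)
    lr <- log(((a + 0.5) * (d + 0.5)) / ((b + 0.5) * (c_ + 0.5)))
    degenerate <- (a + b) %in% c(0L, n) || (a + c_) %in% c(0L, n)
    if (degenerate) {
      p <- NA_real_; call <- "untestable"
    } else {
      p <- stats::fisher.test(matrix(c(a, b, c_, d), 2, 2))$p.value
      call <- if (p < alpha && lr < 0) "exclusive"
      else if (p < alpha && lr > 0) "co-occurring"
      else "neutral"
    }
    out[[i]] <- data.frame(gene_a = ga, gene_b = gb, n_both = a,
                           n_a_only = b, n_b_only = c_, n_neither = d,
                           log_odds_ratio = lr, p_value = p, call = call)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
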