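#' Transcripts-per-million normalization
#'
#' Per sample: \eqn{rate_g = count_g / length_g(kb)}, then
#' \eqn{TPM_g = rate_g / \sum_g rate_g \times 10^6}. Every column of the
#' result sums to exactly one million (up to floating point), and scaling all
#' counts of a sample leaves its TPM unchanged.
#'
#' @param counts Non-negative matrix, genes in rows, samples in columns.
#' @param lengths Gene lengths in nt; either aligned to the rows or named by
#'   gene id.
#' @return TPM matrix with the dimensions and dimnames of `counts`.
#' @examples
#' compute_tpm(matrix(c(10, 20), 2, 1, dimnames = list(c("g1", "g2"), "s1")),
#'             c(g1 = 1000, g2 = 2000))
#' @export
compute_tpm <- function(counts, lengths) {
  counts <- as.matrix(counts)
  if (any(counts < 0)) fail("counts must be non-negative")
  if (!is.null(names(lengths)) && !is.null(rownames(counts))) {
    miss <- setdiff(rownames(counts), names(lengths))
    if (length(miss))
      fail("no length for gene(s): %s", paste(head(miss, 5), collapse = ", "))
    lengths <- lengths[rownames(counts)]
  }
  if (length(lengths) != nrow(counts))
    fail("'lengths' must align with the rows of 'counts'")
  if (any(!is.finite(lengths)) || any(lengths <= 0))
    fail("gene lengths must be positive")
  rate <- counts / (lengths / 1000)
  tot <- colSums(rate)
  zero <- tot == 0
  if (any(zero))
    fail("sample(s) with all-zero counts: %s",
         paste(colnames(counts)[zero], collapse = ", "))
  sweep(rate, 2, tot, "/") * 1e6
}

## Pooled empirical null: for every gene and every unordered within-condition
## replicate pair, the (|M*|, D*) of that pair.
de_null_points <- function(expr, condition, pseudocount) {
  pts_m <- numeric(0); pts_d <- numeric(0)
  for (lev in levels(condition)) {
    cols <- which(condition == lev)
    if (length(cols) < 2) next
    pairs <- utils::combn(cols, 2)
    for (j in seq_len(ncol(pairs))) {
      x <- expr[, pairs[1, j]]; y <- expr[, pairs[2, j]]
      pts_m <- c(pts_m, abs(log2(x + pseudocount) - log2(y + pseudocount)))
      pts_d <- c(pts_d, abs(x - y))
    }
  }
  list(abs_m = pts_m, d = pts_d)
}

#' Empirical-noise differential expression test
#'
#' For each gene, the log2 fold change \eqn{M = \log_2((\bar{x}_A + c) /
#' (\bar{x}_B + c))} and absolute difference \eqn{D = |\bar{x}_A -
#' \bar{x}_B|} of the condition means are compared with an empirical null
#' built by pooling, over all genes, the (M*, D*) values of every
#' within-condition replicate pair. The probability of observing noise at
#' least as extreme is the add-one-smoothed fraction of null points jointly
#' dominating the gene: \eqn{p = (1 + \#\{|M^*| \ge |M| \wedge D^* \ge D\}) /
#' (1 + N)}. A gene is significant when `p < p_threshold` and
#' `|M| >= fc_threshold`.
#'
#' Requires at least two replicates per condition; with fewer, set
#' `fold_change_only = TRUE` to flag genes on fold change alone (p is then
#' `NA` and no empirical probability is claimed).
#'
#' @param expr Expression matrix (TPM recommended; use [compute_tpm()] for
#'   counts), genes in rows.
#' @param condition Factor (or coercible) with two levels aligned to the
#'   columns; the first level is condition A, and "up" means higher in A.
#' @param pseudocount Added to means before the log ratio (default 0.5).
#' @param p_threshold,fc_threshold Significance thresholds (defaults 0.05
#'   and 1).
#' @param fold_change_only Explicit opt-in for designs without replication.
#' @return Data frame of class `de_result`: `gene_id, mean_a, mean_b,
#'   log2fc, d_stat, p_value, significant, direction`.
#' @export
de_test <- function(expr, condition, pseudocount = 0.5, p_threshold = 0.05,
                    fc_threshold = 1, fold_change_only = FALSE) {
  expr <- as.matrix(expr)
  condition <- as.factor(condition)
  if (length(condition) != ncol(expr))
    fail("'condition' must label every column of 'expr'")
  if (nlevels(condition) != 2L) fail("exactly two conditions are required")
  if (any(expr < 0)) fail("expression values must be non-negative")
  reps <- table(condition)
  if (any(reps < 2) && !fold_change_only)
    fail(paste("fewer than 2 replicates in a condition; rerun with",
               "fold_change_only = TRUE to flag genes on fold change alone"))

  a_cols <- condition == levels(condition)[1]
  mean_a <- rowMeans(expr[, a_cols, drop = FALSE])
  mean_b <- rowMeans(expr[, !a_cols, drop = FALSE])
  # difference of logs, so swapping condition labels negates M bit-exactly
  m <- log2(mean_a + pseudocount) - log2(mean_b + pseudocount)
  d <- abs(mean_a - mean_b)

  if (fold_change_only || any(reps < 2)) {
    p <- rep(NA_real_, length(m))
    sig <- abs(m) >= fc_threshold
  } else {
    null <- de_null_points(expr, condition, pseudocount)
    n_null <- length(null$abs_m)
    abs_m <- abs(m)
    p <- vapply(seq_along(m), function(g)
      (1 + sum(null$abs_m >= abs_m[g] & null$d >= d[g])) / (1 + n_null), 0)
    sig <- p < p_threshold & abs(m) >= fc_threshold
  }

  res <- data.frame(
    gene_id = if (is.null(rownames(expr))) as.character(seq_along(m))
              else rownames(expr),
    mean_a = mean_a, mean_b = mean_b, log2fc = m, d_stat = d, p_value = p,
    significant = sig,
    direction = ifelse(m >= 0, "up", "down"),
    row.names = NULL, stringsAsFactors = FALSE)
  class(res) <- c("de_result", class(res))
  attr(res, "thresholds") <- list(p = p_threshold, fc = fc_threshold,
                                  pseudocount = pseudocount)
  attr(res, "conditions") <- levels(condition)
  res
}

#' Summarize differential-expression calls
#'
#' @param results A [de_test()] result.
#' @param biotypes Optional named character vector (gene id -> biotype) for
#'   a per-biotype breakdown of significant calls.
#' @return List with `total`, `up`, `down` significant counts and, when
#'   biotypes are supplied, `by_biotype` (data frame `biotype, total, up,
#'   down`). "Up" means higher in condition A.
#' @export
de_summary <- function(results, biotypes = NULL) {
  sig <- results[results$significant, , drop = FALSE]
  out <- list(total = nrow(sig),
              up = sum(sig$direction == "up"),
              down = sum(sig$direction == "down"))
  if (!is.null(biotypes)) {
    bt <- biotypes[sig$gene_id]
    bt[is.na(bt)] <- "unknown"
    tab <- lapply(split(sig, bt), function(s)
      data.frame(total = nrow(s), up = sum(s$direction == "up"),
                 down = sum(s$direction == "down")))
    out$by_biotype <- cbind(biotype = names(tab), do.call(rbind, tab),
                            row.names = NULL)
  }
  out
}
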