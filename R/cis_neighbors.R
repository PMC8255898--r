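#' Pearson correlation with a t-based p-value
#'
#' Standard Pearson r plus the two-sided p-value from
#' \eqn{t = r \sqrt{(n-2)/(1-r^2)}} on n-2 degrees of freedom. Perfect
#' correlation gives p = 0. Note that with very few samples (e.g. n = 6,
#' a 3-vs-3 design) this p-value rests heavily on normality and is fragile;
#' downstream reports carry it as computed rather than "fixing" it.
#'
#' @param x,y Numeric vectors of equal length n >= 3; neither constant.
#' @param xname,yname Names used in error messages (e.g. gene ids).
#' @return List with `pcc` and `p_value`.
#' @examples
#' pearson_with_p(1:6, c(2, 1, 4, 3, 6, 5))
#' @export
pearson_with_p <- function(x, y, xname = "x", yname = "y") {
  if (length(x) != length(y)) fail("'x' and 'y' must have equal length")
  n <- length(x)
  if (n < 3L) fail("need at least 3 paired samples")
  if (sd(x) == 0) fail("correlation undefined: '%s' is constant", xname)
  if (sd(y) == 0) fail("correlation undefined: '%s' is constant", yname)
  r <- cor(x, y)
  p <- pearson_p(r, n)
  list(pcc = r, p_value = p)
}

pearson_p <- function(r, n) {
  r <- pmin(pmax(r, -1), 1)
  tt <- abs(r) * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
  ifelse(abs(r) >= 1, 0, 2 * pt(tt, df = n - 2, lower.tail = FALSE))
}

## Gene-level union span per gene id (min start, max end over transcripts).
gene_spans <- function(annotation) {
  tx <- if (is.data.frame(annotation)) annotation else annotation$transcripts
  start <- tapply(tx$start, tx$gene_id, min)
  end <- tapply(tx$end, tx$gene_id, max)
  chrom <- tapply(tx$chrom, tx$gene_id, function(x) x[1])
  data.frame(gene_id = names(start), chrom = as.character(chrom),
             start = as.numeric(start), end = as.numeric(end),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Find co-expressed and cis-neighboring lncRNA--mRNA pairs
#'
#' Over all lncRNA x mRNA pairs sharing sample columns, computes the Pearson
#' correlation of expression and its t-based p-value. A pair is
#' **co-expressed** when `|pcc| > coexpr` and `p < p_threshold`. A pair is a
#' **cis neighbor** when additionally the two gene loci are on the same
#' chromosome with an interval gap of at most `window` bp (0 for
#' overlapping or adjacent loci; the window is symmetric, covering both
#' upstream and downstream) and `|pcc| > cis_pcc`. Gene loci are union
#' spans over the gene's transcripts.
#'
#' @param lnc_expr,mrna_expr Expression matrices (genes x samples) for
#'   lncRNAs and mRNAs; columns are matched by name when named.
#' @param annotation Transcript table (or [simulate_annotation()] result)
#'   covering the genes; ids absent from it are skipped with a warning.
#' @param window Genomic window in bp (default 100 kb).
#' @param coexpr Co-expression |PCC| threshold (default 0.8).
#' @param cis_pcc Cis |PCC| threshold (default 0.9; the p-value requirement
#'   is inherited, which is conservative).
#' @param p_threshold Correlation p-value threshold (default 0.05).
#' @return Data frame `lnc_id, mrna_id, pcc, pcc_p, distance, relation`
#'   with `relation` in `{co_expressed, cis_neighbor}`; `distance` is `NA`
#'   for different-chromosome pairs. Constant-expression genes are dropped
#'   with a warning (correlation undefined).
#' @export
find_pairs <- function(lnc_expr, mrna_expr, annotation, window = 1e5,
                       coexpr = 0.8, cis_pcc = 0.9, p_threshold = 0.05) {
  lnc_expr <- as.matrix(lnc_expr); mrna_expr <- as.matrix(mrna_expr)
  if (!is.null(colnames(lnc_expr)) && !is.null(colnames(mrna_expr))) {
    shared <- intersect(colnames(lnc_expr), colnames(mrna_expr))
    if (length(shared) < 3L) fail("fewer than 3 shared samples")
    lnc_expr <- lnc_expr[, shared, drop = FALSE]
    mrna_expr <- mrna_expr[, shared, drop = FALSE]
  } else if (ncol(lnc_expr) != ncol(mrna_expr)) {
    fail("expression matrices must share their sample columns")
  }
  n <- ncol(lnc_expr)
  if (n < 3L) fail("need at least 3 samples")

  spans <- gene_spans(annotation)
  drop_missing <- function(m, what) {
    miss <- setdiff(rownames(m), spans$gene_id)
    if (length(miss)) {
      warning(sprintf("%d %s id(s) missing from annotation, skipped: %s",
                      length(miss), what,
                      paste(head(miss, 5), collapse = ", ")), call. = FALSE)
      m <- m[!rownames(m) %in% miss, , drop = FALSE]
    }
    m
  }
  lnc_expr <- drop_missing(lnc_expr, "lncRNA")
  mrna_expr <- drop_missing(mrna_expr, "mRNA")

  drop_constant <- function(m, what) {
    cons <- apply(m, 1, sd) == 0
    if (any(cons))
      warning(sprintf("%d %s gene(s) with constant expression dropped: %s",
                      sum(cons), what,
                      paste(head(rownames(m)[cons], 5), collapse = ", ")),
              call. = FALSE)
    m[!cons, , drop = FALSE]
  }
  lnc_expr <- drop_constant(lnc_expr, "lncRNA")
  mrna_expr <- drop_constant(mrna_expr, "mRNA")
  empty <- data.frame(lnc_id = character(0), mrna_id = character(0),
                      pcc = numeric(0), pcc_p = numeric(0),
                      distance = numeric(0), relation = character(0))
  if (nrow(lnc_expr) == 0 || nrow(mrna_expr) == 0) return(empty)

  r <- cor(t(lnc_expr), t(mrna_expr))
  p <- pearson_p(r, n)
  hit <- which(abs(r) > coexpr & p < p_threshold, arr.ind = TRUE)
  if (nrow(hit) == 0) return(empty)

  lnc_ids <- rownames(lnc_expr)[hit[, 1]]
  mrna_ids <- rownames(mrna_expr)[hit[, 2]]
  dist <- pair_distances(lnc_ids, mrna_ids, spans)
  pcc <- r[hit]; pcc_p <- p[hit]
  is_cis <- !is.na(dist) & dist <= window & abs(pcc) > cis_pcc &
    pcc_p < p_threshold
  out <- data.frame(lnc_id = lnc_ids, mrna_id = mrna_ids, pcc = pcc,
                    pcc_p = pcc_p, distance = dist,
                    relation = ifelse(is_cis, "cis_neighbor", "co_expressed"),
                    stringsAsFactors = FALSE)
  out <- out[order(out$relation == "co_expressed", out$lnc_id, out$mrna_id), ]
  rownames(out) <- NULL
  out
}

## Interval gap per (lnc, mrna) id pair: 0 when overlapping or adjacent,
## NA across chromosomes; GenomicRanges::distance supplies the gap.
pair_distances <- function(lnc_ids, mrna_ids, spans) {
  rownames(spans) <- spans$gene_id
  a <- spans[lnc_ids, ]; b <- spans[mrna_ids, ]
  gr_a <- GenomicRanges::GRanges(a$chrom, IRanges::IRanges(a$start, a$end))
  gr_b <- GenomicRanges::GRanges(b$chrom, IRanges::IRanges(b$start, b$end))
  suppressWarnings(GenomicRanges::distance(gr_a, gr_b))
}

#' Hypergeometric gene-set enrichment with BH adjustment
#'
#' For each gene set, the raw p-value is the hypergeometric upper tail of
#' the overlap between `selected` and the set within `universe` (a modified
#' Fisher's exact test); p-values are Benjamini--Hochberg adjusted across
#' sets and results are sorted by adjusted p.
#'
#' @param selected Character vector of genes of interest (e.g. cis-neighbor
#'   genes); must be a subset of `universe`.
#' @param gene_sets Named list of character vectors (set id -> genes).
#' @param universe Character vector of all testable genes.
#' @return Data frame `set_id, set_size, overlap, fold, p_raw, p_adjusted`
#'   sorted by `p_adjusted`. Sets empty after intersection with the
#'   universe are dropped. `fold` is the observed/expected overlap ratio.
#' @export
enrich_gene_sets <- function(selected, gene_sets, universe) {
  universe <- unique(universe)
  if (length(universe) == 0) fail("empty universe")
  selected <- unique(selected)
  if (!all(selected %in% universe))
    fail("'selected' must be a subset of 'universe'")
  sets <- lapply(gene_sets, function(s) intersect(unique(s), universe))
  sets <- sets[lengths(sets) > 0]
  if (length(sets) == 0) fail("no gene set overlaps the universe")
  N <- length(universe); k <- length(selected)
  rows <- lapply(names(sets), function(id) {
    m <- length(sets[[id]])
    ov <- length(intersect(selected, sets[[id]]))
    expected <- k * m / N
    data.frame(set_id = id, set_size = m, overlap = ov,
               fold = if (expected > 0) ov / expected else NA_real_,
               p_raw = phyper(ov - 1, m, N - m, k, lower.tail = FALSE),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_adjusted <- p.adjust(out$p_raw, method = "BH")
  out <- out[order(out$p_adjusted, out$p_raw, out$set_id), ]
  rownames(out) <- NULL
  out
}
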