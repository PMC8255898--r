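#' Classify candidate transcripts into lncRNA / mRNA / rejected
#'
#' Applies the identification cascade: a transcript is **rejected** when its
#' length, exon count or read support falls below the minimum (strictly
#' `<`, attributed to the first failing rule in the order length, exons,
#' reads). Among survivors, a transcript is a **lncRNA** when both
#' coding-potential scores fall below their cutoffs (`cnci < cnci_max` AND
#' `cpc < cpc_max`, again strict), otherwise an **mRNA**. Records with a
#' missing score are rejected and listed in the report.
#'
#' Defaults are the conventional cascade: minimum length 200 nt, minimum
#' 1 exon, minimum 3 supporting reads, CNCI < 0 and CPC < -1. (A 1-exon
#' minimum is vacuous; common practice uses 2 — the threshold is exposed
#' rather than silently changed.)
#'
#' @param records Data frame with columns `transcript_id, length, exon_count,
#'   read_support, cnci, cpc` (extra columns pass through).
#' @param min_length,min_exons,min_reads Retention minima (records below any
#'   are rejected).
#' @param cnci_max,cpc_max Coding-potential cutoffs; lncRNA requires both
#'   scores strictly below.
#' @return List with `records` (input plus `biotype` and `reject_reason`
#'   columns) and `report` (list: `total`, `rejected`, `lncRNA`, `mRNA`,
#'   `reasons` named counts, `missing_scores` ids).
#' @examples
#' rec <- data.frame(transcript_id = c("t1", "t2"),
#'                   length = c(150, 500), exon_count = c(1, 2),
#'                   read_support = c(10, 10), cnci = c(-3, -3),
#'                   cpc = c(-2, -2))
#' classify_transcripts(rec)$report
#' @export
classify_transcripts <- function(records, min_length = 200, min_exons = 1,
                                 min_reads = 3, cnci_max = 0, cpc_max = -1) {
  need <- c("transcript_id", "length", "exon_count", "read_support",
            "cnci", "cpc")
  miss <- setdiff(need, names(records))
  if (length(miss)) fail("records missing columns: %s", paste(miss, collapse = ", "))
  n <- nrow(records)
  biotype <- rep(NA_character_, n)
  reason <- rep(NA_character_, n)
  if (n > 0) {
    no_score <- !is.finite(records$cnci) | !is.finite(records$cpc)
    for (i in seq_len(n)) {
      if (records$length[i] < min_length) {
        biotype[i] <- "rejected"; reason[i] <- "length"
      } else if (records$exon_count[i] < min_exons) {
        biotype[i] <- "rejected"; reason[i] <- "exons"
      } else if (records$read_support[i] < min_reads) {
        biotype[i] <- "rejected"; reason[i] <- "reads"
      } else if (no_score[i]) {
        biotype[i] <- "rejected"; reason[i] <- "missing_score"
      } else if (records$cnci[i] < cnci_max && records$cpc[i] < cpc_max) {
        biotype[i] <- "lncRNA"
      } else {
        biotype[i] <- "mRNA"
      }
    }
  }
  out <- records
  out$biotype <- biotype
  out$reject_reason <- reason
  reasons <- c(length = sum(reason == "length", na.rm = TRUE),
               exons = sum(reason == "exons", na.rm = TRUE),
               reads = sum(reason == "reads", na.rm = TRUE),
               missing_score = sum(reason == "missing_score", na.rm = TRUE))
  list(records = out,
       report = list(total = n,
                     rejected = sum(biotype == "rejected"),
                     lncRNA = sum(biotype == "lncRNA"),
                     mRNA = sum(biotype == "mRNA"),
                     reasons = reasons,
                     missing_scores =
                       out$transcript_id[!is.na(reason) & reason == "missing_score"]))
}

#' Summarize lncRNA vs mRNA characteristics
#'
#' Per biotype: record count, mean transcript length, fractions in the
#' length bins \[200, 1000\], (1000, 3000\] and > 3000 nt, the exon-count
#' distribution, and the fraction of transcripts with at most 2 exons.
#'
#' @param records Data frame with columns `length`, `exon_count`, `biotype`.
#' @param biotypes Biotypes to summarize (default lncRNA and mRNA).
#' @return Named list per biotype, each a list with `n`, `mean_length`,
#'   `length_bins` (fractions, summing to 1), `exon_distribution`
#'   (fractions by exon count), `frac_le2_exons`.
#' @export
summarize_characteristics <- function(records,
                                      biotypes = c("lncRNA", "mRNA")) {
  out <- lapply(biotypes, function(b) {
    r <- records[records$biotype == b, , drop = FALSE]
    if (nrow(r) == 0) fail("no records with biotype '%s'", b)
    bins <- c(`[200,1000]` = mean(r$length <= 1000),
              `(1000,3000]` = mean(r$length > 1000 & r$length <= 3000),
              `>3000` = mean(r$length > 3000))
    ex <- table(r$exon_count) / nrow(r)
    list(n = nrow(r),
         mean_length = mean(r$length),
         length_bins = bins,
         exon_distribution = ex,
         frac_le2_exons = mean(r$exon_count <= 2))
  })
  names(out) <- biotypes
  out
}
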