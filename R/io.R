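#' Read longitudinal weight records from CSV
#'
#' Expects a header with columns `animal_id`, `age_days`, `weight_kg`.
#' Validates that ages are non-negative, weights positive, and that each
#' animal's ages are unique; records are returned sorted by animal then age.
#'
#' @param path CSV file path.
#' @return Data frame with the three columns.
#' @export
read_weight_records <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("animal_id", "age_days", "weight_kg")
  if (!all(need %in% names(df)))
    fail("weight file must have columns: %s", paste(need, collapse = ", "))
  df <- df[, need]
  df$age_days <- as.numeric(df$age_days)
  df$weight_kg <- as.numeric(df$weight_kg)
  if (any(!is.finite(df$age_days)) || any(df$age_days < 0))
    fail("age_days must be non-negative numbers")
  if (any(!is.finite(df$weight_kg)) || any(df$weight_kg <= 0))
    fail("weight_kg must be positive numbers")
  df <- df[order(df$animal_id, df$age_days), , drop = FALSE]
  dup <- vapply(split(df$age_days, df$animal_id), anyDuplicated, 0L)
  if (any(dup > 0))
    fail("duplicate ages for animal(s): %s",
         paste(names(dup)[dup > 0], collapse = ", "))
  rownames(df) <- NULL
  df
}

#' Write a growth-fit report as tab-delimited text
#'
#' @param report Data frame from [growth_report()].
#' @param path Output file.
#' @export
write_fit_report <- function(report, path) {
  write.table(report, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a transcript annotation to GTF
#'
#' Emits one `transcript` feature plus its `exon` features per transcript,
#' 1-based inclusive coordinates, with `transcript_id`, `gene_id` and
#' `biotype` attributes.
#'
#' @param transcripts Transcript table as produced by [simulate_annotation()]
#'   (columns `transcript_id, gene_id, chrom, strand, start, end, length,
#'   exon_count, biotype`).
#' @param path Output GTF path.
#' @export
write_annotation_gtf <- function(transcripts, path) {
  tx <- transcripts
  feat <- list()
  feat[[1]] <- GenomicRanges::GRanges(
    tx$chrom, IRanges::IRanges(tx$start, tx$end), strand = tx$strand,
    type = "transcript", transcript_id = tx$transcript_id,
    gene_id = tx$gene_id, biotype = tx$biotype)
  ex <- exon_layout(tx)
  feat[[2]] <- GenomicRanges::GRanges(
    ex$chrom, IRanges::IRanges(ex$start, ex$end), strand = ex$strand,
    type = "exon", transcript_id = ex$transcript_id,
    gene_id = ex$gene_id, biotype = ex$biotype)
  gr <- c(feat[[1]], feat[[2]])
  gr <- gr[order(S4Vectors::decode(GenomicRanges::seqnames(gr)),
                 GenomicRanges::start(gr))]
  rtracklayer::export(gr, path, format = "gtf")
  invisible(path)
}

## Deterministic exon layout: the transcript length is split into exon_count
## exons (remainder on the last), separated by fixed-width introns inside the
## genomic span.
exon_layout <- function(tx) {
  rows <- lapply(seq_len(nrow(tx)), function(i) {
    n <- tx$exon_count[i]
    len <- tx$length[i]
    base <- len %/% n
    sizes <- rep(base, n)
    sizes[n] <- sizes[n] + len - base * n
    intron <- if (n > 1) (tx$end[i] - tx$start[i] + 1 - len) %/% (n - 1) else 0
    starts <- tx$start[i] + c(0, cumsum(sizes[-n] + intron))
    data.frame(chrom = tx$chrom[i], start = starts, end = starts + sizes - 1,
               strand = tx$strand[i], transcript_id = tx$transcript_id[i],
               gene_id = tx$gene_id[i], biotype = tx$biotype[i])
  })
  do.call(rbind, rows)
}

#' Read a transcript annotation from GTF
#'
#' Reconstructs the transcript table from the `transcript` and `exon`
#' features: coordinates of the transcript span, exon count and summed exon
#' length per transcript.
#'
#' @param path GTF file path.
#' @return Data frame with columns `transcript_id, gene_id, chrom, strand,
#'   start, end, length, exon_count, biotype`.
#' @export
read_annotation_gtf <- function(path) {
  gr <- rtracklayer::import(path, format = "gtf")
  m <- S4Vectors::mcols(gr)
  is_tx <- m$type == "transcript"
  is_ex <- m$type == "exon"
  if (!any(is_tx)) fail("no transcript features in %s", path)
  txg <- gr[is_tx]
  exg <- gr[is_ex]
  ex_id <- S4Vectors::mcols(exg)$transcript_id
  exon_count <- table(ex_id)
  exon_len <- tapply(GenomicRanges::width(exg), ex_id, sum)
  id <- S4Vectors::mcols(txg)$transcript_id
  df <- data.frame(
    transcript_id = id,
    gene_id = S4Vectors::mcols(txg)$gene_id,
    chrom = as.character(GenomicRanges::seqnames(txg)),
    strand = as.character(GenomicRanges::strand(txg)),
    start = GenomicRanges::start(txg),
    end = GenomicRanges::end(txg),
    length = as.integer(exon_len[id]),
    exon_count = as.integer(exon_count[id]),
    biotype = S4Vectors::mcols(txg)$biotype,
    stringsAsFactors = FALSE)
  df[order(df$transcript_id), , drop = FALSE] -> df
  rownames(df) <- NULL
  df
}

#' Read a per-transcript score table
#'
#' Tab-delimited with columns `transcript_id, exon_count, read_support,
#' cnci, cpc` by default; `columns` maps arbitrary source column names onto
#' these expected names.
#'
#' @param path TSV file path.
#' @param columns Named character vector mapping expected names to the
#'   file's column names, e.g. `c(cnci = "CNCI_score")`.
#' @return Data frame with the canonical columns.
#' @export
read_score_table <- function(path, columns = character()) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("transcript_id", "exon_count", "read_support", "cnci", "cpc")
  for (nm in names(columns)) {
    if (!columns[[nm]] %in% names(df))
      fail("mapped column '%s' not found in %s", columns[[nm]], path)
    names(df)[names(df) == columns[[nm]]] <- nm
  }
  if (!all(need %in% names(df)))
    fail("score table must provide columns: %s", paste(need, collapse = ", "))
  df[, need]
}

#' Read an expression matrix from delimited text
#'
#' First column gene ids, remaining columns samples.
#'
#' @param path TSV file path.
#' @return Numeric matrix, genes in rows.
#' @export
read_expression_matrix <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- df[[1]]
  if (any(!is.finite(m)) || any(m < 0))
    fail("expression values must be non-negative finite numbers")
  m
}

#' Write an expression matrix as delimited text
#' @param mat Numeric matrix, genes in rows.
#' @param path Output TSV path.
#' @param id_column Name for the gene-id column.
#' @export
write_expression_matrix <- function(mat, path, id_column = "gene_id") {
  df <- data.frame(rownames(mat), mat, check.names = FALSE)
  names(df)[1] <- id_column
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
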