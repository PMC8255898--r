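# Shared fixtures and independent oracles used across test files.

# Published-fit parameter triples (asymptote A kg, shape B, rate k /d)
table1_params <- list(
  logistic        = growth_params("logistic", 135.63, 22.075, 0.017),
  von_bertalanffy = growth_params("von_bertalanffy", 198.903, 0.826, 0.005),
  gompertz        = growth_params("gompertz", 165.829, 4.141, 0.008)
)

# Six-record toy set exercising every branch of the filter cascade
toy_filter_records <- function() {
  data.frame(
    transcript_id = paste0("t", 1:6),
    length = c(150, 500, 500, 2000, 300, 250),
    exon_count = c(1, 1, 3, 5, 2, 1),
    read_support = c(10, 2, 10, 10, 10, 10),
    cnci = c(-3, -3, -3, 4, -0.5, 0.5),
    cpc = c(-2, -2, -2, 2, -1.5, -2),
    stringsAsFactors = FALSE
  )
}

# Interval gap oracle on 1-based inclusive coordinates: 0 when intervals
# overlap or touch, else the count of bases strictly between them.
gap_oracle <- function(s1, e1, s2, e2) {
  if (e1 + 1 >= s2 && e2 + 1 >= s1) return(0)
  if (s2 > e1) s2 - e1 - 1 else s1 - e2 - 1
}

# Brute-force cis scan: all lnc x mRNA pairs, Pearson r via cor(), p via
# cor.test (independent route), gap via gap_oracle; thresholds applied
# directly. Returns "lnc|mrna" keys of cis-neighbor pairs.
brute_force_cis <- function(lnc_expr, mrna_expr, spans, window = 1e5,
                            cis_pcc = 0.9, p_threshold = 0.05) {
  rownames(spans) <- spans$gene_id
  keys <- character(0)
  for (l in rownames(lnc_expr)) {
    for (m in rownames(mrna_expr)) {
      if (spans[l, "chrom"] != spans[m, "chrom"]) next
      d <- gap_oracle(spans[l, "start"], spans[l, "end"],
                      spans[m, "start"], spans[m, "end"])
      if (d > window) next
      ct <- cor.test(lnc_expr[l, ], mrna_expr[m, ])
      if (abs(ct$estimate) > cis_pcc && ct$p.value < p_threshold)
        keys <- c(keys, paste(l, m, sep = "|"))
    }
  }
  keys
}

pair_keys <- function(df, a = "lnc_id", b = "mrna_id")
  paste(df[[a]], df[[b]], sep = "|")

# Small annotation configuration used by interval-heavy tests
small_annotation <- function(planted_cis = 5L, seed = 11L)
  simulate_annotation(n_chromosomes = 2L, chrom_length = 2e7, n_mrna = 30L,
                      n_lnc = 10L, planted_cis = planted_cis, seed = seed)
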