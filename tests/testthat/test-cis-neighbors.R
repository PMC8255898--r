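test_that("pearson_with_p matches the closed-form t transform and cor.test", {
  x <- c(1, 2, 3, 4, 5, 6)
  expect_equal(pearson_with_p(x, 2 * x + 1)$pcc, 1)
  expect_equal(pearson_with_p(x, 2 * x + 1)$p_value, 0)
  expect_equal(pearson_with_p(x, -x)$pcc, -1)
  y <- c(2, 1, 4, 3, 6, 5)
  res <- pearson_with_p(x, y)
  ct <- cor.test(x, y)
  expect_equal(res$pcc, unname(ct$estimate))
  expect_equal(res$p_value, ct$p.value, tolerance = 1e-12)
  # direct formula route
  r <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  tt <- r * sqrt((6 - 2) / (1 - r^2))
  expect_equal(res$p_value, 2 * pt(abs(tt), 4, lower.tail = FALSE))
  expect_error(pearson_with_p(rep(1, 5), 1:5, xname = "geneX"), "geneX")
  expect_error(pearson_with_p(1:2, 2:3), "at least 3")
})

test_that("find_pairs recovers exactly the planted cis pairs (brute-force check)", {
  ann <- small_annotation(planted_cis = 5L, seed = 61)
  ex <- simulate_expression(ann, n_de = 0, n_reps = 3L, seed = 61)
  tpm <- compute_tpm(ex$counts, ex$lengths)
  lnc <- tpm[grep("^LNC", rownames(tpm)), ]
  mrna <- tpm[grep("^MRNA", rownames(tpm)), ]
  pairs <- find_pairs(lnc, mrna, ann)
  cis <- pairs[pairs$relation == "cis_neighbor", ]
  expect_setequal(pair_keys(cis), pair_keys(ann$truth$cis_pairs))
  # independent brute-force route: cor.test + arithmetic interval gap
  spans <- inflectr:::gene_spans(ann)
  expect_setequal(pair_keys(cis), brute_force_cis(lnc, mrna, spans))
  # reported distances agree with the generator truth
  truth_d <- setNames(ann$truth$cis_pairs$distance,
                      pair_keys(ann$truth$cis_pairs))
  expect_equal(unname(truth_d[pair_keys(cis)]), cis$distance)
})

test_that("perfect correlation across chromosomes is never a cis neighbor", {
  ann <- list(transcripts = data.frame(
    transcript_id = c("tl", "tm"), gene_id = c("L1", "M1"),
    chrom = c("chr1", "chr2"), strand = c("+", "+"),
    start = c(1000, 1000), end = c(2000, 2000),
    length = c(1001, 1001), exon_count = c(1, 1),
    biotype = c("lncRNA", "mRNA")))
  lnc <- matrix(c(1, 2, 3, 4, 5, 6.2), 1, dimnames = list("L1", paste0("s", 1:6)))
  mrna <- matrix(c(1.1, 2, 3, 4, 5, 6), 1, dimnames = list("M1", paste0("s", 1:6)))
  pairs <- find_pairs(lnc, mrna, ann)
  expect_equal(nrow(pairs), 1)
  expect_gt(abs(pairs$pcc), 0.99)
  expect_equal(pairs$relation, "co_expressed")
  expect_true(is.na(pairs$distance))
  # same chromosome, overlapping loci: distance 0 and cis-eligible
  ann$transcripts$chrom <- c("chr1", "chr1")
  ann$transcripts$start <- c(1000, 1500)
  ann$transcripts$end <- c(2000, 2500)
  pairs2 <- find_pairs(lnc, mrna, ann)
  expect_equal(pairs2$distance, 0)
  expect_equal(pairs2$relation, "cis_neighbor")
})

test_that("interval gaps agree with a per-base scan on toy chromosomes", {
  # every interval pair on a 40-bp chromosome, vs counting strictly
  # intervening bases
  cases <- expand.grid(s1 = c(1, 5, 12), w1 = c(1, 4), s2 = c(3, 14, 30),
                       w2 = c(2, 6))
  for (i in seq_len(nrow(cases))) {
    c1 <- cases[i, ]
    e1 <- c1$s1 + c1$w1 - 1; e2 <- c1$s2 + c1$w2 - 1
    # bases strictly between the earlier interval's end and the later's start
    if (c1$s1 <= c1$s2) { ge <- e1; gs <- c1$s2 } else { ge <- e2; gs <- c1$s1 }
    base_scan <- sum(seq_len(40) > ge & seq_len(40) < gs)
    spans <- data.frame(gene_id = c("a", "b"), chrom = "chr1",
                        start = c(c1$s1, c1$s2), end = c(e1, e2))
    d <- inflectr:::pair_distances("a", "b", spans)
    expect_equal(unname(d), base_scan)
    expect_equal(unname(d),
                 gap_oracle(c1$s1, e1, c1$s2, e2))
  }
})

test_that("the cis set is monotone in the window and invariant to permutation", {
  ann <- small_annotation(planted_cis = 5L, seed = 71)
  ex <- simulate_expression(ann, n_de = 0, seed = 71)
  tpm <- compute_tpm(ex$counts, ex$lengths)
  lnc <- tpm[grep("^LNC", rownames(tpm)), ]
  mrna <- tpm[grep("^MRNA", rownames(tpm)), ]
  cis_at <- function(w) {
    p <- find_pairs(lnc, mrna, ann, window = w)
    pair_keys(p[p$relation == "cis_neighbor", ])
  }
  w_sets <- lapply(c(1e3, 1e4, 1e5, 1e6), cis_at)
  for (i in 2:4) expect_true(all(w_sets[[i - 1]] %in% w_sets[[i]]))
  # permuting genes and samples (same sample order in both matrices)
  gp <- withr::with_seed(3, sample.int(nrow(lnc)))
  sp <- withr::with_seed(4, sample.int(ncol(lnc)))
  base <- find_pairs(lnc, mrna, ann)
  perm <- find_pairs(lnc[gp, , drop = FALSE][, sp], mrna[, sp], ann)
  expect_setequal(pair_keys(base), pair_keys(perm))
  expect_setequal(base$relation, perm$relation)
})

test_that("ids missing from the annotation are skipped with a warning", {
  ann <- small_annotation(planted_cis = 1L, seed = 81)
  ex <- simulate_expression(ann, n_de = 0, seed = 81)
  tpm <- compute_tpm(ex$counts, ex$lengths)
  lnc <- tpm[grep("^LNC", rownames(tpm)), ]
  mrna <- tpm[grep("^MRNA", rownames(tpm)), ]
  rownames(lnc)[1] <- "UNKNOWN_GENE"
  expect_warning(pairs <- find_pairs(lnc, mrna, ann), "UNKNOWN_GENE")
  expect_false("UNKNOWN_GENE" %in% pairs$lnc_id)
})

test_that("hypergeometric enrichment matches exact enumeration", {
  universe <- paste0("g", 1:20)
  set5 <- paste0("g", 1:5)
  selected <- c(paste0("g", 1:4), "g10") # 4 of the 5 set members
  res <- enrich_gene_sets(selected, list(s1 = set5), universe)
  # exact enumeration of P(X >= 4) drawing 5 from 20 with 5 marked
  tail_p <- sum(vapply(4:5, function(x)
    choose(5, x) * choose(15, 5 - x), 0)) / choose(20, 5)
  expect_equal(res$p_raw, tail_p)
  expect_equal(tail_p, 76 / 15504)
  expect_equal(res$overlap, 4)
  expect_equal(res$fold, (4 / 5) / (5 / 20))
})

test_that("BH adjustment and degenerate enrichment inputs behave as defined", {
  universe <- paste0("g", 1:40)
  sets <- list(a = paste0("g", 1:10), b = paste0("g", 11:20),
               c = paste0("g", 21:30), d = paste0("g", 31:40))
  # force raw p of (0.01, 0.02, 0.03, 0.04) through direct BH on that fixture
  expect_equal(p.adjust(c(0.01, 0.02, 0.03, 0.04), method = "BH"),
               rep(0.04, 4))
  res <- enrich_gene_sets(paste0("g", c(1:3, 11, 21, 31)), sets, universe)
  expect_equal(res$p_adjusted, p.adjust(res$p_raw, "BH")[order(res$p_raw)],
               tolerance = 1e-12)
  expect_true(all(diff(res$p_adjusted) >= 0))
  # selection equal to the single set spanning the whole universe
  u <- paste0("g", 1:5)
  deg <- enrich_gene_sets(u, list(all = u), u)
  expect_equal(deg$p_raw, 1)
  expect_equal(deg$overlap, 5)
  expect_equal(deg$fold, 1)
  expect_error(enrich_gene_sets("x", list(s = "x"), character(0)), "universe")
  expect_error(enrich_gene_sets("zz", list(s = u), u), "subset")
})
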