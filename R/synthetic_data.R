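#' Simulate a weighed growth cohort
#'
#' Emulates a longitudinal weighing study: `n_animals` animals share one true
#' growth curve, each animal's asymptote is scaled by a factor drawn from
#' Normal(1, `animal_cv`), and every weighing adds Normal(0, `noise_sd`) kg of
#' measurement error (weights truncated below at 0.1 kg). Defaults mirror a
#' cohort of 126 animals weighed at 18 time points from birth to 400 d.
#'
#' @param n_animals Number of animals.
#' @param ages Weighing ages in days.
#' @param params True [growth_params()] (default: a logistic curve with
#'   A = 135.63 kg, B = 22.075, k = 0.017/d).
#' @param noise_sd Measurement noise sd in kg (default 2).
#' @param animal_cv Between-animal coefficient of variation of the asymptote
#'   (default 0.05).
#' @param seed Integer seed; the generator is a pure function of its
#'   arguments and the seed.
#' @return List with `records` (data frame `animal_id, age_days, weight_kg`)
#'   and `truth` (list with `params`, `animal_scale`).
#' @export
simulate_growth_cohort <- function(n_animals = 126L,
                                   ages = round(seq(0, 400, length.out = 18)),
                                   params = growth_params("logistic", 135.63,
                                                          22.075, 0.017),
                                   noise_sd = 2, animal_cv = 0.05, seed = 1L) {
  params <- as_growth_params(params)
  if (n_animals < 1L) fail("n_animals must be >= 1")
  if (length(ages) == 0L || any(ages < 0)) fail("ages must be non-empty and non-negative")
  if (noise_sd < 0) fail("noise_sd must be non-negative")
  if (animal_cv < 0) fail("animal_cv must be non-negative")
  with_seed(seed, {
    scale <- rnorm(n_animals, 1, animal_cv)
    scale <- pmax(scale, 0.2)
    base <- evaluate_model(params, ages)
    records <- do.call(rbind, lapply(seq_len(n_animals), function(i) {
      w <- scale[i] * base + rnorm(length(ages), 0, noise_sd)
      data.frame(animal_id = sprintf("animal_%03d", i),
                 age_days = ages, weight_kg = pmax(w, 0.1))
    }))
    rownames(records) <- NULL
    list(records = records,
         truth = list(params = params, animal_scale = scale))
  })
}

#' Simulate an annotated toy genome
#'
#' Places mRNA and lncRNA "genes" (one transcript each) on
#' `n_chromosomes` chromosomes so that exactly `planted_cis` lncRNAs lie
#' within `cis_window` bp of a designated mRNA while every other lncRNA is
#' farther than `cis_window` from all mRNAs. Genes are laid out on a slot
#' grid of pitch `2.5 * cis_window` so the separation guarantees hold by
#' construction; a chromosome too short to host the requested genes raises
#' an error.
#'
#' Transcript lengths are log-normal (lncRNA mode within 200--1000 nt, mRNA
#' within 600--3000 nt); exon counts skew to 1--2 for lncRNAs and >= 3 for
#' mRNAs; coding-potential scores are drawn directly (lncRNA: CNCI ~
#' N(-5, 2), CPC ~ N(-3, 1); mRNA: CNCI ~ N(5, 2), CPC ~ N(2, 1.5)) since the
#' pipeline consumes scores, never sequences.
#'
#' @param n_chromosomes,chrom_length Chromosome count and length in bp.
#' @param n_mrna,n_lnc Numbers of mRNA and lncRNA genes.
#' @param planted_cis Number of lncRNAs planted within the cis window of a
#'   designated mRNA; must be at most `min(n_mrna, n_lnc)`.
#' @param cis_window Window in bp used at generation time (default 100 kb).
#' @param seed Integer seed.
#' @return List with `transcripts` (data frame `transcript_id, gene_id,
#'   chrom, strand, start, end, length, exon_count, biotype`), `scores`
#'   (data frame `transcript_id, exon_count, read_support, cnci, cpc`) and
#'   `truth` (list with `cis_pairs`: data frame `lnc_id, mrna_id, distance`).
#' @export
simulate_annotation <- function(n_chromosomes = 3L, chrom_length = 1e8,
                                n_mrna = 800L, n_lnc = 200L,
                                planted_cis = 10L, cis_window = 1e5,
                                seed = 1L) {
  if (planted_cis > min(n_mrna, n_lnc))
    fail("planted_cis must be <= min(n_mrna, n_lnc)")
  max_span <- 20000
  pitch <- 2.5 * cis_window
  if (pitch < 2 * cis_window + 2 * max_span + 2)
    fail("cis_window too large for the slot pitch")
  slots_per_chrom <- floor((chrom_length - max_span - cis_window) / pitch)
  n_slots_needed <- n_mrna + (n_lnc - planted_cis)
  if (slots_per_chrom * n_chromosomes < n_slots_needed)
    fail("chromosomes too short: %d slots available, %d genes need separation",
         slots_per_chrom * n_chromosomes, n_slots_needed)

  with_seed(seed, {
    slot_chrom <- rep(sprintf("chr%d", seq_len(n_chromosomes)),
                      each = slots_per_chrom)[seq_len(n_slots_needed)]
    slot_start <- rep(1 + pitch * (seq_len(slots_per_chrom) - 1),
                      times = n_chromosomes)[seq_len(n_slots_needed)]
    ord <- sample.int(n_slots_needed)
    slot_chrom <- slot_chrom[ord]; slot_start <- slot_start[ord]

    draw_len <- function(n, meanlog, sdlog, lo, hi)
      pmin(pmax(round(stats::rlnorm(n, meanlog, sdlog)), lo), hi)
    mrna_len <- draw_len(n_mrna, log(1500), 0.55, 300, 15000)
    lnc_len <- draw_len(n_lnc, log(600), 0.6, 200, 10000)
    mrna_exons <- sample(1:12, n_mrna, replace = TRUE,
                         prob = c(0.03, 0.07, rep(0.9 / 10, 10)))
    lnc_exons <- sample(1:4, n_lnc, replace = TRUE,
                        prob = c(0.55, 0.30, 0.10, 0.05))

    span <- function(len, exons) len + (exons - 1) * 500  # fixed 500 bp introns
    mrna_span <- span(mrna_len, mrna_exons)
    lnc_span <- span(lnc_len, lnc_exons)
    stopifnot(all(mrna_span <= max_span), all(lnc_span <= max_span))

    mrna <- data.frame(
      transcript_id = sprintf("MRNA_T%04d", seq_len(n_mrna)),
      gene_id = sprintf("MRNA_G%04d", seq_len(n_mrna)),
      chrom = slot_chrom[seq_len(n_mrna)],
      strand = sample(c("+", "-"), n_mrna, replace = TRUE),
      start = slot_start[seq_len(n_mrna)],
      end = slot_start[seq_len(n_mrna)] + mrna_span - 1,
      length = mrna_len, exon_count = mrna_exons, biotype = "mRNA",
      stringsAsFactors = FALSE)

    # planted lncRNAs sit gap ~ U{0..cis_window - span} downstream of their mRNA
    partner <- sample.int(n_mrna, planted_cis)
    lnc_chrom <- character(n_lnc); lnc_start <- numeric(n_lnc)
    gap <- integer(0)
    if (planted_cis > 0) {
      gap <- sapply(seq_len(planted_cis), function(j)
        sample.int(cis_window - lnc_span[j] + 1, 1) - 1L)
      lnc_chrom[seq_len(planted_cis)] <- mrna$chrom[partner]
      lnc_start[seq_len(planted_cis)] <- mrna$end[partner] + gap + 1
    }
    if (n_lnc > planted_cis) {
      idx <- (planted_cis + 1):n_lnc
      slot_idx <- n_mrna + seq_along(idx)
      lnc_chrom[idx] <- slot_chrom[slot_idx]
      lnc_start[idx] <- slot_start[slot_idx]
    }
    lnc <- data.frame(
      transcript_id = sprintf("LNC_T%04d", seq_len(n_lnc)),
      gene_id = sprintf("LNC_G%04d", seq_len(n_lnc)),
      chrom = lnc_chrom,
      strand = sample(c("+", "-"), n_lnc, replace = TRUE),
      start = lnc_start, end = lnc_start + lnc_span - 1,
      length = lnc_len, exon_count = lnc_exons, biotype = "lncRNA",
      stringsAsFactors = FALSE)

    transcripts <- rbind(mrna, lnc)
    scores <- data.frame(
      transcript_id = transcripts$transcript_id,
      exon_count = transcripts$exon_count,
      read_support = 3L + rnbinom(nrow(transcripts), mu = 20, size = 2),
      cnci = c(rnorm(n_mrna, 5, 2), rnorm(n_lnc, -5, 2)),
      cpc = c(rnorm(n_mrna, 2, 1.5), rnorm(n_lnc, -3, 1)),
      stringsAsFactors = FALSE)

    cis_pairs <- if (planted_cis > 0) {
      data.frame(lnc_id = lnc$gene_id[seq_len(planted_cis)],
                 mrna_id = mrna$gene_id[partner],
                 distance = as.integer(gap), stringsAsFactors = FALSE)
    } else {
      data.frame(lnc_id = character(0), mrna_id = character(0),
                 distance = integer(0))
    }
    list(transcripts = transcripts, scores = scores,
         truth = list(cis_pairs = cis_pairs, cis_window = cis_window))
  })
}

#' Simulate a replicated two-condition count experiment
#'
#' Negative-binomial counts (variance \eqn{\mu + \phi \mu^2}) over the genes
#' of a toy annotation. Baseline means are log-normal(log 50, 1); `n_de`
#' genes get a planted log2 fold change (condition A over condition B) with
#' magnitude drawn uniformly from `log2fc_range` and random sign; expected
#' column sums equal `depth`. Partners of every planted cis pair share a
#' per-sample log-normal latent factor (sd `latent_sd`) and a reduced
#' dispersion `pair_dispersion`, emulating a tightly co-regulated gene pair
#' whose expected TPM correlation exceeds 0.9; cis-pair genes are excluded
#' from the DE draw so the two planted structures stay orthogonal.
#'
#' @param annotation Result of [simulate_annotation()] (or a compatible list
#'   with `transcripts` and `truth$cis_pairs`).
#' @param n_de Number of planted DE genes.
#' @param log2fc_range Interval for |planted log2 fold change|.
#' @param dispersion NB overdispersion \eqn{\phi} (0 gives Poisson).
#' @param depth Expected library size per sample.
#' @param n_reps Replicates per condition (default 3, a 3-vs-3 design).
#' @param latent_sd Log-scale sd of the shared cis-pair factor.
#' @param pair_dispersion Dispersion used for cis-pair genes.
#' @param seed Integer seed.
#' @return List with `counts` (genes x samples matrix, columns `A1..`,
#'   `B1..`), `condition` (factor), `lengths` (named nt lengths for TPM),
#'   and `truth` (list with `de_genes`: data frame `gene_id, log2fc`;
#'   `cis_pairs` passed through).
#' @export
simulate_expression <- function(annotation, n_de = 50L,
                                log2fc_range = c(1.5, 3), dispersion = 0.1,
                                depth = 1e6, n_reps = 3L, latent_sd = 1,
                                pair_dispersion = 0.01, seed = 1L) {
  tx <- annotation$transcripts
  genes <- tx$gene_id
  n_genes <- length(genes)
  if (n_de > n_genes) fail("n_de must be <= number of genes")
  if (dispersion < 0) fail("dispersion must be >= 0")
  cis <- annotation$truth$cis_pairs
  pair_genes <- unique(c(cis$lnc_id, cis$mrna_id))

  with_seed(seed, {
    base <- stats::rlnorm(n_genes, log(50), 1)
    names(base) <- genes
    base[pair_genes] <- 500  # high-expressed, stable cis partners

    eligible <- setdiff(genes, pair_genes)
    if (n_de > length(eligible)) fail("n_de too large once cis-pair genes are excluded")
    de_genes <- sample(eligible, n_de)
    lfc <- runif(n_de, log2fc_range[1], log2fc_range[2]) *
      sample(c(-1, 1), n_de, replace = TRUE)
    names(lfc) <- de_genes

    n_samples <- 2L * n_reps
    condition <- factor(rep(c("A", "B"), each = n_reps), levels = c("A", "B"))
    samples <- paste0(rep(c("A", "B"), each = n_reps), rep(seq_len(n_reps), 2))

    mu <- matrix(base, n_genes, n_samples, dimnames = list(genes, samples))
    # planted fold change: truth log2fc is A over B, so scale condition B down
    mu[de_genes, condition == "B"] <-
      mu[de_genes, condition == "B"] * 2^(-lfc)
    # shared latent factor per cis pair, one draw per sample
    if (nrow(cis) > 0) {
      for (i in seq_len(nrow(cis))) {
        f <- exp(rnorm(n_samples, 0, latent_sd))
        mu[cis$lnc_id[i], ] <- mu[cis$lnc_id[i], ] * f
        mu[cis$mrna_id[i], ] <- mu[cis$mrna_id[i], ] * f
      }
    }
    mu <- sweep(mu, 2, colSums(mu), "/") * depth

    phi <- rep(dispersion, n_genes)
    names(phi) <- genes
    phi[pair_genes] <- pair_dispersion
    counts <- matrix(0, n_genes, n_samples, dimnames = list(genes, samples))
    for (s in seq_len(n_samples)) {
      pois <- phi == 0
      if (any(pois)) counts[pois, s] <- rpois(sum(pois), mu[pois, s])
      if (any(!pois)) counts[!pois, s] <-
          rnbinom(sum(!pois), mu = mu[!pois, s], size = 1 / phi[!pois])
    }

    lengths <- setNames(tx$length, tx$gene_id)
    list(counts = counts, condition = condition, lengths = lengths,
         truth = list(de_genes = data.frame(gene_id = de_genes, log2fc = lfc,
                                            row.names = NULL,
                                            stringsAsFactors = FALSE),
                      cis_pairs = cis))
  })
}
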