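# inflectr

Growth studies in livestock often sample tissue at two physiologically
extreme ages: the **growth inflection point** (IP), where daily gain peaks,
and the **plateau phase** (PP), where it has nearly vanished. Locating the IP
requires fitting a sigmoidal growth curve to longitudinal weights; comparing
the two stages then runs through a standard transcriptome pipeline — lncRNA
identification, differential expression, cis-neighbor discovery — plus
phenotype comparisons. `inflectr` implements that whole workflow as reusable,
tested R functions, together with synthetic-data generators that emulate the
study design (a cohort of 126 pigs weighed at 18 ages from birth to 400 d,
and a 3-vs-3 replicated RNA-seq contrast) so every stage runs with no
external data.

## The models at the core

Three sigmoids with asymptote *A* (kg), shape *B* and rate *k* (/d), and
their closed-form turning points (w = inflection weight):

| model | W(t) | inflection age | inflection weight | max daily gain |
|---|---|---|---|---|
| logistic | A/(1+Be⁻ᵏᵗ) | ln(B)/k | A/2 | kw/2 |
| Gompertz | A·exp(−Be⁻ᵏᵗ) | ln(B)/k | A/e | kw |
| Von Bertalanffy | A(1−Be⁻ᵏᵗ)³ | ln(3B)/k | 8A/27 | 3kw/2 |

Curves are fitted by Levenberg–Marquardt least squares on pooled (age,
weight) points, ranked by R² = 1 − RSE/RST. Downstream, transcripts are
classified lncRNA when length ≥ 200 nt, exon and read-support minima hold,
and both coding-potential scores fall below their cutoffs (CNCI < 0,
CPC < −1); differential expression uses an empirical-noise (M, D) engine at
p < 0.05 and |log₂FC| ≥ 1; cis neighbors are lncRNA–mRNA pairs within a
100-kb genomic window with |Pearson r| > 0.9 (p < 0.05); enrichment is the
hypergeometric test with Benjamini–Hochberg adjustment. See the methods
vignette (`vignettes/growth-inflection-pipeline.Rmd`) for the full
specification of each stage.

## Worked example

The closed-form turning point of a published logistic fit
(A = 135.63 kg, B = 22.075, k = 0.017/d):

```r
library(inflectr)
inflection_summary(growth_params("logistic", A = 135.63, B = 22.075, k = 0.017))
#> <inflection_summary> logistic: day 182.03, 67.81 kg, 576.4 g/d
```

— the animal hits peak gain (576.4 g/d) at day 182 at about half its mature
weight. Fitting all three models to a simulated cohort (126 animals, 18 ages,
logistic truth, 2 kg noise) recovers the generating parameters and ranks the
true model first:

```r
sim <- simulate_growth_cohort(seed = 42)
growth_report(sim$records)
#>             model     A       B        k     R2 inflection_day
#> 1        logistic 135.5 22.1411 0.017022 0.9893          182.0
#> 2        gompertz 148.8  4.4340 0.009713 0.9862          153.3
#> 3 von_bertalanffy 159.1  0.9077 0.007349 0.9830          136.3
#>   inflection_weight_kg max_daily_gain_g converged
#> 1                67.75            576.6      TRUE
#> 2                54.73            531.6      TRUE
#> 3                47.13            519.5      TRUE
```

The expression side, end to end on a synthetic experiment (1000 genes, 50
planted DE genes, 10 planted cis pairs, 3 replicates per condition):

```r
ann <- simulate_annotation(seed = 42)
ex  <- simulate_expression(ann, n_de = 50, seed = 42)
tpm <- compute_tpm(ex$counts, ex$lengths)
de  <- de_test(tpm, ex$condition)
de_summary(de, biotypes = setNames(ann$transcripts$biotype, ann$transcripts$gene_id))
#> $total: 53   $up: 28   $down: 25
#> $by_biotype:  lncRNA 13 (8 up / 5 down)   mRNA 40 (20 up / 20 down)

pairs <- find_pairs(tpm[grep("^LNC", rownames(tpm)), ],
                    tpm[grep("^MRNA", rownames(tpm)), ], ann)
head(pairs[pairs$relation == "cis_neighbor", ], 3)
#>      lnc_id    mrna_id   pcc    pcc_p distance     relation
#> 1 LNC_G0001 MRNA_G0400 0.976 8.88e-04     4139 cis_neighbor
#> 2 LNC_G0002 MRNA_G0238 0.999 1.92e-06    13914 cis_neighbor
#> 3 LNC_G0003 MRNA_G0764 0.941 5.05e-03    34016 cis_neighbor
```

All 10 planted cis pairs are recovered; 53 genes are called DE, of which the
50 planted are found with a handful of false calls — in line with the
engine's measured calibration (sensitivity ≈ 0.98, FDR ≈ 0.11 over 20
seeds). A thin command-line wrapper for the growth fit is in
`inst/scripts/fit-growth.R`.

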