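# copsig

Cuprotosis expression patterns and COPsig prognostic scoring for bulk and
single-cell tumour transcriptomics.

Copper-induced cell death (cuprotosis) works through lipoylated TCA-cycle
enzymes, and the expression of its ten-gene regulator panel varies
coherently across colorectal tumours. `copsig` implements the analysis arc
built on that observation, end to end:

1. **Pattern discovery** — Monti consensus clustering over the regulator
   panel: subsample samples, cluster per candidate k, aggregate
   co-membership into a consensus matrix, and pick k by the proportion of
   ambiguous clustering (PAC = F(0.9) − F(0.1) of the consensus CDF, with
   CDF-area tie-breaking).
2. **Characterisation** — single-sample gene-set enrichment (ssGSEA: the
   rank-weighted integrated running sum with weight |rank|^0.25),
   ESTIMATE-style immune/stromal scores (ESTIMATE = immune + stromal), and
   TMEscore (signature A − signature B).
3. **The COPsig score** — pattern-associated DEGs (limma moderated t/F,
   one-vs-rest, intersected) are filtered for prognostic value (univariate
   Cox p < 0.05), reduced by a Boruta shadow-feature selector, split into
   positively (A) and negatively (B) prognosis-associated signatures, and
   condensed per patient as

   COPsig = PC1(signature A) − PC1(signature B),

   with each PC1 sign fixed to correlate positively with its signature's
   mean z-expression. High/low groups come from a median or fixed-cutoff
   split and feed Kaplan–Meier, log-rank, Cox, and maximally selected
   cutpoint analyses.
4. **Extensions** — ridge drug-response models
   (w = (XᵀX + λI)⁻¹Xᵀy, λ by 10-fold cross-validated Spearman) trained on
   cell-line panels with the standard hygiene (drop haematopoietic/lymphoid
   lines, drop compounds with > 20% missing AUC, kNN-impute the rest), and
   AUCell-style per-cell gene-set activity with a two-component mixture
   threshold for the bimodal activity split.

Seeded synthetic generators (`simulate_bulk_cohort`, `simulate_survival`,
`simulate_cellline_panel`, `simulate_single_cell`) emulate every input the
pipeline consumes, so all stages run and are tested fully offline; the
TSV/GMT/MTX readers accept real cohorts.

## Worked example

Discover the patterns in a synthetic 90-patient cohort and score patients:

```r
library(copsig)

co <- simulate_bulk_cohort(bulk_cohort_spec(
  n_genes = 200, n_samples = 90, n_subtypes = 3, n_regulator_genes = 10,
  n_signature_genes_per_subtype = 20, subtype_effect = 3, seed = 7))
le <- log2_tpm(fpkm_to_tpm(co$expr))

cons <- consensus_cluster(le, co$regulator_genes, k_range = 2:5,
                          n_reps = 100, seed = 11)
cons$chosen_k
#> [1] 3
round(cons$pac, 3)
#>     2     3     4     5
#> 0.449 0.000 0.126 0.236
```

PAC is exactly 0 at k = 3 — every pair of samples is either always or never
co-clustered — and the recovered partition matches the planted subtypes
perfectly (adjusted Rand index 1, three clusters of 30). Tie survival to
the patterns and build the score:

```r
clin <- simulate_survival(setNames(as.character(co$subtype), colnames(le)),
  survival_spec(baseline_hazard = 0.03,
                beta_subtype = c(cop1 = 1.4, cop2 = 0.7, cop3 = 0),
                censor_rate = 0.01, seed = 43))
part <- partition_signature(le, unlist(co$program_genes), co$subtype, clin)
cop <- compute_copsig(le, part)
head(cop$scores, 3)
#>   sample_id      pc1_A     pc1_B     score group
#> 1     s0001 -5.5412861 -3.855258 -1.686029   low
#> 2     s0002  6.6806322 -1.636308  8.316940  high
#> 3     s0003 -0.5160733  6.593644 -7.109718   low

logrank_test(clin, cop$scores$group)
#> chisq 14.6, df 1, p 0.000133
```

The 38-gene A signature tracks the good-prognosis program, the 32-gene B
signature the poor-prognosis programs, and the median-split high-score
group survives significantly longer — the planted structure, recovered.

`run_pipeline(demo_config())` runs all nine stages (simulation, I/O
round-trip, batch correction, clustering, enrichment, DEGs, COPsig,
drug-response, single cell) in under a minute and writes TSV/JSON
artifacts plus a checksummed manifest; reruns with the same config are
bit-identical.

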