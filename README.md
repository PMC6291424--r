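# utrpresence

Quantifying whether predicted miRNA binding sites are actually *present*
on the mRNA a cell expresses — and whether the genes that keep their
sites respond more strongly to miRNA inhibition.

## The problem

Activated, proliferating T helper cells shorten many 3'-UTRs by
alternative polyadenylation, so a binding site predicted from the
annotated 3'-UTR (e.g. by TargetScan) may sit on a segment that most
expressed mRNA molecules of that gene no longer contain. For a study of
miR-31 in repeatedly activated Th1 cells this matters directly: of a
list of putative targets, only the genes that still carry their site can
be de-repressed when the miRNA is inhibited with an antagomir.

`utrpresence` is aimed at transcriptomics analysts who have (i) per-base
RNA-seq coverage, (ii) transcript annotation with 3'-UTRs, (iii) binding
site coordinates, and (iv) an expression matrix from a miRNA-inhibition
experiment, and want to go from those to a presence-stratified target
set with an enrichment-based validation.

## The statistic

For each gene, with per-base depth $d(x)$, exons $e_1..e_n$ and binding
sites $s_1..s_m$ in the 3'-UTR:

$$ r = \max_i \frac{\mathrm{mean}_{x\in s_i} d(x)}{\mathrm{median}_{x\in \bigcup e_j} d(x)} $$

— the maximal ratio of binding-site coverage to median exonic coverage,
an estimate of the fraction of expressed molecules carrying a site.
Genes bin into `high` (r > 0.9), `mid` (0.5 ≤ r ≤ 0.9), `low` (r < 0.5)
and `not_detected`; the expressed genes with r ≥ 0.5 form the **PT₅₀**
set. Downstream, a GSEA engine (signal-to-noise ranking, weighted
running enrichment score, permutation NES and nominal p) tests
de-repression after antagomir treatment, and a resampling procedure
compares the PT₅₀ NES with NES values from random size-matched subsets
of the full target list (Welch's t plus a calibrated empirical
percentile). Synthetic-data generators produce coverage tracks with
planted 3'-UTR retention and two-arm, three-timepoint knockdown
matrices, so the whole pipeline runs end-to-end without downloads.

## Worked example

```r
library(utrpresence)

# 421 putative targets with planted retention fractions
fx <- make_fig2b_fixture(seed = 1)
pres <- presence_table(fx$models, fx$coverage)
classify_bins(pres)
#>         high          mid          low not_detected
#>          134           72           76          139
pt50 <- build_pt50(pres)
length(pt50$members)
#> [1] 206

# two-arm knockdown matrix: de-repression proportional to site presence
spec <- synthetic_spec(effect_size = 1, noise_sd = 0.25, seed = 1)
m <- simulate_knockdown_matrix(pres[pres$expressed, ], spec)
res <- run_gsea(m, list(fx$pt, pt50), gsea_config(n_perm = 1000),
                seed = 1, timepoint = 72)
for (r in res) print(r)
#> gsea_result 'PT': ES 0.906, NES 2.493, nominal p 0.000999 (282 members, 139 dropped)
#> gsea_result 'PT_50': ES 0.955, NES 2.589, nominal p 0.000999 (206 members)

# is PT50 more enriched than a random slice of PT of the same size?
pt50_significance(fx$pt, pt50, m, B = 1000, R = 20,
                  config = gsea_config(n_perm = 200), seed = 1,
                  timepoint = 72)
#> resampling_outcome: mean observed NES 2.604 vs mean null NES 2.343
#>   Welch t 58.434 (df 20.9), p 1.093e-24; empirical percentile 1.000 (B=1000, R=20, seed 1)
```

Reading the output: at 72 h after simulated antagomir treatment both the
full putative-target list (PT, of which the 139 undetectable genes drop
out of the ranked universe) and its high-presence subset (PT₅₀) are
enriched among upregulated genes, PT₅₀ more strongly (NES 2.59 vs 2.49);
the resampling test places the PT₅₀ enrichment above every one of 1000
random size-206 subsets of PT (empirical percentile 1.0). The Welch p is
reported for fidelity to the procedure it implements but is
anti-conservative (see the methods vignette, `vignettes/methods.Rmd`);
the percentile is the calibrated summary.

The expressed-gene filter, qPCR 2^−ΔCT normalization, fold changes and
Mann–Whitney tests live in `presence_filter()`, `delta_ct()`,
`fold_change_vs_control()` and `mann_whitney()`; `run_pipeline()` chains
presence → PT₅₀ → GSEA → resampling from files to a report bundle, and
`inst/scripts/utrpresence.R` exposes the same steps as shell
subcommands.

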