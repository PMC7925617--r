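# stat1gof

Transcriptomic fingerprinting of STAT1 gain-of-function (GOF) mutants.

Heterozygous STAT1 GOF mutations cause chronic mucocutaneous candidiasis and
a wide range of additional phenotypes. A way to dissect what the mutations
do transcriptionally is to complement a STAT1-null cell line with wild-type
STAT1 or with individual GOF mutants (R274W, R321S, T419R, N574I), stimulate
with IFN-γ, and compare each line's stimulated vs unstimulated
transcriptome. `stat1gof` implements that analysis end to end as a tested,
reusable R pipeline:

* **Differential expression** per cell line with a transparent
  negative-binomial Wald test: median-of-ratios size factors
  (`sf_j = median_g c_gj / (∏_k c_gk)^{1/n}`), per-group method-of-moments
  dispersion `α̂ = max(floor, (s² − μ)/μ²)`, Wald statistic
  `z = log2FC / SE` with a delta-method SE, Benjamini–Hochberg FDR
  adjustment, and the study's call filters (≥2-fold, adjusted p < 0.01).
* **Cross-line partitioning** of the up- and down-regulated sets into
  *common* (WT and all GOF), *GOF-shared* (all GOF, not WT), *private*
  (one line), *WT-only*, and *mixed* programs, with class-wise mean linear
  fold increases and non-IRG fractions against a user-supplied
  interferon-regulated-gene list.
* **Promoter GAS-motif analysis**: position-weight-matrix scanning of
  TSS-anchored promoters on the window [−200, +50), with score thresholds
  calibrated to exact p-values by dynamic programming over the discretized
  score distribution (`t(p) = min{t : P(S ≥ t) ≤ p}` under the background
  model), TSS-relative occurrence profiles at three stringencies
  (p < 10⁻³, 10⁻⁴, 10⁻⁵), and Friedman/Dunn contrasts between profile
  curves.
* **ChIP-seq peak contingency**: promoter-window/peak overlap (BED
  half-open convention), with-peak : without-peak ratios per condition
  (GOF sets depleted of WT-up genes), and Yates-corrected chi-squared
  tests `χ² = N(|ad − bc| − N/2)² / [(a+b)(c+d)(a+c)(b+d)]`.
* **Supporting statistics**: error-weighted pathway activation Z-scores
  (`Z = mean_w(log2FC | pathway) − mean_w(log2FC | all selected)`, weights
  `1/SE²`), many-to-one (Dunnett-type) mean comparisons with a Monte-Carlo
  max-|t| adjustment, and PCA with MAD-based outlier flagging.
* **A synthetic-data generator** that emulates the study design — 6 lines
  × {unstimulated, IFN-γ 4 h} × 5 replicates, planted expression programs
  (45 common at mean 5.4-fold in WT amplified 1.4-fold in GOF lines,
  43 GOF-shared at 4.5-fold, line-private programs), promoters carrying
  canonical/degenerate/absent GAS motifs, and peaks concentrated on
  canonical-GAS promoters — plus a ground-truth ledger, so every stage is
  testable without downloads.

## Worked example

```r
library(stat1gof)

cfg <- sim_config(seed = 1)          # the default study design, 5000 genes
sim <- simulate_counts(cfg)
de  <- de_test(sim$counts, "WT")
de$calls
#> de_calls [WT]: 67 up, 2 down (|log2FC| >= 1, adjusted p < 0.01)
```

67 genes pass the 2-fold / adjusted-p < 0.01 filter in the wild-type line
(45 planted common genes, the WT-only gene, and the mixed-program genes
whose line subsets include WT). Partitioning all five lines:

```r
all_de <- de_all_lines(sim$counts, c("WT", cfg$gof_lines))
part <- partition_genes(lapply(all_de, `[[`, "calls"), "WT", cfg$gof_lines)
part$counts[c("common_up", "gof_shared_up", "private_up:T419R")]
#>        common_up    gof_shared_up private_up:T419R
#>               45               43               51
```

The planted class sizes (45 common, 43 GOF-shared, 51 T419R-private) are
recovered exactly at this seed. The common program's fold amplification:

```r
average_fold_increase(all_de, part$members$common_up)
#> fold_summary over 45 genes
#>    WT R274W R321S T419R N574I
#>  5.16  7.31  7.12  6.07  7.58
```

i.e. a 5.2-fold mean increase in WT and ~1.4× that in the non-T419R GOF
lines. Promoter scanning calibrates thresholds exactly:

```r
gas <- pfm_to_pwm(read_jaspar(system.file("extdata",
        "gas_stat1_synthetic.jaspar", package = "stat1gof")))
score_threshold(gas, 1e-5)
#> score_threshold: t = 11.93 bits for p < 1e-05 (attained p = 3.81e-06)
```

The full pipeline (DE → partition → IRG fractions → occurrence profiles →
GAS and ChIP-peak contingency → pathway Z → PCA) runs in one call and is
byte-reproducible for a fixed config and seed:

```r
run_all(run_config(simulate = cfg), "out/")   # writes TSVs + summary.json
```

A thin command-line front end with `simulate`, `de`, `partition`, `scan`,
`chip` and `run-all` subcommands is installed at
`system.file("cli", "stat1gof.R", package = "stat1gof")`.

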