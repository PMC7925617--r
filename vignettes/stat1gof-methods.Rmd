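---
title: "Methods: models, parameters and design choices in stat1gof"
author: "stat1gof authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, parameters and design choices in stat1gof}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`stat1gof` analyses the transcriptomic response of isogenic STAT1 cell
lines — a STAT1-null background complemented with wild-type STAT1 or with a
gain-of-function (GOF) mutant (R274W, R321S, T419R, N574I) — to IFN-γ
stimulation, and relates the response to promoter GAS elements and STAT1
ChIP-seq occupancy. This vignette documents the models behind each stage,
the tunable parameters and their defaults, what the synthetic-data
generator does and does not emulate, and the numerical and design choices
that were genuinely open.

## The study design and its synthetic emulation

The design is 6 cell lines × 2 conditions (unstimulated, IFN-γ 4 h) × 5
replicates. `sim_config()` + `simulate_counts()` emulate it with planted
expression programs:

| class | size (default) | effect (mean linear fold) |
|---|---|---|
| `common_up` (WT + all GOF) | 45 | 5.4 in WT; ×1.4 in R274W/R321S/N574I, ×6.4/5.4 in T419R |
| `gof_shared_up` (all GOF, not WT) | 43 | 4.5 |
| `private_up:<line>` | 14 / 10 / 51 / 35 | 4 |
| `wt_only_up` | 1 | 4 |
| `mixed_up` (≥2 lines, no other pattern) | 30 | 4 |
| `down:<line>` | 2 / 11 / 11 / 61 / 18 | 1/3 |
| `baseline_shift:<line>` (unstimulated shift) | T419R 1↑/21↓, N574I 44↑/90↓ | 2.65 / 2.96↑, 2.70↓ |

Counts are negative binomial with dispersion `nb_dispersion = 0.05` and
baseline means log-uniform on `[50, 2000]` — typical bulk RNA-seq ranges;
neither is dictated by the study, so both are exposed in the config. The
mean in a sample is `μ_g · baseline(line) · fold(line)^[stimulated]`. A
gene's planted fold is its class mean times `Uniform(1 − j, 1 + j)` with
`fold_jitter j = 0.4`: the multiplicative jitter preserves the class mean
exactly in expectation while keeping every planted fold comfortably beyond
the 2-fold call threshold (e.g. the weakest shared-program fold is
4.5 × 0.6 = 2.7). An effect size of exactly 1 plants fold 1, so a
configuration with all effects 1 is a true null. The non-transduced line
(`NT`) carries no program at all: its true fold change is 1 everywhere,
emulating a line that cannot respond to IFN-γ. The per-line GOF
amplification defaults to 1.4 for R274W/R321S/N574I and 6.4/5.4 ≈ 1.19 for
T419R, matching the weaker amplification that distinguishes T419R.

The mixed program deserves a note: each mixed gene responds in a random
subset of ≥2 lines that matches none of the other patterns. The subset may
include WT, so the WT up-set is larger than the common program alone — as
in the real design, where WT shares genes with some but not all mutants.

The synthetic genome is one 2 kb contig per gene with the TSS at position
1000 and a configurable minus-strand fraction (default 0.5) so strand
mirroring in interval logic is actually exercised. Promoters cover
[−200, +50) around the TSS in transcription orientation, with i.i.d.
background bases; the motif policy plants, per class, a canonical GAS copy
(`common_up`), a 1–2-mismatch degenerate copy (`gof_shared_up`), or nothing
(all other classes), uniformly within [−100, 0). Peaks are placed on a
promoter with probability 0.9 / 0.4 / 0.05 for canonical / degenerate /
absent motif classes, each peak a half-open interval overlapping its
promoter window.

**What the generator does not emulate:** sequencing-depth and library-size
batch effects, GC and length bias, real promoter base composition and
motif clustering (CpG islands, Inr elements), dependence between genes,
heterozygosity (the cell model is effectively homozygous per line), or
peak-strength variation. Passing tests therefore demonstrate correctness
of the analysis logic and calibration under the stated statistical model,
not robustness to those real-data artifacts.

## Differential expression

The DE stage is a deliberately transparent stand-in for a full NB GLM
framework: the contribution of this package is everything downstream of
the DE calls, so the test must be correct and simple rather than
bit-compatible with any particular tool.

Per line, counts are normalized with median-of-ratios size factors
computed on that line's ten samples (genes expressed in all samples form
the reference; if none exists, genes non-zero in ≥90% of samples are used,
with a warning). The per-gene Wald statistic is

$$ z = \frac{\log_2(m_s / m_u)}{SE}, \qquad
   SE^2 = \frac{1}{\ln^2 2}\left[\frac{1/m_u + \alpha_u}{n_u} +
   \frac{1/m_s + \alpha_s}{n_s}\right], $$

with group means $m$ on normalized counts and per-group method-of-moments
dispersions $\alpha = \max(10^{-8}, (s^2 - m)/m^2)$. Two points matter
numerically:

* **Per-group dispersion.** The NB variance $m + \alpha m^2$ with the
  unclamped per-group estimate reduces to the group's sample variance,
  floored at the Poisson variance. Estimating $\alpha$ per condition
  rather than pooled across conditions avoids assuming an equal
  dispersion under stimulation and keeps the null well calibrated: with a
  pooled clamped estimate, genes whose pooled sample variance randomly
  fell below the mean received a near-Poisson SE and produced spuriously
  tiny p-values.
* **Zero-mean groups.** When either group mean is zero, a pseudo-mean of
  0.5 normalized counts is added to both means before the fold change and
  SE, keeping fold changes finite. Genes with zero counts everywhere are
  reported with `NA` p and excluded from the Benjamini–Hochberg `m`.

Calls require `|log2FC| ≥ lfc_min` (default 1, i.e. 2-fold) and adjusted
p below `alpha` (default 0.01). The study's wording leaves open whether
p < 0.01 applies to raw or BH-adjusted p-values; since the BH procedure is
described immediately before the cut-off, the default applies it to the
adjusted values, with `use_adjusted = FALSE` available.

Out of scope by design: dispersion shrinkage, GLM covariates, independent
filtering and outlier replacement.

## Partitioning and fold summaries

Partition labels are defined purely set-theoretically on the per-line call
sets and are exhaustive and mutually exclusive over the union of calls:
common (WT and every GOF line), GOF-shared (every GOF line, not WT),
private (exactly one line; the WT case is labeled `wt_only`), and mixed
(≥2 lines, matching no other label — the operationalization of
"non-private or non-common"). Label assignment is invariant to the order
of the GOF lines; the test suite checks it against an exhaustive
enumeration of all 2⁵ membership patterns.

Class fold summaries are **linear-scale arithmetic means** of `2^log2FC`
over the class members, per line — the scale on which values like "5.4-fold
average increase" are reported; log-scale averaging would systematically
understate them.

IRG classification is an exact ID match (after upper-casing) against a
user-supplied list standing in for a type-II interferon-regulated-gene
annotation; genes absent from the list count as non-IRG. The simulator's
IRG fixture contains the common, GOF-shared and WT-only programs, 30% of
the mixed program and 500 non-responsive genes, so non-IRG fractions are
dominated by the private programs — the qualitative signature of interest.

## PWM scanning with exact p-value calibration

A JASPAR-format position frequency matrix is converted to log-odds bits,

$$ s(i, b) = \log_2 \frac{(c_{ib} + q\,p_b) / (C_i + q)}{p_b}, $$

with background $p_b$ (default uniform) and total pseudocount $q = 0.5$.
Scores are discretized to a grid of `eps = 0.01` bits and the exact pmf of
the score of a random background word is computed by per-position
convolution over the four bases; the threshold for a requested p-value is
the smallest grid score `t` with `P(S ≥ t) ≤ p`, reported together with
the attained p. The discretization error of any word's score is at most
`w·eps/2 = 0.045` bits for the 9-bp GAS model — far below any biological
signal; `eps` is exposed for users who want it tighter. If no threshold
attains the requested p (p below the best word's probability), the maximum
score is returned with an `unattainable` flag. The test suite verifies the
convolution against brute-force enumeration of all `4^w` words for widths
up to 8.

Scanning scores every offset on both strands by default (GAS is
quasi-palindromic and strandedness is not specified); minus-strand hits
are reported at the plus-coordinate start of the match's leftmost base.
Windows containing non-ACGT characters are skipped and tallied. Hits at
stricter thresholds are subsets of hits at looser ones by construction —
the stringency-relaxation logic of scanning at p < 10⁻³/10⁻⁴/10⁻⁵.

Occurrence profiles report, for bin centers stepped every 5 bp, the
percentage of promoters with ≥1 hit **start** inside a 25 bp window around
the center. Counting starts (rather than centers or any-overlap) is a
choice; it is configurable via the window/step parameters and documented
here because the upstream tool's convention is not published. The
25 bp / 5 bp defaults resolve a ~100 bp peak without aliasing.

The shipped GAS matrix (`inst/extdata/gas_stat1_synthetic.jaspar`) is a
**synthetic** PFM built around the high-information 9-mer TTCCGGGAA (an
instance of the TTCNNNGAA GAS class) with a degenerate central triplet;
any JASPAR-format matrix (e.g. a HOCOMOCO-derived STAT1 model) can be
substituted.

## Peak / promoter contingency

All interval logic is 0-based half-open (BED convention). The promoter
window is `[tss − 200, tss + 50)` on the plus strand and
`[tss − 49, tss + 201)` on the minus strand, which covers exactly 200 bp
upstream and 50 bp downstream in transcription orientation; the mirroring
is covered by a base-by-base orientation test. Overlap means
`max(starts) < min(ends)` on the same contig — any overlap, not
summit-containment, since the summit convention of the original overlap
tool is not published. For GOF conditions the gene set is first depleted
of WT-up genes (only genes not already up-regulated by WT are scored), and
each GOF (with, without) row is paired with the WT row in a 2×2 table for
the Yates-corrected chi-squared test. A GOF set that empties after
depletion is reported as NA, not zero.

## Statistics

* **Yates chi-squared**: the classical continuity-corrected statistic with
  1 df; zero marginals yield NA with a warning rather than a misleading 0.
* **Friedman test** over blocks (profile position bins) × treatments
  (conditions): mid-ranks within blocks, the usual
  $Q = \frac{12}{nk(k+1)}\sum_j R_j^2 - 3n(k+1)$ divided by the tie
  correction $1 - \sum(t^3 - t)/(nk(k^2-1))$; p from $\chi^2_{k-1}$, or
  from exhaustive within-block permutation (all $(k!)^n$ arrangements) for
  $nk \le 12$. The chi-squared approximation at n = 3 blocks is crude;
  the exact option exists precisely for such instances.
* **Dunn's post hoc**, many-to-one against a reference treatment:
  $z_j = (\bar R_j - \bar R_{ref}) / \sqrt{k(k+1)/(6n)}$, two-sided normal
  p, Bonferroni-adjusted over the $k-1$ comparisons (the adjustment used
  by the common implementations of "Dunn's multiple comparison").
* **Many-to-one mean comparisons** (Dunnett-type): pooled-variance t
  statistics against the control; the family-wise adjustment samples the
  max-|t| null by Monte Carlo (default 10⁵ seeded draws) over the joint
  distribution induced by the shared control mean and pooled variance,
  avoiding multivariate-t quadrature while respecting the comparison
  correlation. A Bonferroni fallback is provided. The heatmap-style
  application collapses genes into the pooled variance — the exact ANOVA
  layout used upstream is not printed, so this operationalization is
  isolated behind one function.
* **Pathway activation Z**: genes are pre-filtered (default
  `|log2FC| ≥ 1`, adjusted p < 0.001); with weights $w = 1/SE^2$,
  $Z = \bar x_w(\text{pathway}) - \bar x_w(\text{all selected})$. Whether
  the upstream score used log2FC or normalized intensities is ambiguous;
  log2FC is the default and the choice is flagged in the documentation.
  Because the raw difference is high-variance for pathways with one or two
  selected members, a standardized variant
  ($Z / \sqrt{1/W_p + 1/W_{all}}$) is also reported and is the right
  statistic for ranking pathways of very different sizes — the package's
  "interferon set scores highest in every GOF line" check uses it.
* **PCA**: samples are projected on the top two components of the
  gene-centered `log2(normalized + 1)` matrix; within each
  (line, condition) group, a sample whose PC1/PC2 distance to the group
  centroid exceeds `median + 3·MAD` is flagged. The original outlier
  exclusion was visual; the MAD rule is this package's explicit,
  reproducible operationalization, with `mad_k` exposed.

## Pipeline, determinism and problem sizes

`run_all()` chains simulate (or load) → DE → partition/folds/IRG → scan +
profiles + Friedman/Dunn → peak contingency → pathway Z → PCA, writing
every table as TSV plus a `summary.json` carrying the seed, a config hash
and every statistic. Every stochastic stage derives its own RNG stream
from the master seed, so identical config + seed reproduce every output
byte for byte; stage failures abort with the stage name.

The test suite exercises the full 5000-gene default design for the
end-to-end checks (partition recovery, fold amplification, peak-ratio
ordering and determinism, seeds 1–3) and scaled-down designs
(~400–2000 genes, program sizes scaled to ~1/4) for unit-level checks —
sizes chosen to estimate each quantity with comfortable margin while
keeping a full suite run around a minute. Null-calibration checks use
2000-gene effect-free simulations pooled over three seeds, because BH
rejection counts in a single contrast are heavy-tailed (rejections
cascade) and only the pooled rate is meaningfully compared to a binomial
bound.

## Known limitations

The DE stage is intentionally minimal: no shrinkage, no covariates, and a
normal reference for a statistic whose per-group variances carry ~4 df,
which makes single-contrast tail behavior slightly anticonservative — the
package relies on BH and the 2-fold filter for practical error control,
and its calibration is verified empirically in the suite. The PWM
background model is order-0; promoters with strong compositional structure
would need a higher-order background the package does not implement. The
Monte-Carlo Dunnett adjustment has O(10⁻³) resolution at the default draw
count. The synthetic generator's independence assumptions (genes,
positions, peaks) make power estimates optimistic relative to correlated
real data.
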