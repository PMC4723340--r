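---
title: "Detecting mother-specific signatures in single-egg maternal transcriptomes"
author: "clutchsig"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting mother-specific signatures in single-egg maternal transcriptomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(clutchsig)
```

## The problem

Maternal mRNA deposited in the oocyte drives early embryogenesis until the
zygotic genome takes over. When individual unfertilized eggs are profiled
on microarrays — several eggs per clutch, one clutch per mother — two
questions arise: which genes are maternally expressed at all, and whether
the variability between eggs is structured by mother. Because each clutch
comes from one mother, "clutch" and "mother" are confounded by design and
are used interchangeably throughout.

`clutchsig` implements that analysis as a set of composable steps:
quality filtering and quantile normalization, expressed-gene calling from
the bimodality of per-probe intensity variance, fold-change variability
statistics, detection of absolutely distinct per-clutch expression levels
("mother signatures"), per-gene ANOVA with q-value FDR control, and
downstream enrichment tools. A synthetic-data generator with ground truth
makes every step testable.

## The expressed/non-expressed model

The calling procedure rests on one empirical assumption: probes measuring
expressed transcripts vary (biologically and technically) much more
across eggs than probes measuring nothing but background. Writing
$v_p = \ln \widehat{\mathrm{Var}}(x_{p\cdot})$ for the log of the
across-experiment variance of probe $p$'s log2 intensity, the empirical
distribution of $v_p$ is bimodal, and the valley between its two modes
splits probes into a low-variance (non-expressed) and a high-variance
(expressed) population. The valley is located on a Gaussian kernel
density estimate with Silverman's rule-of-thumb bandwidth: local maxima
are collected, the two highest kept, and the grid minimum between them
returned. Unimodal input is an error, never a silent threshold; a probe
exactly at the valley goes to the high-variance class (fixed, tested
convention). Probes with zero variance get a finite sentinel below every
finite value, so they always land in the low class.

The split then anchors a per-array empirical-Bayes classification. For
each array separately, class-conditional intensity densities
$f_\mathrm{lo}, f_\mathrm{hi}$ are estimated from that array's low- and
high-class probe intensities (Gaussian KDE by default; a two-Gaussian fit
is available via `density_model = "gaussian"`), and

$$
P(\text{expressed} \mid x) \;=\;
\frac{\pi_\mathrm{hi}\, f_\mathrm{hi}(x)}
     {\pi_\mathrm{hi}\, f_\mathrm{hi}(x) + \pi_\mathrm{lo}\, f_\mathrm{lo}(x)},
$$

with priors $\pi$ equal to the experiment-wide class proportions (the
variance split is an experiment-wide statement, so the prior is shared
across arrays; per-array class proportions would confound array scale
with prevalence). A probe is called expressed on an array when its
posterior exceeds 0.95 — a deliberately strict cut that trades
sensitivity for a low false-positive rate. A transcript is expressed when
its probe passes on at least 4 of the 24 arrays; a gene is expressed when
any of its transcripts is; and a gene's representative probe is the one
with the highest mean intensity over all samples (ties broken by probe
id). Where both class densities vanish the posterior is carried over from
the nearest supported intensity. One caveat worth knowing: between two
well-separated classes both densities are tiny, and a KDE posterior there
is intrinsically noisy — harmless in practice, because essentially no
probes live in that gap, but visible if you evaluate the posterior at
arbitrary points.

## Preprocessing

Three steps, in this order:

1. **Extreme genes.** A gene whose probe has exactly one sample at least
   $\log_2(3000)$ above the maximum of all its other samples is removed:
   a single unrealistically high value against an otherwise absent signal
   is an artifact, not expression.
2. **Suspect probes.** Raw intensities are centered on the array average;
   the per-array scaling factor is the array average minus the grand
   average. Probes whose centered intensities anti-correlate with the
   scaling factors (correlation ≤ −0.8 by default) while varying
   substantially (centered sd above the 90th percentile by default) are
   flagged. These are transcripts that already carry native long poly(A)
   tails: their signal does not follow the array scale, so between-array
   normalization would distort rather than correct them. No numeric
   thresholds are canonical for this filter; both cuts are arguments.
3. **Quantile normalization** between arrays (via
   `limma::normalizeQuantiles`, ties averaged): each column's sorted
   values are replaced by the across-column mean of sorted values. This
   removes per-array multiplicative scaling exactly (the generator plants
   such scales to prove it) and is idempotent.

## Variability statistics

Per gene, on the representative probe's normalized log2 values: the
experiment-wide maximum fold change is $\max_s x_s - \min_s x_s$ (log2
units), and the within-clutch mFC is the largest per-clutch range.
Within-clutch mFC ≤ experiment mFC always; threshold fractions use
"≤" on the linear scale (a gene at exactly FC 2 is inside the "mFC ≤ 2"
bucket). Singleton clutches are an error: a range needs two eggs.

## Mother signatures

For each expressed gene the per-clutch intensity intervals
$[\min, \max]$ are merged by transitive overlap, with closed-interval
overlap: intervals sharing even a single endpoint belong to the same
level, so a *distinct* level requires a strict gap. If more than one
group survives, the gene shows "absolutely distinct mother-specific
levels"; groups are ranked by hull midpoint (ties by group minimum) and
encoded as a digit string, one digit per mother in fixed mother order,
1 = highest. Genes sharing a code form a signature cluster; for two-level
codes the inverse code swaps 1 ↔ 2, and inverse cluster pairs are of
special interest because a regulatory mechanism acting on a gene set in
one mother should produce both directions. The sweep-line merge is
equivalent to exhaustive search over all set partitions of the clutches
for the finest partition with pairwise disjoint hulls — the test suite
proves this equivalence on a thousand random instances. Detection is
deterministic on the ranges; no per-gene significance is attached, which
also means the call is sensitive to single outlier eggs widening a range
(a conservative failure: outliers destroy, never create, distinct
levels — widening any interval can only reduce the level count).

## Differential expression

Per gene a one-way fixed-effects ANOVA with clutch as the factor,
computed in closed form across all genes at once (the matrix-algebra
route the microarray ANOVA packages use), $F$ on
$(k-1,\; n-k)$ degrees of freedom. Genes with zero within-clutch variance
but non-zero between-clutch variance get the smallest representable p and
a flag. Multiple testing uses Storey q-values: $\hat\pi_0(\lambda)$ on a
λ grid (0.05–0.95, step 0.05) smoothed with a cubic spline (3 df) and
read off at the largest λ, clipped to $(0,1]$; q-values are the monotone
step-down $\min_{j \ge i} \hat\pi_0\, m\, p_{(j)}/j$, which reduces
exactly to Benjamini–Hochberg when $\hat\pi_0 = 1$ (`method = "bh"`
forces that). No variance moderation or shrinkage is applied — with
per-gene error variance from 19 within-clutch degrees of freedom the
plain F-test is the transparent choice, and it is what the original
microarray ANOVA machinery computes.

A subtlety of the null: a shared per-array scale offset is a sample-level
effect that makes *every* gene conditionally non-null (all genes inherit
the same clutch-mean pattern), so null-calibration simulations set
`array_scale_sd = 0` rather than relying on normalization to remove the
effect exactly.

## Enrichment tools

**Motifs.** The built-in family holds the 3'UTR elements implicated in
cytoplasmic polyadenylation of stored maternal transcripts: hexamers
AAUAAA/AUUAAA, CPEs UUUUAU and UUUUAMU, the Pumilio element UGUA(N)AUA,
and embryonic CPEs as uninterrupted U-runs of length 11–20, each run
length its own member of the Bonferroni family. An IUPAC pattern is read
as a position-weight model with probability $1/|\text{allowed}|$ per
column against a uniform 0.25 background; a sequence's score is the
average over all same-strand windows of the odds product (expected value
exactly 1 under the background, verified by enumeration). Enrichment is a
one-sided Wilcoxon rank-sum of foreground vs control scores, Bonferroni-
corrected across the family — the discriminative setup in which the
control set holds the remaining sequences of the comparison. The exact
window/pseudocount conventions of the original scoring tool are not
recoverable; the definition above is this package's documented
convention. Note that planting an exact 11-U run enriches the 12–14-U
motifs too (background bases extend runs), so null calibration must use
genuinely unplanted sequences.

**Gene sets.** Overrepresentation is the upper-tail hypergeometric
probability of the observed overlap against a stated universe (equivalent
to one-sided Fisher; term databases are supplied by the user as plain
tables, not bundled). Overlap with an external study's cluster is
reported as the recovered fraction of the reference set.

**Chromosome distribution.** Each signature cluster becomes a row of
per-chromosome gene fractions (rows sum to 1; unmapped genes count in an
`unplaced` column), clustered with Euclidean distance and Ward linkage;
the function reports which inverse-code pairs merge as mutual nearest
neighbours.

## The synthetic-data generator

`generate_dataset()` emulates the statistical structure the analysis
assumes, with every planted label recorded in a truth object:

| parameter | default | meaning |
|---|---|---|
| `eggs_per_clutch` | 5,5,5,4,5 | 24 eggs, five clutches |
| `expressed_fraction` | 0.34 | fraction of genes expressed |
| `bg_mean`, `bg_sd` | 4, 0.1 (log2) | background level and noise of non-expressed probes |
| `expr_mean_range` | 7–13 (log2) | expressed baselines; ≥ 3 log2 above background |
| `egg_sd` | 0.24 (log2) | egg-level noise within a clutch |
| `clutch_sd` | 0.15 (log2) | clutch jitter on non-signature expressed genes |
| `signature_fraction` | 0.2 | expressed genes given mother-level offsets |
| `level_separation` | 2 (log2) | gap between adjacent distinct levels |
| `array_scale_sd` | 0.15 (log2) | per-array multiplicative scale |
| `affinity_sd` | 0.25 (log2) | per-probe affinity offsets |

Non-expressed probes get low mean *and* low variance, expressed probes
high mean and variance — the caller's assumption must hold in the
generator, it is not re-derived. Signature genes draw a two-level code
(a random non-trivial subset of mothers high; multi-level codes behind
`multi_level = TRUE`), realized as mean-centered level offsets
`level_separation` apart; the other expressed genes get i.i.d. clutch
jitter. All randomness flows from one seed through fixed per-stage
sub-seeds, so adding a stage never perturbs earlier ones, and identical
configs are bit-identical.

No study reports the within- vs between-clutch variance components
numerically, so `egg_sd` was fixed once by a Monte-Carlo calibration of
the within-clutch range statistic: under the 5/5/5/4/5 design,
`egg_sd = 0.24` puts ~88% of expressed genes at a within-clutch mFC ≤ 2,
the qualitative pattern single-egg clutch data show. It has not been
tuned further. The generator does **not** emulate: probe
cross-hybridization or sequence-dependent affinity, spatial or dye
artifacts, correlated gene modules, chromosome-biased placement of
signature genes (chromosomes are assigned round-robin, so the
inverse-pair chromosome similarity seen in real data has no synthetic
counterpart), or heavy-tailed egg outliers. Passing the recovery tests
therefore demonstrates correctness of the procedures under their own
assumptions, not robustness to everything real arrays do.

`generate_utrs()` produces i.i.d.-uniform RNA sequences with exact motif
consensus occurrences planted at random positions, for testing the motif
machinery; planted gene sets and lengths are checked up front.

## Numerical and design choices

- **Valley search**: KDE with `bw = "nrd0"` on a 512-point grid; local
  maxima below 5% of the global density maximum are ignored as wiggles.
  Across two-Gaussian mixtures spanning the mixing weights and widths of
  interest, the detected valley lies within 0.1 of the analytic density
  minimum (asserted in the tests).
- **Per-array vs pooled densities**: class densities are estimated per
  array, matching a per-microarray posterior; the two-Gaussian mode is
  the switchable alternative; priors stay global either way.
- **Boundary conventions**: valley → high class; interval overlap closed
  (shared endpoint = same level); FC thresholds inclusive;
  representative-probe ties → smallest probe id. Each is tested.
- **Power framing**: "clutch offsets of 0.5 log2" in the power test means
  each planted clutch offset has magnitude 0.5 (two-level sign patterns
  ±0.5). Under the weaker geometry where only the *group gap* is 0.5, the
  per-gene F at (4, 19) df delivers ≈ 88% power at FDR 5%, not > 95%.
- **False-distinct rate**: measured with `clutch_sd = 0`, because under
  default clutch jitter the detector's distinct calls on unplanted genes
  are detections of genuine jitter, not false positives.
- **Problem sizes**: the recovery suites run at 5,000–10,000 genes × 24
  eggs and 200-sequence UTR sets — large enough for stable rates, small
  enough that the whole suite runs in well under a minute per property.

## Limitations

Mother and clutch are confounded by the design; nothing here can
attribute a signature to genetics vs. environment. The expressed/
non-expressed call is relative (no absolute abundance), and the
distinct-level detector treats ranges as exact — a single outlier egg
collapses a signature. The q-value machinery assumes p-values that are
uniform under the null; strongly correlated genes (shared array effects)
violate that, which is why normalization precedes testing.
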