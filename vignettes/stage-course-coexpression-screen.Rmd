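---
title: "Stage-course co-expression screening: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Stage-course co-expression screening: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stagescreen)
```

## The experimental design being modelled

Fruit development is sampled as an ordered stage course: two genotypes — a
cultivar (AC) and a high-pigment introgression line (HG6-61) — at seven
weekly stages, 7 to 49 days after flowering (DAF). Expression is
RPKM-normalised; ~26,000 genes are detected; the biosynthetic pathways of
interest contribute 46 (ascorbate), 18 (carotenoid) and 14 (flavonoid)
structural genes, screened against a panel of 823 transcription factors
(TFs). Everything downstream works with one number per gene per stage, so a
gene is a point in $\mathbb{R}^7$ and "co-expression" is a 7-point Pearson
correlation.

## Quantification

$$\mathrm{RPKM} = \frac{10^9 \cdot c}{N \cdot L}$$

with $c$ mapped reads of the gene, $N$ total mapped reads and $L$ the
transcript length in bp. The expression floor keeps genes with RPKM ≥ 5.0
at one or more stages. Stage-over-stage fold-change tables carry four
kinds, because a later/earlier ratio is undefined when either stage is
zero: `RATIO` (both detected), `FROM_ZERO` (rendered `"12.29/0"`: the
value is the later-stage RPKM itself), `TO_ZERO` (rendered `"0"`) and
`NOT_DETECTED` (rendered `"-"`). The renderer and parser are exact
inverses, asserted in the tests.

## The significance rule and its exact threshold

For a Pearson correlation $r$ over $n$ points, under the null
$H_0: \rho = 0$,

$$t = \frac{r\sqrt{n-2}}{\sqrt{1-r^2}} \sim t_{n-2}.$$

A pair is significant when $|r| \ge r_{\mathrm{thr}}$ (default 0.8) **and**
$|t| > t_c = t_{1-\alpha/2,\,n-2}$. Solving $t(r^\*) = t_c$ for $r^\*$
gives the exact magnitude that the t-test alone implies:

$$r^\* = \frac{t_c}{\sqrt{n - 2 + t_c^2}}.$$

At the study's operating point $n = 7$, $\alpha = 0.05$:
$t_c = `r round(qt(0.975, 5), 5)`$ and
$r^\* = `r round(significance_threshold_r(7, 0.05), 5)`$, i.e. the
published cut $r > 0.754$ and critical value $2.571$ to three decimals.
One subtlety: $t(0.754, 7) = `r round(corr_t_statistic(0.754, 7), 4)`$ —
evaluating the t statistic at the *rounded* threshold does **not**
reproduce 2.571; the identity holds at the unrounded $r^\*$. The package
always computes with the exact value and rounds only for display.

With only 7 points the test has modest power and the dual rule matters:
the magnitude cut 0.8 is *stricter* than the t-test's implied 0.754, so
the t-test is the binding constraint only when the user lowers
`r_threshold` (e.g. to `significance_threshold_r(n, alpha)` itself, the
exact-t rule used for null calibration).

## Counting, selection and cross-genotype validation

`summarize_tf()` counts, per TF × pathway × genotype, the significant
targets split by sign; the published summary format `"N(P)"` (total, and
positives in parentheses) is written by `write_tf_summary()`.
`select_candidates()` keeps TFs whose count reaches `min_count`, by
default in **both** genotypes — a co-expression pattern that survives a
genetic background change is less likely to be coincidental.
`cross_dataset_validate()` extends the same consolidation to any number of
extra expression matrices.

## Temporal clustering

Profiles are clustered on $\log_2(\mathrm{RPKM} + 1)$. Seeding is
k-means++ (each next centre sampled with probability proportional to the
squared distance from the chosen set), iterations are Lloyd's algorithm
via `stats::kmeans`, and the best SSE over `n_init` restarts is kept;
groups are renumbered by descending size. Restarts matter: on 6-profile
toy instances the package's best-of-50 SSE equals the exhaustive
31-partition optimum for $k = 2$ in 100/100 random trials (an acceptance
contract). `stats::kmeans`' own sampling-based seeding errors on
duplicated rows, which real expression matrices contain; the ++ seeding
handles them.

## The planted-truth generator

Offline testing needs data where the right answer is known. The generator
fixes, a priori:

| Parameter | Default | Rationale |
|---|---|---|
| genotypes | AC, HG6-61 | two-background validation rule |
| stages | 7–49 DAF, weekly | the 7-point axis everything assumes |
| TFs / background | 823 / 25,500 | panel and transcriptome scale |
| pathway sizes | 46/18/14 | ascorbate/carotenoid/flavonoid |
| archetypes | 20 | the k used for real clustering |
| planted links | 29/12/9 (≈50) | proportional to pathway sizes |
| effect size / noise sd | 1.0 / 0.1 | log2-scale affine links + Gaussian noise |
| baselines | N(5,1) TF/SG, N(3.5,1.8) background | most genes pass the floor, most are low-expressed |
| amplitudes | U(2, 6) log2 units | dynamic range of ripening genes |
| p_coreg | 0.7 | pathway co-regulation (below) |

Genes follow temporal archetypes (monotone, early/late induction, peaks,
valleys, high–low–high, plateaus, plus parameterised variants; pairwise
r < 0.95 enforced). A planted link sets the target's log2 profile to an
affine function of its TF's: $y = b + s\,e\,(a \cdot g)$ with sign $s$,
effect $e$, amplitude $a$ and shape $g$ — so at zero noise the pair has
$|r| = 1$ **on the log2 scale**. On raw RPKM, $2^x$ is convex and a
negative-sign link can fall to $r \approx -0.6$; `screen_config()`
therefore exposes `correlation_scale = "raw"` (the published counting
convention) and `"log2"` (matching the planted functional form, used for
recovery scoring). Planted TFs are restricted to dynamic archetypes
(shape sd ≥ 0.25): a flat regulator is undetectable by any correlation
screen, by construction.

Three design choices encode the biology rather than convenience:

- **Pathway co-regulation** (`p_coreg`): unlinked structural genes adopt
  their pathway's characteristic shape (ascorbate → high–low–high,
  carotenoid → increasing, flavonoid → late induction) with probability
  0.7. Without it, the pathway mean is shapeless and a pathway-integral
  metabolite tracks nothing in particular.
- **Genotype lag**: the second genotype delays ripening-linked archetypes
  (maximum at the final stage) by one stage, so the two backgrounds are
  correlated but not identical — the situation the two-genotype rule is
  designed for.
- **Metabolites as integrals**: a metabolite pool accumulates from enzyme
  activity, so each series is
  $\mathrm{rate} \cdot \mathrm{cumsum}(\overline{\mathrm{RPKM}}_{\mathrm{pathway}})$
  with multiplicative noise. Limitation: a pure integral is monotone
  non-decreasing and cannot reproduce metabolites that *decline* through
  ripening (e.g. rutin or chlorogenic acid in real fruit); the model
  targets the accumulation cases (ascorbate forms, lycopene,
  β-carotene).

`archetype_mode = "flat"` switches every shape off, giving pure-noise
profiles for null calibration; `count_model = "nb"` optionally draws
negative-binomial read counts and recomputes RPKM, tying the generator to
the quantification layer.

## Calibration and recovery properties (tested)

- **Null calibration**: with 0 planted links and flat profiles, the
  fraction of pairs significant under the exact-t rule at
  $r^\* = 0.754$ is within 3 binomial SE of $\alpha = 0.05$ over 10,400
  pairs. Pairs sharing a TF are pairwise independent under the null
  (spherical symmetry of the Gaussian), so the binomial SE is the right
  scale.
- **Recovery**: at the default configuration, sensitivity ≥ 0.95 and sign
  accuracy = 1.0 over the 50 planted links; sensitivity is monotone
  non-increasing in noise (checked at sd ∈ {0, 0.3, 1.0}, 20 replicates,
  2 SE). The false discovery proportion is *not* bounded: co-regulated
  pathway members correlate with many TFs that share their archetype,
  exactly as in real fruit — which is why the screen reports candidates,
  not regulators.
- **Oracle equivalence**: screen records equal a hand-written
  product-moment nested loop to 1e−12 (absolute — relative comparison is
  meaningless for $r$ near 0).

## Numerical choices

Correlations use `stats::cor` column-matrix calls with results clamped to
$[-1, 1]$; $|r| = 1$ maps to $t = \pm\infty$ rather than NaN. TSV values
are written element-wise at 15 significant digits (non-scientific), so
matrices round-trip bit-for-bit and manifests can carry stable md5
digests. All seeds are user-supplied integers below $2^{31}$; a config +
seed reproduces every output file byte-for-byte (asserted in the pipeline
tests).
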