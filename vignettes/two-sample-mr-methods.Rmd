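---
title: "Methods: two-sample Mendelian randomization in mrpipe"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: two-sample Mendelian randomization in mrpipe}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mrpipe)
```

## The model and its assumptions

Two-sample Mendelian randomization treats genetic variants as
instrumental variables for an exposure. For variant $j$, write
$\gamma_j$ for its true effect on the exposure and $\Gamma_j$ for its
true effect on the outcome. Under the instrumental-variable assumptions —
relevance ($\gamma_j \neq 0$), independence from confounders, and the
exclusion restriction (the variant affects the outcome only through the
exposure) — the model is linear:

$$\Gamma_j = \theta\,\gamma_j + \alpha_j, \qquad \alpha_j = 0
  \text{ when the exclusion restriction holds},$$

where $\theta$ is the causal effect and $\alpha_j$ a direct
(horizontally pleiotropic) effect. The two GWAS supply estimates
$\hat\beta_{Xj} \sim N(\gamma_j, \sigma_{Xj}^2)$ and
$\hat\beta_{Yj} \sim N(\Gamma_j, \sigma_{Yj}^2)$ from non-overlapping
samples; all estimators operate on the harmonized quadruple
$(\hat\beta_{Xj}, \sigma_{Xj}, \hat\beta_{Yj}, \sigma_{Yj})$.

Estimators differ in which violations they tolerate. IVW is efficient
but biased by any net pleiotropy; MR-Egger estimates $\theta$ and the
mean pleiotropy (its intercept) jointly, under the InSIDE condition
(pleiotropy independent of instrument strength); the weighted median is
consistent while more than half the instrument weight is valid;
MR-PRESSO localizes individual violating variants.

## Instrument selection

The pipeline order is fixed: significance screen, LD clumping, allele
harmonization, weak-instrument filter, confounder blocklist. Parameters
and defaults:

| parameter | default | meaning |
|---|---|---|
| `p_threshold` | 5e-8 | genome-wide significance, strict `<` |
| `clump_kb` | 10,000 kb | clump window, base-pair distance |
| `clump_r2` | 0.001 | neighbours with r² **above** this are dropped |
| `f_min` | 10 | F = β²/SE²; F < 10 removed, F = 10 kept |

Clumping is greedy on ascending p-value; ties resolve by smaller
position, then lexicographic SNP id, so output is deterministic. LD
comes from a user-supplied long-format table (absent pairs are treated
as unlinked, which matches the sparsity of exported LD tables); the
package never computes LD from genotype panels. Records without
coordinates fall back to LD-only exclusion with a warning rather than
failing, which keeps small hand-built fixtures usable. Confounder
screening is a plain blocklist file — there is deliberately no web
query: the analyst curates the list of SNPs associated with confounders
and the run stays reproducible offline.

The F filter runs after harmonization so instrument counts in reports
refer to SNPs that are actually analyzable against the outcome.

## Harmonization

Outcome records are re-expressed on the exposure's effect allele:
identical alleles pass through; swapped alleles negate the outcome beta
and reflect its allele frequency; strand-complemented codings (only
attempted for non-palindromic SNPs, after direct match and swap both
fail, to minimize silent mis-orientation) are complemented and then
resolved. A/T and C/G variants are palindromic — their strand cannot be
read off the alleles — and are removed by default. The optional `infer`
policy keeps a palindromic SNP when both allele frequencies are present,
both minor-allele frequencies fall below 0.42, and the frequencies
identify the strand; with frequencies near 0.5 or missing the SNP is
always removed. Exposure SNPs missing from the outcome are logged as
lost; no proxy search is attempted.

## Estimation and diagnostics: numerical choices

* IVW weights are $w_j = (\hat\beta_{Xj}/\sigma_{Yj})^2$ — the
  first-order delta-method precision of the ratio, ignoring
  exposure-side noise, which is the field's standard choice. The
  random-effects variant uses multiplicative overdispersion with an
  inflation floor of 1 (it never deflates); IVW p-values are normal.
* MR-Egger orients every instrument so $\hat\beta_{Xj} \ge 0$ before
  fitting (the estimator is not invariant to allele coding; orientation
  to the exposure-increasing allele is the accepted convention) without
  mutating the stored instruments. Slope and intercept SEs use the
  overdispersion factor $\max(1, \text{weighted RSS}/(k-2))$ and t
  p-values with $k-2$ df.
* The weighted median interpolates the cumulative-midpoint weight
  function at ½ (ties in ratios resolved by ordered interpolation); its
  SE is a parametric bootstrap (default 1000 replicates, explicit seed)
  perturbing both effect columns by their SEs.
* MR-PRESSO follows the published algorithm shape: per-SNP expected
  outcome effects come from leave-one-out IVW fits; the global and
  per-SNP p-values use the $(1+k)/(n_{\text{sim}}+1)$ Monte-Carlo
  estimator (never zero); per-SNP p-values are Bonferroni-adjusted by
  the instrument count; the corrected estimate re-runs random-effects
  IVW (matching the headline estimator) and is reported only when the
  global test is significant and outliers are flagged — otherwise the
  "after correction" column is NA. The distortion p-value compares the
  observed corrected-vs-raw shift against shifts from dropping random
  subsets of the same size.
* Degenerate inputs degrade gracefully: methods below their instrument
  minimum (IVW 1, Q and leave-one-out 2, Egger and weighted median 3,
  MR-PRESSO 4) are skipped with explicit report entries; a single
  instrument falls back from random- to fixed-effect IVW with a warning.
* The 95 % CI multiplier is fixed at z = 1.959964.

## The Steiger test

Per-SNP variance explained defaults to $r^2 = F/(F + n - 2)$, which
needs no allele frequency and applies to binary-trait summary statistics
on the observed scale (a standardized-scale alternative
$2\,\mathrm{eaf}(1-\mathrm{eaf})\beta^2$ is available for continuous
traits). Sides are compared by Fisher's z transform of the square roots,
scaled by $\sqrt{1/(n_X-3) + 1/(n_Y-3)}$ — the two-independent-samples
form, appropriate because the exposure and outcome GWAS do not share
participants. A caveat worth stating: the per-SNP formula sums linearly,
and for a very strong instrument panel the sum can exceed 1, where it
stops being interpretable as a variance fraction; the direction
comparison caps the summed values just below 1 before the z transform,
and the direction flag itself (strict `>` comparison) is unaffected.
When per-SNP sample sizes vary, their median serves as the scalar GWAS
size; explicit `n_exp`/`n_out` arguments override.

## What the simulator emulates — and what it does not

`simulate_study()` draws, per SNP: a minor-allele frequency uniform on
(0.05, 0.45); a true exposure effect $\gamma_j \sim N(0.2, 0.1)$
truncated below at 0.05; a pleiotropic effect $\alpha_j$ per regime
(none, balanced, directional); then observed effects around
$\gamma_j$ and $\Gamma_j = \theta\gamma_j + \alpha_j$ with GWAS
standard errors $1/\sqrt{2\,\mathrm{maf}(1-\mathrm{maf})\,n}$. Default
sample sizes (337,159 exposure; 216,362 outcome) are of the order of
the biobank and registry GWAS this kind of analysis is run on. The
effect-size distribution is deliberately strong and bounded away from
zero: instruments are coded to the exposure-increasing allele and
represent hits that already passed the significance screen, and the
spread keeps the exposure-effect measurement error small relative to
the effect variance — the NOME condition under which the Egger
intercept is an unbiased estimate of mean pleiotropy. Weaker or
narrower choices reintroduce a regression-dilution bias in the
intercept of the same order as the Monte-Carlo resolution of a
200-replicate experiment, which would make the pleiotropy-recovery
property meaningless as a test.

Harmonization noise is planted only in the outcome file (allele swaps,
strand flips, duplicates) so the exposure-side selection stages stay
undisturbed; palindromic allele pairs are assigned at variant creation
in both files, because being palindromic is a property of the variant,
not of one file's coding. A single master seed drives three split
sub-seed streams (effects, sampling noise, allele edits), so the same
seed reproduces a study byte for byte while components stay
independent.

Preset scenarios pin the study conditions used by the test suite:
`null` (θ = 0), `causal` (θ = 0.5, 80 instruments),
`directional_pleiotropy` (θ = 0.5, α ~ N(0.02, 0.01)), `outlier`
(θ = 0.5, 10 instruments, one shifted 10 outcome-SEs — the small panel
keeps the Bonferroni-adjusted per-SNP floor below the 0.05 flagging
threshold at moderate simulation counts), and `reverse` (true causation
outcome → exposure).

What the simulator does **not** emulate, and hence what passing tests
do not establish about real data: LD between instruments (SNPs are
generated unlinked; clumping is exercised against hand-written LD
tables), case/control effective-sample-size corrections for binary
traits (the continuous-trait SE approximation is used throughout),
winner's-curse bias in the exposure effects, sample overlap between the
two GWAS, population stratification, and effect heterogeneity across
ancestries.

## Problem sizes and determinism

The calibration experiments use 1000 replicates for type-I error, 500
for Q-uniformity, 200 for recovery, pleiotropy, outlier and direction
properties, and 100 for CI coverage, with MR-PRESSO at 200 simulated
datasets inside the suite and its conventional 1000 in the acceptance
script — sizes chosen so the whole suite runs in about a minute while
keeping Monte-Carlo error well inside each property's tolerance.
Replicate seeds are consecutive integers; the acceptance script derives
its seed streams from a single `--seed`. Identical configuration and
inputs reproduce every output file byte for byte.

## Known limitations

* No LD-proxy substitution for exposure SNPs missing from the outcome;
  no indel or multi-allelic support (harmonization logic is SNP-only).
* SIMEX-corrected Egger, mode-based estimators, multivariable MR and
  the Rucker/radial frameworks are out of scope.
* The Steiger r² formula is an observed-scale approximation for binary
  traits; summed r² from strong panels should be read as a comparison
  statistic, not a variance fraction.
* The blocklist stands in for interactive confounder lookups; its
  completeness is the analyst's responsibility.
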