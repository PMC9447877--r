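---
title: "Methods: pooled shRNA dropout-screen analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: pooled shRNA dropout-screen analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dropscreen)
```

## The screen and its statistical model

A pooled dropout screen measures, by sequencing, the abundance of every
hairpin in a library across three arms: a t = 0 reference collected at
infection, and untreated / treated end arms grown in parallel. A gene that
sensitizes cells to the drug is read out as depletion of its hairpins in the
treated arm relative to the untreated arm, with the t = 0 arm guarding
against the converse artifact (hairpins that *rose* in the untreated arm).

Counts are modeled as negative binomial with mean `μ` and variance
`μ + αμ²`, where `α` is the hairpin-level overdispersion. The package's
statistical core mirrors the classic count-based differential-abundance
recipe for screens:

1. **Size factors.** For sample `j`,
   `sf_j = median_i( k_ij / geomean_i )` over hairpins `i` whose counts are
   positive in every sample (only those have a positive geometric mean).
   The median is taken on the ratio scale, and factors are rescaled to
   geometric mean 1: the global scale of size factors is arbitrary, and this
   convention makes small worked examples exact (for two samples with all
   rows in ratio 1:2, the factors are `1/√2` and `√2`). Estimation fails
   loudly if no hairpin is positive everywhere — in a dropout screen that
   indicates an upstream problem, not a condition to paper over.

2. **Dispersions.** Per hairpin, a method-of-moments estimate from the
   pooled within-arm variance of normalized counts,
   `α_MoM = (v − ξ·μ)/μ²` with `ξ = mean(1/sf)` accounting for the
   depth-rescaled Poisson component. A trend `α(μ) = a₀ + a₁/μ` is fit to
   these by least squares (clamped at zero), and each hairpin receives
   `max(α_MoM, trend(μ))`. This conservative "maximum" sharing counters the
   large sampling noise of per-hairpin variance estimates at n = 3 per arm:
   underestimated dispersions would make the Wald test anti-conservative,
   while the maximum rule only ever inflates variances. If any arm has fewer
   than two samples the estimator falls back to pooled ("blind") estimation
   across all samples. All-zero hairpins carry no information; they are
   assigned the trend value just above zero mean and are neutralized
   downstream anyway (p = 1).

3. **Per-hairpin test.** For a contrast of a test arm against a reference
   arm, `log2FC = log2((m_B + c)/(m_A + c))` with pseudocount `c = 0.5`
   normalized counts, and a two-sided Wald p-value on the natural-log fold
   change, with `Var(m) = (μ·Σ 1/sf_j + n·α·μ²)/n²` per arm propagated to
   the log scale by the delta method. The pseudocount keeps fold changes
   finite at zero counts; at the abundances where hits may be called
   (baseMeanA > 100) its bias is below 0.01 log2 units. The construction is
   exactly antisymmetric in the arms: swapping them negates log2FC and
   leaves p-values unchanged. Hairpins with zero counts in both arms get
   log2FC = 0 and p = 1, so uninformative rows can never become hits.

4. **FDR.** Benjamini–Hochberg across all hairpins of a contrast within a
   cell line — targeting and control hairpins together, matching a volcano
   plot in which every dot is one shRNA on a single FDR axis.

The test's calibration is checked empirically, not assumed: under a global
null at the screen's own conditions (dispersion 0.05, n = 3 vs 3, 5,000
hairpins) the acceptance suite requires the fraction of p < 0.05 to lie
within ±0.02 of nominal. The maximum-sharing rule makes the test mildly
conservative rather than anti-conservative, which is the right failure
direction for a hit-calling screen.

## The two-step hit cascade

Gene-level selection uses fixed thresholds (all inequalities strict, as
cutoffs are conventionally drawn on a volcano):

| parameter | default | meaning |
|---|---|---|
| `lfc_max` | −1 | log2FC ceiling a supporting hairpin must undercut |
| `fdr_max` | 0.1 | FDR ceiling for support |
| `basemean_min` | 100 | abundance floor (baseMeanA, reference-arm mean) |
| `min_hairpins` | 2 | independent hairpins required per gene |
| `opposite_lfc_min` | +1 | log2FC floor defining an opposite-direction hairpin |
| `opposite_fdr_max` | 0.1 | FDR ceiling of the opposite-direction veto |
| `t0_quorum` | `min_hairpins` | supporting hairpins that must also pass the t0 filter |

**Primary step** (treated vs untreated): a gene is a hit when at least
`min_hairpins` of its hairpins pass all three supporting criteria and no
hairpin of the gene is a significant opposite-direction change. The veto is
stated without thresholds in screen practice; the symmetric reading —
mirrored cutoffs, log2FC > +1 at FDR < 0.1 — is the default here, and both
veto parameters are exposed. The veto's FDR ceiling is deliberately a
*separate* parameter (defaulting to `fdr_max`): if the two were welded
together, tightening `fdr_max` would simultaneously weaken the veto and
could enlarge the hit set, breaking the monotonicity a threshold dial should
have. With the veto decoupled, tightening any single parameter can only
shrink the hit set, and the property suite asserts exactly that.

**Secondary step** (treated vs t0): each supporting hairpin must also show
log2FC < −1 against the t = 0 reference — fold change only, no FDR or
abundance condition, since this step exists to remove a directional artifact
rather than to re-test significance. How many supporting hairpins must pass
is genuinely ambiguous ("the hit shRNAs should…" can be read as any or all);
the default requires the same quorum as the primary rule (`min_hairpins`),
keeping the gene-level evidence standard consistent across both steps, and
`t0_quorum` exposes `any` and `all` as alternatives.

Control genes (essential / non-essential spike-ins) are never callable hits.
Their role is diagnostic: `summarize_controls()` reports the median and IQR
of treated-vs-t0 log2FC per control class; in a healthy screen the
essential-control median sits well below the non-essential one.

**Intersection.** Hit sets from ≥ 2 cell lines are combined into the full
Venn partition of their union; the all-lines region is the screen's primary
output, since a sensitizer shared by genetically heterogeneous lines is the
strongest candidate.

## What the synthetic screen emulates — and what it does not

`simulate_screen()` draws counts
`K ~ NB(μ, α)` with
`μ = coverage · depth_s · 2^(L_g(arm) · e_h)`, where `L_g` is the gene's
true log2 effect (0 at t0; the essential effect at the untreated end; the
essential plus sensitizer effect at the treated end) and `e_h` is the
hairpin's effect penetrance. Defaults are the screened study's conditions:
535 targeting genes × 5 hairpins, 243 + 272 control hairpins, coverage 1000,
dispersion 0.05, n = 3 per arm, sensitizer and essential effects of −2 log2
units.

Where a value had to be chosen rather than taken from the screen design:

- **Hairpin activity.** Multipliers `a_h ~ lognormal(0, 0.3)` scale each
  hairpin's log2 effect, and 20% of hairpins are inert (`e_h = 0`). Partial
  and failed knockdown are the reason the ≥ 2-hairpin rule exists; without
  them every hairpin of a planted gene would pass and the rule would be
  untestable. The multipliers act on the effect exponent, not on baseline
  abundance, so baseMean stays near `coverage` and the abundance floor is
  exercised at a known scale.
- **Depth factors.** `lognormal(0, 0.2)` per sample — realistic library-size
  spread that makes size-factor normalization consequential.
- **t0 replicates.** The reference is one arm with the same number of
  replicate samples as the end arms, so the treated-vs-t0 contrast has
  within-arm variance to estimate.
- **Control gene grouping.** Control hairpins are grouped into pseudo-genes
  of up to 5; only the hairpin-level totals matter, as controls are never
  called.

The generator reproduces the *count-level* structure the analysis assumes —
NB noise, depth variation, hairpin heterogeneity, essentiality dropout,
treatment-specific depletion — and nothing mechanistic: no infection
bottlenecks, PCR jackpotting, barcode swapping, or cell-cycle biology.
Passing recovery tests therefore demonstrates that the pipeline correctly
inverts its own generative assumptions at screen scale; it cannot
demonstrate robustness to artifacts real screens may contain that the model
omits. One such composition effect is visible even inside the model: if
depleted hairpins make up a large fraction of the library (as happens in a
toy library where essential controls dominate), median-of-ratios
normalization shifts apparent fold changes of flat hairpins — the test
suite probes control separation at the realistic library composition for
this reason.

## Numerical and design notes

- The statistical engine is named only by what it computes; the classic
  screen-analysis tool this recipe follows left its exact test and
  dispersion-sharing mode unstated, so this package fixes a concrete,
  oracle-checkable choice (ratio-scale median; MoM + maximum trend sharing;
  Wald rather than a conditioned exact test) and documents it as its own.
- Whether baseMeanA denotes the reference ("A") arm's mean is a convention;
  here it always does (untreated for the primary contrast, t0 for the
  secondary).
- Canonical orderings (hairpins by gene then id, samples by line, arm,
  replicate) make every output byte-reproducible under a fixed seed;
  re-running an identical configuration reproduces all files identically.
- BH adjustment is delegated to `stats::p.adjust` behind a validating
  wrapper, and is verified against a brute-force step-up oracle in the test
  suite, as are size factors (independent median-of-ratios oracle, plus a
  cross-check against `DESeq2::estimateSizeFactorsForMatrix`) and the full
  hit cascade (literal rule enumeration).
- Problem sizes in the test and acceptance suites: full-library three-line
  studies (3,190 hairpins × 9 samples) over 10 seeds for recovery, 20
  full-library single-line null screens, and 10 × 5,000-hairpin global-null
  calibration runs — comfortably desk-scale, a few seconds in total.

## Limitations

- Two-group contrasts only; no GLM designs, covariates, or shrunken fold
  changes.
- The Wald test relies on large-count normality; at baseMean far below the
  100-count calling floor its p-values are approximate (such hairpins cannot
  become hits, but they do enter the BH pool).
- Hit calling is threshold-based by design; rank-aggregation alternatives
  (RSA, α-RRA) are out of scope.
- The simulator's ground truth is gene-level with independent hairpin
  penetrance; correlated hairpin failures (e.g. shared seed sequences) are
  not modeled.
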