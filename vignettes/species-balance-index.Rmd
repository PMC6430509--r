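---
title: "Deriving a soil bacterial species balance index of crop productivity"
author: "soilSBI"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Deriving a soil bacterial species balance index of crop productivity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(soilSBI)
```

## The problem

Alpha-diversity summaries of a soil microbiome (Shannon entropy, Pielou
evenness, Chao1 richness) compress thousands of amplicon sequence
variants (ASVs) into one number and, in practice, often correlate poorly
with crop performance. soilSBI implements an alternative: identify the
*specific* ASVs whose abundances move with the part of yield that the
environment does not explain, and summarize them as a single supervised
log-ratio — a **species balance index** (SBI). The package covers the
whole derivation for a potato field study design: weather indices, soil
balance coordinates, ordinary least-squares detrending of yield,
a per-ASV correlation screen, the index itself, and a redundancy
analysis for interpreting the index against the environment.

Because ASV counts are compositional (a sequencing run fixes the total),
all microbiome arithmetic happens in Aitchison geometry: proportions are
analysed through log-ratios, never through raw counts.

## Log-ratio machinery

For a composition $x$ with $D$ strictly positive parts closed to 1:

* **clr** (centred log-ratio): $\mathrm{clr}_k = \ln(x_k / g(x))$ with
  $g$ the geometric mean over all parts. Rows sum to 0, and the
  transform is invariant to the overall scale of the input.
* **ilr balance** for disjoint part subsets $R$ (numerator, $r$ parts)
  and $S$ (denominator, $s$ parts):
  $$b = \sqrt{\frac{rs}{r+s}}\,\ln\frac{g(x_R)}{g(x_S)}.$$
  The square-root coefficient makes a full set of $D-1$ balances from a
  strictly bifurcating partition an orthonormal basis, so Euclidean
  distances among ilr coordinates equal clr-space (Aitchison) distances
  — a property the test suite checks against a brute-force oracle.
  A balance is positive when the numerator subset dominates; labels are
  written `[denominator | numerator]`.

The five-part soil composition {Sand, Silt, Clay, C, N} uses the fixed
partition `[Clay,Silt,Sand | N,C]`, `[Clay | Silt,Sand]`,
`[Silt | Sand]`, `[N | C]`: organics split from minerals first, then the
mineral subset by cohesiveness and grain size, then nitrogen against
carbon. Geometric means are always evaluated in log space so long part
lists cannot under- or overflow.

**Zero replacement.** Log-ratios need strictly positive parts, but an
ASV table is mostly zeros. `imputeZeros()` uses a deterministic
multiplicative count-zero replacement: within each sample, every zero
becomes $\delta = 0.65 \times$ (the sample's smallest non-zero
proportion) and the non-zero parts shrink by a common factor so the row
re-closes to 1. This preserves all ratios among observed parts exactly
and keeps every replacement strictly below anything actually observed.
The 0.65 fraction is exposed (`deltaFrac`); any fixed multiplicative
scheme shifts SBI values slightly, which is why the fraction is a
configuration knob rather than a constant.

## Weather indices

Three per-field indices are computed from daily records:

| Index | Definition | Unit |
|-------|------------|------|
| PPT | $\sum_i Rd_i$ (daily rainfall) | mm |
| SDI | $-\sum_i P_i \ln P_i / \ln n$, $P_i = Rd_i/\mathrm{PPT}$ | — |
| GDD | $\sum_i Tm_i \cdot [Tm_i \ge 7]$ | °C·day |

SDI uses the convention $0\ln 0 = 0$; it equals 1 for perfectly even
rain and 0 when all rain falls on one day, and is *undefined* (an error,
not 0) for a dry period. GDD is implemented literally as the source
formula prints it — days at or above the 7 °C base contribute their
**full** mean temperature, not the excess above the base. The textbook
variant $\sum (Tm_i - 7)^+$ is available via `conventional = TRUE` but
is off by default, because the literal formula is the one stated. The
accumulation window defaults to the full series supplied per field and
can be restricted by a start/end date (`window`), since no canonical
window is defined for this design.

## Detrending yield

Yield (t/ha) is regressed by OLS on eight standardized predictors: the
four soil balances, pH (the water-measured value, where both water and
CaCl$_2$ measurements exist), PPT, SDI and GDD. Standardization centres
each column and scales by the $n-1$ sample standard deviation, so
slopes are t/ha per predictor SD; 95% confidence intervals come from
the t distribution on $n-p-1$ degrees of freedom. The **residual
yield** — observed minus fitted — is the screening response downstream.
No field random effect is modelled (the design it emulates used a plain
regression); field-level clustering of the weather predictors is a
known limitation, noted below. Year and cultivar class are likewise not
included by default.

## The screen and the index

1. **Prevalence filter**: keep ASVs observed in at least 2 samples
   (the "contingency of 2" rule, read as presence in $\ge 2$ samples —
   the usual contingency-filter idiom; the threshold is configurable).
2. **Correlation screen**: Pearson correlation (Spearman available)
   between each ASV's clr values and residual yield; two-sided p from
   $t = r\sqrt{(n-2)/(1-r^2)}$ on $n-2$ df. Constant clr columns are
   flagged neutral with a warning and can never be selected.
3. **Selection**: raw $p < 0.05$, split by the sign of $r$. No
   multiple-testing correction by default — the procedure is a
   deliberately liberal one-pass screen (BH adjustment is available but
   off, to match the procedure being emulated).
4. **Index**: with positive set $R$ ($r$ ASVs) and negative set $S$
   ($s$ ASVs), per sample
   $$\mathrm{SBI} = \sqrt{\frac{rs}{r+s}}\,
     \ln\frac{g(\text{positive-set proportions})}
             {g(\text{negative-set proportions})},$$
   computed on the zero-imputed closed proportions (the clr values are
   used for the screen only). The orthonormal coefficient is included
   by default because the index is presented as a balance; it is a
   monotone rescaling, so every correlation involving the index is
   unaffected, and `normalized = FALSE` gives the plain log-ratio.

**Selection bias, by design.** The index is built from ASVs chosen for
their in-sample correlation with residual yield, so its in-sample
correlation with residual yield is optimistically inflated — even under
a pure null the screen picks ~5% of ASVs and the resulting index still
correlates positively in-sample. The test suite demonstrates both this
inflation and its flip side: sets selected on one null dataset
transferred to a fresh draw correlate near zero. Out-of-sample
validation is the user's responsibility; the package deliberately
reproduces the one-pass in-sample procedure.

## Alpha diversity and the comparison

Shannon entropy (natural log, consistent with the log-ratio machinery;
other bases via `base`), Pielou evenness $H/\ln S$, and Chao1
($S + F_1^2/2F_2$, bias-corrected $S + F_1(F_1-1)/(2(F_2+1))$ when no
doubletons exist) are computed on raw, unrarefied counts — no
rarefaction is performed anywhere. `correlateIndices()` puts the three
indices and the SBI side by side against raw and residual yield.

## Redundancy analysis

`fitRda()` regresses the (column-centred) clr table on the standardized
predictors and eigen-decomposes the fitted-value covariance
(constrained axes) and residual covariance (unconstrained axes).
Scaling 1 is reported: site scores $UD$ (inter-sample distances in the
fitted space preserved), species scores as eigenvector loadings, biplot
scores as predictor correlations with the axes. Axis signs are fixed by
forcing the largest-magnitude species loading positive on each axis, so
runs are reproducible; eigenvalues below $10^{-10}$ of the largest are
dropped as numerically null. `projectIndex()` fits a second-degree
polynomial trend surface of the SBI over the first two axes (simple,
deterministic, adequate for contour rendering); the surface is honest
interpolation of in-sample structure, not a model of new sites.

## The synthetic field study

`simulateDataset()` generates the complete input bundle under known
ground truth. Its defaults *are* the study conditions the package
targets, and they stay fixed:

* 13 fields × 4 plots with one plot lost → 51 samples; 2000 ASVs;
  multinomial counts at mean depth 18 000 (sd 8%).
* Soil textures drawn per field around sand / loamy-sand / sandy-loam /
  loam centroids (sand-dominated, as in the emulated production area),
  jittered on the log-ratio scale within field; C 1.5–2.8%, N ≈ C/13,
  pH 4.6–6.2.
* One gamma-rainfall daily series per field (shape 0.2–0.5, mean 2–4
  mm/day over 120 days) and a seasonal temperature curve; plots within
  a field share their weather, as in the real design.
* Yield = 38 − 4·`[Clay | Silt,Sand]` − 3·`[Silt | Sand]` + $m$ +
  N(0, 3²) t/ha, where $m \sim$ N(0, 5²) is a latent **microbial yield
  component**. The texture slopes match the negative texture effects
  the design emulates; weather, pH, `[N | C]` and the organic balance
  carry no true effect.
* 30 positive and 20 negative planted ASVs shift their log-abundance by
  ±1.2 per SD of $m$ (within-sample log noise 0.8, baseline
  log-abundance sd 1.5). Planted baselines are folded to the upper half
  of the abundance distribution: an effect planted in an ASV whose
  expected count at this depth is ≈ 0 is unrecoverable by *any* screen
  and would not emulate the mechanism of interest. The effect size is a
  design-stage power choice: it puts the per-ASV screen correlation
  near 0.5 so that planted recovery is reliable at $n = 51$,
  $\alpha = 0.05$ across seeds rather than at lucky ones.

What the generator does **not** emulate: spatial autocorrelation within
fields, phylogenetic correlation among ASVs (taxonomy is assigned
independently of the planted sets), overdispersion beyond the
log-normal–multinomial hierarchy, year effects, and any direct
microbiome response to soil or weather (so the RDA's constrained
fraction on synthetic data is modest by construction). Passing tests
therefore certify the statistical machinery and the recovery of planted
structure — not that real soils behave this way.

## Problem sizes and numerical conventions

The test suite runs the full 51 × 2000 pipeline (a few seconds), 500
Monte-Carlo replicates for CI coverage, 100 random compositions for the
isometry oracle, and a 51 × 50 response slice for the RDA oracle —
sizes chosen to make every check exact or tightly toleranced while
keeping the suite quick. Closure is validated at 1e-9 relative
tolerance; isometry and RDA oracles at 1e-8; hand-evaluated balance
values at 1e-6. Errors are classed conditions
(e.g. `zeroOrNegativePartError`, `sbiUndefinedError`) so callers can
distinguish failure modes; an empty selection set raises
`sbiUndefinedError` *after* the correlation table has been written.

## Known limitations

* The screen is univariate and uncorrected; it controls nothing beyond
  the per-ASV level and is not a variable-selection method.
* Field-level predictors (weather) with 13 distinct values among 51
  samples leave the detrending step exposed to chance absorption of
  sample-level signal; a mixed model would be the natural extension.
* Chao1 depends on singleton/doubleton counts and is therefore
  sensitive to denoising pipelines that remove singletons.
* The trend surface is quadratic; genuinely multimodal index fields
  over the ordination plane would be smoothed away.
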