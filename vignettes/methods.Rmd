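---
title: "Three-layer miRNA-mRNA-protein integration: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Three-layer miRNA-mRNA-protein integration: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

loopomics reconstructs, as a reusable pipeline, an integrative analysis of a
drug-sensitive vs drug-resistant cell-line pair profiled on three platforms:
two-color 44K-class gene expression arrays, single-channel miRNA arrays, and a
725-antibody protein array, each with 3 biological and 4 technical replicates
per condition and a dye-swap scheme on the two-color platforms. The end point
is the enumeration of (miRNA, mRNA, protein) triplets over a predicted
target relation, and their classification into coherent and incoherent
regulatory loops.

## Preprocessing models

**Low-signal filter (mRNA).** A probe is removed when its foreground falls
below its local background in strictly more than 60% of the arrays where it is
present. The denominator counts arrays, and for two-color arrays the
channel-mean foreground and background are compared; the boundary value (exactly
60%) is kept. Both choices are this package's reading of the rule; the
threshold is a `max_fraction` argument.

**Normexp background correction (protein).** The observed foreground is
modelled as normal background plus exponentially distributed signal,
$X = B + S$, $B \sim N(\mu, \sigma^2)$, $S \sim \mathrm{Exp}(\alpha)$, and the
corrected intensity is $E[S \mid X = x]$ plus an offset (default 16) that damps
low-intensity variance. The conditional expectation is evaluated with limma's
closed form; parameter estimation is deliberately simple method-of-moments —
$\mu,\sigma$ from the measured local background, $\alpha$ from the mean of
foreground minus background — because the pipeline needs a stable estimate per
array, not maximum-likelihood precision.

**Lowess normalization (mRNA).** Log-ratios $M$ are corrected by subtracting a
robust lowess fit of $M$ on the mean log-intensity $A$ (span 0.3, three
robustness iterations; pairs with a missing value pass through unchanged). The
span is a tuning constant with no canonical value; 0.3 follows common
two-color practice.

**Rank-invariant normalization (protein).** Features whose within-channel
intensity ranks agree (relative rank difference at or below 0.05, iterated to a
fixed point) form the invariant set through which the normalization curve is
fitted. Two refinements matter on arrays where a large fraction of features is
truly differential:

* Rank extremes (top and bottom 5% of the average rank) are excluded before
  selection, because rank invariance is trivially satisfied there and strongly
  asymmetric features would otherwise enter the set.
* When an array *set* with a balanced dye swap is normalized
  (`process_two_color()`), one curve is fitted to the pooled invariant sets of
  all arrays in raw Cy5/Cy3 orientation. Differential features displace the
  ranks of null features in one channel, which biases per-array selection in a
  direction that flips with the dye swap; pooling cancels that selection
  artifact while true dye bias — the same Cy5/Cy3 artifact on every array —
  survives and is removed. Per-array curves are available through
  `rank_invariant_normalize()` itself, which is appropriate when few features
  change.

**Variance-stabilizing transform (miRNA).** Single-channel intensities are
calibrated per sample by an affine map matching the quartiles of a virtual
reference sample, then passed through the generalized log
$h(y) = \log_2\!\big((y + \sqrt{y^2 + c^2})/2\big)$, which is $\log_2 y$ for
$y \gg c$. Under the additive + multiplicative error model
$y = \mu e^{\eta} + \varepsilon$ the transformed variance is flat when
$c = \sigma_\varepsilon / \sigma_\eta$; both noise scales are estimated from
technical-replicate residuals (low-intensity quartile for the additive part,
top quartile for the multiplicative part). This is a deliberately simplified
stabilizer — a calibrated arsinh, not a full maximum-likelihood fit — because
the pipeline needs variance stabilization, not bit-compatibility with any
particular implementation.

**Replicate collapse.** Dye-swapped log-ratios are sign-flipped to a common
orientation (positive = resistant over sensitive; the stored `dye` annotation
is the dye of the resistant channel) and technical replicates are averaged,
missing-aware, to one column per biological replicate. Collapsing before the
model fit, rather than modelling technical replicates inside it, is this
package's convention.

## Differential expression

Each layer is tested with a two-group per-feature linear fit followed by
empirical-Bayes variance moderation. For intensity layouts the fit is the
pooled two-sample comparison (`logFC` = resistant − sensitive mean, pooled
variance, $n_1+n_2-2$ df, complete-case per feature); for log-ratio layouts it
is the one-sample analogue ($1/n$ variance factor, $n-1$ df). The prior
$(d_0, s_0^2)$ is estimated by matching the mean and variance of $\log s^2$ to
scaled-F moments (inverse-trigamma solved by Newton iteration, tolerance
$10^{-8}$); equal variances give $d_0 = \infty$. The moderated statistic uses
$\tilde s^2 = (d_0 s_0^2 + d s^2)/(d_0 + d)$ with a $t_{d_0+d}$ reference, and
an explicit $d_0 = 0$ override reproduces the ordinary t exactly. Multiple
testing is controlled by Benjamini-Hochberg adjustment (features failing the
two-per-group rule are excluded from the tested count).

Selection thresholds are layer-specific and inclusive at the boundary:
mRNA FDR ≤ 0.01 with |logFC| ≥ 1; miRNA and protein FDR ≤ 0.1 with no
fold-change gate. One consequence worth knowing: a fold-change gate placed
exactly at the effect size of interest halves recall, because the estimate is
symmetric around the true value — features truly at |logFC| = 1 are called
only about half the time under the mRNA rule. Effects comfortably above the
gate (e.g. 1.5) are essentially always called at these noise levels.

## Integration and loop taxonomy

Differentially expressed miRNAs are paired with differentially expressed
predicted targets (mirSVR-style scores; kept when score ≤ −0.1 by default, the
cutoff being configurable since no canonical value exists). The default
relation label compares signs of the log fold changes — `anti` when opposite —
because with three biological replicates per condition per-pair correlations
are unstable; a correlation mode (Pearson $r \le -0.7$ across matched
replicate profiles, at least four) is provided for larger designs.

Genes altered at both the mRNA and protein level form the core table, with a
concordance flag comparing the two signs. Loops are enumerated over every
predicted (miRNA, gene) pair whose miRNA, mRNA and protein are all
differential, and classified from the sign triple
$(s_{\text{miR}}, s_{\text{mRNA}}, s_{\text{prot}})$:

| pattern | type | coherence | reading |
|---|---|---|---|
| mRNA opposite, protein follows mRNA | A | coherent | degradation propagates to the protein |
| mRNA co-expressed, protein opposite | B | incoherent | translational repression without decay |
| all three co-directional | C | incoherent | expression does not support miRNA action |
| mRNA opposite, protein back at miRNA sign | unclassified | none | taxonomy defines no panel for it |

The eight sign patterns partition exactly 2/2/2/2 and negating all three signs
preserves the type. The fourth pattern is left unclassified rather than forced
into type C because the taxonomy defines only three panels; type A is required
to have the protein concordant with the mRNA, following the degradation
schematic. miRNA genomic clusters are single-linkage groups per chromosome
with consecutive gaps strictly below 1000 kb.

## The synthetic generator

`sim_config()` defaults are the study design: 10,000 gene probes (platform
scale stand-in for 44K), 800 miRNAs, a 725-antibody panel whose feature ids
are gene ids, 3 biological × 4 technical replicates with dye swaps on even
technical replicates, 47 differential miRNAs, 336 differential proteins,
about 700 differential genes, planted loops 38/34/28 by type, |logFC| = 1.5,
and total Gaussian log-scale noise sd 0.25 split equally between biological
and technical components (chosen for analyzability; the studies report no
noise model). Channels are built as truncated-normal background
(μ = 100, σ = 20) plus an exponential per-feature brightness (mean 500,
floored at 20% of the mean so that expressed features sit clear of the
additive background) scaled by $2^{\text{expression}}$. The brightness is
drawn once per feature so the marginal foreground distribution is
normal + exponential — what normexp estimation expects — while ratios are
governed by the stated Gaussian noise.

Biological-replicate effects are drawn per condition; a planted loop's mRNA
and protein inherit the miRNA's replicate effects with the sign of the planted
relation, so anti-correlated pairs really are anti-correlated across
replicates. Planted low-signal probes (5% of null genes) are constructed
below the measured background on every array. Decoy target-map edges emulate
predicted targets that are not differentially expressed: they avoid planted
pairs and never connect a differential miRNA to a gene altered at both
layers, since such an edge would constitute a real, if unplanted, triplet.

What the generator does *not* emulate: spatial artifacts, print-tip effects,
cross-hybridization, antibody cross-reactivity, probe-level sequence effects,
and heavy-tailed or intensity-correlated noise beyond the additive background.
Passing recovery tests therefore demonstrates the pipeline's logic and
calibration under the stated noise model, not robustness to every artifact of
real arrays.

## Numerical choices and degenerate inputs

Lowess uses three robustness iterations throughout; curves are evaluated by
linear interpolation with flat extrapolation beyond the fitted range, and ties
in the predictor are averaged. BH ties are handled by stable sorting. Written
tables render doubles at `%.17g`, so write → read round trips are numerically
exact. Degenerate inputs error early and by name: duplicate feature ids,
samples missing from metadata, non-numeric scores (with the row number),
all-zero intensity samples, rank-invariant sets smaller than 10 (with advice
to fall back to lowess), fewer than 10 finite M/A pairs, zero signs in the
loop classifier, and infeasible planted-loop counts before any output is
generated.

## Problem sizes used in the checks

The test suite exercises the full default scale end to end (three seeds of
the 10,000-gene scenario), an FDR-calibration simulation of 2,000 features ×
3 vs 3 × 200 replicates under the global null, exhaustive hypergeometric
enumeration up to universe size 12, and brute-force BH enumeration on 1,000
short p-vectors. These sizes keep every property estimate stable at
single-CPU scale while remaining faithful to the study's design parameters.
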