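---
title: "Sorting UV spectral fingerprints with ELECTRE TRI-B"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Sorting UV spectral fingerprints with ELECTRE TRI-B}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bsfs)
```

## The screening problem

A medication dissolved in solution absorbs UV light in a profile that is
nearly unique to its active compound. A *baseline spectral fingerprint*
(BSF) samples that profile at a few discrete wavelengths — for Praziquantel
at 240, 250, 260 and 270 nm, the range where inexpensive, durable UV LEDs
exist — giving a short absorbance vector on the saturating 0 (transparent)
to 2 (opaque) instrument scale. A field sample whose fingerprint departs
from the authentic profile is suspect.

The complication is preparation variability. The intended field procedure
(crush the pill with mortar and pestle, dissolve a fixed mass in a fixed
volume, filter through a gauze pad, dilute to an absorbance near 1 at the
lowest wavelength) does not achieve reproducible concentrations, so two
authentic preparations will not produce identical fingerprints. The method
therefore compares a sample not against a point reference but against an
empirically learned *band*, using an outranking sort that is explicit about
borderline evidence.

## The sorting model

### Category system

Replicate authentic preparations — the shipped Praziquantel reference uses
15 — define the authentic band CAT-A: at each wavelength the band runs from
the minimum to the maximum absorbance observed across replicates
(`build_category_system()`, raw min/max, no trimming or quantiles; the
replicates are meant to span preparation variability, not to support a
statistical estimate). Samples below the band fall in CAT-B, above in
CAT-C, and the three categories are ordered on the absorbance axis.

An optional `widen_fraction` implements the intrinsic-range convention of
placing the lower boundary 10% below the observed minimum and the upper
10% above the maximum (capped at 2). The default is 0 — the learned band is
used as observed — because widening trades sensitivity to the cut level
against a wider acceptance region, and the shipped reference data perform
perfectly without it.

### Outranking machinery

For sample $a$ and boundary profile $b$ with per-criterion performances
$g_j$, each wavelength contributes a partial concordance

$$c_j(a,b) = \begin{cases}
1 & g_j(a) \ge g_j(b) - q \\
0 & g_j(a) \le g_j(b) - p \\
\frac{g_j(a) - (g_j(b) - p)}{p - q} & \text{otherwise}
\end{cases}$$

and a partial discordance that rises from 0 at deficit $p$ to 1 at deficit
$v$. Global concordance is the weighted sum $C(a,b) = \sum_j w_j c_j$, and
the credibility index discounts it by every discordance exceeding it:

$$\sigma(a,b) = C(a,b) \prod_{j:\, d_j > C} \frac{1 - d_j(a,b)}{1 - C(a,b)}.$$

$a$ outranks $b$ when $\sigma(a,b) \ge \lambda$ (non-strict, so
$\lambda = 1$ remains usable). The pessimistic assignment scans profiles
downward and places the sample in the highest category whose lower profile
it outranks; the optimistic assignment scans upward and places it just
below the first profile that strictly outranks it.

The verdict rule is deliberately asymmetric: **Authentic** requires both
procedures to agree on CAT-A *and* no indifference with either boundary.
Disagreement between the procedures (incomparability, typically caused by
a veto in both directions) and indifference (mutual outranking, a sample
hugging a boundary) both map to **LQ/C** — in an authenticity screen, a
sample that cannot be placed cleanly in the authentic band is treated as
suspect. This indifference rule is what produces the known loss of one
borderline authentic sample at low cut levels (below), and it takes
precedence over a clean-looking CAT-A/CAT-A agreement.

### Parameters

| Parameter | Meaning | Default | Why |
|---|---|---|---|
| $q$ (AU) | indifference threshold | 0 | min/max boundaries already absorb replicate spread |
| $p$ (AU) | preference threshold | 0.05 | calibrated by grid search on the labelled 25-sample set |
| $v$ (AU) | veto threshold | 0.10 | calibrated jointly with $p$; one deficit $\ge v$ bars authenticity |
| $\lambda$ | credibility cut | 0.85 | user-set operating point: substantive evidence without being unattainable |
| $w_j$ | criterion weights | $1/k$ | no wavelength is privileged; exposed for users who disagree |

$p$ and $v$ are scalars applied to every wavelength and both boundaries.
Calibration (`calibrate_thresholds()`) exhaustively scores every admissible
$(p, v)$ pair — default grid $p \in \{0, 0.01, \ldots, 0.20\}$,
$v \in \{0.01, \ldots, 0.30\}$, $v > p$ — by the unweighted count of false
positives plus false negatives, breaking ties toward the smaller $v$ then
the smaller $p$ (the strictest admissible system). An `fp_weight` argument
lets users who fear false positives more re-weight the objective. $\lambda$
is intentionally *not* calibrated; `lambda_sweep()` plus
`find_breakpoints()` map its constant-error bands instead.

## Worked behaviour on the reference data

```{r reference}
system     <- praziquantel_data("boundaries")
thresholds <- praziquantel_data("thresholds")
validation <- praziquantel_data("validation_set")
confusion(classify_batch(validation, system, thresholds))
```

All 50 blinded samples sort correctly at $\lambda = 0.85$. The sensitivity
sweep shows the operating bands:

```{r sweep}
find_breakpoints(lambda_sweep(validation, system, thresholds,
                              seq(0.7, 1, by = 0.01)))
```

One authentic sample sits barely above the lower boundary (its
$\sigma(a, b_1) = 1$ but $\sigma(b_1, a) = 0.80$): for cuts at or below
0.80 the two outrank each other, the sample is indifferent to the boundary,
and it is rejected. With the boundaries as shipped (printed to two
decimals) the sample outranks the lower boundary with credibility exactly
1, so no rejection occurs as $\lambda \to 1$; a high-cut rejection would
require boundary values recorded at higher precision than the reference
tables provide, and this package does not attempt to reconstruct them.

Two proxy low-quality rows (authentic drug mixed with a second medication
of similar chemistry) deserve comment. At the default cut they are rejected
as *incomparable*: a veto blocks each direction of outranking at one or the
other boundary, and the pessimistic and optimistic procedures disagree
(CAT-B vs CAT-A). At cut levels between roughly 0.16 and 0.72, however,
their credibility of outranking the lower boundary (0.72) clears the cut
while the reverse credibility (0.16) does not, and they are *accepted* —
false positives. Cut levels that low demand less than three-quarters of the
weighted evidence and are outside the method's sensible operating range
(outranking is only meaningful above 0.5, and the engine warns there), but
users lowering $\lambda$ should know the false-positive risk is real; the
sweep makes it visible.

## Synthetic data

The generator emulates the laboratory workflow, not UV physics:

- `generate_authentic()` draws fingerprints around a mean profile under a
  uniform half-range (default) or truncated-normal model, clipped to
  [0, 2]. The shipped defaults use the Praziquantel reference mean profile
  with half-ranges equal to the distance from the mean to the published
  lower boundary (0.26, 0.18, 0.17, 0.14 AU) — the uniform model whose
  extremes reproduce the published band, so min/max boundary learning is
  exercised faithfully.
- `generate_contaminant()` draws smooth random curves — monotone
  exponential decays (salt- and sugar-like), saturating near-opaque curves,
  single Gaussian peaks, and mixtures — spanning the qualitative shapes of
  the physical adulterants used in the reference study. It is labelled
  synthetic throughout: no chromophore or solvent physics is modelled.
- `generate_mixture()` forms convex combinations, the analogue of the
  proxy low-quality samples.

Everything is a pure function of (spec, n, seed), with the caller's RNG
state untouched. What passing the end-to-end recovery test shows is that
the pipeline — learn boundaries, calibrate, classify held-out data —
separates clean in-band samples from beyond-veto contaminants with zero
error; it does not show performance on real adulterants whose spectra fall
*near* the band, which only labelled laboratory data can establish.

## Numerical conventions

- Equality conventions: concordance grants full support at deficit exactly
  $q$; discordance reaches a full veto at deficit exactly $v$ (continuity
  of the interpolants). With $p = q$ the concordance degenerates to a step.
- $\sigma \ge \lambda$ is compared in exact floating arithmetic, no
  epsilon, for reproducibility — users probing knife-edge cuts (e.g.
  $\lambda$ equal to a computed credibility) should expect float rounding
  to decide, as it does at the 0.72 band edge above.
- Normalised weights can sum to $1 \pm$ a few ulp; concordance and
  credibility are clamped to $[0, 1]$.
- Absorbances outside $[0, 2]$ are rejected in strict mode (default) or
  clipped with a warning in lenient mode, mirroring instrument saturation.
  Reference table values are used exactly as printed, with no internal
  rounding.
- At $\lambda = 0$ every credibility clears the cut, all relations are
  indifferent, and *everything* is rejected; the sweep reports this
  degenerate point as its own band rather than hiding it.

## Scope and limitations

- Exactly two boundary profiles and three categories; a separate
  "low-quality" band between CAT-B and CAT-A is a possible extension but
  out of scope, as are per-wavelength thresholds beyond the scalar
  broadcast.
- No concentration estimation, Beer–Lambert quantification, or spectral
  deconvolution of mixtures — the verdict is categorical.
- Boundaries learned from few replicates understate field variability
  (`build_category_system()` warns below 5); authentic samples prepared
  outside the replicate band's spread will be rejected.
- Test and example problem sizes (1000-instance oracle comparisons,
  200-replicate synthetic boundary learning, 50-sample sweeps at 0.01
  resolution) were chosen to exercise the properties at desk scale; the
  engine itself is a handful of arithmetic operations per sample and
  classifies large batches trivially.
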