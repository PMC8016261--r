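---
title: "Measuring heterochromatin-mark enrichment at XIST RNA clouds"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring heterochromatin-mark enrichment at XIST RNA clouds}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(xistscore)
```

## The measurement problem

When the long noncoding RNA XIST is expressed — from its native X-linked
locus or from an inducible transgene — it coats chromatin in *cis* and
nucleates a visible "cloud" detectable by RNA FISH. A central question is
how strongly heterochromatin marks and factors (H3K27me3, ubH2A, MacroH2A,
SMCHD1) concentrate at that cloud relative to the rest of the nucleus, and
how that enrichment changes across constructs, induction times and
inhibitor treatments. Judging such enrichment by eye is subject to operator
bias and hides the substantial cell-to-cell heterogeneity that these
populations show.

`xistscore` quantifies the enrichment per cell from three-channel IF-FISH
images: blue = DAPI (nuclear DNA), green = RNA FISH (the XIST cloud),
red = immunofluorescence for the mark under study.

## The per-cell statistic

For one nucleus, a straight measurement chord is placed through the point
of peak RNA signal, spanning the maximal nuclear width that does not
intersect a nucleolar territory, and the three channels are sampled at
every pixel along it. Chord pixels are then classified by their green
intensity *relative to the chord's green maximum* \(g_{\max}\):

* **RNA-positive**: \(g > 0.5\, g_{\max}\);
* **RNA-negative**: \(g < 0.25\, g_{\max}\);
* **excluded**: everything in between (the ambiguous shoulder of the
  cloud), which keeps the two groups cleanly delineated. Inequalities are
  strict, so a pixel exactly at a threshold is excluded.

The cell's enrichment is the z-score

\[
z \;=\; \frac{\operatorname{median}\!\left(r_{+}\right) -
              \overline{r_{-}}}{\operatorname{SD}\!\left(r_{-}\right)},
\]

where \(r_{+}\) and \(r_{-}\) are the red (mark) intensities over the
RNA-positive and RNA-negative pixels and the SD uses the sample (\(n-1\))
denominator. A z of 1 means the median mark intensity at the cloud sits one
nuclear-background standard deviation above the nuclear average; under a
Gaussian reference, `z_to_percentile()` converts this to a nuclear-intensity
percentile (z = 2.59 is roughly the 99th percentile). The fraction of
chord pixels that are RNA-positive doubles as a relative cloud-size
estimate, and `classify_cloud_morphology()` calls the 2-D cloud *unified*
(one contiguous above-half-maximum region) or *punctate* (several).

Two definitional choices deserve a note, because the verbal description of
the statistic can be read either way:

* the numerator uses the **median** of the positive group — the robust
  summary that matches the "median intensity at the cloud" reading —
  while `mean_pos_red` is also reported for sensitivity checks;
* the denominator uses the SD of the **negative group only**, as the
  operationalisation of "variability across the nucleus"; the positive
  group's own spread never enters.

Both choices are fixed, documented here, and pinned by tests. The z-score
is exactly invariant under positive affine rescalings of the red channel
(gain/offset of the microscope) and the pixel labels are invariant under
positive rescaling of the green channel, so the statistic is comparable
across acquisition settings.

Degenerate inputs are classed errors, not numbers: an all-zero green
profile is a no-signal error, fewer than two negative pixels or a
zero-variance negative group with a real group difference is an
undefined-z error. The one deliberate special case: a perfectly flat red
channel (numerator and denominator both zero) scores z = 0, since a
constant mark is the textbook case of "no enrichment either way".

## Automated chord placement

The original measurement draws the chord by hand in ImageJ. To make the
step reproducible, `xistscore` automates it deterministically:

1. `segment_nucleus()`: Otsu threshold on the blue channel, largest
   connected component, holes filled (EBImage primitives).
2. `detect_nucleolus()`: the largest in-nucleus region below 50% (by
   default) of the median in-nucleus DAPI intensity, with a 25-pixel
   minimum area; an empty result is valid, and a known mask can be passed
   through unchanged, since nucleoli are often annotated by eye.
3. `find_xist_peak()`: the in-nucleus green maximum, ties broken by
   smallest row then smallest column.
4. `place_line()`: over a 1° grid of angles in \([0°, 180°)\), the chord
   through the peak is clipped to the nucleus; chords touching the
   nucleolus are discarded; the longest survivor wins, ties going to the
   smallest angle. Where several near-maximal chords exist a human
   operator's choice is unrecorded; the smallest-angle tie-break is this
   package's convention.
5. `extract_profile()`: the segment is rasterised by uniform parametric
   sampling with nearest-pixel rounding — one sample per step of the
   dominant axis, no interpolation, and exactly reversal-symmetric — and
   all three channels are read at those pixels.

Coordinates are 1-based (row, column) matrix indices throughout, endpoints
inclusive; a single chord is measured per cell.

## The synthetic-nucleus generator

Because the underlying microscopy images are not publicly deposited, every
stage is validated against a generator with known ground truth.
`nucleus_spec()` describes one scene: a DAPI disc (default radius 50 px,
matching a nucleus of measurable length ~100 px) with an optional dimmer
nucleolar disc (radius 10 px), an RNA cloud of radius 8 px (cloud diameter
~16 px, i.e. ~16% of the measured chord), and a red channel drawn i.i.d.
per pixel from \(N(\mu_b, \sigma_b)\) (default 60, 10 on the 8-bit scale)
with a shift of `effect_delta`\(\times \sigma_b\) inside the cloud
footprint. `effect_delta` is thus the ground truth the measured z
estimates; with Gaussian noise the positive-group median is an unbiased
estimator of the shifted mean, making the recovery target exact rather
than approximate. Punctate clouds are `n_foci` disjoint small discs on a
ring inside the cloud footprint.

Two rendering details are this package's own modelling choices:

* the green cloud carries a mild (10%) parabolic taper towards each focus
  rim, so the RNA signal has a well-defined interior maximum as real FISH
  clouds do — with a perfectly flat cloud, the deterministic peak
  tie-break would land on the cloud's tangent edge and the "maximal chord
  through the peak" would touch the cloud in a single pixel, a degenerate
  scene real images do not present. Every cloud pixel remains far above
  the 50% classification threshold, so labels and ground truth are
  unaffected;
* green and blue are rendered noiselessly by default (noise SDs and a
  Gaussian blur are available as knobs, default off), because the
  statistic under study lives in the red channel.

`population_spec()` scales this to an experiment: each of `n_cells`
(default 60, the typical population size per condition) draws its own true
effect from \(N(\texttt{delta\_mean}, \texttt{delta\_sd})\) with
`delta_sd = 1.7` z-units by default, the cell-to-cell heterogeneity scale
observed in strongly-enriching populations. All stochastic operations
require an explicit seed and restore the RNG state afterwards; identical
spec + seed reproduces scenes bit-identically.

What the generator does **not** emulate: point-spread functions, 3-D
stacks, chromatic aberration, uneven illumination, multi-nucleus fields,
or spatially correlated mark texture. Passing tests therefore demonstrate
the correctness and calibration of the *measurement chain*, not robustness
to every artefact of real microscopy.

## Population statistics

Per-cell z-scores are compared between a construct/treatment and its
control with a two-sided Mann-Whitney U test (`mann_whitney()`). For a
pooled size of at most 12 the p-value comes from exact enumeration of all
group assignments (midranks handle ties); beyond that the normal
approximation with tie and continuity correction is used. The crossover is
placed at 12 because that is as far as the approximation's worst-case
two-sided error (~0.016-0.03 against exact enumeration) remains
non-negligible while enumeration stays trivial; at realistic population
sizes (60 vs 60) the approximation agrees with a \(10^5\)-permutation
estimate to better than 0.005.

Families of comparisons use Bonferroni-adjusted thresholds,
`alpha / n_tests` exactly; the family size is a required, user-declared
input (a deletion-panel experiment with 48 comparisons uses thresholds
\(1.04\times10^{-3}\), \(2.08\times10^{-4}\), \(2.08\times10^{-5}\) for
\(\alpha\) = 0.05, 0.01, 0.001), and `assign_stars()` annotates
accordingly. Morphology proportions are compared with a two-sided Fisher
exact test (sum of hypergeometric probabilities no more probable than the
observed table); expression replicates with a two-sided Welch t-test. All
sidedness choices are two-sided, the conservative default where the
original convention is unstated.

`blind_dataset()` / `unblind()` support the blinded-scoring protocol:
identities (cell id, construct, mark, treatment) are replaced by opaque
seeded random codes, scoring proceeds on coded records only, and the key
restores identities after all measurements are collected.

## qPCR relative quantification

`delta_delta_ct()` implements the comparative-CT method: replicates are
averaged at the CT level, \(\Delta CT = \overline{CT}_{target} -
\overline{CT}_{reference}\) per sample, \(\Delta\Delta CT\) is the
**difference** of the test and control \(\Delta CT\)s, and
\(RQ = 2^{-\Delta\Delta CT}\). The difference form is the only one for
which equal expression yields RQ = 1 (printed descriptions of the method
occasionally typeset the combination of the two \(\Delta CT\)s as a
ratio; that form is inconsistent with \(RQ = 2^{-\Delta\Delta CT}\) and is
not used). RQ obeys \(RQ(a,b)\,RQ(b,a) = 1\) and is invariant to adding a
constant to all four mean CTs.

## Worked example

```{r example, eval = FALSE}
library(xistscore)

# a 60-cell "full-length construct" population with true enrichment
# 2.59 +/- 1.7, and a matched null population
full <- simulate_population(population_spec(
  "full", n_cells = 60, delta_mean = 2.59, delta_sd = 1.7, seed = 1))
null <- simulate_population(population_spec(
  "deleted", n_cells = 60, delta_mean = 0, delta_sd = 1.7, seed = 2))

scores <- rbind(score_cells(full), score_cells(null))
cmp <- compare_populations(
  scores, plan = list(list(test = "deleted", control = "full")),
  n_tests = 48)
cmp[, c("group_test", "group_control", "U", "p_value", "stars")]
```

The same chain runs from rendered images through
`extract_cell_profile()`, or end-to-end from a YAML/JSON configuration
through `run_pipeline()`, which writes the per-cell table, the comparison
table, and a manifest that records the configuration hash, seed and a
machine-readable reason for every skipped cell (scored + skipped always
equals the number of input cells).

## Problem sizes and numerical choices

The validation suite exercises the chain at sizes chosen to make
Monte-Carlo targets sharp: parameter recovery uses 200 synthetic cells per
effect level (the SE of the mean measured z is then well under 0.05), the
type-I-error check uses 500 replicate null experiments of two 60-cell
groups (99% binomial band 0.025-0.075 around 0.05), and oracle-equivalence
checks enumerate exhaustively where enumeration is exact: all group
assignments for pooled Mann-Whitney samples up to 12, all 2x2 tables with
total up to 40 for the Fisher test. Tolerances on from-definition oracle
comparisons are \(10^{-10}\)-\(10^{-12}\); invariance checks use
\(10^{-12}\), i.e. machine precision through the handful of floating-point
operations involved.

## Known limitations

* One chord per cell, 2-D only: no averaging over chord angles, no
  area-based or volumetric enrichment.
* The nucleolus detector is a deliberately simple intensity heuristic
  with a ground-truth bypass; heavily textured DAPI may need the bypass.
* No background subtraction or bleaching correction; the affine
  invariance of z makes global gain/offset harmless, but spatially varying
  background is not modelled.
* Bonferroni is the only multiple-testing scheme offered, matching the
  fixed-family design it supports; no FDR procedures.
* The generator's defaults (8-bit, isotropic pixels, geometry above) are
  asserted conventions, not inferred from data.
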