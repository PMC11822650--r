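---
title: "Quantifying reporter-based alpha-synuclein spread: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying reporter-based alpha-synuclein spread: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(synspread)
```

## The assay and its statistical model

Dual-reporter spread assays exploit P2A self-cleavage: one transcript yields
eGFP (retained by the transduced cell) and HA-tagged α-synuclein A53T
(transferable). Gating segmented cell bodies on the two reporters therefore
separates three populations — donors (eGFP⁺ ∧ HA⁺), recipients
(eGFP⁻ ∧ HA⁺) and untransduced cells (eGFP⁻ ∧ HA⁻) — over the
morphology-positive (NFH⁺) population. `synspread` treats a field of view
as a draw from a simple generative model: each of `n_cells` neurons is a
donor with probability `p_transduce` (default 0.6, the transduction
efficiency these cultures typically reach), otherwise a recipient with
probability `p_spread`. The two primary summary statistics are

- transduction efficiency = donors / all gated cells, and
- spread fraction = recipients / (recipients + untransduced), i.e.
  recipients over the eGFP-negative population,

the latter normalized to the control-condition mean when conditions are
compared. The denominator choice is configurable; recipients-over-eGFP⁻ is
the default because the eGFP-negative pool is the population actually at
risk of becoming a recipient.

A cell that gates eGFP⁺ ∧ HA⁻ is biologically unexpected under P2A
co-expression (it would mean reporter without cargo). Such cells are
labelled `AMBIGUOUS`, excluded from both denominators, and reported —
silently dropping them would hide segmentation or staining artefacts;
silently counting them would bias both ratios.

## The synthetic generator: what it emulates, and what it does not

All tests and the reproducibility script run on synthetic fields with known
per-cell ground truth. The generator emulates the *statistical* structure
of the assay, not its optics:

- somata are discs (mean radius 8 px, sd 1, clamped to mean ± 3 sd) with an
  error-function rim equivalent to a Gaussian-blurred hard disc (σ = 1 px),
  placed on a jittered grid that guarantees a minimum centre-to-centre
  separation (default 25 px). Grid placement is deterministic and O(n); it
  trades away the clustering of real cultures for a provable separation
  invariant.
- intensities are additive on a flat background (default 100 ADU) in a
  16-bit range: morphology and donor reporters at 1000 ADU, recipient HA at
  600 ADU, with lognormal per-cell expression variability (CV 0.1). The rim
  profile is truncated at radius + 3 px, so in noiseless images a
  recipient's eGFP pixels equal the background *exactly* while every donor
  soma pixel strictly exceeds it — the property the noiseless oracle tests
  rely on.
- noise is additive Gaussian read noise (optionally preceded by Poisson
  shot noise), clipped to the 16-bit range. Acquisition bit depth and
  exposure are declared defaults, not values inferred from any instrument.
- brain sections swap NFH for an mCherry knockdown reporter (expressed with
  probability `p_mcherry`, default 0.9) and carry a cortical/subcortical
  region layout plus a section footprint used for section-area QC.

The RNG draw order is fixed and documented (classes → placement → radii →
intensity jitter → pixel noise), with the spread draw taken for *every*
non-donor cell. That makes two things true by construction: an independent
script replaying the documented order reproduces the class assignment
exactly, and under a common seed the recipient set is nested as `p_spread`
grows — the basis of the monotonicity checks.

What passing tests on these fields does **not** show: robustness to uneven
illumination, overlapping or irregular somata, out-of-focus light,
staining heterogeneity or densely crossing neurites. The segmentation and
threshold machinery is exercised, not stress-tested against real-world
artefacts.

## Segmentation and intensity measurement

Cell bodies are detected with a local-mean adaptive threshold: a pixel is
foreground when it exceeds the mean of a `window × window` neighbourhood
(default 51 px, computed exactly via an integral image) by more than
`offset` ADU (default 10). Because the rule is relative to the local mean,
adding a constant to the whole channel cannot change the mask — an
invariance the tests assert. On noisy acquisitions the offset should sit at
roughly 3× the read-noise sd; the replication experiments use
`offset = 10 + 3 × noise_sd`. Components outside `[min_area, max_area]`
(defaults 50 px², ∞) are dropped; an optional distance-transform watershed
(EBImage) splits touching somata and is off by default. Labels are
renumbered 1..K in raster order of first pixel, so label identity is
reproducible. Manual masks drawn elsewhere are imported verbatim from TIFF
with provenance `MANUAL`.

Per-cell intensity is the *mean* over the label footprint (matching the
"intensity in the cell body" convention of these assays, not an integrated
sum). Background is the *median* over pixels at least 5 px away from every
cell — median rather than mean so dim debris cannot inflate it. Records
keep both the floored background-subtracted mean (never negative) and the
signed value. The signed value exists because of a calibration subtlety:
control distributions centre on zero, and flooring at zero halves their
spread, which would drag a mean + k·sd rule down to ≈2.2σ and admit ~1.4%
false HA⁺ calls — enough to bias the spread fraction upward by almost two
percentage points. Thresholds are therefore calibrated on signed values,
while classification operates on the floored ones.

## Threshold calibration

Two rules are exposed, each anchored to the control population that defines
it in practice:

- eGFP positivity: `PERCENTILE_OF_CONTROL` (default 99) on non-transduced
  neurons — whether the original assays used a maximum or a percentile of
  the control distribution is not stated anywhere, so the percentile (and
  the rule itself) is configurable;
- HA positivity: `MEAN_PLUS_K_SD` (default k = 3) on a
  secondary-antibody-only control.

Percentiles use linear interpolation (`stats::quantile`, type 7). Entries
record rule, parameter, control description and control size; fewer than 20
control cells flags the entry low-confidence, and a zero-variance control
under the k·sd rule is flagged degenerate. Cells exactly at threshold are
negative (strict inequality) — a documented tie-break, applied everywhere.

For brain sections the mCherry gate is special: sections carry no separate
morphology stain, so somata are detected *on the mCherry channel itself*.
Detection thus already performs the mCherry⁺ gate, and the default
threshold entry (`SEGMENTATION_GATE`, threshold 0) records exactly that
provenance. A percentile rule on a reporter-negative control remains
available for imaging setups that have one.

## Puncta, annexin, morphometry

**Puncta.** Aggregation puncta are scored inside each soma after a white
top-hat (disc radius 3 px) removes the smooth soma signal. A punctum is a
connected component above the cell's top-hat median + k × 1.4826·MAD
(k = 3) with area ≥ 4 px²; a cell is aggregate-positive with ≥ 2 puncta.
The robust location/scale pair is deliberate: with several bright puncta in
a soma, the plain mean/sd pair is inflated by the puncta themselves and a
3-sd cut can land *above* the puncta amplitude. MAD-based cuts keep the
uniform-cell case exact (zero spread → zero puncta) and stay calibrated
when puncta are present. Proteostat and HA positivity in acceptor cells
reuse this one code path with the appropriate channel.

**Annexin.** The imaging readout of scramblase activity is the ratio of
total background-subtracted FITC to total background-subtracted NFH over
all cell footprints, reported per field and normalized to the control
condition downstream. The ratio is invariant to a common gain on both
channels. The flow-style variant gates events mCherry⁺ at a percentile of
non-expressing controls and summarizes FITC by the median (robust;
configurable to mean — the assays report no summary statistic, so the
robust choice is the default).

**Morphometry.** The neurite mask is the adaptive-threshold morphology mask
minus the soma footprints dilated by 3 px — the dilation removes the bright
rim at the soma edge, which would otherwise survive subtraction and
skeletonize into a spurious loop around every cell. The mask is thinned to
a 1-px skeleton (Zhang–Suen), converted to a pixel graph with chain-code
edge weights (1 orthogonal, √2 diagonal, redundant diagonals pruned), and
each connected component is assigned to the nearest soma centroid. Total
tree length is the sum of edge weights × pixel size; primary neurites are
skeleton branches entering a 2-px ring around the subtracted soma boundary,
and each primary's single-neurite length is its longest root-to-tip
geodesic (ties broken by the longer path — "single neurite" has no
universal definition, so this one is explicit and configurable in the
branch-detection ring). Straight, diagonal and Y-shaped test neurites
recover their analytic chain-code lengths within 2%, and lengths are exact
under translation and 90° rotation. Lengths are reported per neuron; field
averages are computed downstream (per-neuron reporting is the
implementation choice; a per-field mean is one `tapply` away).

## Statistics

Group comparisons call the standard machinery: a two-tailed two-sample
Student t-test (pooled variance by default, Welch available) for two
conditions, one-way ANOVA with Tukey HSD post-hoc for multi-condition
designs (pairwise stars in the source figures name no post-hoc method;
Tukey is the conventional choice after one-way ANOVA). Zero-variance
degenerate inputs return the defined limits (t = 0, p = 1 on identical
groups) rather than erroring. ΔΔCt follows the textbook form: per sample
ΔCt = Ct(target) − Ct(reference), ΔΔCt baselined to the control-group mean
ΔCt, relative expression 2^(−ΔΔCt); the control group's geometric mean is 1
by construction and the result is invariant to adding a constant to every
Ct.

In vivo recipient counts are reported as absolute counts per region
(cortical / subcortical split by centroid, conservation checked against the
whole-brain total), with section area reported as a comparability check
rather than used as a divisor; area-normalized counting is available but
not the default, mirroring how section-size QC is used in practice.

## Problem sizes and numerical choices

The replication experiments run at the scale the assays describe:
1000-cell fields for parameter recovery (20 seeds per `p_spread` setting at
5% read noise; estimates land within 2 pp of the generating values and are
strictly monotone under common seeds), and 200-cell fields — the per-
experiment cell count these assays typically quantify — for the two-
condition power study (5 replicate fields per condition, 100 repetitions;
the depleted condition p_spread 0.05 vs control 0.2 is detected by the
pipeline's own t-test in ≥95% of repetitions). The power study simulates at
the record level: per-cell measured means are drawn with standard error
noise_sd/√area — exactly the sampling distribution pixel measurement
produces — and flow through the same calibration, gating, metric and test
code as pixel data. Rendering a thousand full frames would exercise only
the generator loop again, so pixel rendering is reserved for the recovery
sweep and the oracle tests, which do run the full image path.

Degenerate inputs have defined behaviour throughout: empty label maps yield
empty record tables (not errors), a gate capturing zero events errors with
the gate named, a zero control mean refuses normalization, and placement
that cannot satisfy the separation constraint errors with the constraint
named.

## Known limitations

- Disc somata and polyline neurites: no irregular morphology, no touching
  neurites, no 3D stacks, no point-spread-function or photobleaching model.
- The adaptive threshold is a local arithmetic mean; the plug-in convention
  it mirrors does not document its exact statistic, so other local
  statistics (median, Gaussian-weighted) are not provided.
- No spectral unmixing, flat-field correction or FCS parsing; flow tables
  are plain CSV.
- Segmentation offset must be chosen commensurate with noise; the package
  does not auto-estimate it.
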