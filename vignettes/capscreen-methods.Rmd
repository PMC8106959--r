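---
title: "Methods: simulating and quantifying the CaP motor-axon screen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating and quantifying the CaP motor-axon screen}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(capscreen)
```

# The assay being modelled

At 28–30 hpf the zebrafish CaP motor axon has grown ventrally to the
horizontal myoseptum (HM), formed *en passant* synapses with muscle pioneers,
and — in healthy embryos — grown on past it. In *chodl* mutants those synapses
fail to mature and most axons stall at the HM, so the number of axons beyond
the HM (out of the eight scoreable ones, somites 7–14) and the total axon
length are quantitative read-outs of synapse stabilisation. The screen scores
compound-treated mutant embryos against a DMSO-mutant internal control via
the rescue index (ratio of crossing fractions; hits at RI ≥ 2.5), then
measures axon length and, separately, synaptic puncta morphology at the HM.

This package implements that analysis pipeline and a synthetic-embryo
generator with exact ground truth, so every stage can be validated end to end.

# Coordinate frame and geometry

Images are `rows × cols` matrices with rows increasing dorsal → ventral and
columns anterior → posterior; all indices are 1-based (the natural convention
in R). "Beyond the HM" means the axon tip row is strictly greater than
`hm_row`, with a 2 µm margin (below). The default geometry is a
140 × 360 px frame at 1 µm/pixel — pixel size is configurable and all
thresholds are specified in µm — with the spinal exit row at 20, the HM at
row 48, and eight exit points spaced 40 µm apart. The 28 µm exit-to-HM drop
is consistent with the reported mean stalled axon length (35.06 µm): a
stalled axon is somewhat longer than the straight drop because it curves and
grows along the myoseptum.

# The synthetic-embryo generator

## Presets

Each preset encodes one experimental condition as generator parameters;
`list_presets()` shows the registry and every preset's `notes` field records
in plain words which reported statistic each calibrated number encodes:

* `chodl-DMSO` — mean axon length 35.06 µm; crossing probability 2/8 (one or
  two axons beyond the HM in controls); enlarged presynaptic compartment
  (+58 % total puncta area), +83 % presynaptic labelling intensity, reduced
  puncta counts (postsynaptic −37 %).
* `dipyridamole-10uM`, `dipyridamole-30uM`, `iox1-10uM`, `iox1-50uM`,
  `mg132-10uM` — mutant background with length scaled by the reported
  percent-of-control ratio (135 %, 133 %, 139 %, 158 %, 118 %), crossing
  probability scaled by the nominal rescue index, and the per-compound
  presynaptic rescue pattern (dipyridamole rescues area only; IOX1 rescues
  area, count and intensity).
* `wild-type-DMSO` — all eight axons cross; baseline synapse fields.
* `uba1`, `uba1+dipyridamole`, `uba1+quercetin` — wild-type background with
  abnormal-axon rates: baseline 0.12 × 2.17 (the reported +117 % increase
  under UBEI-41), × 0.69 for added dipyridamole (the reported −31 %), and
  0.13 for the quercetin positive control.

Where only group means were reported, spreads are artifact choices: axon
lengths are truncated normal with SD = 20 % of the mean. The wild-type mean
length (56 µm) and the baseline abnormal fraction (0.12) are artifact
choices, flagged as such in the registry notes.

## Axon geometry and ground-truth length

Axons are built as 8-connected pixel chains and the **true length is defined
as the Euclidean step sum of the chain** (1 or √2 px per step), so a perfect
tracer recovers truth exactly on noise-free renderings. Crossed axons descend
ventrally with a gentle sinusoidal wobble (amplitude 1.5 px) and stop when
the target length is reached. Stalled axons longer than the exit-to-HM drop
descend along a single smooth lateral bump (`x = A sin²(πr/D)`, amplitude
solved numerically so the arc length matches the target, capped at
1.12 × the drop) and spend residual length growing along the myoseptum after
a 45° chamfer; the profile leaves the exit and meets the myoseptum
vertically. This shape was chosen so the path is self-avoiding and has low
curvature everywhere — a skeleton-based tracer can follow it without
shortcuts. Its capacity (≈ 48 µm) truncates the upper ~3 % tail of the
stalled-length distribution; the effect on the realized mean is well below
the 2 % calibration tolerance and ground truth always records the rendered,
not the nominal, length.

Crossing status is drawn per embryo (binomial over 8 axons); crossed axons'
lengths are drawn from the same distribution conditioned on reaching past the
myoseptum, so stalled lengths stay unconditional and their mean calibrates to
the preset mean. Branches attach at 30–70 % of the path and extend laterally;
baseline branches are short (2–5.5 µm — below the 8 µm counting line, i.e.
filopodia at this stage), ectopic branches in the UBA1 model extend 11–16 µm.
Abnormal axons take one of three modes: missing (nothing rendered),
truncated (14–30 µm, stopping dorsal of the HM), or ectopically branched;
healthy axons in abnormality presets are drawn above 42 µm so that the length
criterion separates cleanly.

## Puncta and rendering

Each of the first five hemisegments receives presynaptic and postsynaptic
Gaussian puncta inside the 20 × 20 µm ROI at the HM, placed on jittered
anchor layouts that keep thresholded spots separated; a fraction (0.75) of
postsynaptic puncta are co-centred with presynaptic ones so pre/post overlap
is derivable from geometry. Punctum amplitude carries 5 % jitter.

Because the pipeline thresholds at a percentage of the ROI maximum, the
measured area of a Gaussian punctum of scale σ is analytically
π(2 ln(1/f) σ² + 1/6) px² at fraction f — the 1/6 px² term is the expected
subpixel offset of the brightest pixel from the true peak. Preset σ values
invert this response so the *realized total-area ratios* equal the nominal
ones (e.g. +58 % presynaptic area with 3 vs 4 puncta per hemisegment).
Intensity effects are encoded directly as amplitude ratios, which the
mean-over-punctum-pixels read-out preserves.

Rendering: chains are thickened to 2 px, blurred (σ = 0.5 px) as the optical
PSF, and scaled to the channel amplitude. The reporter channel sits on a
fixed tissue background (0.05); the antibody channels carry an
autofluorescence floor proportional to the label amplitude (0.15 × A), which
keeps the background-subtraction pedestal proportional between groups so
group ratios survive the pipeline. Noise is additive Gaussian at
SD = amplitude/SNR (default SNR 10), spatially filtered with the same PSF —
white single-pixel noise is unphysical for diffraction-limited images and its
extreme-value spikes would bias percent-of-maximum thresholds. `snr = Inf`
gives noise-free images for oracle tests. Identical `(preset, seed)` pairs
yield byte-identical images and ground truth.

## Cohorts and variance control

`generate_embryo()` draws every embryo independently. `simulate_cohort()`
additionally offers *stratified* sampling (the default): length quantiles are
systematic across the cohort and crossing/abnormality counts are allocated
evenly with a random remainder. Every draw remains random, but cohort-level
means sit tight on the preset's nominal values — the standard
variance-reduction choice for calibration cohorts. Distribution-shape tests
(e.g. the binomial goodness-of-fit of crossing counts) use the plain
independent mode.

## Screens

`generate_screen()` lays compounds on 96-well plates (three embryos per well,
six per compound). The internal control occupies the first two wells, four
wells in the middle of the plate and the last two wells; `analyse_screen()`
pools them per plate and reports a non-blocking control-drift check
(first-position vs last-position wells, Mann–Whitney). Score-only mode skips
rendering and draws per-embryo crossing counts directly, which makes
thousand-compound screens take seconds. Toxic compounds (death / delayed /
malformed) are flagged, never scored, and excluded before hit calling; dead
embryos render as opaque.

# The quantification modules

## Axon tracing

The original assay traced axons manually from the spinal exit point to the
tip. The automated stand-in: within a hemisegment window around the exit
column (half-width = half the exit spacing), the channel is binarised with
Otsu's threshold, thinned to an 8-connected skeleton (Zhang–Suen), and the
main axon is the geodesic path on the skeleton graph from the pixel nearest
the exit point to the endpoint at maximal geodesic distance, ties broken
toward the more ventral endpoint (the biological growth direction). An axon
is absent when no skeleton pixel lies within the 5 µm capture radius of the
exit point (a robust presence gate rejects windows whose maximum is not
clearly above the noise floor first). Two standard corrections are applied:
the gap between the exit point and the first skeleton pixel is included in
the length (the assay measures from the exit point), and the tip is extended
along its final direction to the visible end of the signal (a permissive
mask at half the Otsu threshold, at most 6 px) because thresholding and
thinning both erode line ends. Residual accuracy on rendered embryos:
within ±10 % per axon and ~3 % on group means, which the oracle tests pin
down; crossing class and branch counts match ground truth exactly on
noise-free renderings.

`classify_hm()` uses a 2 µm margin: crossed iff tip row > hm_row +
margin/pixel size. The margin makes the visual boundary call reproducible;
a tip exactly on the HM is stalled.

`count_branches()` reproduces the line-crossing rule: two counting lines
parallel to the main axon at ±8 µm; skeleton components attached to the main
path (within 1 px) that reach a line are counted once per side they cross
(branches crossing both lines count on both, matching the summation over
sides). Components not touching the axon — e.g. a neighbouring axon's branch
entering the window — are ignored. Filopodia shorter than the offset never
reach a line.

`score_abnormal()` flags an axon as abnormal when it is missing, shorter than
the minimal normal length, or ectopically branched. The defaults: minimal
normal length = exit-to-HM distance + 10 µm (at this stage a normal axon has
passed the myoseptum; no numeric cut was reported, so the rule is
geometry-derived and configurable), and any branch crossing the 8 µm lines
counts as ectopic (branching at this stage is filopodial; also configurable).

## Synaptic puncta

Per hemisegment, a square 400 µm² ROI (side 20 µm) is centred on the HM; an
ROI that would leave the image raises an error rather than being silently
clipped. Background subtraction is a morphological top-hat with a 10 µm disk
(the rolling-ball analogue; the radius was not reported and must exceed the
punctum scale). The "30 % threshold" is interpreted as 30 % of the ROI
maximum after background subtraction — the common ImageJ percent-of-maximum
reading; the fraction is configurable since the original convention is
ambiguous. Puncta are 8-connected components of at least 2 px (single-pixel
noise suppression); area is the retained foreground pixel count × pixel
area; mean intensity is measured over punctum pixels of the
background-subtracted image by default (the raw ROI is selectable, since the
original convention is unstated). Overlap statistics apply the same
quantification to the intersection of the pre- and post-masks, so
overlap area ≤ min(pre, post) holds by construction. `measure_embryo()`
averages four to five hemisegments per embryo and flags embryos with fewer
than four valid ROIs unusable.

Component labelling is done on the pixel adjacency graph (igraph) because
the EBImage labeller joins pixels 4-adjacently while puncta and skeleton
branches are defined 8-adjacently here; a brute-force flood-fill oracle in
the test suite checks the equivalence on hundreds of random masks.

## Screen statistics

The rescue index pools counts over embryos by default
(Σ crossed / Σ scored per group) — robust at six embryos × eight axons; the
per-embryo-fraction mean is available via `method = "per_embryo"` since the
original aggregation is unstated. Hit calling is inclusive at the threshold
(RI = 2.5 is a hit), because the worked example attains the threshold
exactly. Undefined cases (control crossing fraction zero, control mean
length zero) return `NA` with a reason attribute instead of infinities.

`compare_groups()` operationalises "parametric or non-parametric tests, as
appropriate" as a Shapiro–Wilk gate at α = 0.05 per group: all pass → Student
t (two groups) or one-way ANOVA with Dunnett (vs control) / Tukey (all
pairs); any fail → Mann–Whitney U or Kruskal–Wallis with Dunn's test. Dunn's
z statistics use tie-corrected rank variance and carry only the procedure's
built-in Bonferroni-style adjustment over the comparisons made, no further
correction. Groups need n ≥ 3 (the normality test is undefined below that).
A calibration test verifies the gate holds its nominal type-I error at the
assay's typical group size (n = 30; in very small samples normality
pretesting is known to distort test levels slightly — a property of the
gated procedure itself, not of this implementation).

`posthoc_power()` is observed-effect power: noncentral-t at Cohen's d from
the pooled SD for two groups, noncentral-F at Cohen's f for more. The
two-group case is validated against a 50,000-replicate Monte-Carlo oracle of
the t-test; d = 0 returns exactly α. Power conventions (two-sided, pooled
SD) were not reported with the original power values, so the Monte-Carlo
oracle defines this package's convention.

# What the generator does and does not emulate

It emulates: the plate/manifest structure of the imaging platform's CSV
output, the lateral-view trunk image with eight scoreable axons, the
stalled-vs-crossed geometry, branch statistics, HM puncta fields with the
reported effect sizes, embryo-level toxicity states, and per-group
calibration of the measured quantities. It does **not** emulate 3-D stacks or
maximum-intensity-projection stitching, the brightfield/pigmentation channel,
secondary motor axons, tissue autofluorescence structure, antibody
penetration gradients, or optical aberrations. Passing tests therefore show
that the *measurement and statistics pipeline* is correct and well
calibrated on images with known truth — not that the tracer would handle
every artefact of real micrographs.

# Numerical choices and degenerate inputs

* Otsu thresholds are computed on the min–max-normalised window (256 bins).
* Absent axons: empty path, zero length (with a warning from
  `axon_length()`), classified stalled, zero branches, abnormal.
* All-zero ROIs binarise to an empty mask; zero puncta give zero area and
  `NA` intensity.
* Tie-breaks: geodesic endpoint ties go to the more ventral pixel; the
  stalled/crossed boundary is resolved by the 2 µm margin.
* Seeds: every public generator takes an explicit integer seed; derived
  sub-seeds stay below 2³¹.

# Problem sizes used in the tests and the acceptance script

Parameter-recovery runs use 30–50 embryos per group (the scale of the
original group sizes); generator calibration uses 200 truth-only embryos;
the component-labelling oracle uses 500 random masks; the type-I calibration
uses 1,000 simulated comparisons; the power oracle uses 50,000 Monte-Carlo
replicates. A full 982-compound screen replica (12 planted actives at
nominal RI 3.5, 47/22/13 toxic) runs in score-only mode and is required to
recover at least 11 of the 12 actives.

# Known limitations

* The tracer's ~3 % mean underestimate of path length (skeleton end/corner
  effects) is inherent to skeleton-based measurement on rasterised curves;
  group-ratio quantities are largely insensitive to it.
* Abnormal-axon fractions are granular at 8 axons/embryo; recovered
  percent-changes inherit the rounding of count allocation (e.g. 114 %
  realized for a nominal 117 % at 30 + 30 embryos).
* Large mutant puncta close to each other can merge above threshold, which
  lowers discernible counts (as in the real assay) — count ratios are
  therefore qualitative, while area and intensity ratios are calibrated.
* The normality-gated test level is slightly anti-conservative for n ≲ 15.
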