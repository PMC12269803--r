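---
title: "Whole-brain axonal projection density mapping: models, parameters and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Whole-brain axonal projection density mapping: models, parameters and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(axonmap)
```

`axonmap` quantifies mesoscale axonal projections from serial coronal
fluorescence sections and validates every stage on synthetic brains with
known ground truth. This vignette is the package's account of its methods:
the measurement model, the tunable parameters and why their defaults are
what they are, what the synthetic data do and do not emulate, and the
numerical choices made where the procedure was genuinely open.

## The measurement model

An anterograde tracer expressed at a source region fills that region's
axons with fluorophore. After sectioning (80 µm, often with every other
section collected), each section is imaged at several focal planes, and
the per-pixel maximum projection is used for quantification — an axon
passing obliquely through the section is captured at whichever plane it is
sharpest.

Detection is intentionally simple: after normalization and background
subtraction, any pixel whose intensity exceeds a threshold is an axon
pixel (a binary-threshold detector). All downstream metrics are pixel
counts aggregated over an annotation volume in register with the sections:

- **axon density** of region $R$, hemisphere $h$:
  $d(R,h) = A(R,h) / V(R,h)$, where $A$ counts axon-positive pixels and
  $V$ all pixels of the region in the analyzed sections;
- **relative density**: $\mathrm{rel}(R,h) = 100 \cdot A(R,h) / A_{\mathrm{brain}}$,
  a percentage of all detected axon. Because the whole-brain total is the
  denominator, any multiplicative labeling-efficiency factor (virus uptake,
  transport, exposure) cancels — the package's tests assert this invariance
  exactly;
- **proportional density**: $\mathrm{rel}(R)/\mathrm{rel}(S)$ for an
  enclosing scope $S$ (a subtree of the ontology), used to compare the
  *distribution* of projections across animals. Children that partition a
  scope have proportional densities summing to 1, and the package keeps an
  explicit `unassigned` row for axon pixels falling outside the annotation
  so that relative densities over all leaves sum to exactly 100%.

Measurements live on a hierarchical structure tree (Allen-style ontology):
leaf counts roll up to parents by summation, and `rollup()` is linear by
construction. Cortical regions aggregate further into four output networks
(prefrontal, lateral, central, medial) defined by mid-level acronyms; a
leaf counts toward a network if its acronym or any ancestor's is a member,
so e.g. a primary somatosensory leaf counts under SS and hence the central
network. Hemispheres are assigned by the midsagittal plane mapped through
the configured injection side (default right); the rare voxels exactly on
an odd-sized midline plane go to ipsi — a deterministic tie rule of
negligible volume.

## Intensity normalization: the quarter-wise gamma protocol

Sections far from the injection site are systematically dimmer. The
normalization assigns each section a gamma exponent from the ratio
$r_s = m_s / M$ of its mean intensity to the dataset mean, then applies
the standard normalized power law
$\mathrm{out} = I_{\max}\,(\mathrm{in}/I_{\max})^{\gamma}$:

- anterior quarter (first $\lceil n/4\rceil$ sections): $\gamma_s =
  \mathrm{clamp}(r_s, 1.0, 1.5)$ — bright sections are dimmed, never
  brightened, and never by more than $\gamma = 1.5$;
- posterior quarter: $\gamma_s = \mathrm{clamp}(r_s, 0.9, 1.0)$ — dim
  sections are gently brightened, capped to prevent over-enhancement;
- middle half: $\gamma_s = 1$ exactly (untouched).

Two properties matter and are asserted in the tests: the transfer function
is strictly monotone (within-image intensity ordering is preserved, so
segmentation thresholds keep their meaning), and on a series with uniform
means the protocol is exactly inert ($r_s \equiv 1$, masks bit-identical
with the stage on or off).

One regime note: a power-law exponent acts multiplicatively on
$\log(\mathrm{in}/I_{\max})$, so its strength depends on where image means
sit on the intensity scale. Around mid-tone means ($m_s/I_{\max}$ near
$e^{-1} \approx 0.37$), $\gamma_s = r_s$ moves a section's mean almost
exactly onto the dataset mean; at very low means the same exponent
overshoots. The synthetic generator therefore places section means in the
mid-tone range (background offset 0.3 on the unit scale), which is the
regime in which the protocol demonstrably shrinks the spread of section
means — the package's ramp test measures the SD of section means dropping
by roughly half after correction.

Two details are configurable because the procedure leaves them open: the
section mean is computed over tissue pixels (the nonzero annotation
footprint) when an atlas is supplied, else over the whole frame; and the
correction is applied to the raw projection with background subtraction
second, reading the stages in acquisition order. Both choices are exposed
rather than hard-coded.

## Background subtraction and segmentation

The rolling-ball stage is implemented as a top-hat: the background is the
greyscale morphological opening of the image with a disc structuring
element of the stated radius (default 2 px, matched to ~2 µm/px data), and
the output is image minus background, clipped at zero. Features narrower
than the disc — thin axon fibers — pass through unattenuated; flat or
slowly varying background maps to zero. A hand-written erode/dilate double
loop serves as the independent oracle in the tests (compared on interior
pixels, where border conventions cannot differ).

The default threshold is global and robust: median + $k \cdot$ MAD over
the pooled background-subtracted pixels, $k = 5$. With predominantly
background pixels this tracks the noise floor and puts the threshold at
roughly five noise SDs, where the Gaussian false-positive rate across a
full section series is far below one pixel (the tests count it against the
binomial tail bound). Per-section overrides mirror the manual per-section
adjustment used near injection sites, and an optional circular exclusion
zone removes injection-site pixels from both axon and region counts.
Zero-dynamic-range images segment to an empty mask with a warning rather
than failing.

## The synthetic brain: what it emulates, and what it does not

`build_toy_atlas()` tiles an ellipsoidal volume bilaterally with
equal-count blocks (leaves), mirrored across the midline, under a
three-level ontology (root → isocortex-like and subcortical parents →
leaves carrying standard cortical acronyms so network definitions
resolve). The default voxel size is 80 µm so one 80-µm section spans
exactly one annotation plane — mask/annotation alignment is then exact and
counts are exactly interpretable; thicker sections spanning several planes
are supported but register to the middle plane.

`simulate_axon_brain()` places fibers as straight 10-voxel segments with
random position and orientation, clipped to their region, committing
segments one at a time (with the final segment trimmed) so the achieved
per-region fiber fraction equals the prescribed fraction to within
rounding. Straight segments are cheap and produce connected, line-like
axon pixels rather than salt-and-pepper noise; they do not model
branching, boutons, or realistic tortuosity. Sections are rendered with a
per-plane attenuation of fiber intensity (uniform in [0.7, 1], so the
maximum projection restores close to full amplitude), Gaussian pixel noise
(SD 0.02) on a constant offset — the scanner's noise model is not known,
so Gaussian-plus-offset is an explicit, configurable choice — and a
multiplicative anterior→posterior linear brightness ramp (default 1 → 0.5)
that gives the gamma stage a genuine gradient to remove. A nuclear channel
with region-boundary texture is carried for format fidelity only; no
registration is performed on it.

Consequently, passing tests demonstrate that the measurement pipeline
recovers known pixel-level ground truth through rendering, normalization
and segmentation; they do not exercise section-to-atlas registration,
stitching, optical scattering, or biological morphology, all of which real
data add.

## Behavior and group statistics

The open-field zones partition the arena: a concentric center rectangle
with side 0.7× the arena side (area fraction 0.49 — the side-length
reading of the centroid factor; the area reading is accepted via the same
parameter), four corner triangles each spanned by a corner and the two
points 0.3 along its walls (total area fraction $2 f^2 = 0.18$), and the
remainder. Points on boundaries resolve by the precedence corner > center
> rest, so every frame belongs to exactly one zone and fractions sum to 1
exactly. Kinematics are plain step sums over tracked frames in the
analysis window (default the first 300 s); frames with missing coordinates
are excluded from numerator and denominator and reported.

The trajectory generator is a reflected Gaussian random walk whose
stationary occupancy at zero wall bias is uniform; a positive wall bias
adds per-frame drift toward the nearest wall (thigmotaxis). The per-frame
step SD is a free parameter: 0.35 cm (~10 cm/s at 30 Hz) is mouse-like and
is the default for kinematics-flavored uses, while occupancy-calibration
checks use a large step SD (30 cm) so the walk mixes in about one frame
and zone fractions can be compared to analytic areas with binomial
standard errors — at mouse-like step sizes frame-to-frame autocorrelation
would inflate the sampling error far beyond binomial.

Rotarod trials are summarized as the mean latency per day (the quantity
used for group statistics; trials cap at 300 s), with a mouse's overall
score the mean of its day means; a missing day stays visibly missing.
Assay values normalize analyte to total protein per sample. Group
comparisons are the classical fixed-effects one-way ANOVA with Tukey HSD
(via `stats::aov`/`TukeyHSD`) and the unpaired pooled-variance Student
t-test (Welch available behind a flag); both are validated against
hand-written sum-of-squares and pooled-t formulas, the $F = t^2$ identity
for two groups, and a 2000-replicate null simulation showing the type-I
error within 0.05 ± 0.01.

## Validation experiments and problem sizes

The package's end-to-end checks, all built from the generators above, use
these sizes (chosen to make each experiment's sampling error small
relative to what it measures, while keeping a full run in tens of
seconds):

- **Parameter recovery**: 3 brains, 12 leaf regions on a 64×96×64 atlas
  (≈7,600 voxels per region and hemisphere), densities log-spaced
  0.01–0.30, contra = ipsi/2 except a prescribed 3:1 ipsi:contra asymmetry
  in the medial network; full section series. Recovered relative densities
  correlate with the prescription at Pearson r > 0.999 with exact
  region-level rank recovery, and the medial ratio lands within a few
  percent of 3. The full series is used here deliberately: every-other
  collection halves the per-region plane sample, and because fibers are
  10-voxel segments their pixels cluster within planes, so subsampling
  adds region-level sampling noise that belongs to the data, not the
  pipeline.
- **Gamma protocol**: a 6-region brain on a 1 → 0.5 brightness ramp
  (clamps respected, section-mean SD strictly reduced) and an exactly
  uniform-mean stack (stage provably inert).
- **Zone calibration**: ≥50,000 frames of the fast-mixing unbiased walk
  (center 0.49, corner 0.18 within three binomial SEs) plus degenerate
  all-center/all-corner trajectories.
- **Cohort scenario**: wild-type (n = 3) versus perturbed (n = 6) cohorts
  with somatosensory density ×1.5 and secondary-motor ×0.6 and 8%
  per-region log-normal between-animal variation; unpaired t-tests on
  proportional densities detect both perturbations in the correct
  directions.

## Known limitations

Registration to a real atlas is out of scope — sections are assumed in
register (synthetic sections are generated that way; real data should be
registered upstream). The annotation "volume" is counted as projected 2D
pixels per analyzed section, treating each as a column of section
thickness; the constant factor cancels in every reported metric. The
density prescription is per leaf region; within-region spatial structure
(laminar gradients, patchiness) is not modeled, and the package makes no claims about the
biology of any particular projection system — it measures, it does not
interpret.
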