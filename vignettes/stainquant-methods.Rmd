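---
title: "Methods: stain quantification and cohort statistics in stainquant"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: stain quantification and cohort statistics in stainquant}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stainquant)
```

stainquant quantifies trilineage-differentiation assays of mesenchymal
progenitor cells (here: equine adipose-derived stromal cells, ASC) from
calibrated RGB microscopy, and runs the donor-blocked nonparametric
statistics such experiments need. This vignette explains each model and
procedure, the tunable parameters, the synthetic-data generator used for
validation, and the numerical choices and limitations a careful user
should know about.

## Image model and illumination correction

All images are arrays with values in $[0, 1]$ (integer files are rescaled
by their dtype maximum on reading). Uneven illumination and fixed sensor
offsets are removed with a calibration pair — a brightfield reference
captured from an empty slide and a darkfield reference captured with the
light path closed:

$$\mathrm{Corrected} = \frac{\mathrm{Original} - \mathrm{Darkfield}}
{\mathrm{Brightfield} - \mathrm{Darkfield}}$$

applied per pixel and per channel (deconvolution downstream needs all
three color channels, so correction cannot be done on luminance alone).
Two numerical guards are added: the denominator is floored at $10^{-6}$,
and the output is clipped to $[0, 1]$. On synthetic scenes composed as
*scene × field*, correcting with the true field recovers the scene to
round-off (the acceptance script reports the RMSE on a 512×512 image).

Luminance, where needed, is the Rec. 601 weighting
$0.299R + 0.587G + 0.114B$; the weights matter less than consistency,
since every threshold in the package is adaptive or calibrated.

Downscaling uses area-average (anti-aliased) resampling with the height
rounded to preserve aspect ratio; binary masks travel the other way with
nearest-neighbor upscaling so they stay strictly binary.

## Color deconvolution

A stained pixel is modeled as a Beer–Lambert mixture: in optical density
$\mathrm{OD} = -\log_{10} \max(I, 10^{-6})$, co-localized dyes add
linearly, $\mathrm{OD}(p) = \sum_s c_s(p)\, v_s$, with $v_s$ a unit
"stain vector" with nonnegative components. Stain vectors are
parametrized in physics-convention polar coordinates — inclination $\phi$
from the blue OD axis, azimuth $\theta$ in the red–green plane — so a
kernel is a small set of interpretable angles. A 2-stain kernel is
completed with the normalized cross product of its stains: a unit
residual vector orthogonal to both, reported for diagnostics but never
entering assay ratios. Unmixing is multiplication by the inverse of the
stain matrix; negative concentrations (noise, imperfect kernels) are
clipped to zero in the returned maps while raw values are kept for
diagnostics. The log base is a convention only — it cancels in every
ratio the package reports.

Two presets ship with the package (`kernel_preset()`): Oil Red
O/hematoxylin for adipogenic cultures and Alcian blue/Nuclear Fast Red
for chondrogenic pellets. They are reasonable starting angles for this
class of material, not instrument truth; per-batch refinement is what
`estimate_kernel()` is for.

### Programmatic kernel estimation

Historically these kernels were tuned with interactive sliders while
inspecting the unmixed images. `estimate_kernel()` replaces that with a
reproducible optimizer on a 3×3 collage of nine images (deterministic
given a seed). The objective is

* the mean squared magnitude of *negative* raw concentrations (a correct
  kernel never produces negative dye amounts),
* plus, for 2-stain kernels, the mean *squared residual channel* — on
  two-dye material the residual must vanish; without this term the
  objective is exactly flat along out-of-plane rotations whose residual
  happens to stay positive, and along "cone-enlarging" in-plane rotations,
  and no optimizer can recover the true angles,
* plus $\lambda = 0.1$ times the mean pairwise Pearson correlation of the
  clipped stain channels: cleanly separated stains are *anti*-correlated
  across a collage, and any leakage of one dye into the other's channel
  raises the correlation.

The search is a per-stain pattern search over the polar angles (axis and
diagonal moves, step halving from 2° to 0.25°, angles confined to
$[0°, 90°]$). Diagonal moves matter: azimuth and inclination are coupled
along in-plane rotation valleys and axis-only coordinate descent stalls
there. Before the search the OD image is block-averaged 2×2: averaging in
OD space is linear in concentrations, so it suppresses sensor noise
without biasing stain directions (averaging *intensities* would, through
the logarithm). A static report (`kernel_report()`) with per-stain
concentration images and pixel statistics replaces the dynamic
inspection step.

Two caveats. First, the correlation term penalizes *genuine* dye
co-localization as well as leakage, so kernels should be estimated on
material showing well-separated pure-stain regions — which is also what a
human tuner would pick. Second, "SNR" for the noisy-recovery checks is
defined on the image *contrast* ($\mathrm{RMS}(1 - I)$), because the
white background of a brightfield image dominates raw intensity RMS and
would make a nominal 20 dB as large as the entire stain signal. Under
these conditions, angle recovery on synthetic collages is exact
(noise-free) and within ~2–3° at 20 dB.

## Segmentation

Three binarization procedures, matched to the three image classes:

**Adaptive cell mask (adipogenic cultures).** Cells are darker than the
bright background, so the negated luminance is thresholded: a pixel is
foreground when its value exceeds $1.1\mu - 0.3\sigma$, with $\mu$,
$\sigma$ the mean and population standard deviation of a centered square
region around it. The image is first downscaled to a 512-px working
width; the region side is 30 px for 10× and 60 px for 20× images (both at
the working resolution); the mask is upscaled back with nearest-neighbor.
Window borders use symmetric (edge-duplicating) padding. The rule's
geometry is worth understanding: a flat object wider than the window sees
only itself, and a constant can never exceed 1.1 times its own mean, so
the mask detects cell-scale structure, not large flat plateaus; and an
isolated object acquires a faint detection halo where a window corner
clips it ($\sigma$ grows like $\sqrt f$ while $\mu$ grows like $f$ in the
clipped fraction $f$). Both effects are harmless in confluent cultures —
the intended material — and the dye ratios are computed *within* the
mask, where background contributes essentially no dye.

**Pellet mask (chondrogenic micromasses).** One compact dark pellet on a
bright background: downscale to one third of the width (864 px from a
2592-px camera frame), negate, binarize at the Otsu threshold, close with
a discrete disk of radius 4 (working scale) to fill small holes, keep
only the largest 8-connected component (removing air bubbles and debris),
and upscale. Otsu maximizes the between-class variance over a 256-bin
histogram of $[0, 1]$; ties break toward the lowest threshold; a constant
image has no separating threshold and is rejected (the pellet pipeline
converts that into an empty mask with a warning). Whether the closing
radius applies at working or native scale is ambiguous in the underlying
protocol; working scale is used and the radius is a parameter.

**Confluency mask (phase contrast).** Cells are brighter than the
background; the mask is simply $value > \mathrm{mean}(image) + 0.07$,
with no resizing. The offset is empirical but stable because the mean
adapts per image; the mask area is invariant under adding a constant to
the whole image.

Connected components are 8-connected throughout. Component labeling is
EBImage's `bwlabel` (4-connected) followed by a union-find merge of
labels that touch diagonally.

## Assay metrics

* **Adipogenic:** cell-mask area fraction; Oil Red O to hematoxylin
  concentration-*mass* ratio within the mask; and the "concentration
  percentage", Oil Red O mass over total two-stain mass. Mass sums (not
  means of per-pixel ratios) are used deliberately: per-pixel ratios
  explode where the denominator concentration is near zero.
* **Chondrogenic:** pellet area (fraction and pixels) as a micromass-size
  measure; Alcian blue to Nuclear Fast Red mass ratio within the pellet.
* **Osteogenic (von Kossa):** a single dye needs no unmixing; the score
  is $1 - \mathrm{mean}$ corrected luminance, larger for darker (more
  mineralized) images, bounded in $[0, 1]$.
* **Confluency:** mask area as a percentage of the image.
* **LIVE/DEAD:** dead cells are bright red spots: Otsu-binarize the red
  channel, label 8-connected components, drop components below
  `min_area = 10` px, count the rest. Two guards: the Otsu threshold is
  floored at `min_intensity = 0.2` (Otsu always splits a histogram, so a
  spot-free frame would otherwise binarize its own background noise), and
  frames whose foreground exceeds half the image are rejected as
  saturated. Viable (green) cells vary too much in morphology for this
  spot model and are deliberately not counted.
* **Histology score:** three blinded categories — seeded-surface
  distribution (0–4), integration (0–3), opposite-surface distribution
  (0–3) — summed to 0–10.

Undefined quantities (ratios over empty masks) propagate as missing
values, never as zeros.

## Statistics

The cohort design blocks on donor ($n = 7$). Because metric distributions
are skewed and sample sizes small, the battery is nonparametric:

**Friedman test** across $k \ge 3$ matched conditions, with mid-rank ties
and the tie-corrected statistic
$\chi^2 = (k-1)\sum_j (R_j - n(k{+}1)/2)^2 / (A - C)$, $A$ the sum of
squared ranks, $C = nk(k+1)^2/4$. The default p-value is the chi-square
approximation on $k-1$ df (what mainstream statistics software reports);
`exact = TRUE` computes the full $(k!)^n$ within-block permutation
distribution by dynamic programming over column rank sums, conditional on
the observed tie pattern. At $n = 7$, $k = 3$ the exact test is
noticeably conservative (null rejection 2.7% at $\alpha = 0.05$ versus
5.1% for the approximation) — discreteness, not error.

**Wilcoxon signed-rank** for paired post-hoc comparisons (condition vs.
control, day 1 vs. day 3). Zero differences are dropped before ranking
(Wilcoxon's treatment; Pratt's is available), ties get mid-ranks, and for
$n \le 25$ the p-value is exact via the full $2^n$ sign-flip distribution
(computed by convolution, valid under ties). Larger $n$ falls back to a
normal approximation with tie and continuity corrections. At $n = 7$ the
exact two-sided test rejects a true null 4.7% of the time at
$\alpha = 0.05$ — the closest attainable level from below.

Significance is two-sided at $p < 0.05$ with no multiple-testing
correction by default, mirroring the practice this battery reproduces; a
Holm option exists per comparison family. Extreme outliers (beyond 3 IQR
from the quartiles) are excluded from *boxplot display only*; every test
always uses the full data.

**Expression ratios** use the efficiency-corrected (Pfaffl) form
$E_t^{\Delta Ct_t} / E_r^{\Delta Ct_r}$ with $\Delta Ct$ measured
control-minus-sample and a default efficiency of 2 when none was
measured; fold changes are then normalized to each donor's own control
within culture system, day and gene, so control fold changes are
identically 1. **Generation time** is the doubling time
$t \cdot \log 2 / (\log N_1 - \log N_0)$, undefined (missing, with a
warning) when no growth occurred.

## Synthetic data: what it emulates, and what it does not

The generator produces every input class with known ground truth:

* **Stained brightfield scenes:** disks/ellipses carrying per-stain OD
  amounts, composed through the forward Beer–Lambert model, multiplied by
  a radial quadratic vignette $1 - k\,\hat r^2$ (a plausible stand-in for
  an uncharacterized microscope field), plus optional clipped Gaussian
  noise. Renders return the exact masks and concentration maps used.
* **LIVE/DEAD frames:** isotropic Gaussian spots (a PSF-like shape) over
  a positively skewed background, placed by rejection sampling under a
  minimum-separation constraint (default $6\sigma_{spot}$), with optional
  single-pixel specks to exercise the size filter.
* **Cohorts:** $value = baseline \times donor \times condition \times
  day \times e^{N(0,\sigma)}$ with $\sigma = \sqrt{\log(1 + CV^2)}$,
  lognormal donor effects (scale 0.3 — a moderate, realistic donor
  spread for primary cells), residual CV 20% by default, and the full
  experimental-group structure: nine conditions in monolayer, eight in
  static and four in dynamic scaffold culture, days 1 and 3, seven
  donors. Effects are multiplicative because all assay metrics are
  nonnegative.

Everything is bit-reproducible given a seed. What passing tests on these
data *show* is that the pipeline's arithmetic, thresholds, geometry
handling and statistics are correct and correctly coupled. What they do
*not* show: robustness to real histology — out-of-focus regions, stain
batch variation, scaffold fiber texture, touching cells, chromatic
aberration — none of which the generator models. Kernel presets in
particular are exercised only on synthetic material.

## Problem sizes and numerical choices

Validation workloads were sized to be decisive yet quick: 512×512 images
for the illumination check; 64×64 tiles (3×3 collages) for kernel
recovery; 100 random 64×64 images for the threshold-versus-oracle
equalities; 864×648 scenes for the pellet pipeline; 20 seeds × {0, 25,
40} planted spots for counting; 10,000 simulated null cohorts for type-I
calibration and 500 for power. Key constants: denominator and OD floors
$10^{-6}$; 256 Otsu bins with low-tie-break; closing radius 4 at working
scale; `min_area` 10 px and `min_intensity` 0.2 for spot counting;
$\lambda = 0.1$ and 0.25° resolution for kernel search. Each is a
documented parameter, not a hidden constant.

## Known limitations

* The adaptive rule's halo/plateau behavior (above) makes isolated large
  flat objects a poor fit for the cell mask — use the pellet pipeline for
  compact single objects.
* Kernel estimation assumes at most three simultaneous stains and
  benefits strongly from pure-stain regions; heavily co-localized
  material biases the correlation term.
* The exact Friedman permutation distribution is limited to $k \le 5$,
  $n \le 12$ blocks (state space growth); beyond that the chi-square
  approximation is used.
* Histology scoring is manual by design; the package only aggregates.
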