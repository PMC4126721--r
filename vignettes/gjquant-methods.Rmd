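---
title: "Methods: automated gap-junction and interstitial-collagen quantification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: automated gap-junction and interstitial-collagen quantification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gjquant)
```

## The problem

Connexin-43 (Cx43) is the principal gap-junction protein coupling
cardiomyocytes. In healthy tissue it concentrates at intercalated discs
(IDs), the end-to-end junctions between cells, where it is anchored by
N-Cadherin (N-Cad). In aged and diseased myocardium part of the Cx43
pool redistributes to lateral cell borders ("lateralization"), a
remodeling change relevant to arrhythmia. Quantifying how much Cx43 is
ID-associated versus lateralized from double-immunostained confocal
images is usually done with manual outlining or strict pixel-by-pixel
overlap, both of which are operator-dependent or biased: Cx43 and N-Cad
belong to one molecular complex but do not overlap pixel-for-pixel, so
strict colocalization undercounts junctional Cx43 ("stellate" Cx43
pixels sit a few pixels off the N-Cad plaque).

A second, related quantification problem is interstitial collagen (IC)
in Masson's-Trichrome-stained sections, conventionally measured by
manually outlining blue-stained regions.

`gjquant` implements automated pipelines for both measurements, plus a
synthetic scene generator with exact ground truth used to validate every
stage.

## Per-image threshold calibration

Each fluorescence channel is 8-bit (0 = no staining, 255 = saturation).
The positive-staining threshold is calibrated per image in two stages.

**Stage 1 — initial threshold.** For every candidate threshold $t$ the
foreground is the set of pixels with intensity $\ge t$. As $t$ rises the
foreground mean increases monotonically while the foreground standard
deviation rises to a peak and falls again; the initial threshold is the
$t$ at that peak, and the foreground mean $\mu_{fg}$ and standard
deviation $\sigma_{fg}$ are recorded there. Candidates whose foreground
holds fewer than `min_fg_count` pixels (default 10) are ignored, since
their statistics are noise-dominated; ties take the smallest $t$.

**Stage 2 — refinement.** Candidate thresholds are parameterized as
$t(R) = \mathrm{round}(\mu_{fg} + R\,\sigma_{fg})$ for $R$ on a grid
(default $-3$ to $3$, step $0.01$), and each is scored by the
between-class statistic

$$J_T = \frac{P_1 P_2 (\mu_1 - \mu_2)^2}{\sigma_1^2 + \sigma_2^2},$$

where $P_1, P_2$ are the background ($< t$) and foreground ($\ge t$)
pixel counts and $\mu_i, \sigma_i$ the class means and *population*
standard deviations (these are full-population pixel statistics, not
samples). The $R$ with the largest defined score wins; ties take the
smaller $R$. The quantified result for a channel is the *integrated
intensity*: the sum of intensities over all positive pixels (a
pixel-count mode is available via `gj_config(measure = "count")` for
sensitivity analysis).

Numerical edge cases: candidates where one class is empty are undefined
and skipped. Candidates where both class variances are zero (each class
a single intensity) have an undefined ratio; they are skipped while any
finite score exists, but when *no* candidate has a finite score — e.g.
an exactly two-valued image, where every separating threshold yields
zero within-class variance — such a candidate is accepted as a perfect
separation (smallest $R$ first), so clean two-valued images still
threshold between their modes. Constant channels raise a "degenerate
image" error, which the image-level pipeline converts into a flagged
record rather than a failure.

A note on the score's shape: because the denominator is the *unweighted*
sum of within-class variances, $J_T$ is not monotone-equivalent to the
classical weighted between-class variance. On images whose positive
pixels are very sparse and broadly spread in intensity, its maximum can
sit on the bright shoulder of the foreground mode rather than in the
valley between modes, trimming the dim tail of true signal. This is a
property of the statistic itself; it motivates the intensity
distributions chosen for the synthetic scenes (below) and is worth
keeping in mind with unusually dim, sparse staining. The per-image
optimal $R$ is reported in every record, and a fixed cohort-level $R$
can be imposed with `gj_config(fixed_r = ...)` when a common calibration
across a study is preferred.

## The DNCU dilation sweep ("blur algorithm")

Every positive N-Cad pixel is dilated into a disk of radius $r$ (in
inter-pixel distances, IPD; 1 IPD = one pixel spacing) — a *dilated
N-Cad unit* (DNCU). Cx43 intensity on pixels covered by any DNCU is
end-to-end (`cx43_ee`); the rest is side-by-side (`cx43_ss`). The
implementation computes one exact Euclidean distance transform of the
N-Cad mask (`EBImage::distmap`, verified in the test suite against an
all-pairs brute force) and thresholds squared integer distances, so each
radius of the sweep is exactly the disk dilation of `dilate_mask()` at
negligible cost.

Sweeping $r = 0 \dots 40$ produces a non-decreasing coverage curve with
a characteristic biphasic shape when lateralized Cx43 is present: a
fast rise while the disks grow over the stellate Cx43 around the
plaques, a first plateau once all ID-associated signal is covered, a
second rise when the disks start reaching lateralized Cx43, and a second
plateau. The first plateau's level is the end-to-end amount; total minus
that level is the side-by-side amount.

**Plateau rule.** The curve's plateaus are detected with a scale-free
rule: a plateau is a maximal run of at least `plateau_window` (default
3) consecutive unit-radius steps whose per-step rise is below
`plateau_tol` (default 0.005) times the curve maximum; its level is the
mean of the spanned values. Defaults were chosen so that single planted
pixels of typical intensity do not break a plateau on realistic image
sizes, while the rise phases (which move percent-scale fractions of the
total per step) always do. `cx43_ss` is computed as total minus the
first-plateau level rather than as the difference of two plateau levels,
so it remains defined when the second plateau is truncated by the sweep
limit; when a second plateau exists the sweep records whether it reaches
the total (where the two definitions coincide). The reported
`optimal_radius` is the first radius of the first plateau. A curve with
no detectable plateau flags the record (`no_plateau`); an empty N-Cad
mask yields an all-side-by-side record flagged `empty_ncad`.

## N-Cad internal-reference normalization

Sectioning depth, fiber orientation and staining efficiency scale both
channels of an image roughly multiplicatively. Because N-Cad expression
is stable in aging and failing hearts, the ratio of any quantified Cx43
value to the integrated N-Cad intensity of the same image cancels such
joint gain exactly — an algebraic identity, reported alongside (never
instead of) the raw values. The N-Cad channel is thresholded by the same
two-stage calibration; normalization by N-Cad positive-pixel count
instead of intensity is available (`gj_config(normalize_by = "count")`).

## Z-stacks: layer-by-layer versus maximum projection

A confocal stack is quantified layer by layer — each layer is an
independent image with its own thresholds and its own sweep — and, for
comparison, once more on the maximum-intensity projection of the stack.
The layerwise aggregate sums raw values across layers and normalizes
once by the summed N-Cad (`aggregate = "sum"`), which weights layers by
signal content the way a projection does; averaging per-layer normalized
values is available as `aggregate = "mean_norm"`. Degenerate layers are
excluded from the aggregate with a warning, never silently.

Projection quantification systematically *overestimates* end-to-end and
*underestimates* side-by-side Cx43 whenever in-plane structure moves
across focal planes: the projected N-Cad image is a union over layers,
so Cx43 that is far from N-Cad in its own layer can be covered by
another layer's N-Cad after projection, and repeated signal collapses
from a per-layer sum to a single maximum. The drifting-plaque synthetic
stacks (below) make this a geometric certainty, and the package asserts
the direction of the bias there.

## The synthetic scene generators

No imaging data ship with the package; every algorithm is validated on
generated scenes whose ground truth is exact by construction
(deterministic given a seed; truth intensity sums are computed from the
rendered pixel values over the planted label sets).

**Gap-junction scenes** (`generate_gj_image()`). Six elongated N-Cad
plaques (20×5 px, emulating intercalated discs at 40× magnification) in
a 192×192 field; 150 Cx43 pixels per plaque, split between an
ID-associated pool planted within 3 px of a plaque (including strictly
overlapping and stellate pixels) and a lateralized pool planted 25–31 px
from every plaque pixel; circular nuclei in the blue channel. Foreground
intensities are drawn from N(200, 8), background from N(15, 6), rounded
and clipped to 8 bits; an optional per-image gain rescales all channels.
These distributions were chosen — deliberately, and documented here as a
self-consistency — so that the $J_T$ calibration separates the planted
modes essentially exactly: with sparse foreground and a wide foreground
spread the score's shoulder-seeking behaviour (above) would otherwise
truncate the dim tail of the planted signal and no threshold could
recover the planted sums. The planted separation (25 px) exceeds the
stellate offset (3 px) by far more than the plateau window, which is
what makes the two-plateau read-off well posed. What these scenes do
*not* emulate: point-spread blur, chromatic shift, autofluorescence
texture, intensity-correlated clustering. Passing tests therefore
demonstrate correctness of the algorithmic chain, not robustness to
every optical artifact of real microscopy.

**Drifting-plaque stacks** (`generate_gj_zstack()`). Layers share one
scene in which all Cx43 is stationary while the N-Cad plaques translate
by `drift` (default 14 px) per layer — an idealization of fiber
orientation changing across focal planes, with the ID-associated pool
anchored to the first layer's plaque positions and the lateral pool kept
at least 25 px from *every* layer's plaques. Plaque long axes are drawn
perpendicular to the drift direction (intercalated discs lie across the
fiber axis; the drift runs along it), and drift paths of distinct
plaques are laid out with guaranteed gaps. The drift default matters:
it must exceed the plaque cross-section plus the stellate offset plus
the plateau window (with a rasterization margin), or later layers'
plateau analysis re-absorbs the drifted-away Cx43 into the end-to-end
pool and the projection bias is no longer a geometric consequence.
Intensities are redrawn per layer, so the projection's maximum over
layers also exceeds any single layer's draw on stationary pixels.

**Trichrome scenes** (`generate_mt_image()`). Contiguous blobs of
unstained white space (target share of all pixels) and collagen (target
share of *tissue* pixels, matching the IC definition) over a muscle
background, colored muscle (180, 80, 70), collagen (90, 215, 225), white
(230, 215, 230) with Gaussian noise (sd 6). The palette was chosen by
checking the classification inequalities against the mixture statistics
across the planted-fraction grid, so the default generator is
classifiable by the default rules — again a deliberate, documented
self-consistency; `mt_palette(hard_mode = TRUE)` shifts collagen toward
muscle for robustness probing. Planted fractions returned in the truth
are the actually rendered pixel shares.

## Interstitial collagen classification

Masson's Trichrome stains collagen blue, myoplasm red, nuclei dark;
unstained white space is a sectioning artifact that must not enter the
denominator. Pixels are classified against the image's own per-channel
means and population standard deviations with strict inequalities:

* white: $I_G > \mu_G + 0.9\sigma_G$ and $I_R > \mu_R + 0.9\sigma_R$;
* muscle/nuclei: $I_B < \mu_B + 0.3\sigma_B$ and $I_G < \mu_G - 0.1\sigma_G$;
* collagen: $I_B > \mu_B + 0.9\sigma_B$, $I_R < \mu_R + 0.25\sigma_R$,
  $\mu_G + 0.75\sigma_G < I_G < \mu_G + 2\sigma_G$.

Precedence: white is assigned first (open space must never contribute to
a stain class); muscle and collagen are evaluated on the remaining
pixels; pixels satisfying both are assigned muscle, which avoids
overestimating collagen; everything else is unclassified tissue. The IC
fraction is collagen over tissue, where tissue is all non-white pixels —
unclassified pixels count as tissue, so ambiguous nuclei affect class
counts but not the fraction's denominator choice. The coefficients are
config-overridable because stain batches vary; per-image statistics
provide no correction across sections stained in different batches, so
cross-group comparisons should use same-batch staining.

## Problem sizes and determinism

Validation in the test suite and the acceptance script uses 192×192
single scenes (20 seeds × three lateral fractions), 6-layer 192×192
stacks (10 seeds), 128×128 trichrome images across planted collagen
fractions {0, 0.05, 0.15, 0.30}, and 20-replicate gain-jitter
experiments — sizes at which every recovery margin above holds with
order-of-magnitude headroom while a full run stays in tens of seconds.
All analysis paths are deterministic: identical inputs and configuration
produce byte-identical reports, and all generator randomness is a pure
function of the scene seed.

## Known limitations

* The threshold statistic's shoulder-seeking behaviour on sparse,
  wide-spread foregrounds (discussed above) is inherent to the printed
  formula; `fixed_r` is the practical mitigation on real cohorts.
* Dilation is 2-D within each layer; no volumetric DNCUs across layers.
* No per-cell segmentation or ID-plaque instance counting; quantities
  are field-level intensity sums.
* No stain normalization or color deconvolution for trichrome images.
* Sub-integer dilation radii are not implemented (the sweep is defined
  on integer IPDs).
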