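# gjquant

Automated, operator-independent quantification of two histology readouts
of cardiac remodeling:

1. **Gap-junction abundance and distribution** from connexin-43 (Cx43) /
   N-Cadherin (N-Cad) double-immunostained confocal images. Cx43 couples
   cardiomyocytes electrically; in healthy tissue it sits at
   intercalated discs (IDs, the end-to-end cell junctions) anchored by
   N-Cad, while in aged and diseased hearts part of it redistributes to
   lateral cell borders. `gjquant` splits the Cx43 signal into the
   ID-associated (end-to-end, `cx43_ee`) and lateralized (side-by-side,
   `cx43_ss`) pools and normalizes both to the co-stained N-Cad signal
   as an internal reference.
2. **Interstitial collagen fraction** from Masson's-Trichrome-stained
   bright-field RGB images, by per-image channel-statistics
   thresholding.

It is aimed at groups quantifying gap-junction remodeling or fibrosis in
IHC sections who want a reproducible alternative to manual outlining and
to strict pixel-by-pixel colocalization.

## Method

For each fluorescence channel a positive-staining threshold is
calibrated per image: the initial threshold is placed at the maximum of
the foreground standard-deviation curve (foreground = pixels ≥ t),
fixing the foreground statistics µ_fg and σ_fg; candidate thresholds
round(µ_fg + R·σ_fg) for R ∈ [−3, 3] are then scored with the
between-class statistic

    J_T = P1 · P2 · (µ1 − µ2)² / (σ1² + σ2²)

(P = class pixel counts, µ/σ = class means and population SDs below and
at-or-above the threshold), and the best R defines the optimal
threshold. The quantified measure is the integrated intensity of
positive pixels.

Every positive N-Cad pixel is then dilated into a Euclidean disk of
radius r (in inter-pixel distances, IPD) — a dilated N-Cad unit (DNCU).
Cx43 intensity covered by DNCUs is end-to-end; the rest side-by-side.
Sweeping r = 0…40 gives a non-decreasing coverage curve whose first
plateau level is the end-to-end amount (this includes "stellate" Cx43
that sits a few pixels off the N-Cad plaque and is missed by strict
pixel-by-pixel overlap); total minus first plateau is the side-by-side
amount. Z-stacks are quantified layer by layer (each layer with its own
calibration) and compared against maximum-projection quantification,
which systematically overestimates end-to-end signal when structures
move across focal planes.

Trichrome pixels are classified as unstained white space,
muscle/nuclei, or collagen by strict inequalities on each channel's
per-image mean and SD; the interstitial-collagen fraction is collagen
pixels over tissue (non-white) pixels.

A synthetic scene generator (confocal-like fields, drifting-plaque
Z-stacks, trichrome mosaics) provides exact ground truth for every
algorithm; the package's tests validate the whole chain against it and
against brute-force oracles.

## Worked example

```r
library(gjquant)

# a synthetic field with 20% of Cx43 planted at lateral membranes
scene <- generate_gj_image(gj_scene_spec(seed = 42, lateral_fraction = 0.2))
q <- quantify_image(scene$image, image_id = "demo")
q
#> <gj_quantification 'demo': Cx43 total 180291 (E-E 144240, S-S 36051),
#>  N-Cad 128742, E-E/N-Cad 1.120>
q$sweep
#> <dncu_sweep: total Cx43 180291, 2 plateau(s), ee=144240, ss=36051,
#>  optimal radius 3 IPD>
scene$truth$id_intensity        # planted ID-associated Cx43: 144232
scene$truth$lateral_intensity   # planted lateral Cx43:        36059
```

The two plateaus of the dilation sweep recover the planted split within
0.1%: `cx43_ee` (144240) is the integrated intensity of ID-associated
Cx43, `cx43_ss` (36051) the lateralized pool, and the first plateau
begins at 3 IPD — the planted stellate offset. `cx43_ee_norm` etc. are
the same quantities divided by the image's integrated N-Cad intensity.

```r
mt <- generate_mt_image(collagen_fraction = 0.15, seed = 42)
quantify_collagen(mt$image)
#> <collagen_quantification: 16384 px (3256 white, 11141 muscle,
#>  1966 collagen), IC fraction 0.1498>
```

The recovered interstitial-collagen fraction (0.1498) matches the
planted 0.15: 1966 collagen pixels over 16384 − 3256 tissue pixels.

## Command line

```sh
CLI=$(Rscript -e 'cat(system.file("cli", "gjquant", package = "gjquant"))')
Rscript $CLI synth --kind gj --out scenes/ --seed 1 --n 3
Rscript $CLI gj --input scenes/ --report report.csv
Rscript $CLI collagen --input mt_images/ --report ic.csv
Rscript $CLI stack --input stack.tif --report stack.csv
```

Batch runs write one CSV row per image (per layer plus aggregate and
projection rows in stack mode), continue past corrupt inputs with
per-item logged failures, and are byte-reproducible. Defaults can be
overridden with `--config config.yaml` or flags (`--max-radius`,
`--plateau-tol`, `--fixed-r`, …).

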