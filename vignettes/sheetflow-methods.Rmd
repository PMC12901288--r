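---
title: "Quantifying collective sheet migration with sheetflow: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying collective sheet migration with sheetflow}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sheetflow)
```

# The measurement problem

In a scratch-wound (wound-healing) assay, a cell-free gap is cut into a
confluent monolayer and the two flanking cell sheets are imaged for about a
day. The biological questions — does the sheet advance, how fast, and how
mechanically coherent is its motion — require a velocity field of the bulk
sheet, not just the position of its edge. Brightfield movies carry no
segmentable cell outlines, but they carry texture, and texture is enough for
particle image velocimetry (PIV): the displacement of a small interrogation
window between consecutive frames is the location of the peak of the
cross-correlation between the two windows.

sheetflow implements that pipeline end to end:

1. **PIV engine** — multi-pass FFT cross-correlation with subpixel peak
   fitting and normalized-median-test vector validation (`run_piv()`).
2. **Wound-centric metrics** — signed closure velocity, time-averaged
   "summation maps", distributions of summed displacement and mean closure
   speed, and automated wound-area closure curves (`summation_map()`,
   `displacement_distribution()`, `closure_curve()`).
3. **Kymograph features** — velocity and strain kymographs reduced to
   chunk-sum feature vectors, embedded by PCA and compared across
   conditions with a permutation test (`velocity_kymograph()`,
   `strain_kymograph()`, `chunk_features()`, `pca_embed()`,
   `cluster_separation()`).
4. **Synthetic ground truth** — a seed-deterministic movie generator whose
   prescribed velocity field is known exactly at every grid node
   (`generate_movie()`), used by the test suite as the oracle for all of
   the above.

# The PIV model

Frames are divided into square interrogation windows placed at top-left
offsets $i \cdot s$, $s = \mathrm{round}(w(1 - \text{overlap}))$; the number
of windows along a dimension of size $D$ is
$\lfloor (D - w)/s \rfloor + 1$. With the default 24 px windows at 50%
overlap, a 600 × 800 px frame yields a 49 × 65 vector grid.

Each window pair is cross-correlated by FFT with zero padding to $2w$, after
subtracting the window means and normalizing by the product of window norms.
Two numerical details matter on smooth cellular texture:

* **Overlap (taper) correction.** The zero-padded estimate at displacement
  $d$ only sums over $w - |d|$ overlapping pixels per axis, which multiplies
  the surface by a triangular taper. Left in place, the taper tilts the
  local peak shape and biases any subpixel fit toward zero by up to ~0.3 px
  at half-integer displacements. sheetflow divides the taper out, clamping
  the correction at half-window overlap so distant, noise-dominated lags are
  not amplified into spurious peaks.
* **Subpixel estimator.** The classical axis-wise three-point Gaussian fit,
  $\delta = (\ln c_- - \ln c_+) / (2\ln c_- - 4\ln c_0 + 2\ln c_+)$, is
  tuned to narrow particle-image peaks. Cell-sheet texture is smooth, its
  correlation peak is broad, and the realization noise of a single 24 px
  window then leaves the three-point fit with ~0.2 px of scatter. The
  default estimator (`subpixel = "gaussian2d"`) therefore fits a 2-D
  Gaussian (log-paraboloid, ordinary least squares) over the 5 × 5 peak
  neighbourhood, which averages that noise down to below 0.1 px RMS over
  the tested translation range; the three-point Gaussian and a pure
  parabolic fit remain available and serve as the fallback near surface
  borders or non-positive samples.

The two-pass scheme follows the two stated window sizes: a 48 px pass,
validated, predicts integer window offsets (bilinear interpolation, rounded)
for the 24 px refinement pass. No window deformation is attempted.

**Vector validation** is the normalized median test on 3 × 3
neighbourhoods, per component: residual
$r = |d - \mathrm{med}| / (\mathrm{med}(|n_i - \mathrm{med}|) + \epsilon)$
with defaults $\epsilon = 0.1$ px and threshold 2.0; failing vectors (and
vectors already rejected by the peak-to-second-peak ratio, default minimum
1.2, with the second peak sought outside a radius-2 neighbourhood of the
first) are replaced by the median of their passing neighbours and flagged
in a `replaced` mask. Downstream statistics use measured-or-replaced
vectors and never zero-fill gaps, which would bias sheets toward apparent
immotility.

# Wound-centric conventions

The wound is a vertical band; closure is horizontal. All signed summaries
fold the sign of the horizontal velocity $u$ so that positive means motion
toward the wound on both sides: $s = u \cdot \mathrm{sign}(x_c - x)$, zero
exactly at the centre column. The *summation map* is the per-grid-point time
mean of $s$ (the name follows the field's usage of summing PIV frames and
dividing by their number), in µm/min. Summed displacement per grid point is
defined as that time mean multiplied by total elapsed time, so the identity
*summed displacement = mean speed × time* holds exactly even where some
frame pairs were invalid. Histograms use 41 bins symmetric about zero with
range set by the 99th percentile of absolute values.

Wound area is segmented automatically: the local variance map (sliding
window, default side equal to the refinement window) is thresholded by
Otsu's method, and the wound is the largest connected low-variance component
intersecting the configured band — *provided* its mean local variance is at
most half that of the high-variance class. That contrast requirement is what
distinguishes a genuine wound from the low tail of homogeneous texture; a
frame failing it is treated as closed (area 0, flagged) inside
`closure_curve()` and as an error for a single standalone call, where a
manual mask can be supplied instead. Closure is expressed as
$100 (1 - A_t/A_0)$: 0% at the first frame, 100% at full closure, negative
when the wound expands. Segmentation accuracy degrades when the remaining
gap narrows below roughly three variance windows (~70 px at defaults); the
closure curve should be sampled accordingly, and the endpoint is still
caught exactly by the closed-frame convention.

# Kymographs, chunk features, and clustering

A kymograph entry at (distance $d$, time $t$) is the **median** over grid
rows of the signed closure velocity (or of the strain magnitude) in grid
column $d$ at frame pair $t$; the median is robust to residual outlier
vectors. By default mirror columns equidistant from the two vertical frame
edges are averaged after sign folding (`fold = TRUE`), matching a wound at
the frame centre; entries from columns with no usable vector are linearly
interpolated along time and flagged.

"Strain" here needs care. The package exposes two velocity-gradient
summaries: the horizontal normal strain rate $\partial u / \partial x$
(`mode = "strain"`, the default for `strain_field()`) and the curl
$\partial v / \partial x - \partial u / \partial y$
(`mode = "vorticity"`). Monolayer shear — rows of the sheet sliding past
one another, i.e. a vertical gradient of horizontal velocity — is invisible
to $\partial u / \partial x$ but captured by the vorticity mode, which is
why the pipeline and the phenotype-clustering workflow compute strain
kymographs with `mode = "vorticity"`. Both derivatives use central
differences on the PIV grid (one-sided at edges), in 1/min after
calibration.

Each kymograph is reduced to a feature vector by splitting its time axis
into `n_chunks` contiguous blocks (default 8; earlier blocks take the
remainder) and summing all entries per block, so the feature vector
conserves the kymograph total exactly. Feature vectors are embedded with
PCA (SVD on centred columns; unit scaling optional and off by default since
chunk sums share units; a deterministic sign convention makes the
largest-magnitude loading of each component positive). Group separation is
the mean silhouette of the condition labels on the first two scores, with a
permutation p-value under a fixed, recorded seed:
$p = (1 + \#\{s_\pi \ge s\}) / (n_\pi + 1)$.

# The synthetic generator: what it emulates, and what it does not

`generate_movie()` renders two textured sheets flanking a low-texture wound
band. The texture is white noise low-pass filtered with a periodic Gaussian
kernel whose scale makes the autocorrelation fall to $1/e$ at
`texture_corr_len` pixels; it reproduces the *correlation statistics* PIV
needs, not cell morphology, lamellipodia, proliferation, or intensity drift.
Sheets are advected by periodic subpixel Fourier shifts of a per-row
displacement field — rigid per sheet plus a shear term — so the prescribed
velocity is honoured exactly and is returned as ground truth on the PIV
grid; the wound edges advance with the sheets, so the band narrows at the
closure speed. Consequences for interpretation: passing tests demonstrate
that the *measurement chain* is accurate on motion of this kind, not that
real astrocyte movies are free of the texture evolution (cell shape change,
division, focus drift) that degrades real correlations.

Default study conditions, chosen once: 600 × 800 px frames; 30 frames at
48 min/frame (a 24 h recording); 1.3 µm/px; wound half-width 60 px. Four
presets encode the canonical migratory phenotypes: `forward` and `reversed`
at ±0.065 µm/min (≈ 94 µm of advance per sheet over 24 h — the scale at
which a ~200 µm scratch closes within a day, or visibly expands),
`immotile` at zero with zero jitter (so frames differ only by pixel noise),
and `sheared` with zero net closure and a vertical gradient of horizontal
velocity of 5 × 10⁻⁴ /min (±0.1 µm/min at the frame edges — large enough to
dominate the PIV-derivative noise floor of ≈ 1 × 10⁻⁴ /min, small enough to
respect the quarter-window displacement budget). Per-frame speed jitter is
0.01 µm/min for the motile presets; pixel noise is 0.02 intensity units
against a texture amplitude of 0.18; sheet-to-wound texture variance
contrast is 8 (the segmentation requires ≥ 2). Movies are written as 16-bit
multi-page TIFFs after per-movie min-max scaling, a common microscopy
dialect; PIV is invariant to that affine rescaling.

A note on scale: the phenotype-recovery checks in the test suite run at
300 × 400 px (grids of 24 × 32 vectors) with 30 frames and 6–10 seeds per
preset, which keeps the full suite at desk scale while leaving every effect
far above the measurement noise floor.

# Numerical and design choices

* **Seeds.** One user seed fans out to independent streams (left/right/wound
  textures, speed jitter, pixel noise, per-movie sub-seeds in the pipeline)
  through a multiplicative congruential map, so consecutive seeds do not
  share textures and every artifact is bit-reproducible.
* **Grid/centre convention.** Row = y downward, column = x rightward,
  origin at the top-left; window centres at $i s + (w+1)/2$ in 1-based
  pixel units. Velocities stay in px/frame internally; every user-facing
  summary converts to µm and µm/min via the calibration carried by the
  series.
* **Frame interval.** The recording interval of a 24 h movie is
  configuration, not constant: `min_per_frame` defaults to 48 (30 frames /
  24 h) and a `stride` option measures displacement across skipped frames
  (renormalized per frame) when inter-frame motion is too small.
* **Chunking axis.** Chunks split the *time* axis and span the full
  distance axis: the feature vector is a coarse temporal signature of the
  migration pattern, which is the property the clustering is meant to
  compare. The worked 32 × 144 → 8-chunk example is axis-ambiguous;
  time-chunking is the choice here and `n_chunks` is configurable.
* **Degenerate inputs.** Zero-variance windows are flagged invalid rather
  than raising; correlation peaks on the surface border return the integer
  displacement flagged low-confidence; an all-invalid field aborts with the
  frame pair named; identical points in a silhouette evaluate to 0 rather
  than 0/0.
* **Wound-centre column.** The signed-velocity fold sets $s = 0$ exactly at
  the centre column. Whether the centre column should instead inherit a
  side is unknowable from a centred wound; the zero convention is neutral
  and affects a single grid column at most.

# Known limitations

* Brightfield texture evolution in real movies (shape change, division,
  debris) is not emulated; real-data accuracy will be worse than the
  synthetic benchmarks, particularly near the advancing edge.
* No window deformation or optical-flow refinement: strong velocity
  gradients within one window bias the estimate toward the window mean.
* Wound segmentation assumes a variance contrast of at least 2 between
  sheet and wound and a roughly vertical band; irregular or diagonal wounds
  need a manual mask.
* The PCA/silhouette machinery assumes each movie is one independent
  observation; fields from the same dish are not modelled hierarchically.
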