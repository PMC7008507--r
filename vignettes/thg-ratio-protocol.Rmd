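---
title: "Measuring the intrinsic cytoplasm-to-collagen THG brightness ratio: model, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring the intrinsic cytoplasm-to-collagen THG brightness ratio}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(thgratio)
```

## The measurement model

Harmonic generation microscopy records two co-registered signals per depth:
second-harmonic generation (SHG), produced in skin almost exclusively by
dermal collagen, and third-harmonic generation (THG), produced by lipid and
protein interfaces and enhanced by orders of magnitude wherever melanin is
present. In a vitiligo lesion the basal keratinocytes are melanin-free, so
their cytoplasmic THG level is the intrinsic keratinocyte baseline. The
package estimates, at the dermal–epidermal junction (DEJ), the ratio

$$R = \frac{\overline{THG}_{\mathrm{cytoplasm}} - N}
          {\overline{THG}_{\mathrm{collagen}} - N}$$

with $N$ the photomultiplier noise floor (mean THG grayscale of uniformly
dark regions). Its assumptions, each reflected in a phase of the protocol:

* **A dark-noise offset is additive and spatially uniform.** The detector
  contributes a random grayscale with stable mean everywhere, so one deep,
  signal-free region estimates $N$ for the whole stack. Subtracting $N$
  from both masked means makes $R$ invariant to detector gain and offset
  (tested as an algebraic property).
* **Vignetting multiplies both channels equally.** Scanning optics dim the
  field edge. Because cytoplasm and collagen are measured inside the same
  thresholded ROI and the dimming is a common gain, its effect cancels in
  the ratio to first order.
* **Collagen and cytoplasm can be separated per frame.** Collagen is
  SHG-bright and tubular; cytoplasm is THG-bright with dark nuclei.
  Segmentation is per-frame (2-D), as the underlying protocol's was.
* **One noise value per stack.** The formula uses a single $N$ for all
  subimages of a stack, taken at the deep noise frame (see below).

A stack's ratio is the unweighted mean over its qualified subimages (at
least three), and a cohort is reported as mean ± SEM (sample standard
deviation over $\sqrt{n}$, $n$ = number of included stacks, not patients).

## The five phases and their parameters

All numeric constants live in one place, `run_config()`:

| parameter | default | units | role and rationale |
|---|---|---|---|
| `roi_threshold` | 1600 | grayscale | ROI selection on THG and collagen coverage/segmentation on SHG. 1600/150 ≈ 10.7 ≥ the desired SNR of 10 (`snr_at_threshold()`). Applied literally to both channels; `roi_method = "otsu"` derives it from the histogram instead. |
| `shg_coverage_min` | 0.25 | fraction | screening rule 1; **strict** (> 0.25), a coverage of exactly 25% fails. |
| `min_cells` | 10 | cells | screening rule 3; **inclusive** (≥ 10). |
| `coherence_floor` | 0.3 | – | operationalises "fibers clear enough to see their orientation" as structure-tensor coherence of the segmented collagen; visual in the original protocol, so configurable. |
| `min_qualified_subimages` | 3 | subimages | a stack enters the cohort only with ≥ 3 qualified subimages. |
| `melanin_ratio_cutoff` | 1.6 | – | phototype-I skin reaches ≈ 1.6, so a higher ratio implies melanin; **strict** (> 1.6 excluded, 1.6 itself included), used both as preview case 3 and as the inspecting-phase rule. |
| `noise_depth_index` | 80 | frame | the "80th subimage" (1-based, counting from the surface; ≈ 144 µm at 1.8 µm/step), clamped to the deepest frame with a logged fallback. |
| `focus_floor` | 0.055 | – | preview blur admission floor on `focus_score()` (variance of the discrete Laplacian / squared mean). Calibrated once: sharp cohort frames score ≈ 0.6, σ = 8 px blurred frames ≈ 0.030, and the sparsest-edge sharp scene (six giant cells) ≈ 0.09–0.10; 0.055 is the geometric mean of the two clusters it must separate. |
| `cell_diameter_px` | 21 | px | expected basal-cell diameter (12 µm at 0.576 µm/px); sets the watershed seed separation (half this value). |

Segmentation internals (arguments of `segment_collagen()` /
`segment_cells()`): minimum component sizes of 30 px (fiber), 100 px
(cell) and 15 px (nucleus) at the 295 µm / 512 px scale; a ridge-filter
scale of 2 px; a pre-smoothing σ of 1 px. The ridge filter is treated as a
fiber-*core* detector: its Otsu-cut response is dilated back over the
suprathreshold set to recover full tube width, and the result is
re-intersected with the suprathreshold set so no sub-threshold pixel is
ever labeled collagen (a hard invariant checked in the tests).

Manual steps of the original protocol (removing non-collagen regions,
falling back to hand-drawn cytoplasm when fewer than 10 cells survive) are
replaced by declarative region lists in the config, making them
reproducible and testable. Exclusion regions are subtracted from the
masks; the per-frame report records `auto` vs `manual` provenance. The
pipeline additionally subtracts the segmented collagen from the cytoplasm
mask — the automatic counterpart of manually removing "fiber regions" from
the cell segmentation.

## The synthetic stack generator

`generate_stack()` renders the world the analysis assumes, not skin
optics. Per stack it builds one basal-cell mosaic (a seeded Voronoi
partition with 2 px dark membrane lines, one dark elliptical nucleus per
cell at 0.4–0.6 of the cell diameter, optional bright supranuclear melanin
caps) and one fiber set (constant-intensity tubes along random walks whose
headings follow a von Mises-like distribution, sampled as a wrapped normal
with sd $1/\sqrt{\kappa}$ — adequate for the concentrated κ = 8 default).
Frames above the DEJ show the mosaic (keratinocyte columns are vertically
coherent), the DEJ window shows mosaic plus fibers (fibers take precedence
so truth masks stay disjoint), deeper frames show fibers under exponential
depth attenuation (1/e length 15 µm). A cosine vignette multiplies signal
but not noise; independent Gaussian noise with mean 150 and sd 50 is added
everywhere and values are clipped to the 14-bit range.

Deliberate deviations from a literal reading of the scene description,
made so the generator's own calibration contract (truth-mask means within
1% of the configured class means) is exactly satisfiable:

* fibers are **hard tubes**, not Gaussian-profiled ones — a soft profile
  has no natural mask support, so its truth-masked mean could never equal
  the configured plateau value;
* the vignette radius uses the **sup-norm** (square falloff), so the flat
  core is rectangular and the threshold-derived rectangular ROI has a
  clean referent;
* truth masks are **restricted to the unvignetted core** and to
  unattenuated depths: they mark pixels rendered at nominal intensity.
  Scene content in the falloff ring is rendered but unlabeled, and a
  separate `background_mask` marks zero-signal (noise-only) voxels.

Intensity calibration: the protocol's published constants fix the noise
floor (≈ 150), the threshold (1600) and the final ratio (≈ 1.106), but not
absolute vitiligo cytoplasm or collagen THG levels. The defaults use
cytoplasm 1809 and collagen THG 1650 — consistent with all three
constraints, with both classes safely above the 1600 threshold, and giving
a true ratio of (1809−150)/(1650−150) = 1.106. Collagen SHG is 3000
(clearly suprathreshold for coverage), nuclei 450, melanin caps 6000
(> 2 × even the brightened melanin-preset cytoplasm median, as the
bright-piece detector requires). The default fiber density (40
tubes/frame) puts SHG coverage at 0.34–0.45 of the ROI across seeds — a
qualified preset must clear the strict 25% screen by a margin, and the
`sparse_collagen` preset (7 tubes, ≈ 10%) must fail it. Cell count 120
per 256 px frame gives 51–77 segmentable cells in the ROI, comfortably
above the 10-cell screen; `few_cells` uses 6.

What the generator does **not** emulate — and hence what a green test does
not establish: optical point-spread functions and resolution anisotropy,
Poisson photon statistics (noise is Gaussian and signal-independent),
scattering-induced depth-dependent blur, melanocyte dendrites, hair
follicles, capillaries and other non-collagen SHG/THG sources, patient
motion other than a global blur, and any correlation between channels
beyond geometry. Green acceptance tests establish that the pipeline
*recovers the parameters of this stated world*; they are not evidence
about real patient images.

## Numerical choices

* **Indexing** is 1-based everywhere (R convention); "the 80th subimage"
  is depth index 80. For shorter stacks the deepest frame is used and the
  fallback logged.
* **Otsu's threshold** uses a 256-bin histogram between the observed min
  and max; degenerate (constant) inputs return that constant, and
  near-constant frames (range < 10⁻⁶ of the mean) segment to zero cells
  rather than amplifying float jitter.
* **Connected components, chamfer 3–4 distance transform and seeded
  priority-flood watershed** are compiled (Rcpp). The watershed priority
  queue breaks elevation ties FIFO, making labels deterministic; seeds are
  greedy distance-transform maxima (strongest first) with a minimum
  separation of half the configured cell diameter.
* **Nucleus detection** is per cell, relative to the cell's own Otsu cut —
  a global dark threshold would fail under vignetting. Candidate basins
  are the compact holes closed during foreground filling (interior
  distance ≥ 2.5 px), which distinguishes nuclei from thin membrane
  fragments; border-touching background is never treated as a hole.
* **Cell drop rules**: components touching the ROI border are judged on
  their thick core (distance > 2.5 px), so a thin bright fiber corridor
  reaching the border does not disqualify an interior cell.
* **Boundary semantics** follow the protocol wording exactly: coverage
  strict (> 25%), cell count inclusive (≥ 10), qualified subimages ≥ 3,
  inspection strict (> 1.6 excluded).
* **Serialization** is baseline TIFF 6.0 (16-bit unsigned, uncompressed,
  little-endian, one strip per page), written and parsed natively; 14-bit
  data lives in 16-bit containers with the declared `bit_depth` governing
  the validity range. Metadata is a key=value text block in the first
  page's ImageDescription with a plain-text sidecar fallback. Round trips
  are bit-exact and the tests cross-check the format against an
  independent reader.

## Open design points, resolved

* The published threshold 1600 is stated for THG at ROI selection and for
  SHG at coverage screening; both are followed literally with one shared
  constant (configurable separately from the generator's intensities).
* Whether excluded regions should be removed from the collagen mask or
  from the ROI is left to the caller: exclusions apply to masks, and a
  smaller ROI can equally be passed in.
* "Bottom 80th subimage" is read as the 80th frame from the surface; both
  readings land in uniformly dark dermis and differ by one 1.8 µm step.
* The preview-phase provisional ratio uses threshold-proxy masks
  (THG-bright & SHG-dark as cytoplasm; SHG-bright as collagen) without
  exclusions — a deliberately coarse pre-filter; borderline stacks are
  settled by the full processing phase and the 1.6 inspection rule.

## Known limitations

The segmentation operators are replacements with the same contracts as the
unpublished programs used originally; their acceptance surface is
ground-truth recovery on synthetic scenes, not replication of the original
implementations. The focus metric is edge-density dependent: a sharp scene
with very few cells scores lower than a normal one, which is why the floor
is calibrated against the sparsest sharp preset. All segmentation is 2-D
per frame; no patient-level mixed-effects aggregation is attempted (stacks,
not patients, are the cohort unit).
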